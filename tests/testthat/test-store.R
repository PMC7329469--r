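trio_vcf_path <- function(gts, extra_lines = list()) {
  write_vcf_fixture(c(list(snv_line("1", 100, "A", "T", gts)), extra_lines),
                    samples = c("S1", "S2", "S3"),
                    path = withr::local_tempfile(fileext = ".vcf",
                                                 .local_envir = parent.frame()))
}

test_that("a family contributes one observation regardless of carrier count", {
  path <- trio_vcf_path(c("0/1:99", "0/1:99", "0/1:99"))
  store <- store_new()
  rep <- load_case(store, read_ped(trio_ped()), snv_vcf = read_vcf(path))
  expect_equal(rep$n_loaded_snv, 1L)
  doc <- get_observation(store, "1_100_A_T")
  expect_equal(doc$obs_count, 1L)
  expect_equal(doc$hom_count, 0L)
  expect_equal(doc$case_ids, "FAM1")
})

test_that("the homozygote counter tracks any passing 1/1 individual", {
  store <- store_new()
  vcf <- singleton_vcf(data.frame(chrom = "1", pos = 100, ref = "A", alt = "T",
                                  gt = "1/1", gq = 99), "P1")
  load_case(store, singleton_ped("C1", "P1"), snv_vcf = vcf)
  doc <- get_observation(store, "1_100_A_T")
  expect_equal(doc$obs_count, 1L)
  expect_equal(doc$hom_count, 1L)

  # het carrier in a second case: obs grows, hom does not
  vcf2 <- singleton_vcf(data.frame(chrom = "1", pos = 100, ref = "A",
                                   alt = "T", gt = "0/1", gq = 99), "P2")
  load_case(store, singleton_ped("C2", "P2"), snv_vcf = vcf2)
  doc <- get_observation(store, "1_100_A_T")
  expect_equal(doc$obs_count, 2L)
  expect_equal(doc$hom_count, 1L)
  expect_equal(doc$case_ids, c("C1", "C2"))
})

test_that("the GQ gate is strict, defaults to 20 and is disabled at 0", {
  rec <- data.frame(chrom = "1", pos = c(100, 200, 300), ref = "A", alt = "T",
                    gt = "0/1", gq = c(15L, 20L, 21L))
  make <- function() singleton_vcf(rec, "P1")

  store <- store_new()
  rep <- load_case(store, singleton_ped("C1", "P1"), snv_vcf = make())
  expect_equal(rep$n_loaded_snv, 1L) # only GQ 21 passes a threshold of 20
  expect_equal(rep$n_filtered_gq, 2L)
  expect_null(get_observation(store, "1_100_A_T"))
  expect_null(get_observation(store, "1_200_A_T"))
  expect_equal(get_observation(store, "1_300_A_T")$obs_count, 1L)

  store0 <- store_new()
  rep0 <- load_case(store0, singleton_ped("C1", "P1"), snv_vcf = make(),
                    gq_threshold = 0)
  expect_equal(rep0$n_loaded_snv, 3L)
  expect_equal(rep0$n_filtered_gq, 0L)
})

test_that("a missing GQ passes no positive threshold but is loaded at threshold 0", {
  fix <- cbind(CHROM = "1", POS = "100", ID = ".", REF = "A", ALT = "T",
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gtm <- cbind("GT", "0/1")
  colnames(gtm) <- c("FORMAT", "P1")
  vcf <- varobs:::new_vcf_data(character(), fix, gtm)

  store <- store_new()
  rep <- load_case(store, singleton_ped("C1", "P1"), snv_vcf = vcf)
  expect_equal(rep$n_loaded_snv, 0L)
  expect_equal(rep$n_filtered_gq, 1L)

  store0 <- store_new()
  rep0 <- load_case(store0, singleton_ped("C1", "P1"), snv_vcf = vcf,
                    gq_threshold = 0)
  expect_equal(rep0$n_loaded_snv, 1L)
})

test_that("reference and no-call genotypes never create an observation", {
  path <- trio_vcf_path(c("0/0:99", "./.", "0/0:88"))
  store <- store_new()
  rep <- load_case(store, read_ped(trio_ped()), snv_vcf = read_vcf(path))
  expect_equal(rep$n_loaded_snv, 0L)
  expect_equal(rep$n_rejected, 1L)
  expect_null(get_observation(store, "1_100_A_T"))
})

test_that("duplicate case loads are refused atomically", {
  path <- trio_vcf_path(c("0/1:99", "0/0:99", "0/0:99"))
  store <- store_new()
  load_case(store, read_ped(trio_ped()), snv_vcf = read_vcf(path))
  before <- dump_lines(store)
  expect_error(load_case(store, read_ped(trio_ped()),
                         snv_vcf = read_vcf(path)),
               "already exists")
  expect_identical(dump_lines(store), before)
  expect_equal(store_n_cases(store), 1L)
})

test_that("pedigree individuals absent from the VCF are an error naming them", {
  path <- write_vcf_fixture(list(snv_line("1", 100, "A", "T", "0/1:99")),
                            samples = "OTHER")
  store <- store_new()
  expect_error(load_case(store, singleton_ped("C1", "P1"),
                         snv_vcf = read_vcf(path)),
               "P1")
  expect_equal(store_n_cases(store), 0L)
})

test_that("load then delete restores the previous store state exactly", {
  coh <- generate_cohort(n_cases = 4, n_common_snv = 30, n_private_snv = 5,
                         n_recurrent_sv = 4, n_private_sv = 2, seed = 8)
  store <- store_new()
  a <- coh$cases[[coh$case_ids[1]]]
  b <- coh$cases[[coh$case_ids[2]]]
  load_case(store, b$ped, snv_vcf = b$snv, sv_vcf = b$sv)
  before <- dump_lines(store)
  load_case(store, a$ped, snv_vcf = a$snv, sv_vcf = a$sv)
  expect_false(identical(dump_lines(store), before))
  delete_case(store, coh$case_ids[1])
  expect_identical(dump_lines(store), before)

  # load A, load B, delete A equals a load-B-only store
  s2 <- store_new()
  load_case(s2, a$ped, snv_vcf = a$snv, sv_vcf = a$sv)
  load_case(s2, b$ped, snv_vcf = b$snv, sv_vcf = b$sv)
  delete_case(s2, coh$case_ids[1])
  s3 <- store_new()
  load_case(s3, b$ped, snv_vcf = b$snv, sv_vcf = b$sv)
  # cluster ids depend on creation history, so compare cluster geometry
  ct2 <- cluster_table(s2)[, -(1:2)]
  ct3 <- cluster_table(s3)[, -(1:2)]
  o2 <- do.call(order, ct2)
  o3 <- do.call(order, ct3)
  expect_equal(ct2[o2, ], ct3[o3, ], ignore_attr = TRUE)
  keys <- sort(ls(s3$snv))
  expect_identical(sort(ls(s2$snv)), keys)
  for (k in keys) expect_equal(s2$snv[[k]], s3$snv[[k]])
})

test_that("deleting an absent case or from an empty store errors", {
  store <- store_new()
  expect_error(delete_case(store, "NOPE"), "not in the store")
})

test_that("deleting the sole contributor of a cluster removes the cluster", {
  store <- store_new()
  sv <- sv_row("DEL", "1", 10000, pos_b = 50000)
  vcf <- singleton_vcf(data.frame(chrom = "1", pos = 10000, ref = "N",
                                  alt = "<DEL>", info = "SVTYPE=DEL;END=50000",
                                  gt = "0/1", gq = 99), "P1", mode = "sv")
  load_case(store, singleton_ped("C1", "P1"), sv_vcf = vcf)
  expect_equal(nrow(cluster_table(store)), 1L)
  delete_case(store, "C1")
  expect_equal(nrow(cluster_table(store)), 0L)
  expect_null(match_cluster(store, sv))
  expect_equal(length(ls(store$clusters)), 0L)
})

test_that("observation counts are conserved and order-invariant on the SNV side", {
  coh <- generate_cohort(n_cases = 8, n_common_snv = 60, n_private_snv = 6,
                         n_recurrent_sv = 0, n_private_sv = 0, seed = 13)
  orders <- list(coh$case_ids, rev(coh$case_ids),
                 coh$case_ids[c(5, 2, 8, 1, 7, 3, 6, 4)])
  dumps <- lapply(orders, function(ord) {
    store <- store_new()
    total_expected <- 0L
    for (cid in ord) {
      cs <- coh$cases[[cid]]
      rep <- load_case(store, cs$ped, snv_vcf = cs$snv)
      total_expected <- total_expected + rep$n_loaded_snv
    }
    keys <- ls(store$snv)
    stats <- vapply(keys, function(k) {
      d <- store$snv[[k]]
      c(d$obs_count, d$hom_count, length(d$case_ids))
    }, numeric(3))
    # conservation: total observations equal the sum of loaded lines
    expect_equal(sum(stats[1, ]), total_expected)
    # per-document invariants
    expect_true(all(stats[1, ] == stats[3, ]))
    expect_true(all(stats[2, ] <= stats[1, ]))
    expect_true(all(stats[1, ] <= store_n_cases(store)))
    paste(dump_lines(store), collapse = "\n")
  })
  norm <- function(x) gsub('"vcf_paths":\\[[^]]*\\]', "", x)
  expect_identical(norm(dumps[[1]]), norm(dumps[[2]]))
  expect_identical(norm(dumps[[1]]), norm(dumps[[3]]))
})

test_that("store dump and restore round-trips bytes and future behaviour", {
  coh <- generate_cohort(n_cases = 5, n_common_snv = 40, n_private_snv = 4,
                         n_recurrent_sv = 5, n_private_sv = 2, seed = 21)
  store <- build_store_from_cohort(coh, coh$case_ids[1:4])
  d <- withr::local_tempdir()
  store_dump(store, d)
  restored <- store_restore(d)
  expect_identical(dump_lines(restored), dump_lines(store))

  # the restored store behaves identically on the next insertion
  cs <- coh$cases[[coh$case_ids[5]]]
  r1 <- load_case(store, cs$ped, snv_vcf = cs$snv, sv_vcf = cs$sv)
  r2 <- load_case(restored, cs$ped, snv_vcf = cs$snv, sv_vcf = cs$sv)
  expect_equal(unclass(r1), unclass(r2))
  expect_identical(dump_lines(restored), dump_lines(store))
})
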
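test_that("a minimal well-formed SNV line parses with category and GQ", {
  path <- write_vcf_fixture(list(
    snv_line("1", 100, "A", "T", c("0/1:99", "0/0:30")),
    snv_line("1", 200, "GA", "G", c("1/1:80", "./."))
  ), samples = c("S1", "S2"))
  vcf <- read_vcf(path)
  expect_s3_class(vcf, "vcf_data")
  expect_equal(vcf$n, 2L)
  expect_equal(vcf$chrom, c("1", "1"))
  expect_equal(vcf$pos, c(100L, 200L))
  expect_equal(vcf$ref, c("A", "GA"))
  expect_equal(vcf$alt, c("T", "G"))
  expect_equal(vcf$category, c("SNV", "INDEL"))
  expect_equal(vcf$samples, c("S1", "S2"))
  expect_equal(vcf$gq[1, ], c(S1 = 99L, S2 = 30L))
  expect_true(vcf$carrier[1, "S1"])
  expect_false(vcf$carrier[1, "S2"])
  expect_true(vcf$homalt[2, "S1"])
  expect_true(vcf$gt_missing[2, "S2"])
  expect_true(is.na(vcf$gq[2, "S2"]))
})

test_that("multi-allelic lines are rejected naming the position, or skipped on request", {
  path <- write_vcf_fixture(list(
    snv_line("1", 100, "A", "T", "0/1:99"),
    snv_line("1", 500, "A", "T,G", "0/1:99")
  ), samples = "S1")
  expect_error(read_vcf(path), "not decomposed.*1:500")
  expect_warning(vcf <- read_vcf(path, skip_bad_records = TRUE),
                 "multi-allelic")
  expect_equal(vcf$n, 1L)
  expect_equal(vcf$pos, 100L)
})

test_that("break-end ALT is preserved verbatim and parsed as the reference parser does", {
  path <- write_vcf_fixture(list(
    sv_line("1", 321680, "N[2:321681[", "SVTYPE=BND", "0/1:60", id = "bnd_1"),
    sv_line("2", 321681, "]1:321680]N", "SVTYPE=BND", "0/1:60", id = "bnd_2"),
    sv_line("2", 400000, "<DEL>", "SVTYPE=DEL;END=450000", "0/1:60")
  ))
  vcf <- read_vcf(path)
  expect_equal(vcf$category, c("SV", "SV", "SV"))
  expect_equal(vcf$alt[1], "N[2:321681[")

  skip_if_not_installed("VariantAnnotation")
  ref <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(ref)
  expect_equal(vcf$chrom, as.character(GenomicRanges::seqnames(rr)))
  expect_equal(vcf$pos, BiocGenerics::start(rr))
  expect_equal(vcf$alt,
               vapply(VariantAnnotation::alt(ref), as.character, character(1)))
  expect_equal(vcf$ref, as.character(VariantAnnotation::ref(ref)))
})

test_that("snv mode refuses SV records; sv mode forces SV categories", {
  path <- write_vcf_fixture(list(
    snv_line("1", 100, "A", "T", "0/1:99"),
    sv_line("1", 5000, "<DEL>", "SVTYPE=DEL;END=9000", "0/1:60")
  ), samples = "S1")
  expect_error(read_vcf(path, mode = "snv"), "SV record")
  expect_equal(read_vcf(path, mode = "sv")$category, c("SV", "SV"))
  expect_equal(read_vcf(path, mode = "auto")$category, c("SNV", "SV"))
})

test_that("PED parsing handles trios, singletons and error cases", {
  trio <- read_ped(trio_ped())
  expect_equal(trio$case_id, "FAM1")
  expect_equal(nrow(trio$individuals), 3L)
  expect_equal(trio$individuals$father_id[1], "S2")
  expect_equal(trio$individuals$mother_id[1], "S3")
  expect_true(trio$individuals$affected[1])

  single <- read_ped(write_ped_fixture(list(c("F2", "P1", "0", "0", "2", "2"))))
  expect_equal(nrow(single$individuals), 1L)
  expect_true(is.na(single$individuals$father_id))

  mixed <- write_ped_fixture(list(c("FA", "X1", "0", "0", "1", "1"),
                                  c("FB", "X2", "0", "0", "1", "1")))
  expect_error(read_ped(mixed), "FA.*FB")
  expect_equal(read_ped(mixed, case_id = "OVERRIDE")$case_id, "OVERRIDE")

  expect_error(read_ped(write_ped_fixture(list(c("F", "X", "0", "0", "1")))),
               "fewer than 6")
  expect_error(read_ped(write_ped_fixture(list(
    c("F", "X", "0", "0", "1", "1"), c("F", "X", "0", "0", "2", "1")))),
    "duplicate individual")
  expect_message(
    dang <- read_ped(write_ped_fixture(list(c("F", "X", "GHOST", "0", "1", "2")))),
    "GHOST")
  expect_equal(attr(dang, "dangling_parents"), "GHOST")
})

test_that("PED individual count equals row count across generated fixtures", {
  set.seed(11)
  for (k in c(1, 2, 5, 9)) {
    rows <- lapply(seq_len(k), function(i) {
      c("FAM", paste0("I", i), "0", "0", sample(1:2, 1), sample(1:2, 1))
    })
    expect_equal(nrow(read_ped(write_ped_fixture(rows))$individuals), k)
  }
})

test_that("write_vcf produces a valid header-only file for an empty stream", {
  out <- withr::local_tempfile(fileext = ".vcf")
  rec <- data.frame(chrom = character(), pos = integer(), id = character(),
                    ref = character(), alt = character(), qual = character(),
                    filter = character(), stringsAsFactors = FALSE)
  rec$info <- list()
  write_vcf(rec, out)
  vcf <- read_vcf(out)
  expect_equal(vcf$n, 0L)
})

test_that("write_vcf rejects undeclared INFO keys and unsorted records", {
  out <- withr::local_tempfile(fileext = ".vcf")
  rec <- data.frame(chrom = "1", pos = 10L, id = NA, ref = "A", alt = "T",
                    qual = NA, filter = NA, stringsAsFactors = FALSE)
  rec$info <- list(list(Obs = 1L))
  expect_error(write_vcf(rec, out), "undeclared INFO")
  defs <- data.frame(ID = "Obs", Number = "1", Type = "Integer",
                     Description = "obs")
  write_vcf(rec, out, info_defs = defs)
  expect_match(readLines(out)[length(readLines(out))], "Obs=1")

  rec2 <- rbind(rec, rec)
  rec2$chrom <- c("2", "1")
  rec2$info <- list(list(Obs = 1L), list(Obs = 1L))
  rec3 <- rbind(rec2, rec2[1, ])
  expect_error(write_vcf(rec3, out, info_defs = defs), "not sorted")
  rec4 <- rec2
  rec4$chrom <- c("1", "1")
  rec4$pos <- c(20L, 10L)
  expect_error(write_vcf(rec4, out, info_defs = defs), "not sorted")
})

test_that("write then read reproduces chrom/pos/ref/alt/INFO exactly", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(1:30, 1)
    chrom <- sort(sample(c("1", "2", "X"), n, replace = TRUE))
    rec <- data.frame(
      chrom = chrom, pos = NA_integer_, id = NA_character_,
      ref = sample(c("A", "C", "GT"), n, replace = TRUE),
      alt = sample(c("G", "T", "TA"), n, replace = TRUE),
      qual = NA_character_, filter = "PASS", stringsAsFactors = FALSE)
    for (ch in unique(chrom)) {
      rec$pos[rec$chrom == ch] <- sort(sample.int(1e6, sum(rec$chrom == ch)))
    }
    rec$info <- lapply(seq_len(n), function(i) {
      list(Obs = sample(1:50, 1), Frq = "0.05")
    })
    defs <- data.frame(ID = c("Obs", "Frq"), Number = "1",
                       Type = c("Integer", "Float"),
                       Description = c("obs", "frq"))
    out <- withr::local_tempfile(fileext = ".vcf")
    write_vcf(rec, out, info_defs = defs)
    back <- read_vcf(out)
    expect_equal(back$chrom, rec$chrom)
    expect_equal(back$pos, rec$pos)
    expect_equal(back$ref, rec$ref)
    expect_equal(back$alt, rec$alt)
    expect_equal(back$info,
                 vapply(rec$info, varobs:::render_info, character(1)))
    expect_true(all(vapply(back$alt, function(a) !grepl(",", a), logical(1))))
  }
})
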
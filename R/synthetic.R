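#' Generate a synthetic family cohort
#'
#' Emulates the input stream of a diagnostic lab at desk scale: a panel of
#' common SNVs shared across cases with carrier counts drawn from a power-law
#' site frequency spectrum, private SNVs unique to each case, recurrent SVs
#' re-called across cases with jittered breakpoints, and private SVs. Cases
#' are a mix of singletons and trios; genotypes carry GQ values with a small
#' low-quality fraction so the GQ gate is exercised. A truth table records
#' every variant's true cohort frequency and every recurrent SV's identity.
#'
#' All output is deterministic for a given seed. Variant classes live in
#' disjoint position bands and recurrent/private SV loci are spaced at least
#' 1 Mb apart, so distinct true events can never fall within one padding
#' interval of each other.
#'
#' @param n_cases number of cases (>= 1).
#' @param n_common_snv number of shared SNV sites.
#' @param n_private_snv private SNVs per case.
#' @param n_recurrent_sv number of recurrent SV events (each seen in >= 2
#'   cases).
#' @param sv_jitter_frac breakpoint jitter, uniform in plus/minus this
#'   fraction of the event's padding interval, applied independently per
#'   endpoint per observation.
#' @param n_private_sv private SVs per case.
#' @param af_exponent exponent of the carrier-count spectrum (probability of
#'   carrier count i proportional to 1/i^exponent; 1 gives the neutral 1/i
#'   shape).
#' @param p_trio probability that a case is a trio rather than a singleton.
#' @param p_hom probability that a carrier call is homozygous alternative.
#' @param p_low_gq probability that an individual genotype gets GQ in 5..20
#'   (below the default gate) instead of 30..99.
#' @param seed random seed; the cohort is byte-identical per seed.
#' @param dir optional directory; when given, one VCF + PED pair per case and
#'   the truth tables are written there.
#' @return a `synthetic_cohort`: list with `case_ids`, `cases` (per case:
#'   `ped`, `snv` and `sv` `vcf_data` objects), `snv_truth`, `sv_truth`,
#'   `sv_obs` (one row per generated SV observation with its jittered
#'   endpoints) and `params`.
#' @export
generate_cohort <- function(n_cases = 220, n_common_snv = 200,
                            n_private_snv = 20, n_recurrent_sv = 30,
                            sv_jitter_frac = 0.25, n_private_sv = 5,
                            af_exponent = 1, p_trio = 0.25, p_hom = 0.10,
                            p_low_gq = 0.05, seed = 1, dir = NULL) {
  if (n_cases < 1) stop("n_cases must be >= 1", call. = FALSE)
  if (n_recurrent_sv > 0 && n_cases < 2) {
    stop("recurrent SVs need at least 2 cases", call. = FALSE)
  }
  set.seed(seed)
  case_ids <- sprintf("case%04d", seq_len(n_cases))
  chroms <- as.character(1:22)
  bases <- c("A", "C", "G", "T")

  is_trio <- stats::runif(n_cases) < p_trio
  peds <- lapply(seq_len(n_cases), function(i) {
    cid <- case_ids[i]
    ind <- if (is_trio[i]) {
      data.frame(
        ind_id = paste0(cid, c("_child", "_father", "_mother")),
        father_id = c(paste0(cid, "_father"), NA, NA),
        mother_id = c(paste0(cid, "_mother"), NA, NA),
        sex = c("0", "1", "2"),
        affected = c(TRUE, FALSE, FALSE),
        stringsAsFactors = FALSE)
    } else {
      data.frame(ind_id = paste0(cid, "_1"), father_id = NA_character_,
                 mother_id = NA_character_, sex = "0", affected = TRUE,
                 stringsAsFactors = FALSE)
    }
    structure(list(case_id = cid, individuals = ind), class = "pedigree")
  })
  names(peds) <- case_ids

  draw_gq <- function(n) {
    low <- stats::runif(n) < p_low_gq
    ifelse(low, sample(5:20, n, replace = TRUE),
           sample(30:99, n, replace = TRUE))
  }

  # ---- common SNV sites: power-law carrier-count spectrum ----
  site_chrom <- sample(chroms, n_common_snv, replace = TRUE)
  site_pos <- sample.int(9000000L, n_common_snv) + 999999L
  site_ref <- sample(bases, n_common_snv, replace = TRUE)
  site_alt <- vapply(site_ref, function(r) sample(setdiff(bases, r), 1),
                     character(1), USE.NAMES = FALSE)
  k_prob <- (1 / seq_len(n_cases))^af_exponent
  site_k <- sample.int(n_cases, n_common_snv, replace = TRUE, prob = k_prob)
  site_carriers <- lapply(site_k, function(k) sort(sample.int(n_cases, k)))

  # ---- private SNVs: disjoint position band, globally unique ----
  n_priv_total <- n_cases * n_private_snv
  priv_pos <- if (n_priv_total) sample.int(9000000L, n_priv_total) + 19999999L else integer()
  priv_chrom <- sample(chroms, n_priv_total, replace = TRUE)
  priv_ref <- sample(bases, n_priv_total, replace = TRUE)
  priv_alt <- vapply(priv_ref, function(r) sample(setdiff(bases, r), 1),
                     character(1), USE.NAMES = FALSE)
  priv_case <- rep(seq_len(n_cases), each = n_private_snv)

  # ---- recurrent SVs: spaced loci, jittered endpoints per observation ----
  sv_types <- c("DEL", "DUP", "INV")
  rsv <- NULL
  if (n_recurrent_sv > 0) {
    rsv <- data.frame(
      truth_id = sprintf("rsv%03d", seq_len(n_recurrent_sv)),
      sv_type = sample(sv_types, n_recurrent_sv, replace = TRUE),
      chrom = sample(chroms, n_recurrent_sv, replace = TRUE),
      pos_a = 40000000L + (seq_len(n_recurrent_sv) - 1L) * 1000000L,
      length = round(10^stats::runif(n_recurrent_sv, 3, 5)),
      stringsAsFactors = FALSE)
    rsv$pos_b <- rsv$pos_a + rsv$length - 1L
    rsv$pad <- padding_interval(rsv$length)
    cand_k <- 2:n_cases # sample over indices: safe when this has length 1
    k_prob2 <- (1 / cand_k)^af_exponent
    rsv$n_carrier_cases <- cand_k[sample.int(length(cand_k), n_recurrent_sv,
                                             replace = TRUE, prob = k_prob2)]
    rsv_carriers <- lapply(rsv$n_carrier_cases,
                           function(k) sort(sample.int(n_cases, k)))
  }

  # ---- private SVs: one exclusive 1 Mb locus per event ----
  n_psv_total <- n_cases * n_private_sv
  psv <- NULL
  if (n_psv_total > 0) {
    psv <- data.frame(
      truth_id = sprintf("psv%05d", seq_len(n_psv_total)),
      sv_type = sample(sv_types, n_psv_total, replace = TRUE),
      chrom = sample(chroms, n_psv_total, replace = TRUE),
      pos_a = 100000000L + (seq_len(n_psv_total) - 1L) * 1000000L,
      length = round(10^stats::runif(n_psv_total, 3, 4.7)),
      case = rep(seq_len(n_cases), each = n_private_sv),
      stringsAsFactors = FALSE)
    psv$pos_b <- psv$pos_a + psv$length - 1L
  }

  # per-case variant assembly
  empty_fix <- function() {
    matrix(character(0), nrow = 0, ncol = 8,
           dimnames = list(NULL, FIX_COLS))
  }
  make_gt_mat <- function(gts, gqs, ind) {
    n <- nrow(gts)
    m <- if (n > 0) {
      cbind("GT:GQ", matrix(paste0(gts, ":", gqs), nrow = n))
    } else {
      matrix(character(0), nrow = 0, ncol = length(ind) + 1L)
    }
    colnames(m) <- c("FORMAT", ind)
    m
  }
  make_case <- function(i) {
    cid <- case_ids[i]
    ind <- peds[[i]]$individuals$ind_id
    n_ind <- length(ind)

    assign_gts <- function(n_rec) {
      # genotype layout per record for this family; returns character matrix
      gts <- matrix("0/0", nrow = n_rec, ncol = n_ind)
      hom <- stats::runif(n_rec) < p_hom
      if (is_trio[i]) {
        # column 1 child, 2 father, 3 mother
        gts[hom, 1] <- "1/1"
        gts[hom, 2:3] <- "0/1"
        child_inherits <- stats::runif(n_rec) < 0.5
        gts[!hom, 2] <- "0/1"
        gts[!hom & child_inherits, 1] <- "0/1"
      } else {
        gts[, 1] <- ifelse(hom, "1/1", "0/1")
      }
      gts
    }

    carried_common <- which(vapply(site_carriers, function(cc) i %in% cc,
                                   logical(1)))
    mine_priv <- which(priv_case == i)
    snv_rec <- data.frame(
      chrom = c(site_chrom[carried_common], priv_chrom[mine_priv]),
      pos = c(site_pos[carried_common], priv_pos[mine_priv]),
      ref = c(site_ref[carried_common], priv_ref[mine_priv]),
      alt = c(site_alt[carried_common], priv_alt[mine_priv]),
      stringsAsFactors = FALSE)
    ord <- order(as.integer(snv_rec$chrom), snv_rec$pos)
    snv_rec <- snv_rec[ord, , drop = FALSE]
    n_rec <- nrow(snv_rec)
    gts <- assign_gts(n_rec)
    gqs <- matrix(draw_gq(n_rec * n_ind), nrow = n_rec)
    gt_mat <- make_gt_mat(gts, gqs, ind)
    fix <- if (n_rec > 0) {
      cbind(CHROM = snv_rec$chrom,
            POS = as.character(snv_rec$pos),
            ID = ".", REF = snv_rec$ref, ALT = snv_rec$alt,
            QUAL = ".", FILTER = "PASS", INFO = ".")
    } else {
      empty_fix()
    }

    my_rsv <- if (is.null(rsv)) integer() else {
      which(vapply(rsv_carriers, function(cc) i %in% cc, logical(1)))
    }
    my_psv <- if (is.null(psv)) integer() else which(psv$case == i)
    sv_rec <- if (length(my_rsv) + length(my_psv) > 0) {
      data.frame(
        truth_id = c(rsv$truth_id[my_rsv], psv$truth_id[my_psv]),
        sv_type = c(rsv$sv_type[my_rsv], psv$sv_type[my_psv]),
        chrom = c(rsv$chrom[my_rsv], psv$chrom[my_psv]),
        pos_a = as.numeric(c(rsv$pos_a[my_rsv], psv$pos_a[my_psv])),
        pos_b = as.numeric(c(rsv$pos_b[my_rsv], psv$pos_b[my_psv])),
        stringsAsFactors = FALSE)
    } else {
      data.frame(truth_id = character(), sv_type = character(),
                 chrom = character(), pos_a = numeric(), pos_b = numeric(),
                 stringsAsFactors = FALSE)
    }
    if (length(my_rsv)) {
      # jitter recurrent breakpoints within a fraction of the padding
      jit <- floor(sv_jitter_frac * rsv$pad[my_rsv])
      draw <- function(j) if (j >= 1) sample.int(2 * j + 1, 1) - j - 1 else 0
      ja <- vapply(jit, draw, numeric(1))
      jb <- vapply(jit, draw, numeric(1))
      k <- seq_along(my_rsv)
      sv_rec$pos_a[k] <- sv_rec$pos_a[k] + ja
      sv_rec$pos_b[k] <- sv_rec$pos_b[k] + jb
    }
    ord <- order(as.integer(sv_rec$chrom), sv_rec$pos_a)
    sv_rec <- sv_rec[ord, , drop = FALSE]
    n_sv <- nrow(sv_rec)
    sv_gts <- assign_gts(n_sv)
    sv_gqs <- matrix(draw_gq(n_sv * n_ind), nrow = n_sv)
    sv_gt_mat <- make_gt_mat(sv_gts, sv_gqs, ind)
    sv_fix <- if (n_sv > 0) {
      cbind(CHROM = sv_rec$chrom,
            POS = format(sv_rec$pos_a, scientific = FALSE, trim = TRUE),
            ID = sv_rec$truth_id,
            REF = "N",
            ALT = paste0("<", sv_rec$sv_type, ">"),
            QUAL = ".", FILTER = "PASS",
            INFO = paste0("SVTYPE=", sv_rec$sv_type, ";END=",
                          format(sv_rec$pos_b, scientific = FALSE,
                                 trim = TRUE)))
    } else {
      empty_fix()
    }

    meta <- c("##fileformat=VCFv4.2",
              "##source=varobs synthetic cohort")
    list(
      ped = peds[[i]],
      snv = new_vcf_data(meta, fix, gt_mat, mode = "auto",
                         source = sprintf("synthetic:%s:snv", cid)),
      sv = new_vcf_data(meta, sv_fix, sv_gt_mat, mode = "sv",
                        source = sprintf("synthetic:%s:sv", cid)),
      sv_obs = if (n_sv > 0) {
        cbind(case_id = cid,
              sv_rec[, c("truth_id", "sv_type", "chrom", "pos_a", "pos_b")])
      }
    )
  }

  cases <- lapply(seq_len(n_cases), make_case)
  names(cases) <- case_ids

  snv_truth <- data.frame(
    key = c(snv_key(site_chrom, site_pos, site_ref, site_alt),
            if (n_priv_total) snv_key(priv_chrom, priv_pos, priv_ref, priv_alt)),
    n_carrier_cases = c(site_k, rep(1L, n_priv_total)),
    private = c(rep(FALSE, n_common_snv), rep(TRUE, n_priv_total)),
    stringsAsFactors = FALSE)
  snv_truth$true_af <- snv_truth$n_carrier_cases / n_cases

  sv_truth <- rbind(
    if (!is.null(rsv)) {
      data.frame(truth_id = rsv$truth_id, sv_type = rsv$sv_type,
                 chrom = rsv$chrom, pos_a = rsv$pos_a, pos_b = rsv$pos_b,
                 length = rsv$length, pad = rsv$pad,
                 n_carrier_cases = rsv$n_carrier_cases,
                 private = FALSE, stringsAsFactors = FALSE)
    },
    if (!is.null(psv)) {
      data.frame(truth_id = psv$truth_id, sv_type = psv$sv_type,
                 chrom = psv$chrom, pos_a = psv$pos_a, pos_b = psv$pos_b,
                 length = psv$length, pad = padding_interval(psv$length),
                 n_carrier_cases = 1L, private = TRUE,
                 stringsAsFactors = FALSE)
    })
  if (is.null(sv_truth)) {
    sv_truth <- data.frame(truth_id = character(), sv_type = character(),
                           chrom = character(), pos_a = integer(),
                           pos_b = integer(), length = numeric(),
                           pad = integer(), n_carrier_cases = integer(),
                           private = logical(), stringsAsFactors = FALSE)
  }
  sv_truth$true_af <- sv_truth$n_carrier_cases / n_cases

  obs_rows <- Filter(Negate(is.null), lapply(cases, `[[`, "sv_obs"))
  sv_obs <- if (length(obs_rows)) {
    do.call(rbind, c(obs_rows, list(make.row.names = FALSE)))
  }
  for (cid in case_ids) cases[[cid]]$sv_obs <- NULL

  cohort <- structure(list(
    case_ids = case_ids,
    cases = cases,
    snv_truth = snv_truth,
    sv_truth = sv_truth,
    sv_obs = sv_obs,
    params = list(n_cases = n_cases, n_common_snv = n_common_snv,
                  n_private_snv = n_private_snv,
                  n_recurrent_sv = n_recurrent_sv,
                  sv_jitter_frac = sv_jitter_frac,
                  n_private_sv = n_private_sv, af_exponent = af_exponent,
                  p_trio = p_trio, p_hom = p_hom, p_low_gq = p_low_gq,
                  seed = seed)
  ), class = "synthetic_cohort")

  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d case(s), %d SNV site(s), %d SV event(s), seed %d\n",
              length(x$case_ids), nrow(x$snv_truth), nrow(x$sv_truth),
              x$params$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One `<case>.snv.vcf`, `<case>.sv.vcf` and `<case>.ped` per case plus
#' `snv_truth.tsv` / `sv_truth.tsv`. Output contains no timestamps, so runs
#' with the same seed are byte-identical.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt_defs <- data.frame(
    ID = c("GT", "GQ"), Number = "1", Type = c("String", "Integer"),
    Description = c("Genotype", "Genotype quality"), stringsAsFactors = FALSE)
  sv_defs <- data.frame(
    ID = c("SVTYPE", "END"), Number = "1", Type = c("String", "Integer"),
    Description = c("Structural variant type", "End position"),
    stringsAsFactors = FALSE)
  for (cid in cohort$case_ids) {
    cs <- cohort$cases[[cid]]
    for (part in c("snv", "sv")) {
      v <- cs[[part]]
      rec <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id, ref = v$ref,
                        alt = v$alt, qual = NA, filter = "PASS",
                        info = ifelse(is.na(v$info), ".", v$info),
                        stringsAsFactors = FALSE)
      write_vcf(rec, file.path(dir, sprintf("%s.%s.vcf", cid, part)),
                info_defs = if (part == "sv") sv_defs else NULL,
                format_defs = gt_defs, gt = v$gt)
    }
    ind <- cs$ped$individuals
    ped_lines <- paste(cid, ind$ind_id,
                       ifelse(is.na(ind$father_id), "0", ind$father_id),
                       ifelse(is.na(ind$mother_id), "0", ind$mother_id),
                       ind$sex, ifelse(ind$affected, "2", "1"), sep = "\t")
    writeLines(ped_lines, file.path(dir, paste0(cid, ".ped")))
  }
  utils::write.table(cohort$snv_truth, file.path(dir, "snv_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$sv_truth, file.path(dir, "sv_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Build a store from (a subset of) a synthetic cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @param case_ids cases to load (default: all).
#' @param store an existing store to load into (default: a fresh one).
#' @param params store parameters for a fresh store.
#' @return the store.
#' @export
build_store_from_cohort <- function(cohort, case_ids = cohort$case_ids,
                                    store = NULL, params = store_params()) {
  if (is.null(store)) store <- store_new(params)
  for (cid in case_ids) {
    cs <- cohort$cases[[cid]]
    load_case(store, cs$ped, snv_vcf = cs$snv, sv_vcf = cs$sv)
  }
  store
}

#' Database-size filtering experiment
#'
#' Reproduces, on synthetic data, the qualitative relationship between the
#' size of a local observation database and its filtering power: databases of
#' increasing size are built from a random subset of the cohort, held-out test
#' cases are annotated against each, and the fraction of their variants at or
#' above the frequency cutoff (i.e. removed as common) is recorded. Within a
#' replicate the databases are nested (a larger database extends the smaller
#' one), mirroring a continuously growing store and making the curves paired
#' across sizes.
#'
#' @param cohort a `synthetic_cohort`.
#' @param db_sizes database sizes (numbers of cases) to evaluate.
#' @param test_case_ids held-out cases; must be disjoint from the database
#'   pool.
#' @param af_cutoff frequency at or above which a variant is filtered as
#'   common (default 0.01).
#' @param replicates number of independent random draws of the database
#'   subsets.
#' @param seed seed for the subset draws.
#' @param db_pool cases eligible for the databases; defaults to all cohort
#'   cases except the test cases. An overlap with the test cases is an error.
#' @return data frame with columns `replicate`, `db_size`, `kind`
#'   (`"snv"`/`"sv"`) and `frac_filtered` (mean over test cases of the
#'   per-case filtered fraction).
#' @export
size_experiment <- function(cohort, db_sizes, test_case_ids,
                            af_cutoff = 0.01, replicates = 1, seed = 1,
                            db_pool = NULL) {
  stopifnot(all(test_case_ids %in% cohort$case_ids))
  if (is.null(db_pool)) db_pool <- setdiff(cohort$case_ids, test_case_ids)
  overlap <- intersect(db_pool, test_case_ids)
  if (length(overlap)) {
    stop("database pool overlaps the test cases: ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  if (max(db_sizes) > length(db_pool)) {
    stop("largest db_size (", max(db_sizes), ") exceeds the database pool (",
         length(db_pool), ")", call. = FALSE)
  }

  # test-case query sets, computed once
  test_queries <- lapply(test_case_ids, function(cid) {
    cs <- cohort$cases[[cid]]
    list(keys = snv_keys(cs$snv), sv = sv_coordinates(cs$sv))
  })

  measure <- function(store) {
    n_cases <- store_n_cases(store)
    per_case <- vapply(test_queries, function(q) {
      snv_frq <- vapply(q$keys, function(k) {
        doc <- get_observation(store, k)
        if (is.null(doc)) 0 else doc$obs_count / n_cases
      }, numeric(1))
      sv_frq <- vapply(seq_len(nrow(q$sv)), function(i) {
        hit <- query_sv(store, q$sv[i, ])
        if (is.null(hit)) 0 else hit$frequency
      }, numeric(1))
      frac <- function(x) if (length(x)) mean(x >= af_cutoff) else 0
      c(frac(snv_frq), frac(sv_frq))
    }, numeric(2))
    rowMeans(per_case)
  }

  set.seed(seed)
  sizes <- sort(unique(as.integer(db_sizes)))
  out <- list()
  for (r in seq_len(replicates)) {
    perm <- sample(db_pool)
    store <- store_new()
    loaded <- 0L
    for (s in sizes) {
      if (s > 0L) {
        for (cid in perm[seq.int(loaded + 1L, s)]) {
          cs <- cohort$cases[[cid]]
          load_case(store, cs$ped, snv_vcf = cs$snv, sv_vcf = cs$sv)
        }
        loaded <- s
        m <- measure(store)
      } else {
        m <- c(0, 0)
      }
      out[[length(out) + 1L]] <- data.frame(
        replicate = r, db_size = s, kind = c("snv", "sv"),
        frac_filtered = m, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
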
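#' Default store parameters
#'
#' Tunable settings frozen into a store at creation: the GQ gate and the SV
#' cluster padding policy. Later loads must use the same padding policy, or
#' cluster geometry would become inconsistent across cases.
#'
#' @param gq_threshold genotype quality gate: a variant line is loaded only if
#'   at least one individual carries the alternative allele with GQ strictly
#'   above this value. 0 disables the gate (all calls, including those without
#'   a GQ, are loaded).
#' @param sv_max_pad_bp endpoint interval (bp) for SVs longer than
#'   `sv_large_threshold_bp` and for interchromosomal variants.
#' @param sv_small_frac fraction of the SV length used as the endpoint
#'   interval for small SVs.
#' @param sv_large_threshold_bp length (bp) above which (strictly) the fixed
#'   `sv_max_pad_bp` interval applies.
#' @param profile_threshold genotype-profile concordance at or above which two
#'   samples are considered the same individual.
#' @param profile_min_sites minimum number of jointly called panel sites for a
#'   profile comparison to be meaningful.
#' @return named list of parameters.
#' @export
store_params <- function(gq_threshold = 20L, sv_max_pad_bp = 2000L,
                         sv_small_frac = 0.10, sv_large_threshold_bp = 10000L,
                         profile_threshold = 0.95, profile_min_sites = 10L) {
  list(gq_threshold = as.integer(gq_threshold),
       sv_max_pad_bp = as.integer(sv_max_pad_bp),
       sv_small_frac = as.numeric(sv_small_frac),
       sv_large_threshold_bp = as.integer(sv_large_threshold_bp),
       profile_threshold = as.numeric(profile_threshold),
       profile_min_sites = as.integer(profile_min_sites))
}

#' Create an empty observation store
#'
#' The store is an embedded document store holding cases, small-variant
#' observation documents keyed by [snv_key()], and SV cluster documents. It
#' lives in memory and persists as a directory of JSON-lines files
#' ([store_dump()] / [store_restore()]), so cases can be added continuously
#' without ever rebuilding the database.
#'
#' @param params parameter list from [store_params()].
#' @return an `obs_store` object.
#' @export
store_new <- function(params = store_params()) {
  s <- new.env(parent = emptyenv())
  s$cases <- new.env(parent = emptyenv())
  s$snv <- new.env(parent = emptyenv())
  s$clusters <- new.env(parent = emptyenv())
  s$cluster_index <- new.env(parent = emptyenv())
  s$n_clusters_created <- 0L
  s$params <- params
  class(s) <- "obs_store"
  s
}

#' @export
print.obs_store <- function(x, ...) {
  cat(sprintf("<obs_store> %d case(s), %d SNV/INDEL document(s), %d SV cluster(s)\n",
              store_n_cases(x), length(ls(x$snv)), length(ls(x$clusters))))
  cat(sprintf("  gq_threshold=%d, sv padding: %d bp (>%d bp), %.0f%% below\n",
              x$params$gq_threshold, x$params$sv_max_pad_bp,
              x$params$sv_large_threshold_bp, 100 * x$params$sv_small_frac))
  invisible(x)
}

#' Number of cases in a store
#' @param store an `obs_store`.
#' @return integer case count (the denominator of observation frequencies).
#' @export
store_n_cases <- function(store) length(ls(store$cases))

#' List case ids in a store
#' @param store an `obs_store`.
#' @return character vector of case ids, sorted.
#' @export
store_case_ids <- function(store) sort(ls(store$cases))

#' Check whether a case is already present
#'
#' A case is present either by case id or — when genotype profiles are given
#' and the store holds profiles — by genotype-profile concordance at or above
#' the store's `profile_threshold` against any stored sample (a re-upload of
#' the same individual under a new id).
#'
#' @param store an `obs_store`.
#' @param case_id candidate case id.
#' @param profiles optional named list of [build_profile()] vectors for the
#'   candidate case's samples.
#' @return list with `status` in `absent` / `present_by_id` /
#'   `present_by_profile`, plus `matched_case` and `similarity` when found by
#'   profile.
#' @export
case_exists <- function(store, case_id, profiles = NULL) {
  if (!is.null(store$cases[[case_id]])) {
    return(list(status = "present_by_id", matched_case = case_id,
                similarity = NA_real_))
  }
  if (!is.null(profiles) && length(profiles)) {
    for (cid in ls(store$cases)) {
      stored <- store$cases[[cid]]$profiles
      if (is.null(stored) || !length(stored)) next
      for (p in profiles) {
        for (q in stored) {
          sim <- profile_similarity(p, q,
                                    min_sites = store$params$profile_min_sites)
          if (!is.na(sim) && sim >= store$params$profile_threshold) {
            return(list(status = "present_by_profile", matched_case = cid,
                        similarity = sim))
          }
        }
      }
    }
  }
  list(status = "absent", matched_case = NA_character_, similarity = NA_real_)
}

# Per-line pass/hom summary for the individuals of one pedigree.
# A line passes when at least one individual carries the alternative allele
# and that same individual clears the GQ gate; the homozygote flag is set
# only by a passing 1/1 individual. Lines whose carriers all fail the gate
# are "gq-filtered"; lines with no carrier at all are "rejected".
line_status <- function(vcf, ind_ids, gq_threshold) {
  idx <- match(ind_ids, vcf$samples)
  carrier <- vcf$carrier[, idx, drop = FALSE]
  homalt <- vcf$homalt[, idx, drop = FALSE]
  gq <- vcf$gq[, idx, drop = FALSE]
  gate <- if (gq_threshold == 0L) {
    matrix(TRUE, nrow = nrow(carrier), ncol = ncol(carrier))
  } else {
    !is.na(gq) & gq > gq_threshold
  }
  passing <- carrier & gate
  has_carrier <- rowSums(carrier) > 0L
  pass <- rowSums(passing) > 0L
  list(pass = pass,
       hom = rowSums(homalt & passing) > 0L,
       n_filtered_gq = sum(has_carrier & !pass),
       n_rejected = sum(!has_carrier))
}

#' Load one case into the store
#'
#' Counts every passing variant line exactly once for the case, no matter how
#' many family members carry it (the guard against enrichment of pathogenic
#' alleles in affected families). SNV/INDEL records are upserted by exact key;
#' SV records are routed to the on-the-fly cluster matcher. The load is atomic
#' per case: a duplicate case or a VCF/PED mismatch is refused before any
#' counter is touched.
#'
#' @param store an `obs_store`.
#' @param ped a `pedigree` from [read_ped()].
#' @param snv_vcf,sv_vcf `vcf_data` objects (either may be `NULL`; a combined
#'   file read with `mode = "auto"` can be passed as `snv_vcf` and its SV
#'   records are routed correctly).
#' @param case_id case id; defaults to the pedigree family id.
#' @param gq_threshold GQ gate; defaults to the store parameter.
#' @param profiles optional named list of genotype profiles for the case's
#'   samples (see [build_profile()]); stored with the case and used for
#'   duplicate detection.
#' @param check_profile when `TRUE`, a profile match against a stored case is
#'   a hard refusal; otherwise it only warns (relatives can legitimately share
#'   much of a profile).
#' @return a `load_report` list: counts of loaded, GQ-filtered and rejected
#'   lines plus the number of new SV clusters.
#' @export
load_case <- function(store, ped, snv_vcf = NULL, sv_vcf = NULL,
                      case_id = NULL, gq_threshold = NULL, profiles = NULL,
                      check_profile = FALSE) {
  if (is.null(case_id)) case_id <- ped$case_id
  if (is.null(gq_threshold)) gq_threshold <- store$params$gq_threshold
  gq_threshold <- as.integer(gq_threshold)
  ind_ids <- ped$individuals$ind_id

  vcfs <- Filter(Negate(is.null), list(snv = snv_vcf, sv = sv_vcf))
  if (length(vcfs) == 0L) stop("no variant file given", call. = FALSE)
  for (v in vcfs) {
    missing <- setdiff(ind_ids, v$samples)
    if (length(missing)) {
      stop("pedigree individual(s) absent from VCF sample columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  ex <- case_exists(store, case_id, profiles)
  if (ex$status == "present_by_id") {
    stop("case '", case_id, "' already exists in the store (matched by id); ",
         "load refused, no counters changed", call. = FALSE)
  }
  if (ex$status == "present_by_profile") {
    msg <- sprintf(
      "genotype profile of case '%s' matches stored case '%s' (concordance %.3f)",
      case_id, ex$matched_case, ex$similarity)
    if (check_profile) {
      stop(msg, "; load refused, no counters changed", call. = FALSE)
    }
    warning(msg, call. = FALSE)
  }

  # ---- plan phase: parse everything before touching any counter ----
  snv_plan <- NULL # data.frame(key, chrom, pos, ref, alt, hom)
  sv_plan <- NULL # sv_coordinates rows + hom
  n_filtered_gq <- 0L
  n_rejected <- 0L
  for (v in vcfs) {
    if (v$n == 0L) next
    st <- line_status(v, ind_ids, gq_threshold)
    n_filtered_gq <- n_filtered_gq + st$n_filtered_gq
    n_rejected <- n_rejected + st$n_rejected
    small <- which(st$pass & v$category %in% c("SNV", "INDEL"))
    if (length(small)) {
      plan <- data.frame(key = snv_keys(v, small),
                         chrom = v$chrom[small], pos = v$pos[small],
                         ref = v$ref[small], alt = v$alt[small],
                         hom = st$hom[small], stringsAsFactors = FALSE)
      snv_plan <- rbind(snv_plan, plan)
    }
    svr <- which(st$pass & v$category == "SV")
    if (length(svr)) {
      coords <- sv_coordinates(v, svr)
      coords$hom <- st$hom[svr]
      sv_plan <- rbind(sv_plan, coords)
    }
  }
  if (!is.null(snv_plan) && anyDuplicated(snv_plan$key)) {
    # one observation per case even if a line is duplicated in the input
    hom_by_key <- tapply(snv_plan$hom, snv_plan$key, any)
    snv_plan <- snv_plan[!duplicated(snv_plan$key), , drop = FALSE]
    snv_plan$hom <- as.logical(hom_by_key[snv_plan$key])
  }

  # ---- commit phase ----
  n_clusters_new <- 0L
  sv_contrib <- NULL
  if (!is.null(sv_plan) && nrow(sv_plan)) {
    cluster_ids <- character(nrow(sv_plan))
    for (i in seq_len(nrow(sv_plan))) {
      res <- insert_sv(store, sv_plan[i, ], case_id, is_hom = sv_plan$hom[i])
      cluster_ids[i] <- res$cluster_id
      n_clusters_new <- n_clusters_new + res$created
    }
    sv_contrib <- data.frame(cluster_id = cluster_ids,
                             pos_a = sv_plan$pos_a, pos_b = sv_plan$pos_b,
                             hom = sv_plan$hom, stringsAsFactors = FALSE)
  }
  if (!is.null(snv_plan) && nrow(snv_plan)) {
    snv_env <- store$snv
    for (i in seq_len(nrow(snv_plan))) {
      k <- snv_plan$key[i]
      doc <- snv_env[[k]]
      if (is.null(doc)) {
        snv_env[[k]] <- list(key = k, chrom = snv_plan$chrom[i],
                             pos = snv_plan$pos[i], ref = snv_plan$ref[i],
                             alt = snv_plan$alt[i],
                             obs_count = 1L,
                             hom_count = as.integer(snv_plan$hom[i]),
                             case_ids = case_id)
      } else {
        doc$obs_count <- doc$obs_count + 1L
        doc$hom_count <- doc$hom_count + as.integer(snv_plan$hom[i])
        doc$case_ids <- c(doc$case_ids, case_id)
        snv_env[[k]] <- doc
      }
    }
  }

  store$cases[[case_id]] <- list(
    case_id = case_id,
    individuals = ped$individuals,
    profiles = profiles,
    vcf_paths = unname(vapply(vcfs, function(v) v$source, character(1))),
    loaded_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    snv_contrib = if (is.null(snv_plan)) {
      data.frame(key = character(), hom = logical())
    } else snv_plan[, c("key", "hom")],
    sv_contrib = if (is.null(sv_contrib)) {
      data.frame(cluster_id = character(), pos_a = numeric(),
                 pos_b = numeric(), hom = logical())
    } else sv_contrib
  )

  structure(list(case_id = case_id,
                 n_loaded_snv = if (is.null(snv_plan)) 0L else nrow(snv_plan),
                 n_loaded_sv = if (is.null(sv_plan)) 0L else nrow(sv_plan),
                 n_filtered_gq = n_filtered_gq,
                 n_rejected = n_rejected,
                 n_clusters_new = n_clusters_new),
            class = "load_report")
}

#' @export
print.load_report <- function(x, ...) {
  cat(sprintf(
    "loaded case %s: %d snv, %d sv observations (%d new clusters); %d gq-filtered, %d rejected\n",
    x$case_id, x$n_loaded_snv, x$n_loaded_sv, x$n_clusters_new,
    x$n_filtered_gq, x$n_rejected))
  invisible(x)
}

#' Remove a case and all its observations
#'
#' Exact inverse of [load_case()]: every observation attributed to the case
#' is decremented (SV cluster position accumulators included), documents whose
#' count reaches zero are removed, and the case document is deleted. Loading a
#' case and deleting it restores the previous store state.
#'
#' @param store an `obs_store`.
#' @param case_id id of a present case.
#' @return a `delete_report` list with the numbers of decremented and removed
#'   documents.
#' @export
delete_case <- function(store, case_id) {
  doc <- store$cases[[case_id]]
  if (is.null(doc)) {
    stop("case '", case_id, "' is not in the store", call. = FALSE)
  }
  n_snv_removed <- 0L
  sc <- doc$snv_contrib
  for (i in seq_len(nrow(sc))) {
    k <- sc$key[i]
    d <- store$snv[[k]]
    d$obs_count <- d$obs_count - 1L
    d$hom_count <- d$hom_count - as.integer(sc$hom[i])
    d$case_ids <- d$case_ids[-match(case_id, d$case_ids)]
    if (d$obs_count == 0L) {
      rm(list = k, envir = store$snv)
      n_snv_removed <- n_snv_removed + 1L
    } else {
      store$snv[[k]] <- d
    }
  }
  n_clusters_removed <- 0L
  vc <- doc$sv_contrib
  for (i in seq_len(nrow(vc))) {
    cid <- vc$cluster_id[i]
    cl <- store$clusters[[cid]]
    cl$obs_count <- cl$obs_count - 1L
    cl$hom_count <- cl$hom_count - as.integer(vc$hom[i])
    cl$pos_sum_a <- cl$pos_sum_a - vc$pos_a[i]
    cl$pos_sum_b <- cl$pos_sum_b - vc$pos_b[i]
    cl$case_ids <- cl$case_ids[-match(case_id, cl$case_ids)]
    if (cl$obs_count == 0L) {
      rm(list = cid, envir = store$clusters)
      key <- cluster_index_key(cl$sv_type, cl$chrom_a, cl$chrom_b)
      ids <- store$cluster_index[[key]]
      store$cluster_index[[key]] <- setdiff(ids, cid)
      n_clusters_removed <- n_clusters_removed + 1L
    } else {
      store$clusters[[cid]] <- cl
    }
  }
  rm(list = case_id, envir = store$cases)
  structure(list(case_id = case_id,
                 n_snv_decremented = nrow(sc), n_snv_removed = n_snv_removed,
                 n_sv_decremented = nrow(vc),
                 n_clusters_removed = n_clusters_removed),
            class = "delete_report")
}

#' @export
print.delete_report <- function(x, ...) {
  cat(sprintf(
    "deleted case %s: %d snv decremented (%d removed), %d sv decremented (%d clusters removed)\n",
    x$case_id, x$n_snv_decremented, x$n_snv_removed, x$n_sv_decremented,
    x$n_clusters_removed))
  invisible(x)
}

#' Look up a small-variant observation by exact key
#'
#' @param store an `obs_store`.
#' @param key a key from [snv_key()].
#' @return the observation document (list with `obs_count`, `hom_count`,
#'   `case_ids`, allele fields) or `NULL` when the variant has never been
#'   observed.
#' @export
get_observation <- function(store, key) store$snv[[key]]
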
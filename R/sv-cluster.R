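#' Endpoint padding interval for an SV
#'
#' Breakpoint coordinates of the same structural variant differ between
#' samples and callers, so cluster endpoints carry a tolerance interval. The
#' interval is a fixed 2 kb for variants longer than 10 kb — and for
#' interchromosomal variants, whose length is infinite — and 10% of the
#' variant length for smaller ones (rounded half away from zero, floor 1 bp).
#' The boundary is strict: a 10,000 bp variant takes the fractional branch.
#'
#' @param length SV length in bp (`Inf` for interchromosomal variants).
#' @param max_pad_bp fixed interval for large variants (default 2000).
#' @param frac fraction of the length used for small variants (default 0.10).
#' @param large_threshold_bp strict length cutoff between the two regimes
#'   (default 10000).
#' @return integer interval in bp.
#' @examples
#' padding_interval(50000) # 2000
#' padding_interval(5000)  # 500
#' padding_interval(Inf)   # 2000
#' @export
padding_interval <- function(length, max_pad_bp = 2000L, frac = 0.10,
                             large_threshold_bp = 10000L) {
  if (any(is.na(length)) || any(length <= 0)) {
    stop("SV length must be positive", call. = FALSE)
  }
  out <- integer(base::length(length))
  big <- is.infinite(length) | length > large_threshold_bp
  out[big] <- as.integer(max_pad_bp)
  # round half away from zero; R's round() would round half to even
  out[!big] <- pmax(1L, as.integer(floor(frac * length[!big] + 0.5)))
  out
}

cluster_index_key <- function(sv_type, chrom_a, chrom_b) {
  paste(sv_type, chrom_a, chrom_b, sep = "\t")
}

#' Find the cluster matching an SV, if any
#'
#' An SV matches a cluster when the SV type is identical, the chromosome pair
#' is identical, and both endpoints lie within the cluster's padding interval
#' of the corresponding mean endpoint. Among several candidates the closest
#' cluster wins, with distance the sum of the two endpoint offsets; ties go to
#' the earliest-created cluster so replays are deterministic.
#'
#' @param store an `obs_store`.
#' @param sv one row of [sv_coordinates()] (or an equivalent list with
#'   `sv_type`, `chrom_a`, `pos_a`, `chrom_b`, `pos_b`).
#' @return the matching cluster document, or `NULL`.
#' @export
match_cluster <- function(store, sv) {
  key <- cluster_index_key(sv$sv_type, sv$chrom_a, sv$chrom_b)
  ids <- store$cluster_index[[key]]
  if (is.null(ids) || length(ids) == 0L) return(NULL)
  best <- NULL
  best_d <- Inf
  best_seq <- Inf
  for (cid in ids) {
    cl <- store$clusters[[cid]]
    da <- abs(sv$pos_a - cl$pos_sum_a / cl$obs_count)
    db <- abs(sv$pos_b - cl$pos_sum_b / cl$obs_count)
    if (da > cl$interval_bp || db > cl$interval_bp) next
    d <- da + db
    if (d < best_d || (d == best_d && cl$seq < best_seq)) {
      best <- cl
      best_d <- d
      best_seq <- cl$seq
    }
  }
  best
}

#' Insert an SV observation, creating or joining a cluster
#'
#' Clusters are created and updated on the fly as SVs arrive. With no match, a
#' new cluster is founded at the SV's positions with a padding interval from
#' the founding SV's length; the interval never changes afterwards. On a
#' match, the observation count, homozygote count and exact position
#' accumulators are updated, so the cluster mean is always the arithmetic mean
#' of its members' positions.
#'
#' @param store an `obs_store`.
#' @param sv one row of [sv_coordinates()].
#' @param case_id contributing case id.
#' @param is_hom whether any passing individual carried the variant 1/1.
#' @return list with `cluster_id` and logical `created`.
#' @export
insert_sv <- function(store, sv, case_id, is_hom = FALSE) {
  cl <- match_cluster(store, sv)
  if (is.null(cl)) {
    store$n_clusters_created <- store$n_clusters_created + 1L
    cid <- sprintf("sv%08d", store$n_clusters_created)
    store$clusters[[cid]] <- list(
      cluster_id = cid,
      seq = store$n_clusters_created,
      sv_type = sv$sv_type,
      chrom_a = sv$chrom_a,
      chrom_b = sv$chrom_b,
      pos_sum_a = as.numeric(sv$pos_a),
      pos_sum_b = as.numeric(sv$pos_b),
      interval_bp = padding_interval(sv$length,
                                     store$params$sv_max_pad_bp,
                                     store$params$sv_small_frac,
                                     store$params$sv_large_threshold_bp),
      obs_count = 1L,
      hom_count = as.integer(is_hom),
      case_ids = case_id
    )
    key <- cluster_index_key(sv$sv_type, sv$chrom_a, sv$chrom_b)
    store$cluster_index[[key]] <- c(store$cluster_index[[key]], cid)
    return(list(cluster_id = cid, created = TRUE))
  }
  cl$obs_count <- cl$obs_count + 1L
  cl$hom_count <- cl$hom_count + as.integer(is_hom)
  cl$pos_sum_a <- cl$pos_sum_a + as.numeric(sv$pos_a)
  cl$pos_sum_b <- cl$pos_sum_b + as.numeric(sv$pos_b)
  cl$case_ids <- c(cl$case_ids, case_id)
  store$clusters[[cl$cluster_id]] <- cl
  list(cluster_id = cl$cluster_id, created = FALSE)
}

#' Query the store for a structural variant
#'
#' Read-only lookup using the same matching rules as insertion — this is how
#' annotation decides whether a query SV has been observed. The store is never
#' mutated by a query.
#'
#' @param store an `obs_store`.
#' @param sv one row of [sv_coordinates()].
#' @return list with `cluster_id`, `obs_count`, `hom_count` and `frequency`
#'   (`obs_count / n_cases`), or `NULL` when no cluster matches.
#' @export
query_sv <- function(store, sv) {
  cl <- match_cluster(store, sv)
  if (is.null(cl)) return(NULL)
  list(cluster_id = cl$cluster_id,
       obs_count = cl$obs_count,
       hom_count = cl$hom_count,
       frequency = cl$obs_count / store_n_cases(store))
}

#' Summarise the SV clusters of a store
#'
#' @param store an `obs_store`.
#' @return data frame with one row per cluster (type, chromosome pair, mean
#'   endpoint positions, interval, counts), sorted by creation order.
#' @export
cluster_table <- function(store) {
  ids <- ls(store$clusters)
  if (length(ids) == 0L) {
    return(data.frame(cluster_id = character(), seq = integer(),
                      sv_type = character(), chrom_a = character(),
                      mean_a = numeric(), chrom_b = character(),
                      mean_b = numeric(), interval_bp = integer(),
                      obs_count = integer(), hom_count = integer()))
  }
  rows <- lapply(ids, function(cid) {
    cl <- store$clusters[[cid]]
    data.frame(cluster_id = cl$cluster_id, seq = cl$seq, sv_type = cl$sv_type,
               chrom_a = cl$chrom_a, mean_a = cl$pos_sum_a / cl$obs_count,
               chrom_b = cl$chrom_b, mean_b = cl$pos_sum_b / cl$obs_count,
               interval_bp = cl$interval_bp, obs_count = cl$obs_count,
               hom_count = cl$hom_count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$seq), , drop = FALSE]
}
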
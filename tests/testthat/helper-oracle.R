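# Brute-force reference implementation of the sequential SV clustering rules,
# kept deliberately independent of the store: clusters hold the full list of
# member positions and means are recomputed with mean() at every comparison.

oracle_pad <- function(length, max_pad = 2000, frac = 0.10, thresh = 10000) {
  if (is.infinite(length) || length > thresh) return(as.integer(max_pad))
  max(1L, as.integer(floor(frac * length + 0.5)))
}

oracle_insert <- function(clusters, sv) {
  best <- 0L
  best_d <- Inf
  for (j in seq_along(clusters)) {
    cl <- clusters[[j]]
    if (cl$sv_type != sv$sv_type || cl$chrom_a != sv$chrom_a ||
        cl$chrom_b != sv$chrom_b) next
    da <- abs(sv$pos_a - mean(cl$as))
    db <- abs(sv$pos_b - mean(cl$bs))
    if (da > cl$interval || db > cl$interval) next
    d <- da + db
    if (d < best_d) { # ties keep the earlier (lower j) cluster
      best <- j
      best_d <- d
    }
  }
  if (best == 0L) {
    clusters[[length(clusters) + 1L]] <- list(
      sv_type = sv$sv_type, chrom_a = sv$chrom_a, chrom_b = sv$chrom_b,
      as = sv$pos_a, bs = sv$pos_b, interval = oracle_pad(sv$length))
  } else {
    clusters[[best]]$as <- c(clusters[[best]]$as, sv$pos_a)
    clusters[[best]]$bs <- c(clusters[[best]]$bs, sv$pos_b)
  }
  clusters
}

oracle_cluster <- function(svs) {
  clusters <- list()
  for (i in seq_len(nrow(svs))) clusters <- oracle_insert(clusters, svs[i, ])
  clusters
}

oracle_state <- function(clusters) {
  data.frame(
    sv_type = vapply(clusters, `[[`, character(1), "sv_type"),
    chrom_a = vapply(clusters, `[[`, character(1), "chrom_a"),
    chrom_b = vapply(clusters, `[[`, character(1), "chrom_b"),
    mean_a = vapply(clusters, function(cl) mean(cl$as), numeric(1)),
    mean_b = vapply(clusters, function(cl) mean(cl$bs), numeric(1)),
    interval_bp = vapply(clusters, function(cl) as.integer(cl$interval),
                         integer(1)),
    obs_count = vapply(clusters, function(cl) length(cl$as), integer(1)),
    stringsAsFactors = FALSE)
}

store_state <- function(store) {
  ct <- cluster_table(store)
  ct <- ct[order(ct$seq), c("sv_type", "chrom_a", "chrom_b", "mean_a",
                            "mean_b", "interval_bp", "obs_count")]
  rownames(ct) <- NULL
  ct
}

insert_all <- function(svs, store = store_new()) {
  for (i in seq_len(nrow(svs))) {
    insert_sv(store, svs[i, ], case_id = sprintf("case%04d", i))
  }
  store
}

# Random clustering instance: SVs scattered around a handful of anchor events
# so that matches, near-misses and multi-candidate situations all occur.
random_sv_instance <- function(n, n_anchors = 4) {
  types <- c("DEL", "DUP", "INV")
  anchors <- data.frame(
    sv_type = sample(types, n_anchors, replace = TRUE),
    chrom = sample(c("1", "2"), n_anchors, replace = TRUE),
    pos_a = sample.int(1000000L, n_anchors) + 100000,
    length = round(10^stats::runif(n_anchors, 3, 4.5)))
  idx <- sample.int(n_anchors, n, replace = TRUE)
  pad <- vapply(anchors$length[idx], oracle_pad, integer(1))
  # offsets up to 1.5x the padding: some inside, some outside the interval
  off_a <- round(stats::runif(n, -1.5, 1.5) * pad)
  off_b <- round(stats::runif(n, -1.5, 1.5) * pad)
  pos_a <- anchors$pos_a[idx] + off_a
  pos_b <- anchors$pos_a[idx] + anchors$length[idx] - 1 + off_b
  data.frame(sv_type = anchors$sv_type[idx], chrom_a = anchors$chrom[idx],
             pos_a = pmin(pos_a, pos_b), chrom_b = anchors$chrom[idx],
             pos_b = pmax(pos_a, pos_b),
             length = abs(pos_b - pos_a) + 1, stringsAsFactors = FALSE)
}
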
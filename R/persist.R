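to_jsonl <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    as.character(jsonlite::toJSON(d, auto_unbox = TRUE, digits = NA,
                                  null = "null", dataframe = "columns"))
  }, character(1))
  writeLines(lines, path)
}

from_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE,
         simplifyDataFrame = FALSE)
}

# Canonical, deterministic document shapes used for dumping, so dumps of
# equal stores diff cleanly (fixed field order, sorted keys, explicit types).
case_doc <- function(cs) {
  profiles <- NULL
  if (!is.null(cs$profiles) && length(cs$profiles)) {
    profiles <- lapply(cs$profiles, function(p) {
      list(site_list_id = attr(p, "site_list_id"), calls = as.list(p))
    })
  }
  list(case_id = cs$case_id,
       individuals = lapply(as.list(cs$individuals), as.list),
       profiles = profiles,
       vcf_paths = as.list(cs$vcf_paths),
       loaded_at = cs$loaded_at,
       snv_contrib = list(key = as.list(cs$snv_contrib$key),
                          hom = as.list(cs$snv_contrib$hom)),
       sv_contrib = list(cluster_id = as.list(cs$sv_contrib$cluster_id),
                         pos_a = as.list(as.numeric(cs$sv_contrib$pos_a)),
                         pos_b = as.list(as.numeric(cs$sv_contrib$pos_b)),
                         hom = as.list(cs$sv_contrib$hom)))
}

#' Dump a store to a directory of JSON-lines files
#'
#' Writes `meta.json`, `cases.jsonl`, `snv.jsonl` and `sv_clusters.jsonl`.
#' Documents are emitted in a deterministic order with a fixed field order, so
#' two dumps of the same store are byte-identical apart from case load
#' timestamps, and dumps of different stores diff cleanly. Cluster position
#' accumulators are stored exactly, so a restored store matches on every
#' future insertion.
#'
#' @param store an `obs_store`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
store_dump <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format = "varobs-store-v1",
               n_cases = store_n_cases(store),
               params = store$params)
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             file.path(dir, "meta.json"))

  cases <- lapply(store_case_ids(store),
                  function(cid) case_doc(store$cases[[cid]]))
  to_jsonl(cases, file.path(dir, "cases.jsonl"))

  snv <- lapply(sort(ls(store$snv)), function(k) {
    d <- store$snv[[k]]
    list(key = d$key, chrom = d$chrom, pos = as.integer(d$pos), ref = d$ref,
         alt = d$alt, obs_count = as.integer(d$obs_count),
         hom_count = as.integer(d$hom_count),
         case_ids = as.list(sort(d$case_ids, method = "radix")))
  })
  to_jsonl(snv, file.path(dir, "snv.jsonl"))

  cl_ids <- ls(store$clusters)
  seqs <- vapply(cl_ids, function(cid) store$clusters[[cid]]$seq, numeric(1))
  clusters <- lapply(cl_ids[order(seqs)], function(cid) {
    cl <- store$clusters[[cid]]
    list(cluster_id = cl$cluster_id, seq = as.integer(cl$seq),
         sv_type = cl$sv_type, chrom_a = cl$chrom_a, chrom_b = cl$chrom_b,
         pos_sum_a = as.numeric(cl$pos_sum_a),
         pos_sum_b = as.numeric(cl$pos_sum_b),
         interval_bp = as.integer(cl$interval_bp),
         obs_count = as.integer(cl$obs_count),
         hom_count = as.integer(cl$hom_count),
         case_ids = as.list(sort(cl$case_ids, method = "radix")))
  })
  to_jsonl(clusters, file.path(dir, "sv_clusters.jsonl"))
  invisible(dir)
}

#' Restore a store from a dump directory
#'
#' @param dir directory written by [store_dump()].
#' @return an `obs_store` equivalent to the dumped one.
#' @export
store_restore <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not a store directory (no meta.json): ", dir, call. = FALSE)
  }
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(meta$format, "varobs-store-v1")) {
    stop("unrecognised store format in ", meta_path, call. = FALSE)
  }
  params <- utils::modifyList(store_params(), meta$params)
  store <- store_new(params)

  unnull <- function(col, as = as.character) {
    as(unlist(lapply(col, function(v) if (is.null(v)) NA else v)))
  }
  for (d in from_jsonl(file.path(dir, "cases.jsonl"))) {
    profiles <- d$profiles
    if (!is.null(profiles)) {
      profiles <- lapply(profiles, function(p) {
        structure(as.character(unlist(p$calls)),
                  site_list_id = p$site_list_id)
      })
    }
    ind <- d$individuals
    store$cases[[d$case_id]] <- list(
      case_id = d$case_id,
      individuals = data.frame(
        ind_id = unnull(ind$ind_id),
        father_id = unnull(ind$father_id),
        mother_id = unnull(ind$mother_id),
        sex = unnull(ind$sex),
        affected = unnull(ind$affected, as.logical),
        stringsAsFactors = FALSE),
      profiles = profiles,
      vcf_paths = as.character(unlist(d$vcf_paths)),
      loaded_at = d$loaded_at,
      snv_contrib = data.frame(
        key = unnull(d$snv_contrib$key),
        hom = unnull(d$snv_contrib$hom, as.logical),
        stringsAsFactors = FALSE),
      sv_contrib = data.frame(
        cluster_id = unnull(d$sv_contrib$cluster_id),
        pos_a = unnull(d$sv_contrib$pos_a, as.numeric),
        pos_b = unnull(d$sv_contrib$pos_b, as.numeric),
        hom = unnull(d$sv_contrib$hom, as.logical),
        stringsAsFactors = FALSE)
    )
  }

  for (d in from_jsonl(file.path(dir, "snv.jsonl"))) {
    store$snv[[d$key]] <- list(key = d$key, chrom = d$chrom,
                               pos = as.integer(d$pos), ref = d$ref,
                               alt = d$alt,
                               obs_count = as.integer(d$obs_count),
                               hom_count = as.integer(d$hom_count),
                               case_ids = as.character(unlist(d$case_ids)))
  }

  for (d in from_jsonl(file.path(dir, "sv_clusters.jsonl"))) {
    cl <- list(cluster_id = d$cluster_id, seq = as.integer(d$seq),
               sv_type = d$sv_type, chrom_a = d$chrom_a, chrom_b = d$chrom_b,
               pos_sum_a = as.numeric(d$pos_sum_a),
               pos_sum_b = as.numeric(d$pos_sum_b),
               interval_bp = as.integer(d$interval_bp),
               obs_count = as.integer(d$obs_count),
               hom_count = as.integer(d$hom_count),
               case_ids = as.character(unlist(d$case_ids)))
    store$clusters[[cl$cluster_id]] <- cl
    key <- cluster_index_key(cl$sv_type, cl$chrom_a, cl$chrom_b)
    store$cluster_index[[key]] <- c(store$cluster_index[[key]],
                                    cl$cluster_id)
  }
  # the id counter restarts above the highest live cluster: removed clusters
  # left no references behind, so their ids are free for reuse
  seqs <- vapply(ls(store$clusters),
                 function(cid) store$clusters[[cid]]$seq, numeric(1))
  store$n_clusters_created <- as.integer(max(c(0, seqs)))
  store
}

`%||%` <- function(a, b) if (is.null(a)) b else a
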
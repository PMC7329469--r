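# Local-frequency INFO fields added by annotation and export.
OBS_INFO_DEFS <- data.frame(
  ID = c("Obs", "Hom", "Frq"),
  Number = c("1", "1", "1"),
  Type = c("Integer", "Integer", "Float"),
  Description = c(
    "Number of cases in the local observation store carrying the variant",
    "Number of those cases with a homozygous-alternative call",
    "Local observation frequency: Obs divided by the number of cases in the store"
  ),
  stringsAsFactors = FALSE
)

fmt_frq <- function(x) format(signif(x, 4), scientific = FALSE, trim = TRUE)

store_meta_header <- function(store) {
  p <- store$params
  c(sprintf("##varobs_nCases=%d", store_n_cases(store)),
    sprintf("##varobs_gqThreshold=%d", p$gq_threshold),
    sprintf("##varobs_svPadding=max_pad_bp=%d,small_frac=%s,large_threshold_bp=%d",
            p$sv_max_pad_bp, format(p$sv_small_frac), p$sv_large_threshold_bp))
}

# deterministic natural chromosome order used for export sorting: all-digit
# names ascend numerically, everything else follows lexicographically
chrom_rank <- function(chroms) {
  u <- unique(chroms)
  num <- grepl("^[0-9]+$", u)
  levels <- c(u[num][order(as.numeric(u[num]))],
              sort(u[!num], method = "radix"))
  match(chroms, levels)
}

#' Annotate a query VCF with local observation counts
#'
#' Adds `Obs`, `Hom` and `Frq` INFO fields to every query record found in the
#' store: SNVs/INDELs by exact key lookup, SVs through the read-only cluster
#' matcher (the same rules used at insertion). Records not found pass through
#' byte-identical; the store itself is never modified.
#'
#' @param query path to a decomposed query VCF.
#' @param store an `obs_store`.
#' @param out output VCF path.
#' @return an `annotate_report` list with the numbers of annotated SNV/INDEL
#'   and SV records (and of SV records whose coordinates could not be
#'   interpreted, which pass through unannotated).
#' @export
annotate_vcf <- function(query, store, out) {
  vcf <- read_vcf(query, mode = "auto")
  con <- if (grepl("\\.gz$", query)) gzfile(query, "rt") else file(query, "rt")
  lines <- readLines(con)
  close(con)
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) != vcf$n) {
    stop("internal parse mismatch between raw and parsed VCF", call. = FALSE)
  }

  n_snv <- 0L
  n_sv <- 0L
  n_failed <- 0L
  ann <- rep(NA_character_, vcf$n)
  small <- which(vcf$category %in% c("SNV", "INDEL"))
  if (length(small)) {
    keys <- snv_keys(vcf, small)
    for (k in seq_along(small)) {
      doc <- get_observation(store, keys[k])
      if (!is.null(doc)) {
        ann[small[k]] <- sprintf("Obs=%d;Hom=%d;Frq=%s", doc$obs_count,
                                 doc$hom_count,
                                 fmt_frq(doc$obs_count / store_n_cases(store)))
        n_snv <- n_snv + 1L
      }
    }
  }
  for (i in which(vcf$category == "SV")) {
    coords <- tryCatch(sv_coordinates(vcf, i), error = function(e) NULL)
    if (is.null(coords)) {
      n_failed <- n_failed + 1L
      next
    }
    hit <- query_sv(store, coords[1, ])
    if (!is.null(hit)) {
      ann[i] <- sprintf("Obs=%d;Hom=%d;Frq=%s", hit$obs_count, hit$hom_count,
                        fmt_frq(hit$frequency))
      n_sv <- n_sv + 1L
    }
  }

  for (j in which(!is.na(ann))) {
    fields <- strsplit(lines[body_idx[j]], "\t", fixed = TRUE)[[1]]
    fields[8] <- if (fields[8] %in% c(".", "")) ann[j] else paste0(fields[8], ";", ann[j])
    lines[body_idx[j]] <- paste(fields, collapse = "\t")
  }

  hdr_end <- max(which(startsWith(lines, "#")))
  new_hdr <- c(sprintf('##INFO=<ID=%s,Number=%s,Type=%s,Description="%s">',
                       OBS_INFO_DEFS$ID, OBS_INFO_DEFS$Number,
                       OBS_INFO_DEFS$Type, OBS_INFO_DEFS$Description),
               store_meta_header(store))
  lines <- c(lines[seq_len(hdr_end - 1L)], new_hdr, lines[hdr_end:length(lines)])
  writeLines(lines, out)
  structure(list(n_annotated_snv = n_snv, n_annotated_sv = n_sv,
                 n_failed_sv = n_failed, out = out),
            class = "annotate_report")
}

#' @export
print.annotate_report <- function(x, ...) {
  cat(sprintf("annotated %d snv/indel and %d sv record(s)", x$n_annotated_snv,
              x$n_annotated_sv))
  if (x$n_failed_sv > 0) {
    cat(sprintf(" (%d sv record(s) skipped: uninterpretable coordinates)",
                x$n_failed_sv))
  }
  cat(" -> ", x$out, "\n", sep = "")
  invisible(x)
}

#' Export the store as a frequency VCF
#'
#' SNV/INDEL export writes one line per observation document at its true
#' chromosome/position/alleles. SV export writes one line per cluster at the
#' rounded mean endpoint positions (halves round down, so a mean of 100200.5
#' is emitted as 100200) with a symbolic ALT named by the SV type; INFO
#' carries `SVTYPE`, `END` (`CHR2` as well when interchromosomal) and the
#' cluster's fixed padding interval `PAD`. Both carry `Obs`, `Hom` and `Frq`
#' and a header recording the number of cases and the store parameters, so the
#' file is self-describing for downstream annotation tools.
#'
#' @param store an `obs_store`.
#' @param out output VCF path.
#' @param which `"snv"` or `"sv"`.
#' @return the output path, invisibly; an empty store yields a header-only
#'   file.
#' @export
export_vcf <- function(store, out, which = c("snv", "sv")) {
  which <- match.arg(which)
  n_cases <- store_n_cases(store)
  if (which == "snv") {
    keys <- ls(store$snv)
    docs <- lapply(keys, function(k) store$snv[[k]])
    rec <- data.frame(
      chrom = vapply(docs, `[[`, character(1), "chrom"),
      pos = vapply(docs, function(d) as.integer(d$pos), integer(1)),
      id = rep(NA_character_, length(docs)),
      ref = vapply(docs, `[[`, character(1), "ref"),
      alt = vapply(docs, `[[`, character(1), "alt"),
      qual = rep(NA_character_, length(docs)),
      filter = rep(NA_character_, length(docs)),
      stringsAsFactors = FALSE
    )
    rec$info <- lapply(docs, function(d) {
      list(Obs = d$obs_count, Hom = d$hom_count,
           Frq = fmt_frq(d$obs_count / n_cases))
    })
    rec <- rec[order(chrom_rank(rec$chrom), rec$pos), , drop = FALSE]
    return(invisible(write_vcf(rec, out, info_defs = OBS_INFO_DEFS,
                               meta_extra = store_meta_header(store))))
  }

  cl <- cluster_table(store)
  info_defs <- rbind(
    data.frame(
      ID = c("SVTYPE", "END", "CHR2", "PAD"),
      Number = "1",
      Type = c("String", "Integer", "String", "Integer"),
      Description = c(
        "Structural variant type of the cluster",
        "Rounded mean position of cluster endpoint B",
        "Chromosome of endpoint B when interchromosomal",
        "Fixed endpoint padding interval of the cluster in bp"),
      stringsAsFactors = FALSE),
    OBS_INFO_DEFS)
  round_half_down <- function(x) as.integer(ceiling(x - 0.5))
  rec <- data.frame(
    chrom = cl$chrom_a,
    pos = round_half_down(cl$mean_a),
    id = cl$cluster_id,
    ref = rep("N", nrow(cl)),
    alt = if (nrow(cl)) paste0("<", cl$sv_type, ">") else character(),
    qual = rep(NA_character_, nrow(cl)),
    filter = rep(NA_character_, nrow(cl)),
    stringsAsFactors = FALSE
  )
  rec$info <- lapply(seq_len(nrow(cl)), function(i) {
    info <- list(SVTYPE = cl$sv_type[i])
    if (cl$chrom_a[i] != cl$chrom_b[i]) info$CHR2 <- cl$chrom_b[i]
    info$END <- round_half_down(cl$mean_b[i])
    info$PAD <- cl$interval_bp[i]
    info$Obs <- cl$obs_count[i]
    info$Hom <- cl$hom_count[i]
    info$Frq <- fmt_frq(cl$obs_count[i] / n_cases)
    info
  })
  rec <- rec[order(chrom_rank(rec$chrom), rec$pos), , drop = FALSE]
  invisible(write_vcf(rec, out, info_defs = info_defs,
                      meta_extra = store_meta_header(store)))
}
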
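#' @importFrom utils head tail
NULL

FIX_COLS <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")

#' Extract a key from VCF INFO strings
#'
#' Vectorised lookup of `KEY=value` (or a bare flag) in raw INFO strings.
#'
#' @param info character vector of INFO strings (`NA` or "." for empty).
#' @param key INFO key to extract.
#' @return character vector: the value, `""` for a bare flag, `NA` when the
#'   key is absent.
#' @keywords internal
info_field <- function(info, key) {
  out <- rep(NA_character_, length(info))
  ok <- !is.na(info) & info != "."
  if (!any(ok)) return(out)
  pat <- paste0("(?:^|;)", key, "(=([^;]*))?(?:;|$)")
  m <- regexec(pat, info[ok], perl = TRUE)
  hit <- regmatches(info[ok], m)
  out[ok] <- vapply(hit, function(h) {
    if (length(h) == 0L) return(NA_character_)
    if (h[2] == "") "" else h[3]
  }, character(1))
  out
}

# Extract one FORMAT sub-field (e.g. GQ) for every record x sample.
# `gt` is the vcfR-style matrix whose first column is FORMAT.
extract_format_field <- function(gt, key) {
  if (is.null(gt) || ncol(gt) < 2L) {
    return(matrix(NA_character_, nrow = NROW(gt), ncol = 0L))
  }
  fmt <- gt[, 1L]
  smp <- gt[, -1L, drop = FALSE]
  out <- matrix(NA_character_, nrow = nrow(smp), ncol = ncol(smp),
                dimnames = dimnames(smp))
  idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                function(f) match(key, f), integer(1))
  for (k in sort(unique(idx[!is.na(idx)]))) {
    rows <- which(!is.na(idx) & idx == k)
    for (j in seq_len(ncol(smp))) {
      cells <- strsplit(smp[rows, j], ":", fixed = TRUE)
      out[rows, j] <- vapply(cells, function(x) {
        if (length(x) >= k) x[k] else NA_character_
      }, character(1))
    }
  }
  out[out == "."] <- NA_character_
  out
}

# Parse a matrix of GT strings into carrier / hom-alt / missing logicals.
# Alleles are restricted to {0, 1, .} on decomposed input; a carrier has at
# least one "1" allele, hom-alt means a diploid 1/1 (or 1|1) call.
parse_gt_matrix <- function(gtm) {
  n <- length(gtm)
  flat <- as.vector(gtm)
  carrier <- rep(FALSE, n)
  homalt <- rep(FALSE, n)
  ok <- !is.na(flat) & flat != "."
  if (any(ok)) {
    alleles <- strsplit(flat[ok], "[/|]")
    carrier[ok] <- vapply(alleles, function(a) any(a == "1"), logical(1))
    homalt[ok] <- vapply(alleles, function(a) {
      length(a) == 2L && all(a == "1")
    }, logical(1))
  }
  missing <- !ok | vapply(
    ifelse(ok, flat, "."),
    function(g) all(strsplit(g, "[/|]")[[1]] == "."), logical(1))
  dim(carrier) <- dim(homalt) <- dim(missing) <- dim(gtm)
  dimnames(carrier) <- dimnames(homalt) <- dimnames(missing) <- dimnames(gtm)
  list(carrier = carrier, homalt = homalt, missing = missing)
}

is_symbolic_alt <- function(alt) grepl("^<.+>$", alt)
is_breakend_alt <- function(alt) grepl("[][]", alt)

#' Construct a parsed VCF container from header and body matrices
#'
#' Internal constructor shared by [read_vcf()] and the synthetic cohort
#' generator, so in-memory cohorts follow exactly the same code path as
#' records parsed from disk.
#'
#' @param meta character vector of `##` header lines.
#' @param fix character matrix with the 8 fixed VCF columns.
#' @param gt character matrix with FORMAT plus one column per sample, or
#'   `NULL` for a sites-only VCF.
#' @param mode how to assign the record category: `"auto"` classifies each
#'   record as SV (symbolic or break-end ALT, or an SVTYPE INFO key) versus
#'   SNV/INDEL by allele length; `"snv"` forbids SV records; `"sv"` marks
#'   every record as SV.
#' @param skip_bad_records downgrade rejection of malformed records
#'   (multi-allelic ALT, SV record in an snv-mode file) to a warning and drop
#'   the record instead of failing.
#' @param source provenance string (file path) kept for reporting.
#' @return an object of class `vcf_data`.
#' @keywords internal
new_vcf_data <- function(meta, fix, gt = NULL, mode = c("auto", "snv", "sv"),
                         skip_bad_records = FALSE, source = NA_character_) {
  mode <- match.arg(mode)
  fix <- as.matrix(fix)
  if (nrow(fix) > 0 && is.null(colnames(fix))) colnames(fix) <- FIX_COLS
  alt <- as.character(fix[, "ALT"])

  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    lines <- paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"])
    if (!skip_bad_records) {
      stop("input is not decomposed: multi-allelic ALT at ",
           paste(head(lines, 5), collapse = ", "),
           if (sum(multi) > 5) sprintf(" (and %d more)", sum(multi) - 5),
           "; decompose and normalize the VCF first", call. = FALSE)
    }
    warning("skipping ", sum(multi), " multi-allelic record(s)")
    fix <- fix[!multi, , drop = FALSE]
    if (!is.null(gt)) gt <- gt[!multi, , drop = FALSE]
    alt <- alt[!multi]
  }

  info <- as.character(fix[, "INFO"])
  sv_like <- is_symbolic_alt(alt) | is_breakend_alt(alt) |
    !is.na(info_field(info, "SVTYPE"))
  ref <- as.character(fix[, "REF"])

  category <- character(length(alt))
  if (mode == "sv") {
    category[] <- "SV"
  } else {
    small <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")
    if (mode == "snv" && any(sv_like)) {
      lines <- paste0(fix[sv_like, "CHROM"], ":", fix[sv_like, "POS"])
      if (!skip_bad_records) {
        stop("SV record(s) in a small-variant file at ",
             paste(head(lines, 5), collapse = ", "), call. = FALSE)
      }
      warning("skipping ", sum(sv_like), " SV record(s) in snv mode")
      keep <- !sv_like
      fix <- fix[keep, , drop = FALSE]
      if (!is.null(gt)) gt <- gt[keep, , drop = FALSE]
      alt <- alt[keep]; ref <- ref[keep]; info <- info[keep]
      small <- small[keep]; sv_like <- sv_like[keep]
    }
    category <- if (mode == "snv") small else ifelse(sv_like, "SV", small)
  }

  samples <- if (!is.null(gt) && ncol(gt) >= 2L) colnames(gt)[-1L] else character()
  gtm <- extract_format_field(gt, "GT")
  parsed <- parse_gt_matrix(gtm)
  gqm <- extract_format_field(gt, "GQ")
  gq <- matrix(suppressWarnings(as.integer(gqm)), nrow = nrow(gqm),
               ncol = ncol(gqm), dimnames = dimnames(gqm))

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (nrow(fix) > 0 && (any(is.na(pos)) || any(pos < 1L))) {
    stop("malformed POS column (non-integer or < 1)", call. = FALSE)
  }
  nonsym <- !is_symbolic_alt(alt) & !is_breakend_alt(alt)
  if (any(nonsym & (is.na(ref) | ref == "" | ref == "."))) {
    stop("empty REF on a non-symbolic record", call. = FALSE)
  }

  structure(list(
    meta = meta,
    fix = fix,
    gt = gt,
    samples = samples,
    chrom = as.character(fix[, "CHROM"]),
    pos = pos,
    id = as.character(fix[, "ID"]),
    ref = ref,
    alt = alt,
    info = info,
    category = category,
    carrier = parsed$carrier,
    homalt = parsed$homalt,
    gt_missing = parsed$missing,
    gq = gq,
    n = nrow(fix),
    source = source
  ), class = "vcf_data")
}

#' Read a decomposed VCF file
#'
#' Parses a (plain or gzipped) VCF into a `vcf_data` container with per-record
#' category assignment and per-sample genotype carrier / homozygote / GQ
#' matrices. The input must be decomposed: any multi-allelic line is rejected
#' with an error naming the offending position, since silently splitting would
#' hide non-normalized alleles.
#'
#' @param path path to a VCF (optionally bgzip/gzip compressed).
#' @inheritParams new_vcf_data
#' @return a `vcf_data` object; records are kept in file order.
#' @examples
#' vcf <- read_vcf(system.file("extdata", "example_trio.vcf", package = "varobs"))
#' vcf$category
#' @export
read_vcf <- function(path, mode = c("auto", "snv", "sv"),
                     skip_bad_records = FALSE) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- if (ncol(v@gt) > 0) v@gt else NULL
  new_vcf_data(v@meta, v@fix, gt, mode = mode,
               skip_bad_records = skip_bad_records, source = path)
}

#' @export
print.vcf_data <- function(x, ...) {
  cat(sprintf("<vcf_data> %d record(s), %d sample(s)\n", x$n, length(x$samples)))
  if (x$n > 0) {
    tab <- table(x$category)
    cat("  categories:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a PED pedigree file
#'
#' Reads a whitespace-delimited 6+ column PED file describing one case
#' (family or singleton). All rows must share one family id unless `case_id`
#' overrides it.
#'
#' @param path path to the PED file.
#' @param case_id optional override for the family id column; required when
#'   the file mixes family ids.
#' @return a `pedigree`: list with `case_id` and an `individuals` data frame
#'   (ind_id, father_id, mother_id, sex, affected). Parent ids that do not
#'   resolve within the case are allowed and recorded in the
#'   `dangling_parents` attribute.
#' @export
read_ped <- function(path, case_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty PED file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 6L)) {
    stop("PED line(s) with fewer than 6 columns: line ",
         paste(which(ncols < 6L), collapse = ", "), call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  fam_ids <- unique(m[, 1L])
  if (length(fam_ids) > 1L && is.null(case_id)) {
    stop("PED file mixes family ids (", paste(sort(fam_ids), collapse = ", "),
         "); pass an explicit case id to override", call. = FALSE)
  }
  if (is.null(case_id)) case_id <- fam_ids[1L]
  ind <- data.frame(
    ind_id = m[, 2L],
    father_id = ifelse(m[, 3L] %in% c("0", "."), NA_character_, m[, 3L]),
    mother_id = ifelse(m[, 4L] %in% c("0", "."), NA_character_, m[, 4L]),
    sex = m[, 5L],
    affected = m[, 6L] == "2",
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ind$ind_id)) {
    stop("duplicate individual id(s) in PED: ",
         paste(unique(ind$ind_id[duplicated(ind$ind_id)]), collapse = ", "),
         call. = FALSE)
  }
  parents <- stats::na.omit(c(ind$father_id, ind$mother_id))
  dangling <- setdiff(parents, ind$ind_id)
  ped <- structure(list(case_id = case_id, individuals = ind),
                   class = "pedigree")
  attr(ped, "dangling_parents") <- dangling
  if (length(dangling)) {
    message("pedigree ", case_id, ": parent id(s) not present in case: ",
            paste(dangling, collapse = ", "))
  }
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> case %s: %d individual(s)\n",
              x$case_id, nrow(x$individuals)))
  invisible(x)
}

# Render one INFO list (named list; TRUE for flags) as an INFO string.
render_info <- function(info) {
  if (is.null(info) || length(info) == 0L) return(".")
  parts <- vapply(seq_along(info), function(i) {
    v <- info[[i]]
    k <- names(info)[i]
    if (isTRUE(v)) k
    else paste0(k, "=", if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else as.character(v))
  }, character(1))
  paste(parts, collapse = ";")
}

#' Write records as a VCF file
#'
#' Writes a valid VCF 4.2 with the given INFO declarations. Records must be
#' grouped into contiguous chromosome blocks and position-sorted within them;
#' an INFO key used by a record but not declared in `info_defs` is an error.
#'
#' @param records data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `qual`, `filter` and `info` (either a list column of named lists or a
#'   character vector of pre-rendered INFO strings).
#' @param path output file path.
#' @param info_defs data frame declaring INFO fields (columns `ID`, `Number`,
#'   `Type`, `Description`); may be `NULL` when no structured INFO is used.
#' @param meta_extra extra `##` header lines (e.g. store parameters).
#' @param format_defs data frame declaring FORMAT fields, same columns as
#'   `info_defs`; only used when `gt` is given.
#' @param gt optional character matrix (FORMAT column plus one column per
#'   sample) written verbatim after the fixed columns.
#' @return the path, invisibly.
#' @export
write_vcf <- function(records, path, info_defs = NULL,
                      meta_extra = character(), format_defs = NULL, gt = NULL) {
  n <- nrow(records)
  if (n > 0) {
    runs <- rle(as.character(records$chrom))
    if (anyDuplicated(runs$values)) {
      stop("records are not sorted: chromosome ",
           runs$values[duplicated(runs$values)][1],
           " appears in more than one block", call. = FALSE)
    }
    for (block in split(records$pos, factor(records$chrom, levels = runs$values))) {
      if (is.unsorted(block)) {
        stop("records are not sorted by position within a chromosome",
             call. = FALSE)
      }
    }
  }

  if (is.list(records$info) && !is.character(records$info)) {
    declared <- if (is.null(info_defs)) character() else info_defs$ID
    used <- unique(unlist(lapply(records$info, names)))
    bad <- setdiff(used, declared)
    if (length(bad)) {
      stop("undeclared INFO key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    info_str <- vapply(records$info, render_info, character(1))
  } else {
    info_str <- as.character(records$info)
    info_str[is.na(info_str) | info_str == ""] <- "."
  }

  hdr_def <- function(kind, defs) {
    if (is.null(defs) || nrow(defs) == 0L) return(character())
    sprintf('##%s=<ID=%s,Number=%s,Type=%s,Description="%s">',
            kind, defs$ID, defs$Number, defs$Type, defs$Description)
  }
  header <- c("##fileformat=VCFv4.2",
              meta_extra,
              hdr_def("INFO", info_defs),
              hdr_def("FORMAT", format_defs))
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(gt)) cols <- c(cols, "FORMAT", colnames(gt)[-1L])
  header <- c(header, paste(cols, collapse = "\t"))

  dot <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == ""] <- "."
    x
  }
  body <- character()
  if (n > 0) {
    body <- paste(records$chrom, format(records$pos, scientific = FALSE, trim = TRUE),
                  dot(records$id), records$ref, records$alt,
                  dot(records$qual), dot(records$filter), info_str, sep = "\t")
    if (!is.null(gt)) {
      body <- paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}
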
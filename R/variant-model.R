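#' Canonical key for a small variant
#'
#' Builds the canonical document id for an SNV/INDEL by joining chromosome,
#' position, reference and alternative allele with `"_"`. The separator keeps
#' the key injective over its components (raw concatenation would confuse
#' e.g. chromosome "1" at 2300 with chromosome "12" at 300).
#'
#' @param chrom,pos,ref,alt vectors of the four components (recycled).
#' @return character vector of keys.
#' @examples
#' snv_key("1", 100, "A", "T")
#' @export
snv_key <- function(chrom, pos, ref, alt) {
  paste(chrom, format(pos, scientific = FALSE, trim = TRUE), ref, alt, sep = "_")
}

#' Canonical keys for the small-variant records of a VCF
#'
#' @param vcf a `vcf_data` object.
#' @param which row indices; defaults to all SNV/INDEL records. Including an
#'   SV record is an error: structural variants have no exact key and are
#'   matched through clusters instead.
#' @return character vector of keys, one per selected record.
#' @export
snv_keys <- function(vcf, which = NULL) {
  if (is.null(which)) which <- which(vcf$category %in% c("SNV", "INDEL"))
  if (any(vcf$category[which] == "SV")) {
    stop("cannot build an exact key for an SV record; use sv_coordinates()",
         call. = FALSE)
  }
  snv_key(vcf$chrom[which], vcf$pos[which], vcf$ref[which], vcf$alt[which])
}

#' Parse a break-end ALT allele
#'
#' Extracts the mate chromosome and position from break-end notation such as
#' `N[2:321681[` or `]13:123456]T`.
#'
#' @param alt a single ALT string in break-end notation.
#' @return list with `chrom` (character) and `pos` (integer) of the mate.
#' @export
parse_breakend <- function(alt) {
  m <- regexec("^([A-Za-z.*]*)([\\[\\]])([^\\[\\]:]+):([0-9]+)([\\[\\]])([A-Za-z.*]*)$",
               alt, perl = TRUE)
  g <- regmatches(alt, m)[[1]]
  if (length(g) == 0L || g[3] != g[6] || (g[2] == "" && g[7] == "")) {
    stop("unparseable break-end ALT: ", alt, call. = FALSE)
  }
  list(chrom = g[4], pos = as.integer(g[5]))
}

# Deterministic chromosome ordering used to normalize interchromosomal
# endpoint pairs: numeric comparison when both names are all-digits,
# lexicographic otherwise. Names are compared as exact strings (no "chr"
# prefix harmonization).
chrom_lt <- function(a, b) {
  num_a <- grepl("^[0-9]+$", a)
  num_b <- grepl("^[0-9]+$", b)
  if (num_a && num_b) as.numeric(a) < as.numeric(b) else a < b
}

sv_coords_one <- function(chrom, pos, alt, info) {
  pos <- as.numeric(pos)
  if (is_breakend_alt(alt)) {
    mate <- parse_breakend(alt)
    if (mate$chrom == chrom) {
      a <- min(pos, mate$pos); b <- max(pos, mate$pos)
      return(list(sv_type = "BND", chrom_a = chrom, pos_a = a,
                  chrom_b = chrom, pos_b = b, length = b - a + 1))
    }
    # interchromosomal: infinite length; order the endpoint pair so that
    # matching is symmetric for the two mates of a pair
    if (chrom_lt(chrom, mate$chrom)) {
      return(list(sv_type = "BND", chrom_a = chrom, pos_a = pos,
                  chrom_b = mate$chrom, pos_b = as.numeric(mate$pos),
                  length = Inf))
    }
    return(list(sv_type = "BND", chrom_a = mate$chrom,
                pos_a = as.numeric(mate$pos),
                chrom_b = chrom, pos_b = pos, length = Inf))
  }

  svtype <- info_field(info, "SVTYPE")
  if (is_symbolic_alt(alt)) {
    inner <- sub("^<(.+)>$", "\\1", alt)
    sv_type <- toupper(strsplit(inner, ":", fixed = TRUE)[[1]][1])
  } else if (!is.na(svtype) && nzchar(svtype)) {
    sv_type <- toupper(svtype)
  } else {
    stop("cannot determine SV type at ", chrom, ":", pos, call. = FALSE)
  }

  end <- suppressWarnings(as.numeric(info_field(info, "END")))
  svlen <- suppressWarnings(abs(as.numeric(info_field(info, "SVLEN"))))

  if (sv_type == "INS" && !is.na(svlen)) {
    # END is typically POS for insertions; a 1 bp span would make fractional
    # padding degenerate, so the padding derives from the insert length
    if (svlen <= 0) stop("non-positive SVLEN at ", chrom, ":", pos, call. = FALSE)
    return(list(sv_type = sv_type, chrom_a = chrom, pos_a = pos,
                chrom_b = chrom, pos_b = pos, length = svlen))
  }
  if (!is.na(end)) {
    a <- min(pos, end); b <- max(pos, end)
    return(list(sv_type = sv_type, chrom_a = chrom, pos_a = a,
                chrom_b = chrom, pos_b = b, length = b - a + 1))
  }
  if (!is.na(svlen)) {
    if (svlen <= 0) stop("non-positive SVLEN at ", chrom, ":", pos, call. = FALSE)
    return(list(sv_type = sv_type, chrom_a = chrom, pos_a = pos,
                chrom_b = chrom, pos_b = pos + svlen, length = svlen + 1))
  }
  stop("SV record at ", chrom, ":", pos,
       " has neither END nor SVLEN", call. = FALSE)
}

#' Endpoint coordinates of structural variant records
#'
#' Derives the SV type and the endpoint pair (position A, position B) of each
#' structural variant record. Position A is the CHROM/POS of the record; for
#' intrachromosomal variants position B comes from INFO/END (or POS +
#' |SVLEN|), for break-ends from the mate coordinate in the ALT column.
#' Intrachromosomal length is `pos_b - pos_a + 1` (insertion length is
#' |SVLEN| with both endpoints at POS); interchromosomal variants have
#' infinite length.
#'
#' @param vcf a `vcf_data` object.
#' @param which row indices; defaults to all records with category SV.
#' @return data frame with one row per selected record: `sv_type`, `chrom_a`,
#'   `pos_a`, `chrom_b`, `pos_b`, `length` (numeric, `Inf` when
#'   interchromosomal) and `row` (index into `vcf`).
#' @export
sv_coordinates <- function(vcf, which = NULL) {
  if (is.null(which)) which <- which(vcf$category == "SV")
  if (any(vcf$category[which] != "SV")) {
    stop("sv_coordinates() called on a non-SV record", call. = FALSE)
  }
  rows <- lapply(which, function(i) {
    sv_coords_one(vcf$chrom[i], vcf$pos[i], vcf$alt[i], vcf$info[i])
  })
  data.frame(
    sv_type = vapply(rows, `[[`, character(1), "sv_type"),
    chrom_a = vapply(rows, `[[`, character(1), "chrom_a"),
    pos_a = vapply(rows, `[[`, numeric(1), "pos_a"),
    chrom_b = vapply(rows, `[[`, character(1), "chrom_b"),
    pos_b = vapply(rows, `[[`, numeric(1), "pos_b"),
    length = vapply(rows, `[[`, numeric(1), "length"),
    row = as.integer(which),
    stringsAsFactors = FALSE
  )
}
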
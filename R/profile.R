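#' Read a genotype-profile site panel
#'
#' The panel is a tab-separated table of common SNV sites (columns `chrom`,
#' `pos`, `ref`, `alt`) used to fingerprint samples. The packaged default
#' panel (`profile_panel_synthetic.tsv`) is a synthetic 50-site panel intended
#' for the synthetic genome model of [generate_cohort()]; production use
#' should supply a panel of common polymorphic sites for the relevant genome
#' build.
#'
#' @param path panel file; defaults to the packaged synthetic panel.
#' @return data frame of sites with a `site_list_id` attribute (a hash of the
#'   canonical site keys, so profiles are only compared across the same
#'   panel).
#' @export
read_profile_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "profile_panel_synthetic.tsv",
                        package = "varobs")
  }
  if (!file.exists(path)) stop("no such panel file: ", path, call. = FALSE)
  panel <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = c("character", "integer",
                                            "character", "character"),
                             stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(panel))) {
    stop("malformed panel file (need columns chrom, pos, ref, alt): ", path,
         call. = FALSE)
  }
  keys <- snv_key(panel$chrom, panel$pos, panel$ref, panel$alt)
  if (anyDuplicated(keys)) {
    stop("malformed panel file: duplicated site(s)", call. = FALSE)
  }
  attr(panel, "site_list_id") <- rlang::hash(keys)
  panel
}

#' Build genotype profiles for every sample of a VCF
#'
#' For each sample, the call at every panel site is classified as `hom-ref`,
#' `het`, `hom-alt` or `missing` (site absent from the VCF, or genotype not
#' called). Profiles over the same panel can be compared with
#' [profile_similarity()] to detect re-uploads of the same individual under a
#' different case id.
#'
#' @param vcf a `vcf_data` object.
#' @param panel a panel from [read_profile_panel()].
#' @return named list (one element per sample) of character vectors of length
#'   `nrow(panel)`, each carrying the panel's `site_list_id` attribute.
#' @export
build_profile <- function(vcf, panel) {
  site_keys <- snv_key(panel$chrom, panel$pos, panel$ref, panel$alt)
  small <- which(vcf$category %in% c("SNV", "INDEL"))
  vcf_keys <- if (length(small)) snv_keys(vcf, small) else character()
  hit <- match(site_keys, vcf_keys) # index into `small`, or NA
  if (all(is.na(hit)) && length(vcf$samples)) {
    warning("no panel site found in the VCF; profiles are all-missing and ",
            "profiling is effectively skipped", call. = FALSE)
  }
  out <- lapply(seq_along(vcf$samples), function(j) {
    calls <- rep("missing", length(site_keys))
    for (i in which(!is.na(hit))) {
      row <- small[hit[i]]
      calls[i] <-
        if (vcf$gt_missing[row, j]) "missing"
        else if (vcf$homalt[row, j]) "hom-alt"
        else if (vcf$carrier[row, j]) "het"
        else "hom-ref"
    }
    structure(calls, site_list_id = attr(panel, "site_list_id"))
  })
  names(out) <- vcf$samples
  out
}

#' Concordance between two genotype profiles
#'
#' Fraction of panel sites, non-missing in both profiles, with identical
#' calls. When fewer than `min_sites` sites are jointly called the comparison
#' is unreliable and the function returns 0 with attribute
#' `low_coverage = TRUE`.
#'
#' @param p,q profiles from [build_profile()] over the same panel.
#' @param min_sites minimum number of jointly called sites (default 10).
#' @return concordance in `[0, 1]`.
#' @export
profile_similarity <- function(p, q, min_sites = 10L) {
  if (!identical(attr(p, "site_list_id"), attr(q, "site_list_id"))) {
    stop("profiles were built over different site panels", call. = FALSE)
  }
  if (length(p) != length(q)) {
    stop("profiles have different lengths", call. = FALSE)
  }
  both <- p != "missing" & q != "missing"
  if (sum(both) < min_sites) {
    return(structure(0, low_coverage = TRUE))
  }
  sum(p[both] == q[both]) / sum(both)
}
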
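# In-code fixture builders shared across test files.

vcf_header <- function(samples = character()) {
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples)) cols <- c(cols, "FORMAT", samples)
  c("##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(cols, collapse = "\t"))
}

# body lines: each a character vector of fields, already in column order;
# sample column names default to S1, S2, ... when genotype fields are present
write_vcf_fixture <- function(lines, samples = NULL,
                              path = withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())) {
  if (is.null(samples)) {
    n_extra <- max(lengths(lines)) - 9L
    samples <- if (n_extra >= 1) paste0("S", seq_len(n_extra)) else character()
  }
  writeLines(c(vcf_header(samples),
               vapply(lines, paste, character(1), collapse = "\t")), path)
  path
}

fmt_pos <- function(pos) format(pos, scientific = FALSE, trim = TRUE)

snv_line <- function(chrom, pos, ref, alt, gts) {
  c(chrom, fmt_pos(pos), ".", ref, alt, ".", "PASS", ".", "GT:GQ", gts)
}

sv_line <- function(chrom, pos, alt, info, gts, id = ".") {
  c(chrom, fmt_pos(pos), id, "N", alt, ".", "PASS", info, "GT:GQ", gts)
}

write_ped_fixture <- function(rows,
                              path = withr::local_tempfile(fileext = ".ped",
                                .local_envir = parent.frame())) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

trio_ped <- function(case_id = "FAM1", prefix = "S") {
  write_ped_fixture(list(
    c(case_id, paste0(prefix, 1), paste0(prefix, 2), paste0(prefix, 3), "1", "2"),
    c(case_id, paste0(prefix, 2), "0", "0", "1", "1"),
    c(case_id, paste0(prefix, 3), "0", "0", "2", "1")
  ), path = withr::local_tempfile(fileext = ".ped",
                                  .local_envir = parent.frame()))
}

singleton_ped <- function(case_id, ind_id = paste0(case_id, "_1")) {
  structure(list(case_id = case_id, individuals = data.frame(
    ind_id = ind_id, father_id = NA_character_, mother_id = NA_character_,
    sex = "0", affected = TRUE, stringsAsFactors = FALSE)),
    class = "pedigree")
}

# a one-sample in-memory VCF from a record table (columns chrom,pos,ref,alt,
# optional info, gt, gq)
singleton_vcf <- function(rec, ind_id, mode = "auto") {
  gt <- if (is.null(rec$gt)) "0/1" else rec$gt
  gq <- if (is.null(rec$gq)) 99L else rec$gq
  fix <- cbind(CHROM = as.character(rec$chrom), POS = as.character(rec$pos),
               ID = ".", REF = rec$ref, ALT = rec$alt, QUAL = ".",
               FILTER = "PASS",
               INFO = if (is.null(rec$info)) "." else rec$info)
  gtm <- cbind("GT:GQ", paste0(gt, ":", gq))
  colnames(gtm) <- c("FORMAT", ind_id)
  varobs:::new_vcf_data(character(), fix, gtm, mode = mode,
                        source = "fixture")
}

# dump a store and return its bytes with load timestamps blanked
dump_lines <- function(store) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  store_dump(store, d)
  lines <- unlist(lapply(c("meta.json", "cases.jsonl", "snv.jsonl",
                           "sv_clusters.jsonl"),
                         function(f) readLines(file.path(d, f))))
  gsub('"loaded_at":"[^"]*"', '"loaded_at":""', lines)
}

sv_row <- function(sv_type, chrom_a, pos_a, chrom_b = chrom_a, pos_b,
                   length = pos_b - pos_a + 1) {
  data.frame(sv_type = sv_type, chrom_a = chrom_a, pos_a = pos_a,
             chrom_b = chrom_b, pos_b = pos_b, length = length,
             stringsAsFactors = FALSE)
}
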
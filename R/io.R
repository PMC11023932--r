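# readers/writers for the package's external formats: FASTA references,
# FASTQ reads, YAML design files, TSV tallies.

#' Read amplicon references from FASTA
#'
#' @param path FASTA path.
#' @return Named list of [amplicon_reference()] objects.
#' @export
read_amplicon_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i)
    amplicon_reference(names(ss)[i], as.character(ss[[i]])))
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Write amplicon references to FASTA
#'
#' @param amplicons List of [amplicon_reference()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_fasta <- function(amplicons, path) {
  if (inherits(amplicons, "amplicon_reference")) amplicons <- list(amplicons)
  ss <- Biostrings::DNAStringSet(vapply(amplicons, `[[`, character(1),
                                        "sequence"))
  names(ss) <- vapply(amplicons, `[[`, character(1), "name")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read reads from FASTQ (Phred+33)
#'
#' @param path FASTQ path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_reads_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  data.frame(id = names(ss),
             seq = as.character(ss),
             qual = as.character(S4Vectors::mcols(ss)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  q <- Biostrings::PhredQuality(reads$qual)
  qss <- Biostrings::QualityScaledDNAStringSet(ss, q)
  Biostrings::writeQualityScaledXStringSet(qss, path)
  invisible(path)
}

#' Read a pegRNA design from YAML
#'
#' Expected keys: `spacer`, `pbs_len`, `rt_template`, `edit_type`,
#' `position_rel_nick`, `ref_allele`, `alt_allele`; optional `pam_pattern`
#' (default NGG) and `window_half_width` (default 10).
#'
#' @param path YAML path.
#' @return List with `design` (a [pegrna_design()]) and `half_width`.
#' @export
read_design_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("spacer", "pbs_len", "rt_template", "edit_type",
            "position_rel_nick")
  miss <- setdiff(need, names(y))
  if (length(miss))
    pq_stop(sprintf("design file lacks keys: %s", paste(miss, collapse = ",")),
            "bad_input")
  edit <- edit_spec(y$edit_type, y$position_rel_nick,
                    ref_allele = if (is.null(y$ref_allele)) "" else y$ref_allele,
                    alt_allele = if (is.null(y$alt_allele)) "" else y$alt_allele)
  design <- pegrna_design(
    spacer = y$spacer, pbs_len = y$pbs_len, rt_template = y$rt_template,
    intended_edit = edit,
    pam_pattern = if (is.null(y$pam_pattern)) "NGG" else y$pam_pattern)
  list(design = design,
       half_width = if (is.null(y$window_half_width)) 10L
                    else as.integer(y$window_half_width))
}

#' Write a pegRNA design to YAML
#'
#' @param design A [pegrna_design()].
#' @param path Output path.
#' @param half_width Window half-width to record, default 10.
#' @return `path`, invisibly.
#' @export
write_design_yaml <- function(design, path, half_width = 10L) {
  e <- design$intended_edit
  yaml::write_yaml(list(
    spacer = design$spacer, pam_pattern = design$pam_pattern,
    pbs_len = design$pbs_len, rt_template = design$rt_template,
    edit_type = e$edit_type, position_rel_nick = e$position_rel_nick,
    ref_allele = e$ref_allele, alt_allele = e$alt_allele,
    window_half_width = as.integer(half_width)), path)
  invisible(path)
}

#' One-row TSV summary of an outcome tally
#'
#' @param tally An `outcome_tally` from [tally_outcomes()].
#' @param sample Sample label.
#' @return data.frame with one row: class counts and the five frequencies.
#' @export
tally_row <- function(tally, sample = "sample") {
  stopifnot(inherits(tally, "outcome_tally"))
  cbind(data.frame(sample = sample, n_reads = tally$n_reads,
                   n_aligned = tally$n_aligned),
        as.data.frame(as.list(tally$counts)),
        as.data.frame(as.list(tally$frequencies)))
}

#' Read a screen count table from TSV
#'
#' @param path TSV with columns `sgrna_id`, `gene`, `tss`, `non_targeting`,
#'   `count_pos`, `count_neg`.
#' @return Validated `data.table`.
#' @export
read_screen_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("gene", "tss")))
  if (is.null(dt$gene)) dt$gene <- ""
  if (is.null(dt$tss)) dt$tss <- ""
  dt$gene[is.na(dt$gene)] <- ""
  dt$tss[is.na(dt$tss)] <- ""
  screen_count_table(dt)
}
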
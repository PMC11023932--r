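# domain types: amplicon references, edit specifications, pegRNA designs,
# quantification windows.  Coordinates are 0-based half-open throughout.

#' Read-outcome classes
#'
#' Every amplicon read is assigned exactly one of these classes:
#' `HDR_CLEAN` (intended edit, no indel in the quantification window),
#' `HDR_INDEL` (intended edit plus a window indel), `REF_INDEL`
#' (reference allele with a window indel), `REF_CLEAN` (unedited),
#' `DISCARDED_QUALITY` (failed the mean-quality filter) and `UNALIGNED`
#' (below the alignment identity floor for both alleles).
#' @export
READ_CLASSES <- c("HDR_CLEAN", "HDR_INDEL", "REF_INDEL", "REF_CLEAN",
                  "DISCARDED_QUALITY", "UNALIGNED")

#' Construct an amplicon reference
#'
#' @param name Identifier.
#' @param sequence DNA string over A/C/G/T/N; lowercase is normalised to
#'   uppercase.
#' @return An `amplicon_reference` object (list with `name`, `sequence`,
#'   `length`).
#' @examples
#' amplicon_reference("amp1", "acgtACGT")
#' @export
amplicon_reference <- function(name, sequence) {
  sequence <- normalize_dna(sequence)
  assert_dna(sequence, "sequence")
  structure(list(name = as.character(name), sequence = sequence,
                 length = nchar(sequence)),
            class = "amplicon_reference")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("<amplicon_reference> %s (%d bp)\n", x$name, x$length))
  invisible(x)
}

#' Specify an intended prime edit
#'
#' Positions are counted on the nicked strand: +1 is the first base 3' of
#' the pegRNA nick.
#'
#' @param edit_type One of `"substitution"`, `"insertion"`, `"deletion"`.
#' @param position_rel_nick Integer >= 1.
#' @param ref_allele Reference base(s) replaced/removed; empty for insertion.
#' @param alt_allele Installed base(s); empty for deletion.
#' @return An `edit_spec` object.
#' @examples
#' edit_spec("substitution", 7, "GG", "CA")   # the +7 GG-to-CA edit
#' edit_spec("insertion", 1, "", "CAT")
#' @export
edit_spec <- function(edit_type = c("substitution", "insertion", "deletion"),
                      position_rel_nick, ref_allele = "", alt_allele = "") {
  edit_type <- match.arg(edit_type)
  position_rel_nick <- as.integer(position_rel_nick)
  if (is.na(position_rel_nick) || position_rel_nick < 1L)
    pq_stop("'position_rel_nick' must be an integer >= 1 (+1 = first base 3' of the nick)",
            "bad_input")
  ref_allele <- normalize_dna(ref_allele)
  alt_allele <- normalize_dna(alt_allele)
  if (nchar(ref_allele)) assert_dna(ref_allele, "ref_allele", allow_n = FALSE)
  if (nchar(alt_allele)) assert_dna(alt_allele, "alt_allele", allow_n = FALSE)
  ok <- switch(edit_type,
    substitution = nchar(ref_allele) > 0L &&
      nchar(ref_allele) == nchar(alt_allele),
    insertion = nchar(ref_allele) == 0L && nchar(alt_allele) > 0L,
    deletion = nchar(ref_allele) > 0L && nchar(alt_allele) == 0L)
  if (!ok)
    pq_stop(sprintf("invalid ref/alt alleles for a %s", edit_type), "bad_edit")
  structure(list(edit_type = edit_type, position_rel_nick = position_rel_nick,
                 ref_allele = ref_allele, alt_allele = alt_allele),
            class = "edit_spec")
}

#' @export
print.edit_spec <- function(x, ...) {
  cat(sprintf("<edit_spec> +%d %s %s-to-%s\n", x$position_rel_nick,
              x$edit_type,
              if (nchar(x$ref_allele)) x$ref_allele else "-",
              if (nchar(x$alt_allele)) x$alt_allele else "-"))
  invisible(x)
}

#' Describe a pegRNA design
#'
#' @param spacer Spacer sequence (DNA, >= 16 nt; 20 nt is typical).
#' @param pbs_len Primer-binding-site length in nt (>= 1).
#' @param rt_template RT template written 5'->3' as it appears in the pegRNA
#'   3' extension (RNA or DNA alphabet).
#' @param intended_edit An [edit_spec()].
#' @param pam_pattern IUPAC PAM, `"NGG"` for SpCas9 by default; use e.g.
#'   `"NNGRRT"` for SaCas9.
#' @return A `pegrna_design` object.
#' @export
pegrna_design <- function(spacer, pbs_len, rt_template, intended_edit,
                          pam_pattern = "NGG") {
  spacer <- normalize_dna(spacer)
  assert_dna(spacer, "spacer", allow_n = FALSE)
  if (nchar(spacer) < 16L) pq_stop("spacer must be >= 16 nt", "bad_input")
  pbs_len <- as.integer(pbs_len)
  if (is.na(pbs_len) || pbs_len < 1L) pq_stop("pbs_len must be >= 1", "bad_input")
  rt_template <- normalize_dna(rt_template, rna_ok = TRUE)
  if (nchar(rt_template) == 0L)
    pq_stop("rt_template must be non-empty", "empty_template")
  assert_dna(rt_template, "rt_template", allow_n = FALSE)
  pam_pattern <- toupper(pam_pattern)
  if (!nchar(pam_pattern) || grepl("[^ACGTRYSWKMBDHVN]", pam_pattern))
    pq_stop("pam_pattern must be a non-empty IUPAC string", "bad_input")
  stopifnot(inherits(intended_edit, "edit_spec"))
  structure(list(spacer = spacer, pam_pattern = pam_pattern,
                 pbs_len = pbs_len, rt_template = rt_template,
                 intended_edit = intended_edit),
            class = "pegrna_design")
}

#' @export
print.pegrna_design <- function(x, ...) {
  cat(sprintf("<pegrna_design> spacer %s | PAM %s | PBS %d nt | RT template %d nt\n",
              x$spacer, x$pam_pattern, x$pbs_len, nchar(x$rt_template)))
  print(x$intended_edit)
  invisible(x)
}

#' Quantification window around the nick
#'
#' Half-open interval `[center - half_width, center + half_width)` in which
#' indels are scored; reads with window-overlapping indels are "discarded"
#' from clean-edit counting.
#'
#' @param center Cut coordinate (see [nick_position()]).
#' @param half_width Integer >= 1, default 10.
#' @param amplicon_length Optional; when given, the span is clipped to
#'   `[0, amplicon_length)`.
#' @param footprint Optional half-open interval (length-2 integer vector)
#'   that the window must contain; the window is expanded symmetrically
#'   until it does.
#' @return A `quant_window` object with fields `center`, `half_width`,
#'   `start`, `end`.
#' @examples
#' quant_window(37, 10)  # span [27, 47)
#' @export
quant_window <- function(center, half_width = 10L, amplicon_length = NULL,
                         footprint = NULL) {
  center <- as.integer(center)
  half_width <- as.integer(half_width)
  if (is.na(half_width) || half_width < 1L)
    pq_stop("half_width must be >= 1", "bad_input")
  if (!is.null(footprint)) {
    stopifnot(length(footprint) == 2L)
    need <- max(center - footprint[1L], footprint[2L] - center)
    half_width <- max(half_width, as.integer(need))
  }
  start <- center - half_width
  end <- center + half_width
  if (!is.null(amplicon_length)) {
    start <- max(0L, start)
    end <- min(as.integer(amplicon_length), end)
    if (start >= end)
      pq_stop("quantification window falls outside the amplicon", "bad_window")
  }
  structure(list(center = center, half_width = half_width,
                 start = as.integer(start), end = as.integer(end)),
            class = "quant_window")
}

#' @export
print.quant_window <- function(x, ...) {
  cat(sprintf("<quant_window> center %d, half-width %d, span [%d,%d)\n",
              x$center, x$half_width, x$start, x$end))
  invisible(x)
}

#' Alignment scoring parameters
#'
#' Global affine-gap alignment scores used to assign reads to alleles.
#' A gap of length L costs `gap_open + L * gap_extend`; `N` never matches.
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores (penalties
#'   negative).
#' @param min_identity Identity floor below which a read is `UNALIGNED`
#'   (fraction of alignment columns with matching bases; default 0.6).
#' @param tie Allele assigned when both alignment scores tie: `"ref"`
#'   (default, conservative) or `"hdr"`.
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(match = 5L, mismatch = -4L, gap_open = -20L,
                             gap_extend = -2L, min_identity = 0.6,
                             tie = c("ref", "hdr")) {
  tie <- match.arg(tie)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_identity = min_identity, tie = tie),
            class = "alignment_params")
}
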
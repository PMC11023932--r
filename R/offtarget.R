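# offtarget_flap: derive the 3' DNA flap from the pegRNA extension, walk it
# along an off-target amplicon from the nick to the first mismatching
# (diagnostic) nucleotide, and count converted reads.

#' 3' DNA flap encoded by a pegRNA design
#'
#' The reverse transcriptase copies the RT template into DNA; the resulting
#' 3' flap, written 5'->3' along the nicked strand starting at the base 3'
#' of the nick, is the reverse complement of the RT template (U pairs as A).
#'
#' @param design A [pegrna_design()] (or a character RT template).
#' @return Character scalar, the flap sequence 5'->3'.
#' @examples
#' flap_from_design("UCGAG")  # "CTCGA"
#' @export
flap_from_design <- function(design) {
  rt <- if (inherits(design, "pegrna_design")) design$rt_template
        else normalize_dna(design, rna_ok = TRUE)
  if (!nchar(rt)) pq_stop("RT template is empty", "empty_template")
  assert_dna(rt, "rt_template", allow_n = FALSE)
  revcomp(rt)
}

#' Find the diagnostic nucleotide of an off-target site
#'
#' Walks the flap along the off-target amplicon from the nucleotide 3' of
#' the nick (on the nicked strand) and returns the first position at which
#' the amplicon differs from the flap.  Reads converted at this position are
#' the off-target reads.
#'
#' @param amplicon The off-target [amplicon_reference()].
#' @param cut Cut coordinate from [nick_position()] on the off-target hit.
#' @param strand Strand of the off-target protospacer hit.
#' @param flap Flap sequence from [flap_from_design()].
#' @return A `diagnostic_site`: list with `offset` (0-based distance from
#'   the nick), `expected_base` and `ref_base` (on the nicked strand), and
#'   `plus_pos`/`plus_expected`/`plus_ref` (the same site expressed on the
#'   + strand of the stored amplicon).
#' @export
find_diagnostic_site <- function(amplicon, cut, strand, flap) {
  stopifnot(inherits(amplicon, "amplicon_reference"), strand %in% c("+", "-"))
  assert_dna(flap, "flap", allow_n = FALSE)
  L <- amplicon$length
  n <- nchar(flap)
  for (i in seq_len(n) - 1L) {
    pos <- if (strand == "+") cut + i else cut - 1L - i
    if (pos < 0L || pos >= L)
      pq_stop("off-target amplicon ends before a diagnostic site is reached",
              "out_of_bounds")
    plus_base <- substr(amplicon$sequence, pos + 1L, pos + 1L)
    ref_base <- if (strand == "+") plus_base else revcomp(plus_base)
    fb <- substr(flap, i + 1L, i + 1L)
    # N in the amplicon is treated as a mismatch (never "converted")
    if (fb != ref_base) {
      return(structure(list(
        offset = i, expected_base = fb, ref_base = ref_base,
        plus_pos = pos,
        plus_expected = if (strand == "+") fb else revcomp(fb),
        plus_ref = plus_base, strand = strand),
        class = "diagnostic_site"))
    }
  }
  pq_stop("flap matches the off-target amplicon over its whole length; no diagnostic nucleotide",
          "no_diagnostic_site")
}

#' @export
print.diagnostic_site <- function(x, ...) {
  cat(sprintf("<diagnostic_site> offset +%d from nick: expected %s, reference %s (%s strand)\n",
              x$offset, x$expected_base, x$ref_base, x$strand))
  invisible(x)
}

#' Off-target conversion frequency at a diagnostic site
#'
#' Reads are aligned to the off-target reference only.  Reads with a
#' window-overlapping indel are counted in `n_indel` and excluded from base
#' calling; remaining aligned reads carrying the flap base at the
#' diagnostic coordinate are `n_converted`.  The off-target frequency is
#' `(n_converted + n_indel) / n_aligned`.  A read is counted at most once
#' (converted reads that also carry a window indel count as indel reads).
#'
#' @param seqs Character vector of read sequences.
#' @param quals Per-read Phred list or `NULL`.
#' @param amplicon Off-target [amplicon_reference()].
#' @param site [find_diagnostic_site()] result.
#' @param window [quant_window()] on the off-target amplicon.
#' @param min_mean_q Mean-quality threshold (default 30).
#' @param params [alignment_params()].
#' @return An `offtarget_tally`: list with `n_reads`, `n_aligned`,
#'   `n_converted`, `n_indel`, `f_offtarget` and the `site`.
#' @export
offtarget_frequency <- function(seqs, quals, amplicon, site, window,
                                min_mean_q = 30, params = alignment_params()) {
  stopifnot(inherits(site, "diagnostic_site"), inherits(window, "quant_window"))
  keep <- rep(TRUE, length(seqs))
  if (!is.null(quals))
    keep <- vapply(quals, function(q) passes_quality(q, min_mean_q), logical(1))
  seqs <- seqs[keep]
  res <- cpp_offtarget_batch(seqs, amplicon$sequence, window$start, window$end,
                             site$plus_pos, params$min_identity,
                             params$match, params$mismatch,
                             params$gap_open, params$gap_extend)
  n_aligned <- sum(res$status != 0L)
  if (n_aligned == 0L)
    pq_stop("no reads aligned to the off-target amplicon", "zero_aligned")
  n_indel <- sum(res$status == 1L)
  n_converted <- sum(res$status == 2L & res$base == site$plus_expected)
  structure(list(n_reads = length(keep), n_aligned = n_aligned,
                 n_converted = n_converted, n_indel = n_indel,
                 f_offtarget = (n_converted + n_indel) / n_aligned,
                 site = site),
            class = "offtarget_tally")
}

#' @export
print.offtarget_tally <- function(x, ...) {
  cat(sprintf("<offtarget_tally> %d aligned: %d converted, %d indel; f_offtarget = %.4f\n",
              x$n_aligned, x$n_converted, x$n_indel, x$f_offtarget))
  invisible(x)
}

#' Quantify off-target prime editing for one amplicon/design/read set
#'
#' Pipeline: locate the off-target protospacer, derive the nick and the 3'
#' flap, find the diagnostic nucleotide, and count converted and
#' indel-containing reads.
#'
#' @inheritParams quantify_amplicon
#' @param half_width Window half-width for the indel check (default 10,
#'   mirroring the on-target convention).
#' @return List with `tally` (an `offtarget_tally`), `hit`, `cut`, `site`,
#'   `window`.
#' @export
quantify_offtarget <- function(amplicon, design, reads, half_width = 10L,
                               min_mean_q = 30, params = alignment_params()) {
  hit <- locate_protospacer(amplicon, design)
  cut <- nick_position(hit)
  flap <- flap_from_design(design)
  site <- find_diagnostic_site(amplicon, cut, hit$strand, flap)
  window <- quant_window(cut, half_width, amplicon$length)
  tally <- offtarget_frequency(reads$seq, read_quals(reads), amplicon, site,
                               window, min_mean_q, params)
  list(tally = tally, hit = hit, cut = cut, site = site, window = window)
}
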
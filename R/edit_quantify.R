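# edit_quantify: locate the protospacer, derive the nick, build the expected
# edited allele, align reads to both alleles and tally outcome frequencies.

#' Locate a protospacer + PAM on an amplicon
#'
#' Exact search for the spacer followed (3' on the hit strand) by a PAM
#' matching the design's IUPAC pattern, over both strands.  Coordinates are
#' reported on the + strand of the amplicon, 0-based half-open.
#'
#' @param amplicon An [amplicon_reference()].
#' @param design A [pegrna_design()].
#' @return A `protospacer_hit`: list with `start`, `end`, `strand`,
#'   `pam_start`, `pam_end`.
#' @export
locate_protospacer <- function(amplicon, design) {
  stopifnot(inherits(amplicon, "amplicon_reference"),
            inherits(design, "pegrna_design"))
  seqstr <- amplicon$sequence
  spacer <- design$spacer
  plen <- nchar(design$pam_pattern)
  slen <- nchar(spacer)
  hits <- list()
  # + strand: spacer at [s,e), PAM at [e, e+plen)
  for (s in find_all_fixed(seqstr, spacer)) {
    e <- s + slen
    if (e + plen <= amplicon$length &&
        iupac_match_str(design$pam_pattern,
                        substr(seqstr, e + 1L, e + plen))) {
      hits[[length(hits) + 1L]] <- list(start = s, end = e, strand = "+",
                                        pam_start = e, pam_end = e + plen)
    }
  }
  # - strand: revcomp(spacer) at [s,e) on +, PAM revcomp-pattern at [s-plen, s)
  rc_spacer <- revcomp(spacer)
  rc_pam <- revcomp(design$pam_pattern)
  for (s in find_all_fixed(seqstr, rc_spacer)) {
    e <- s + slen
    if (s - plen >= 0L &&
        iupac_match_str(rc_pam, substr(seqstr, s - plen + 1L, s))) {
      hits[[length(hits) + 1L]] <- list(start = s, end = e, strand = "-",
                                        pam_start = s - plen, pam_end = s)
    }
  }
  if (length(hits) == 0L)
    pq_stop("spacer+PAM not found on either strand of the amplicon", "not_found")
  if (length(hits) > 1L)
    pq_stop(sprintf("spacer+PAM found %d times; amplicon is ambiguous",
                    length(hits)), "ambiguous")
  structure(c(hits[[1L]], list(spacer_length = slen)),
            class = "protospacer_hit")
}

# all 0-based start positions of fixed pattern p in x
find_all_fixed <- function(x, p) {
  m <- gregexpr(p, x, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

#' Nick (cut) coordinate of a protospacer hit
#'
#' The Cas9 nickase cleaves the protospacer-containing strand 3 nt 5' of the
#' PAM.  The returned coordinate `c` means the nicked strand is cleaved
#' between + strand positions `c - 1` and `c`; edit position +1 is the first
#' base 3' of the cut on the nicked strand.
#'
#' @param hit A `protospacer_hit` from [locate_protospacer()].
#' @return Integer cut coordinate.
#' @examples
#' # + strand hit, protospacer [20,40), PAM [40,43) -> cut at 37
#' @export
nick_position <- function(hit) {
  stopifnot(inherits(hit, "protospacer_hit"))
  if (hit$strand == "+") hit$pam_start - 3L else hit$pam_end + 3L
}

# + strand half-open footprint of the edit on the reference allele and the
# length change on the edited allele
edit_footprint <- function(cut, strand, edit) {
  k <- edit$position_rel_nick
  nref <- nchar(edit$ref_allele)
  if (strand == "+") {
    s <- cut + k - 1L
    c(s, s + max(nref, 1L))
  } else {
    e <- cut - k + 1L
    c(e - max(nref, 1L), e)
  }
}

#' Build the expected edited (HDR) allele
#'
#' Applies the intended edit to the amplicon at the position implied by the
#' cut coordinate and strand, returning the + strand sequence of the
#' expected allele.  Substitution/deletion `ref_allele` must match the
#' amplicon on the nicked strand.
#'
#' @param amplicon An [amplicon_reference()].
#' @param cut Cut coordinate from [nick_position()].
#' @param strand `"+"` or `"-"` (strand of the protospacer hit).
#' @param edit An [edit_spec()].
#' @return Character scalar, the edited amplicon sequence on the + strand.
#' @export
build_edited_allele <- function(amplicon, cut, strand, edit) {
  stopifnot(inherits(amplicon, "amplicon_reference"),
            inherits(edit, "edit_spec"), strand %in% c("+", "-"))
  seqstr <- amplicon$sequence
  if (strand == "-") {
    # operate on the nicked strand: mirror, apply + strand logic, mirror back
    rc <- revcomp(seqstr)
    out <- apply_edit_plus(rc, amplicon$length - cut, edit)
    return(revcomp(out))
  }
  apply_edit_plus(seqstr, cut, edit)
}

apply_edit_plus <- function(seqstr, cut, edit) {
  L <- nchar(seqstr)
  k <- edit$position_rel_nick
  pos <- cut + k - 1L # 0-based index of the first edited/insertion-point base
  nref <- nchar(edit$ref_allele)
  if (pos < 0L || pos + nref > L ||
      (edit$edit_type == "insertion" && pos > L))
    pq_stop("edit footprint exceeds the amplicon", "out_of_bounds")
  if (edit$edit_type %in% c("substitution", "deletion")) {
    found <- substr(seqstr, pos + 1L, pos + nref)
    if (found != edit$ref_allele)
      pq_stop(sprintf("ref_allele '%s' does not match amplicon ('%s' at %d)",
                      edit$ref_allele, found, pos), "ref_mismatch")
  }
  switch(edit$edit_type,
    substitution = paste0(substr(seqstr, 1L, pos), edit$alt_allele,
                          substr(seqstr, pos + nref + 1L, L)),
    insertion = paste0(substr(seqstr, 1L, pos), edit$alt_allele,
                       substr(seqstr, pos + 1L, L)),
    deletion = paste0(substr(seqstr, 1L, pos),
                      substr(seqstr, pos + nref + 1L, L)))
}

#' Mean-quality read filter
#'
#' A read passes iff its mean Phred quality is at least `min_mean_q`
#' (the "-q 30" semantics: whole-read mean, no per-base masking).
#'
#' @param quals Numeric vector of per-base Phred scores.
#' @param min_mean_q Threshold, default 30.
#' @return Logical scalar.
#' @export
passes_quality <- function(quals, min_mean_q = 30) {
  if (length(quals) == 0L) pq_stop("zero-length read", "empty_read")
  if (any(quals < 0)) pq_stop("negative Phred score", "bad_input")
  mean(quals) >= min_mean_q
}

#' Align a read to both alleles and assign it
#'
#' Global affine-gap alignment of the read against the reference and the
#' expected-edit (HDR) alleles; the read is assigned to the higher-scoring
#' allele (ties go to `params$tie`), or to neither (`NONE`) when the best
#' alignment's identity is below `params$min_identity`.
#'
#' @param read_seq Read sequence (character scalar).
#' @param ref_seq,hdr_seq The two candidate allele sequences.
#' @param params [alignment_params()].
#' @return A `pe_assignment`: list with `assigned` (`"REF"`, `"HDR"` or
#'   `"NONE"`), `score_ref`, `score_hdr`, `identity`, and `alignment`
#'   (gapped `pattern`/`subject` strings of the assigned allele; of the
#'   reference if unassigned).
#' @export
align_and_assign <- function(read_seq, ref_seq, hdr_seq,
                             params = alignment_params()) {
  assert_dna(read_seq, "read_seq")
  ar <- cpp_align(read_seq, ref_seq, params$match, params$mismatch,
                  params$gap_open, params$gap_extend)
  ah <- cpp_align(read_seq, hdr_seq, params$match, params$mismatch,
                  params$gap_open, params$gap_extend)
  to_hdr <- if (params$tie == "ref") ah$score > ar$score else ah$score >= ar$score
  best <- if (to_hdr) ah else ar
  assigned <- if (best$identity < params$min_identity) "NONE"
              else if (to_hdr) "HDR" else "REF"
  structure(list(assigned = assigned, score_ref = ar$score,
                 score_hdr = ah$score, identity = best$identity,
                 alignment = list(pattern = best$pattern,
                                  subject = best$subject)),
            class = "pe_assignment")
}

#' Indels of a gapped alignment in reference coordinates
#'
#' @param pattern,subject Gapped read/reference strings of equal length.
#' @return data.frame with columns `type` (`"insertion"`/`"deletion"`),
#'   `ref_start`, `ref_end` (half-open; for insertions both equal the
#'   position after the left anchor), `anchor` (left-anchor reference
#'   coordinate for insertions, `NA` for deletions), `length`.
#' @export
alignment_indels <- function(pattern, subject) {
  p <- strsplit(pattern, "")[[1L]]
  s <- strsplit(subject, "")[[1L]]
  stopifnot(length(p) == length(s))
  out <- list()
  ref_pos <- 0L
  i <- 1L
  n <- length(p)
  while (i <= n) {
    if (s[i] == "-") {
      len <- 0L
      while (i <= n && s[i] == "-") { len <- len + 1L; i <- i + 1L }
      out[[length(out) + 1L]] <- data.frame(
        type = "insertion", ref_start = ref_pos, ref_end = ref_pos,
        anchor = ref_pos - 1L, length = len)
    } else if (p[i] == "-") {
      a <- ref_pos
      while (i <= n && i <= n && p[i] == "-" && s[i] != "-") {
        ref_pos <- ref_pos + 1L; i <- i + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        type = "deletion", ref_start = a, ref_end = ref_pos,
        anchor = NA_integer_, length = ref_pos - a)
    } else {
      ref_pos <- ref_pos + 1L; i <- i + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(type = character(), ref_start = integer(),
                      ref_end = integer(), anchor = integer(),
                      length = integer()))
  do.call(rbind, out)
}

#' Classify an assigned read
#'
#' A read is indel-containing iff any insertion or deletion of its alignment
#' overlaps the quantification window on the assigned amplicon: deletions by
#' half-open interval overlap, insertions when their left anchor lies in the
#' window span.  Substitution-only discrepancies never make a read
#' indel-containing.
#'
#' @param assignment A `pe_assignment` from [align_and_assign()].
#' @param window A [quant_window()] defined on the assigned amplicon.
#' @return One of `READ_CLASSES` (`UNALIGNED` for `NONE` assignments).
#' @export
classify_read <- function(assignment, window) {
  stopifnot(inherits(assignment, "pe_assignment"),
            inherits(window, "quant_window"))
  if (assignment$assigned == "NONE") return("UNALIGNED")
  ind <- alignment_indels(assignment$alignment$pattern,
                          assignment$alignment$subject)
  has <- FALSE
  if (nrow(ind)) {
    ins <- ind$type == "insertion"
    hit_ins <- ins & ind$anchor >= window$start & ind$anchor < window$end
    hit_del <- !ins & ind$ref_start < window$end & ind$ref_end > window$start
    has <- any(hit_ins | hit_del)
  }
  if (assignment$assigned == "HDR") {
    if (has) "HDR_INDEL" else "HDR_CLEAN"
  } else {
    if (has) "REF_INDEL" else "REF_CLEAN"
  }
}

#' Tally outcome classes into the five outcome frequencies
#'
#' Denominator `n_aligned` is the number of reads assigned to either allele
#' (`HDR_CLEAN + HDR_INDEL + REF_INDEL + REF_CLEAN`).  The five reported
#' frequencies are: intended editing without indels (`HDR_CLEAN/n_aligned`),
#' intended editing with indels (`HDR_INDEL/n_aligned`), total intended
#' editing, total indels, and indels without intended editing.  Headline
#' reporting follows the convention that "intended edit" means
#' `f_intended_wo_indel` and "indels" means `f_total_indels`.
#'
#' @param classes Character vector of `READ_CLASSES` values.
#' @return An `outcome_tally`: list with `counts` (named integer vector over
#'   all six classes), `n_reads`, `n_aligned` and `frequencies` (named
#'   numeric vector of the five frequencies).
#' @export
tally_outcomes <- function(classes) {
  bad <- setdiff(unique(classes), READ_CLASSES)
  if (length(bad))
    pq_stop(sprintf("unknown read class: %s", paste(bad, collapse = ",")),
            "bad_input")
  counts <- vapply(READ_CLASSES, function(k) sum(classes == k), integer(1))
  n_aligned <- sum(counts[c("HDR_CLEAN", "HDR_INDEL", "REF_INDEL", "REF_CLEAN")])
  if (n_aligned == 0L)
    pq_stop("no reads aligned to either amplicon", "zero_aligned")
  f_hdr_clean <- counts[["HDR_CLEAN"]] / n_aligned
  f_hdr_indel <- counts[["HDR_INDEL"]] / n_aligned
  f_ref_indel <- counts[["REF_INDEL"]] / n_aligned
  # totals are sums of the component frequencies so that the identities
  # f_total_intended = f_intended_wo_indel + f_intended_w_indel and
  # f_total_indels = f_intended_w_indel + f_indels_wo_intended hold
  # bitwise, not merely to rounding
  freqs <- c(
    f_intended_wo_indel = f_hdr_clean,
    f_intended_w_indel = f_hdr_indel,
    f_total_intended = f_hdr_clean + f_hdr_indel,
    f_total_indels = f_hdr_indel + f_ref_indel,
    f_indels_wo_intended = f_ref_indel)
  structure(list(counts = counts, n_reads = length(classes),
                 n_aligned = n_aligned, frequencies = freqs),
            class = "outcome_tally")
}

#' @export
print.outcome_tally <- function(x, ...) {
  cat(sprintf("<outcome_tally> %d reads, %d aligned\n", x$n_reads, x$n_aligned))
  print(x$counts)
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Classify a batch of reads against reference and edited alleles
#'
#' Vectorised pipeline core: quality filter, global alignment to both
#' alleles, identity floor, window-indel scoring.
#'
#' @param seqs Character vector of read sequences.
#' @param quals List of per-base Phred vectors (or `NULL` to skip the
#'   quality filter).
#' @param ref_seq,hdr_seq Allele sequences (+ strand).
#' @param window_ref,window_hdr [quant_window()]s on the respective alleles.
#' @param min_mean_q Mean-quality threshold (default 30).
#' @param params [alignment_params()].
#' @return Character vector of `READ_CLASSES`, one per read.
#' @export
classify_reads <- function(seqs, quals, ref_seq, hdr_seq,
                           window_ref, window_hdr,
                           min_mean_q = 30, params = alignment_params()) {
  n <- length(seqs)
  classes <- rep("DISCARDED_QUALITY", n)
  keep <- rep(TRUE, n)
  if (!is.null(quals)) {
    stopifnot(length(quals) == n)
    keep <- vapply(quals, function(q) passes_quality(q, min_mean_q), logical(1))
  }
  if (any(keep)) {
    res <- cpp_classify_batch(seqs[keep], ref_seq, hdr_seq,
                              window_ref$start, window_ref$end,
                              window_hdr$start, window_hdr$end,
                              params$min_identity, params$tie == "ref",
                              params$match, params$mismatch,
                              params$gap_open, params$gap_extend)
    code <- res$class
    classes[keep] <- c("UNALIGNED", "HDR_CLEAN", "HDR_INDEL",
                       "REF_INDEL", "REF_CLEAN")[code + 1L]
  }
  classes
}

#' Quantify prime-editing outcomes for one amplicon/design/read set
#'
#' Full pipeline: locate the protospacer, derive the nick, build the
#' expected edited allele, centre the quantification window at the nick
#' (auto-expanded to contain the intended-edit footprint and clipped to the
#' amplicon), classify every read and tally the five outcome frequencies.
#'
#' @param amplicon An [amplicon_reference()].
#' @param design A [pegrna_design()].
#' @param reads data.frame with columns `id`, `seq` and either `qual`
#'   (Phred+33 string) or a list-column `quals`; see [read_reads_fastq()].
#' @param half_width Window half-width (default 10; per-edit values may be
#'   supplied when known).
#' @param min_mean_q Mean-quality threshold (default 30).
#' @param params [alignment_params()].
#' @return List with `tally` ([tally_outcomes()] result), `hit`, `cut`,
#'   `hdr_seq`, `window_ref`, `window_hdr`, `classes`.
#' @export
quantify_amplicon <- function(amplicon, design, reads, half_width = 10L,
                              min_mean_q = 30, params = alignment_params()) {
  hit <- locate_protospacer(amplicon, design)
  cut <- nick_position(hit)
  edit <- design$intended_edit
  hdr_seq <- build_edited_allele(amplicon, cut, hit$strand, edit)
  fp_ref <- edit_footprint(cut, hit$strand, edit)
  # footprint on the edited allele: same interval, width of the alt allele
  nalt <- max(nchar(edit$alt_allele), 1L)
  fp_hdr <- if (hit$strand == "+") c(fp_ref[1L], fp_ref[1L] + nalt)
            else c(fp_ref[2L] - nalt, fp_ref[2L])
  window_ref <- quant_window(cut, half_width, amplicon$length, fp_ref)
  window_hdr <- quant_window(cut, half_width, nchar(hdr_seq), fp_hdr)
  quals <- read_quals(reads)
  classes <- classify_reads(reads$seq, quals, amplicon$sequence, hdr_seq,
                            window_ref, window_hdr, min_mean_q, params)
  list(tally = tally_outcomes(classes), hit = hit, cut = cut,
       hdr_seq = hdr_seq, window_ref = window_ref, window_hdr = window_hdr,
       classes = classes)
}

# per-read Phred vectors from a reads data.frame (quals list-column, or
# decoded from a Phred+33 'qual' string column); NULL if neither present
read_quals <- function(reads) {
  if (!is.null(reads$quals)) return(reads$quals)
  if (!is.null(reads$qual)) return(lapply(reads$qual, phred_decode))
  NULL
}

phred_decode <- function(q) as.integer(charToRaw(q)) - 33L
phred_encode <- function(v) rawToChar(as.raw(as.integer(v) + 33L))
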
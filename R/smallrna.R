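# smallrna_integrity: closest-endpoint annotation assignment, three-bin
# activity classification of pegRNA fragments, coverage and 3' integrity.

#' Fragment bins
#'
#' `CIS_ACTIVE`: intact spacer 5' end and intact 3' extension (can direct
#' editing in cis); `TRANS_ACTIVE`: 3' extension intact but 5' end lost;
#' `INACTIVE`: 3' extension truncated.
#' @export
FRAGMENT_BINS <- c("CIS_ACTIVE", "TRANS_ACTIVE", "INACTIVE")

#' Build a fragment table
#'
#' @param ref Reference name(s).
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"`/`"-"` (default `"+"`).
#' @param proper_pair Logical (default `TRUE`).
#' @return data.frame of fragments.
#' @export
fragments <- function(ref, start, end, strand = "+", proper_pair = TRUE) {
  df <- data.frame(ref = as.character(ref), start = as.integer(start),
                   end = as.integer(end), strand = strand,
                   proper_pair = proper_pair, stringsAsFactors = FALSE)
  if (any(df$start < 0L) || any(df$start >= df$end))
    pq_stop("fragments need 0 <= start < end", "bad_input")
  if (!all(df$strand %in% c("+", "-")))
    pq_stop("strand must be '+' or '-'", "bad_input")
  df
}

#' Keep analysable fragments
#'
#' The integrity analysis uses only properly paired, sense-strand fragments.
#'
#' @param frags Fragment data.frame.
#' @return Filtered data.frame.
#' @export
eligible_fragments <- function(frags) {
  frags[frags$proper_pair & frags$strand == "+", , drop = FALSE]
}

#' Assign a fragment to the closest-matching annotation
#'
#' Among annotations the fragment overlaps, returns the one minimising
#' `|frag.start - ann.start| + |frag.end - ann.end|`; ties are broken by the
#' shorter annotation, then lexicographic name.
#'
#' @param start,end Fragment coordinates (0-based half-open).
#' @param annotations data.frame with columns `name`, `start`, `end`.
#' @return The winning annotation name (character scalar).
#' @export
assign_fragment <- function(start, end, annotations) {
  stopifnot(all(c("name", "start", "end") %in% names(annotations)))
  if (anyDuplicated(annotations$name))
    pq_stop("annotation names must be unique", "bad_input")
  ov <- annotations$start < end & annotations$end > start
  if (!any(ov))
    pq_stop("fragment overlaps no annotation", "no_overlap")
  a <- annotations[ov, , drop = FALSE]
  d <- abs(start - a$start) + abs(end - a$end)
  o <- order(d, a$end - a$start, a$name)
  a$name[o[1L]]
}

#' Vectorised closest-annotation assignment
#'
#' @param frags Fragment data.frame.
#' @param annotations Annotation data.frame (`name`, `start`, `end`).
#' @return Character vector of annotation names (`NA` where a fragment
#'   overlaps none).
#' @export
assign_fragments <- function(frags, annotations) {
  vapply(seq_len(nrow(frags)), function(i) {
    tryCatch(assign_fragment(frags$start[i], frags$end[i], annotations),
             pq_no_overlap = function(e) NA_character_)
  }, character(1))
}

#' Region map of a pegRNA reference
#'
#' Tiles the pegRNA 5'->3' as spacer, scaffold, RT template, PBS and an
#' optional 3' motif (e.g. a structured epegRNA motif or polyU tract).
#' Tolerances (nt) define how much 5'/3' erosion still counts as intact.
#'
#' @param spacer_len,scaffold_len,rt_len,pbs_len,motif_len Region lengths
#'   in nt (motif optional, 0 to omit).
#' @param start_tol,end_tol 5'/3' tolerances in nt, default 3 each.
#' @return A `peg_region_map`: list with `regions` (data.frame `name`,
#'   `start`, `end`), `length`, `start_tol`, `end_tol`.
#' @export
peg_region_map <- function(spacer_len = 20L, scaffold_len = 76L,
                           rt_len = 13L, pbs_len = 13L, motif_len = 0L,
                           start_tol = 3L, end_tol = 3L) {
  lens <- c(spacer = spacer_len, scaffold = scaffold_len,
            rt_template = rt_len, pbs = pbs_len, motif = motif_len)
  lens <- lens[lens > 0L]
  if (!length(lens)) pq_stop("all regions empty", "bad_input")
  ends <- cumsum(as.integer(lens))
  starts <- c(0L, ends[-length(ends)])
  structure(list(regions = data.frame(name = names(lens), start = starts,
                                      end = ends, row.names = NULL),
                 length = ends[[length(ends)]],
                 start_tol = as.integer(start_tol),
                 end_tol = as.integer(end_tol)),
            class = "peg_region_map")
}

#' @export
print.peg_region_map <- function(x, ...) {
  cat(sprintf("<peg_region_map> %d nt, tolerances 5' %d / 3' %d\n",
              x$length, x$start_tol, x$end_tol))
  print(x$regions)
  invisible(x)
}

#' Bin pegRNA fragments by inferred functional capacity
#'
#' Default rule (configurable through the region map's tolerances):
#' `CIS_ACTIVE` iff `start <= start_tol` and `end >= L - end_tol` (5' end of
#' the spacer and the 3' extension both intact); `TRANS_ACTIVE` iff
#' `end >= L - end_tol` with `start > start_tol` (extension intact, 5'
#' lost); `INACTIVE` otherwise (3' extension truncated).
#'
#' @param frags Fragment data.frame (use [eligible_fragments()] first for
#'   raw alignments).
#' @param regions A [peg_region_map()].
#' @return Character vector over `FRAGMENT_BINS`, one per fragment.
#' @export
bin_fragments <- function(frags, regions) {
  stopifnot(inherits(regions, "peg_region_map"))
  L <- regions$length
  tail_ok <- frags$end >= L - regions$end_tol
  head_ok <- frags$start <= regions$start_tol
  ifelse(tail_ok & head_ok, "CIS_ACTIVE",
         ifelse(tail_ok, "TRANS_ACTIVE", "INACTIVE"))
}

#' Per-position fragment coverage
#'
#' Position `p` is covered by a fragment iff `start <= p < end`; the sum of
#' the profile equals the summed fragment lengths exactly.
#'
#' @param frags Fragment data.frame.
#' @param L Reference length.
#' @return Integer vector of length `L`.
#' @export
coverage_profile <- function(frags, L) {
  L <- as.integer(L)
  if (nrow(frags) == 0L) return(integer(L))
  if (any(frags$start < 0L) || any(frags$end > L))
    pq_stop("fragment outside [0, L)", "out_of_bounds")
  cov <- IRanges::coverage(IRanges::IRanges(start = frags$start + 1L,
                                            end = frags$end),
                           width = L)
  as.integer(cov)
}

#' Fraction of fragments with an intact 3' end
#'
#' Summary of 3' integrity: the fraction of fragments whose end reaches
#' within `tol` nt of the reference 3' terminus.
#'
#' @param frags Fragment data.frame.
#' @param L Reference length.
#' @param tol Tolerance in nt, default 3.
#' @return Proportion in `[0, 1]`.
#' @export
three_prime_intact_fraction <- function(frags, L, tol = 3L) {
  if (nrow(frags) == 0L) pq_stop("no fragments", "empty_input")
  mean(frags$end >= L - tol)
}

#' Read fragments from a BED3+/TSV file
#'
#' Accepts BED (ref, start, end and optionally name, score, strand) or a
#' TSV with headered columns `ref`, `start`, `end` and optionally `strand`,
#' `proper_pair`.
#'
#' @param path File path.
#' @return Fragment data.frame.
#' @export
read_fragments <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^(ref|#?chrom)\\b", first) || grepl("\tstart\t", first)) {
    dt <- data.table::fread(path, sep = "\t")
    data.table::setnames(dt, names(dt)[1L], "ref")
    fragments(dt$ref, dt$start, dt$end,
              strand = if (!is.null(dt$strand)) dt$strand else "+",
              proper_pair = if (!is.null(dt$proper_pair))
                as.logical(dt$proper_pair) else TRUE)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = FALSE)
    strand <- if (ncol(dt) >= 6L) dt[[6L]] else "+"
    fragments(dt[[1L]], dt[[2L]], dt[[3L]], strand = strand)
  }
}

#' Extract proper-pair fragments from a BAM/SAM file
#'
#' Uses Rsamtools to read concordantly aligned ("proper pair") alignments
#' and reduces each pair to the interval its fragment spans: one record per
#' pair is kept (the forward-oriented leftmost mate, positive template
#' length), giving the half-open interval [pos - 1, pos - 1 + TLEN).  The
#' fragment is sense-strand ("+") when that leftmost forward read is the
#' first mate of its pair.
#'
#' @param path BAM or SAM path (SAM files are converted on the fly).
#' @param min_mapq Minimum mapping quality, default 0.
#' @return Fragment data.frame.
#' @export
read_fragments_bam <- function(path, min_mapq = 0L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    pq_stop("Rsamtools is required for BAM/SAM input", "bad_input")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, destination = tempfile(),
                             overwrite = TRUE, indexDestination = FALSE)
  }
  # keep one record per pair: the forward-oriented leftmost mate (TLEN > 0)
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isMinusStrand = FALSE)
  par <- Rsamtools::ScanBamParam(flag = flag,
                                 what = c("rname", "pos", "isize",
                                          "flag", "mapq"))
  b <- Rsamtools::scanBam(path, param = par)[[1L]]
  keep <- !is.na(b$pos) & !is.na(b$isize) & b$isize > 0L &
    (is.na(b$mapq) | b$mapq >= min_mapq)
  first_mate <- bitwAnd(b$flag[keep], 64L) > 0L
  start <- b$pos[keep] - 1L
  fragments(as.character(b$rname)[keep], start, start + b$isize[keep],
            strand = ifelse(first_mate, "+", "-"), proper_pair = TRUE)
}

#' Summarise fragment bins
#'
#' @param bins Character vector over `FRAGMENT_BINS`.
#' @return Named list with counts and proportions per bin.
#' @export
bin_summary <- function(bins) {
  counts <- vapply(FRAGMENT_BINS, function(b) sum(bins == b), integer(1))
  list(counts = counts, proportions = counts / max(sum(counts), 1L),
       n = sum(counts))
}
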
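# synthetic_data: seeded generators for amplicon reads, screen count tables
# and pegRNA fragments, each emitting a truth table.

#' Programmed outcome mixture for simulated amplicon reads
#'
#' @param p_hdr_clean,p_hdr_indel,p_ref_indel,p_ref_clean Class proportions
#'   (must sum to 1).
#' @param error_rate Per-base substitution sequencing-error rate, in
#'   `[0, 0.05]` (default 0.001, i.e. 0.1%).
#' @param indel_lengths Candidate window-indel lengths for the indel
#'   classes (default 1-5 nt, uniform).
#' @param p_deletion Probability a class-required indel is a deletion
#'   (default 2/3, i.e. deletion:insertion = 2:1).
#' @return An `outcome_mixture` list.
#' @export
outcome_mixture <- function(p_hdr_clean = 0.25, p_hdr_indel = 0.05,
                            p_ref_indel = 0.10, p_ref_clean = 0.60,
                            error_rate = 0.001, indel_lengths = 1:5,
                            p_deletion = 2 / 3) {
  p <- c(HDR_CLEAN = p_hdr_clean, HDR_INDEL = p_hdr_indel,
         REF_INDEL = p_ref_indel, REF_CLEAN = p_ref_clean)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    pq_stop("mixture proportions must be >= 0 and sum to 1", "bad_config")
  if (error_rate < 0 || error_rate > 0.05)
    pq_stop("error_rate must be in [0, 0.05]", "bad_config")
  structure(list(proportions = p, error_rate = error_rate,
                 indel_lengths = as.integer(indel_lengths),
                 p_deletion = p_deletion),
            class = "outcome_mixture")
}

#' Simulate amplicon reads from a programmed outcome mixture
#'
#' Each read's true class is drawn from the mixture.  HDR classes start
#' from the expected edited allele, REF classes from the reference; the
#' indel classes receive one uniform-length indel placed uniformly within
#' the quantification window.  Indels never overlap the intended-edit
#' footprint: a window indel that erased the edited bases would make the
#' "edited with indel" and "indel only" classes indistinguishable, so the
#' generator keeps the programmed classes observable.  Finally i.i.d.
#' substitution errors are applied at `error_rate` per base.  Reads span
#' the full amplicon (pre-merged amplicon sequencing).
#'
#' @param amplicon An [amplicon_reference()].
#' @param design A [pegrna_design()].
#' @param mixture An [outcome_mixture()].
#' @param n Number of reads.
#' @param seed Integer seed; generation is deterministic and leaves the
#'   global RNG untouched.
#' @param half_width Quantification-window half-width used to place indels
#'   (default 10, matching the quantifier's default).
#' @param quality Constant Phred score for simulated bases (default 37).
#' @param vary_quality Draw per-base qualities uniformly from
#'   `quality - 5 .. quality` instead, to exercise the quality filter.
#' @return List with `reads` (data.frame `id`, `seq`, `qual`) and `truth`
#'   (data.frame `id`, `class`), plus `ref_seq`, `hdr_seq`, `cut`.
#' @export
sim_amplicon_reads <- function(amplicon, design, mixture = outcome_mixture(),
                               n, seed, half_width = 10L, quality = 37L,
                               vary_quality = FALSE) {
  stopifnot(inherits(mixture, "outcome_mixture"))
  hit <- locate_protospacer(amplicon, design)
  cut <- nick_position(hit)
  edit <- design$intended_edit
  hdr_seq <- build_edited_allele(amplicon, cut, hit$strand, edit)
  fp_ref <- edit_footprint(cut, hit$strand, edit)
  nalt <- max(nchar(edit$alt_allele), 1L)
  fp_hdr <- if (hit$strand == "+") c(fp_ref[1L], fp_ref[1L] + nalt)
            else c(fp_ref[2L] - nalt, fp_ref[2L])
  win_ref <- quant_window(cut, half_width, amplicon$length, fp_ref)
  win_hdr <- quant_window(cut, half_width, nchar(hdr_seq), fp_hdr)
  with_local_seed(seed, {
    classes <- sample(names(mixture$proportions), n, replace = TRUE,
                      prob = mixture$proportions)
    seqs <- ifelse(startsWith(classes, "HDR"), hdr_seq, amplicon$sequence)
    need_indel <- which(classes %in% c("HDR_INDEL", "REF_INDEL"))
    for (i in need_indel) {
      win <- if (classes[i] == "HDR_INDEL") win_hdr else win_ref
      fp <- if (classes[i] == "HDR_INDEL") fp_hdr else fp_ref
      seqs[i] <- apply_window_indel(seqs[i], win, fp, mixture)
    }
    # substitution errors: touch only the reads that drew any
    n_err <- stats::rbinom(n, nchar(seqs), mixture$error_rate)
    for (i in which(n_err > 0L)) {
      seqs[i] <- apply_sub_errors(seqs[i], n_err[i])
    }
    ids <- sprintf("read_%06d", seq_len(n))
    qual <- if (vary_quality) {
      vapply(nchar(seqs), function(L)
        phred_encode(sample(seq(quality - 5L, quality), L, replace = TRUE)),
        character(1))
    } else {
      vapply(nchar(seqs), function(L)
        strrep(rawToChar(as.raw(quality + 33L)), L), character(1))
    }
    list(reads = data.frame(id = ids, seq = seqs, qual = qual,
                            stringsAsFactors = FALSE),
         truth = data.frame(id = ids, class = classes,
                            stringsAsFactors = FALSE),
         ref_seq = amplicon$sequence, hdr_seq = hdr_seq, cut = cut)
  })
}

# one uniform-length indel placed uniformly in the window, avoiding the
# intended-edit footprint [fp[1], fp[2])
apply_window_indel <- function(seqstr, win, fp, mixture) {
  len <- sample(mixture$indel_lengths, 1L)
  del <- stats::runif(1) < mixture$p_deletion
  if (del) {
    # candidate deletion starts keeping [s, s+len) inside the window and
    # clear of the footprint
    cand <- seq(win$start, max(win$start, win$end - len))
    cand <- cand[cand + len <= win$end &
                   (cand + len <= fp[1L] | cand >= fp[2L])]
    if (!length(cand)) { # very tight window: fall back to an insertion
      return(apply_insertion(seqstr, win, fp))
    }
    s <- if (length(cand) == 1L) cand else sample(cand, 1L)
    paste0(substr(seqstr, 1L, s), substr(seqstr, s + len + 1L, nchar(seqstr)))
  } else {
    apply_insertion(seqstr, win, fp, len)
  }
}

apply_insertion <- function(seqstr, win, fp, len = NULL) {
  if (is.null(len)) len <- sample(1:5, 1L)
  # anchor = base 5' of the inserted run; keep it in the window and outside
  # the footprint so the edit stays intact
  cand <- seq(win$start, win$end - 1L)
  cand <- cand[cand < fp[1L] - 1L | cand >= fp[2L]]
  s <- if (length(cand) == 1L) cand else sample(cand, 1L)
  ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
  paste0(substr(seqstr, 1L, s + 1L), ins,
         substr(seqstr, s + 2L, nchar(seqstr)))
}

apply_sub_errors <- function(seqstr, k) {
  L <- nchar(seqstr)
  pos <- sample.int(L, min(k, L))
  ch <- strsplit(seqstr, "")[[1L]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Configuration for a simulated CRISPRi reporter screen
#'
#' Emulates a pooled library with `sgrnas_per_gene` sgRNAs per gene (5,
#' matching genome-scale CRISPRi library design) plus non-targeting
#' controls; sgRNA abundances are log-normal, sequencing counts are
#' negative-binomial around `depth` x relative abundance, and planted
#' regulator genes multiply their active sgRNAs' marker-positive
#' expectation by `2^effect`.
#'
#' @param n_genes Number of targeted genes.
#' @param sgrnas_per_gene sgRNAs per gene, default 5.
#' @param n_nt Number of non-targeting sgRNAs, default 1001 (odd, so the
#'   non-targeting median is an element).
#' @param depth Mean sequencing depth per sgRNA, default 500.
#' @param abundance_meanlog,abundance_sdlog Log-normal baseline abundance
#'   parameters (defaults 0 and 0.5, a realistic pooled-library skew).
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson sampling.  Default 0.01.
#' @param planted Named numeric vector: log2 effect per planted gene name
#'   (e.g. `c(gene0001 = 2)`), or `NULL` for a null screen.
#' @param active_per_gene Number of sgRNAs per planted gene that carry the
#'   effect, default 3 (CRISPRi sgRNAs vary in potency).
#' @param seed Integer seed.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes = 1000L, sgrnas_per_gene = 5L,
                              n_nt = 1001L, depth = 500,
                              abundance_meanlog = 0, abundance_sdlog = 0.5,
                              dispersion = 0.01, planted = NULL,
                              active_per_gene = 3L, seed = 1L) {
  if (depth <= 0) pq_stop("depth must be > 0", "bad_config")
  if (dispersion < 0) pq_stop("dispersion must be >= 0", "bad_config")
  if (!is.null(planted)) {
    if (is.null(names(planted)) || any(!nzchar(names(planted))))
      pq_stop("planted effects must be a named vector", "bad_config")
    if (any(!is.finite(planted)))
      pq_stop("planted effects must be finite", "bad_config")
  }
  structure(list(n_genes = as.integer(n_genes),
                 sgrnas_per_gene = as.integer(sgrnas_per_gene),
                 n_nt = as.integer(n_nt), depth = depth,
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 dispersion = dispersion, planted = planted,
                 active_per_gene = as.integer(active_per_gene),
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

# NB draw with var = mu + dispersion mu^2; Poisson when dispersion == 0
rnb <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate a screen count table
#'
#' Gene names are `gene0001 ...`; each gene has one TSS (`P1`).  Planted
#' genes (see [screen_sim_config()]) shift the marker-positive expectation
#' of their first `active_per_gene` sgRNAs by `2^effect`; all other sgRNAs,
#' including non-targeting controls, share the null expectation.
#'
#' @param config A [screen_sim_config()].
#' @return List with `table` (a screen count table, see
#'   [screen_count_table()]) and `truth` (data.frame of planted genes and
#'   effects).
#' @export
sim_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_local_seed(config$seed, {
    genes <- sprintf("gene%04d", seq_len(config$n_genes))
    gene_col <- rep(genes, each = config$sgrnas_per_gene)
    n_targ <- length(gene_col)
    ids <- c(sprintf("%s_sg%d", gene_col,
                     rep(seq_len(config$sgrnas_per_gene), config$n_genes)),
             sprintf("nt_%05d", seq_len(config$n_nt)))
    gene_all <- c(gene_col, rep("", config$n_nt))
    tss_all <- c(rep("P1", n_targ), rep("", config$n_nt))
    nt <- c(rep(FALSE, n_targ), rep(TRUE, config$n_nt))
    n_all <- length(ids)
    ab <- stats::rlnorm(n_all, config$abundance_meanlog,
                        config$abundance_sdlog)
    mu <- config$depth * ab / mean(ab)
    eff <- numeric(n_all)
    if (!is.null(config$planted)) {
      unknown <- setdiff(names(config$planted), genes)
      if (length(unknown))
        pq_stop(sprintf("planted gene(s) not in library: %s",
                        paste(unknown, collapse = ",")), "bad_config")
      for (g in names(config$planted)) {
        rows <- which(gene_all == g)[seq_len(config$active_per_gene)]
        eff[rows] <- config$planted[[g]]
      }
    }
    count_neg <- rnb(n_all, mu, config$dispersion)
    count_pos <- rnb(n_all, mu * 2^eff, config$dispersion)
    table <- data.table::data.table(
      sgrna_id = ids, gene = gene_all, tss = tss_all, non_targeting = nt,
      count_pos = count_pos, count_neg = count_neg)
    truth <- if (is.null(config$planted)) {
      data.frame(gene = character(), effect = numeric(),
                 active_sgrnas = integer())
    } else {
      data.frame(gene = names(config$planted),
                 effect = unname(config$planted),
                 active_sgrnas = config$active_per_gene)
    }
    list(table = table, truth = truth)
  })
}

#' Configuration for simulated pegRNA fragments
#'
#' Two generation modes: programmed bin proportions (`proportions`), or a
#' geometric 5'/3' truncation model (`p5`, `p3`: per-base truncation
#' probabilities; truncation length `T ~ Geom(p)` clipped to the
#' reference).
#'
#' @param L pegRNA reference length (default 122 nt: 20 nt spacer + 76 nt
#'   scaffold + 13 nt RT template + 13 nt PBS).
#' @param n Number of fragments.
#' @param proportions Numeric length-3 (cis, trans, inactive), summing to
#'   1, or `NULL` to use the truncation model.
#' @param p5,p3 Geometric truncation parameters (used when `proportions`
#'   is `NULL`).
#' @param start_tol,end_tol Intactness tolerances matching
#'   [peg_region_map()], default 3/3.
#' @param seed Integer seed.
#' @return A `fragment_sim_config` list.
#' @export
fragment_sim_config <- function(L = 122L, n = 1000L, proportions = NULL,
                                p5 = 0.02, p3 = 0.02, start_tol = 3L,
                                end_tol = 3L, seed = 1L) {
  if (!is.null(proportions)) {
    if (length(proportions) != 3L || any(proportions < 0) ||
        abs(sum(proportions) - 1) > 1e-9)
      pq_stop("proportions must be 3 non-negative values summing to 1",
              "bad_config")
  } else if (p5 <= 0 || p5 > 1 || p3 <= 0 || p3 > 1) {
    pq_stop("truncation probabilities must be in (0, 1]", "bad_config")
  }
  structure(list(L = as.integer(L), n = as.integer(n),
                 proportions = proportions, p5 = p5, p3 = p3,
                 start_tol = as.integer(start_tol),
                 end_tol = as.integer(end_tol), seed = as.integer(seed)),
            class = "fragment_sim_config")
}

#' Simulate pegRNA fragments
#'
#' In proportions mode each fragment's bin is drawn first and its endpoints
#' drawn uniformly from the coordinates consistent with that bin (given the
#' tolerances).  In truncation mode both endpoints erode geometrically and
#' the truth bin is derived from the realised endpoints.
#'
#' @param config A [fragment_sim_config()].
#' @return List with `fragments` (data.frame, see [fragments()]) and
#'   `truth` (data.frame `id`, `bin`).
#' @export
sim_fragments <- function(config) {
  stopifnot(inherits(config, "fragment_sim_config"))
  L <- config$L
  st <- config$start_tol
  et <- config$end_tol
  with_local_seed(config$seed, {
    n <- config$n
    if (!is.null(config$proportions)) {
      bins <- sample(FRAGMENT_BINS, n, replace = TRUE,
                     prob = config$proportions)
      start <- integer(n)
      end <- integer(n)
      cis <- bins == "CIS_ACTIVE"
      trans <- bins == "TRANS_ACTIVE"
      inact <- bins == "INACTIVE"
      start[cis] <- sample(0:st, sum(cis), replace = TRUE)
      end[cis] <- L - sample(0:et, sum(cis), replace = TRUE)
      start[trans] <- sample((st + 1L):(L - et - 1L), sum(trans),
                             replace = TRUE)
      end[trans] <- L - sample(0:et, sum(trans), replace = TRUE)
      # inactive: 3' truncated beyond tolerance; 5' anywhere upstream
      end[inact] <- sample((st + 2L):(L - et - 1L), sum(inact),
                           replace = TRUE)
      start[inact] <- vapply(end[inact], function(e)
        sample.int(e, 1L) - 1L, integer(1))
    } else {
      t5 <- stats::rgeom(n, config$p5)
      t3 <- stats::rgeom(n, config$p3)
      start <- pmin(t5, L - 2L)
      end <- pmax(L - t3, start + 1L)
      bins <- bin_fragments(data.frame(start = start, end = end),
                            peg_region_map(spacer_len = L, scaffold_len = 0L,
                                           rt_len = 0L, pbs_len = 0L,
                                           start_tol = st, end_tol = et))
    }
    ids <- sprintf("frag_%06d", seq_len(n))
    frags <- fragments("pegRNA", start, end)
    frags$id <- ids
    list(fragments = frags, truth = data.frame(id = ids, bin = bins,
                                               stringsAsFactors = FALSE))
  })
}
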
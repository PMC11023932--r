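# screen_stats: sgRNA-level enrichment phenotypes between sorted
# populations, gene-level scores, pseudogene nulls and empirical FDR.

#' Validate a screen count table
#'
#' @param table data.frame/data.table with columns `sgrna_id`, `gene`,
#'   `tss`, `non_targeting` (logical or 0/1), `count_pos`, `count_neg`.
#' @return A validated `data.table` (copy).
#' @export
screen_count_table <- function(table) {
  need <- c("sgrna_id", "gene", "tss", "non_targeting",
            "count_pos", "count_neg")
  miss <- setdiff(need, names(table))
  if (length(miss))
    pq_stop(sprintf("count table lacks columns: %s", paste(miss, collapse = ",")),
            "bad_input")
  dt <- data.table::as.data.table(table)[, need, with = FALSE]
  dt[, `:=`(non_targeting = as.logical(non_targeting),
            count_pos = as.numeric(count_pos),
            count_neg = as.numeric(count_neg))]
  if (anyNA(dt$count_pos) || anyNA(dt$count_neg) ||
      any(dt$count_pos < 0) || any(dt$count_neg < 0) ||
      any(dt$count_pos != round(dt$count_pos)) ||
      any(dt$count_neg != round(dt$count_neg)))
    pq_stop("counts must be non-negative integers", "bad_input")
  if (!any(dt$non_targeting))
    pq_stop("no non-targeting sgRNAs in the table", "no_non_targeting")
  if (anyDuplicated(dt$sgrna_id))
    pq_stop("duplicate sgrna_id values", "bad_input")
  targ <- dt[!dt$non_targeting]
  if (nrow(targ) && (any(!nzchar(targ$gene)) || any(!nzchar(targ$tss))))
    pq_stop("targeting sgRNAs must carry non-empty gene and tss labels",
            "bad_input")
  dt
}

#' Impose a per-sample read-count minimum
#'
#' Every count below `floor` is raised to `floor`, independently in each
#' sorted population (default mode).  `mode = "filter"` instead drops rows
#' whose counts are below the floor in both samples, for sensitivity
#' analysis.
#'
#' @param table A screen count table (see [screen_count_table()]).
#' @param floor Minimum read count, default 50.
#' @param mode `"floor"` (default) or `"filter"`.
#' @return The adjusted `data.table`.
#' @export
apply_count_floor <- function(table, floor = 50, mode = c("floor", "filter")) {
  mode <- match.arg(mode)
  dt <- screen_count_table(table)
  if (mode == "filter") {
    dt <- dt[dt$count_pos >= floor | dt$count_neg >= floor]
    if (!nrow(dt)) pq_stop("all rows removed by the count filter", "bad_input")
  }
  dt[, `:=`(count_pos = pmax(count_pos, floor),
            count_neg = pmax(count_neg, floor))]
  dt
}

#' sgRNA-level enrichment phenotypes
#'
#' For each sgRNA, the raw log2 enrichment is
#' `log2((count_pos/total_pos) / (count_neg/total_neg))` (counts normalised
#' to each sample's total); the phenotype is this enrichment centred on the
#' median raw enrichment of the non-targeting sgRNAs, so the non-targeting
#' median phenotype is 0.
#'
#' @param table A floored count table (see [apply_count_floor()]).
#' @return `data.table` with columns `sgrna_id`, `gene`, `tss`,
#'   `non_targeting`, `phenotype`.
#' @export
sgrna_phenotypes <- function(table) {
  dt <- screen_count_table(table)
  if (!any(dt$non_targeting))
    pq_stop("no non-targeting sgRNAs", "no_non_targeting")
  tp <- sum(dt$count_pos)
  tn <- sum(dt$count_neg)
  if (tp <= 0 || tn <= 0) pq_stop("sample totals must be positive", "bad_input")
  if (any(dt$count_pos == 0) || any(dt$count_neg == 0))
    pq_stop("zero counts present; apply the count floor first", "bad_input")
  r <- log2((dt$count_pos / tp) / (dt$count_neg / tn))
  med <- stats::median(r[dt$non_targeting])
  phen <- r - med
  # second centring pass removes any floating-point residual of the median
  resid <- stats::median(phen[dt$non_targeting])
  if (resid != 0) phen <- phen - resid
  out <- dt[, c("sgrna_id", "gene", "tss", "non_targeting"), with = FALSE]
  out[, phenotype := phen]
  out
}

#' Gene-level phenotype scores
#'
#' For each transcription start site, the score is the signed mean of the
#' `k` sgRNA phenotypes that are strongest by absolute value (all sgRNAs
#' when fewer than `k` are present).  Non-targeting rows are ignored.
#'
#' @param phenotypes Output of [sgrna_phenotypes()] (or any data.frame with
#'   `gene`, `tss`, `phenotype` and optionally `non_targeting`).
#' @param k Number of strongest sgRNAs to average, default 3.
#' @return `data.table` with `gene`, `tss`, `score`, `n_sgrnas_used`, sorted
#'   by decreasing `|score|`.
#' @export
gene_scores <- function(phenotypes, k = 3L) {
  dt <- data.table::as.data.table(phenotypes)
  if (!is.null(dt$non_targeting)) dt <- dt[!dt$non_targeting]
  if (!nrow(dt)) pq_stop("no targeting sgRNAs", "bad_input")
  k <- as.integer(k)
  # deterministic order: strongest first, sgrna_id breaks |phenotype| ties
  if (!is.null(dt$sgrna_id)) {
    data.table::setorderv(dt, c("sgrna_id"))
  }
  dt <- dt[order(-abs(dt$phenotype))]
  out <- dt[, list(score = mean(utils::head(phenotype, k)),
                   n_sgrnas_used = min(.N, k)),
            by = c("gene", "tss")]
  out[order(-abs(out$score))]
}

#' Collapse multi-TSS gene scores to one score per gene
#'
#' Genes assayed at several transcription start sites report the TSS score
#' of largest magnitude (ties broken by TSS label).
#'
#' @param tss_scores Output of [gene_scores()].
#' @return `data.table` with one row per gene (`gene`, `tss`, `score`,
#'   `n_sgrnas_used`).
#' @export
collapse_gene_scores <- function(tss_scores) {
  dt <- data.table::as.data.table(tss_scores)
  data.table::setorderv(dt, "tss")
  dt <- dt[order(-abs(dt$score))]
  out <- dt[, utils::head(.SD, 1L), by = "gene"]
  out[order(-abs(out$score))]
}

#' Assemble non-targeting pseudogenes
#'
#' Negative-control pseudogenes are built by randomly assigning
#' non-targeting sgRNAs to synthetic "genes" of `group_size` members
#' (5, matching the screen analysis convention).  In the default auto mode
#' the groups are disjoint (`floor(n_nt / group_size)` pseudogenes); with
#' `replace = TRUE` any number of pseudogenes can be resampled, each still
#' drawn without replacement within the group.
#'
#' @param nt_ids Character vector of non-targeting sgRNA ids.
#' @param group_size Members per pseudogene, default 5.
#' @param n_pseudogenes Number of pseudogenes; `NULL` (auto) gives disjoint
#'   groups covering the NT set.
#' @param seed Integer seed (sampling is reproducible and leaves the global
#'   RNG untouched).
#' @param replace Resample NT sgRNAs across pseudogenes (required when
#'   `n_pseudogenes > floor(n_nt/group_size)`).
#' @return A `pseudogene_set`: list with `groups` (named list of id
#'   vectors), `group_size`, `seed`, `replace`.
#' @export
make_pseudogenes <- function(nt_ids, group_size = 5L, n_pseudogenes = NULL,
                             seed = 1L, replace = FALSE) {
  nt_ids <- as.character(nt_ids)
  group_size <- as.integer(group_size)
  if (length(nt_ids) < group_size)
    pq_stop(sprintf("need >= %d non-targeting sgRNAs, got %d", group_size,
                    length(nt_ids)), "too_few_nt")
  n_auto <- length(nt_ids) %/% group_size
  if (is.null(n_pseudogenes)) n_pseudogenes <- n_auto
  n_pseudogenes <- as.integer(n_pseudogenes)
  if (!replace && n_pseudogenes > n_auto)
    pq_stop("disjoint mode supports at most floor(n_nt/group_size) pseudogenes; set replace = TRUE",
            "too_few_nt")
  groups <- with_local_seed(seed, {
    if (replace) {
      lapply(seq_len(n_pseudogenes),
             function(i) sample(nt_ids, group_size, replace = FALSE))
    } else {
      perm <- sample(nt_ids, n_pseudogenes * group_size, replace = FALSE)
      split(perm, rep(seq_len(n_pseudogenes), each = group_size))
    }
  })
  names(groups) <- sprintf("pseudo_%05d", seq_len(n_pseudogenes))
  structure(list(groups = groups, group_size = group_size, seed = seed,
                 replace = replace),
            class = "pseudogene_set")
}

#' @export
print.pseudogene_set <- function(x, ...) {
  cat(sprintf("<pseudogene_set> %d pseudogenes of %d NT sgRNAs (seed %s, %s)\n",
              length(x$groups), x$group_size, format(x$seed),
              if (x$replace) "resampled" else "disjoint"))
  invisible(x)
}

#' Score pseudogenes like genes
#'
#' Applies the [gene_scores()] top-k rule to each pseudogene's member
#' phenotypes, giving the null score distribution.
#'
#' @param phenotypes Output of [sgrna_phenotypes()].
#' @param pseudogenes A [make_pseudogenes()] result.
#' @param k Top-k rule, default 3 (match the gene scoring).
#' @return Numeric vector of pseudogene scores (one per pseudogene).
#' @export
pseudogene_scores <- function(phenotypes, pseudogenes, k = 3L) {
  stopifnot(inherits(pseudogenes, "pseudogene_set"))
  dt <- data.table::as.data.table(phenotypes)
  phen <- dt$phenotype
  names(phen) <- dt$sgrna_id
  long <- data.table::data.table(
    gene = rep(names(pseudogenes$groups),
               each = pseudogenes$group_size),
    tss = "pseudo",
    phenotype = phen[unlist(pseudogenes$groups, use.names = FALSE)])
  if (anyNA(long$phenotype))
    pq_stop("pseudogene member not present in the phenotype table", "bad_input")
  sc <- gene_scores(long, k = k)
  out <- sc$score
  names(out) <- sc$gene
  out
}

#' Empirical FDR from pseudogene null scores
#'
#' Each gene's empirical p-value is
#' `(1 + #[pseudogenes with |score| >= |gene score|]) / (1 + n_pseudogenes)`;
#' Benjamini-Hochberg correction over all genes gives the FDR, and genes at
#' `fdr <= threshold` are flagged as hits.
#'
#' @param genes Gene-score table ([gene_scores()] or
#'   [collapse_gene_scores()] output).
#' @param pseudo_scores Numeric vector of pseudogene scores (>= 20).
#' @param threshold Hit threshold on the FDR, default 0.01.
#' @return The gene table with `empirical_p`, `fdr` and `hit` columns,
#'   sorted by increasing `empirical_p`.
#' @export
empirical_fdr <- function(genes, pseudo_scores, threshold = 0.01) {
  if (length(pseudo_scores) < 20L)
    pq_stop(sprintf("need >= 20 pseudogene scores, got %d",
                    length(pseudo_scores)), "too_few_pseudogenes")
  dt <- data.table::as.data.table(genes)
  ps <- sort(abs(pseudo_scores))
  B <- length(ps)
  # #{|pseudo| >= |score|} via binary search on the sorted null
  n_ge <- B - findInterval(abs(dt$score), ps, left.open = TRUE)
  dt[, empirical_p := (1 + n_ge) / (1 + B)]
  dt[, fdr := stats::p.adjust(empirical_p, method = "BH")]
  dt[, hit := fdr <= threshold]
  dt[order(dt$empirical_p, -abs(dt$score))]
}

#' Export sgRNA phenotypes for an external mixture-model fit
#'
#' Writes the sgRNA-level phenotype table in the three-column layout
#' (sgRNA id, gene, phenotype, with non-targeting rows flagged) consumed by
#' hierarchical mixture-model hit callers; the fit itself is performed
#' outside this package.
#'
#' @param phenotypes Output of [sgrna_phenotypes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_for_crisphiermix <- function(phenotypes, path) {
  dt <- data.table::as.data.table(phenotypes)
  cols <- c("sgrna_id", "gene", "phenotype", "non_targeting")
  empty <- data.table::data.table(sgrna_id = character(), gene = character(),
                                  phenotype = numeric(),
                                  non_targeting = logical())
  out <- if (nrow(dt)) dt[, cols, with = FALSE] else empty
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Full reporter-screen analysis
#'
#' Count floor, sgRNA phenotypes, per-TSS and per-gene scores, pseudogene
#' null, empirical FDR.
#'
#' @param table Raw screen count table.
#' @param floor Read-count minimum, default 50.
#' @param k Top-k sgRNAs per gene score, default 3.
#' @param pseudogene_size NT sgRNAs per pseudogene, default 5.
#' @param n_pseudogenes Number of pseudogenes (`NULL` = disjoint auto).
#' @param seed Seed for pseudogene sampling.
#' @param fdr_threshold Hit threshold, default 0.01.
#' @param floor_mode `"floor"` or `"filter"`, see [apply_count_floor()].
#' @param replace_pseudogenes Resample pseudogenes with replacement.
#' @return List with `sgrna` (phenotypes), `tss` (per-TSS scores), `genes`
#'   (per-gene scores with `empirical_p`/`fdr`/`hit`), `pseudogenes`,
#'   `pseudo_scores`.
#' @export
screen_analysis <- function(table, floor = 50, k = 3L, pseudogene_size = 5L,
                            n_pseudogenes = NULL, seed = 1L,
                            fdr_threshold = 0.01,
                            floor_mode = c("floor", "filter"),
                            replace_pseudogenes = FALSE) {
  floored <- apply_count_floor(table, floor, match.arg(floor_mode))
  phen <- sgrna_phenotypes(floored)
  tss <- gene_scores(phen, k = k)
  genes <- collapse_gene_scores(tss)
  pg <- make_pseudogenes(phen$sgrna_id[phen$non_targeting],
                         group_size = pseudogene_size,
                         n_pseudogenes = n_pseudogenes, seed = seed,
                         replace = replace_pseudogenes)
  ps <- pseudogene_scores(phen, pg, k = k)
  genes <- empirical_fdr(genes, ps, threshold = fdr_threshold)
  list(sgrna = phen, tss = tss, genes = genes, pseudogenes = pg,
       pseudo_scores = ps)
}
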
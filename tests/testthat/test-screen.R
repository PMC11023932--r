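# screen enrichment statistics: count floor, phenotypes, gene scores,
# pseudogenes, empirical FDR, mixture-model export

toy_table <- function() {
  data.frame(
    sgrna_id = c("g1_sg1", "g1_sg2", "g2_sg1", "nt_1", "nt_2", "nt_3"),
    gene = c("g1", "g1", "g2", "", "", ""),
    tss = c("P1", "P1", "P1", "", "", ""),
    non_targeting = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    count_pos = c(200, 3, 120, 100, 100, 100),
    count_neg = c(100, 120, 50, 100, 100, 100))
}

test_that("count floor raises low counts per sample and leaves the rest", {
  t <- apply_count_floor(toy_table(), floor = 50)
  expect_equal(t$count_pos[t$sgrna_id == "g1_sg2"], 50)
  expect_equal(t$count_pos[t$sgrna_id == "g1_sg1"], 200)
  expect_equal(t$count_neg[t$sgrna_id == "g2_sg1"], 50)
  # boundary: counts already at the floor are unchanged
  t50 <- toy_table(); t50$count_pos[] <- 50; t50$count_neg[] <- 50
  expect_equal(apply_count_floor(t50, 50)$count_pos, rep(50, 6))
  # floor 0 is the identity
  expect_equal(apply_count_floor(toy_table(), 0)$count_pos,
               toy_table()$count_pos)
  # filter mode drops rows below the floor in both samples
  tf <- apply_count_floor(toy_table(), floor = 200, mode = "filter")
  expect_false("g2_sg1" %in% tf$sgrna_id[tf$count_pos < 200 &
                                           tf$count_neg < 200])
})

test_that("phenotypes are NT-median-centred log2 enrichments", {
  phen <- sgrna_phenotypes(apply_count_floor(toy_table(), 50))
  # NT sgRNAs all have identical counts, so raw NT enrichment is constant
  # and centred phenotypes are exactly 0
  expect_equal(phen$phenotype[phen$non_targeting], rep(0, 3))
  # equal totals here, so g1_sg1 = log2(200/100) = 1 after centring
  expect_equal(phen$phenotype[phen$sgrna_id == "g1_sg1"], 1.0)
  zero <- toy_table(); zero$count_pos[2] <- 0
  expect_error(sgrna_phenotypes(zero), class = "pq_bad_input")
})

test_that("phenotypes are invariant to per-sample scaling", {
  t <- apply_count_floor(toy_table(), 50)
  p1 <- sgrna_phenotypes(t)
  t2 <- data.table::copy(t)
  t2$count_pos <- t2$count_pos * 10
  p2 <- sgrna_phenotypes(t2)
  expect_equal(p2$phenotype, p1$phenotype)
})

test_that("NT median phenotype is exactly zero", {
  set.seed(90)
  for (n_nt in c(7, 8, 101)) {
    tab <- data.frame(
      sgrna_id = c(sprintf("g%d_sg1", 1:5), sprintf("nt_%d", 1:n_nt)),
      gene = c(sprintf("g%d", 1:5), rep("", n_nt)),
      tss = c(rep("P1", 5), rep("", n_nt)),
      non_targeting = c(rep(FALSE, 5), rep(TRUE, n_nt)),
      count_pos = rpois(5 + n_nt, 300),
      count_neg = rpois(5 + n_nt, 300))
    phen <- sgrna_phenotypes(apply_count_floor(tab, 50))
    expect_identical(median(phen$phenotype[phen$non_targeting]), 0)
  }
})

test_that("gene scores average the strongest k sgRNAs by absolute value", {
  phen <- data.frame(
    sgrna_id = sprintf("sg%d", 1:5), gene = "g", tss = "P1",
    non_targeting = FALSE,
    phenotype = c(2.0, -1.5, 1.0, 0.2, -0.1))
  sc <- gene_scores(phen, k = 3)
  expect_equal(sc$score, (2.0 - 1.5 + 1.0) / 3) # = 0.5
  expect_equal(sc$n_sgrnas_used, 3L)
  # constant phenotypes give the constant
  phen$phenotype <- 1.0
  expect_equal(gene_scores(phen, 3)$score, 1.0)
  # fewer sgRNAs than k: use all available
  two <- phen[1:2, ]; two$phenotype <- c(3.0, 1.0)
  sc2 <- gene_scores(two, 3)
  expect_equal(sc2$score, 2.0)
  expect_equal(sc2$n_sgrnas_used, 2L)
})

test_that("gene scores are bounded and order-invariant", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    phen <- data.frame(sgrna_id = sprintf("sg%d", 1:n), gene = "g",
                       tss = "P1", non_targeting = FALSE,
                       phenotype = rnorm(n))
    sc <- gene_scores(phen, 3)
    expect_lte(abs(sc$score), max(abs(phen$phenotype)) + 1e-12)
    perm <- phen[sample(n), ]
    expect_equal(gene_scores(perm, 3)$score, sc$score)
  }
})

test_that("multi-TSS genes collapse to the strongest TSS", {
  tss <- data.frame(gene = c("g", "g"), tss = c("P1", "P2"),
                    score = c(0.5, -1.2), n_sgrnas_used = c(3L, 3L))
  g <- collapse_gene_scores(tss)
  expect_equal(nrow(g), 1L)
  expect_equal(g$score, -1.2)
  expect_equal(g$tss, "P2")
})

test_that("pseudogene assembly is seeded, disjoint and sized correctly", {
  nt <- sprintf("nt_%04d", 1:1000)
  pg <- make_pseudogenes(nt, group_size = 5, seed = 3)
  expect_length(pg$groups, 200L)
  expect_true(all(lengths(pg$groups) == 5L))
  expect_equal(anyDuplicated(unlist(pg$groups)), 0L)
  pg2 <- make_pseudogenes(nt, group_size = 5, seed = 3)
  expect_identical(pg$groups, pg2$groups)
  pg3 <- make_pseudogenes(nt, group_size = 5, seed = 4)
  expect_false(identical(pg$groups, pg3$groups))
  expect_error(make_pseudogenes(sprintf("nt_%d", 1:4), group_size = 5),
               class = "pq_too_few_nt")
  # resampling mode supports more pseudogenes than the NT pool allows
  pg4 <- make_pseudogenes(nt, 5, n_pseudogenes = 500, seed = 1,
                          replace = TRUE)
  expect_length(pg4$groups, 500L)
  expect_true(all(vapply(pg4$groups,
                         function(g) anyDuplicated(g) == 0L, logical(1))))
})

test_that("empirical p-values follow the plus-one rule", {
  genes <- data.frame(gene = c("top", "mid"), tss = "P1",
                      score = c(5.0, 1.0), n_sgrnas_used = 3L)
  set.seed(10)
  pseudo <- rnorm(200, 0, 1)
  pseudo <- pseudo[order(abs(pseudo))]
  res <- empirical_fdr(genes, pseudo)
  expect_equal(res$empirical_p[res$gene == "top"], 1 / 201)
  # a gene at the pseudogene median magnitude sits near p = 0.5
  med_gene <- data.frame(gene = "med", tss = "P1",
                         score = median(abs(pseudo)), n_sgrnas_used = 3L)
  pm <- empirical_fdr(med_gene, pseudo)$empirical_p
  expect_gt(pm, 0.4); expect_lt(pm, 0.6)
  expect_error(empirical_fdr(genes, pseudo[1:10]),
               class = "pq_too_few_pseudogenes")
  # BH never lowers a p-value's rank order
  expect_true(all(res$fdr >= res$empirical_p - 1e-12))
})

test_that("mixture-model export round-trips and flags NT rows", {
  phen <- sgrna_phenotypes(apply_count_floor(toy_table(), 50))
  path <- tempfile(fileext = ".tsv")
  export_for_crisphiermix(phen, path)
  back <- data.table::fread(path)
  expect_equal(nrow(back), 6L)
  expect_equal(back$phenotype, phen$phenotype)
  expect_equal(sum(back$non_targeting), 3L)
  # empty input -> header-only file
  path2 <- tempfile(fileext = ".tsv")
  export_for_crisphiermix(phen[0, ], path2)
  expect_equal(nrow(data.table::fread(path2)), 0L)
})

test_that("full screen analysis recovers a strongly planted regulator", {
  cfg <- screen_sim_config(n_genes = 150, n_nt = 151, depth = 800,
                           planted = c(gene0042 = 2.5),
                           active_per_gene = 5L, seed = 99)
  sim <- sim_screen(cfg)
  res <- screen_analysis(sim$table, n_pseudogenes = 20000, seed = 7,
                         replace_pseudogenes = TRUE)
  expect_equal(res$genes$gene[1], "gene0042")
  expect_true(res$genes$hit[1])
})
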
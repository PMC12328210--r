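test_that("expression on-calls respect the inclusive 20% threshold", {
  expect_true(call_expressed(0.25, 0.20))
  expect_true(call_expressed(0.20, 0.20))   # exactly at threshold: on
  expect_false(call_expressed(0.0, 0.20))
  expect_false(call_expressed(0.20, 0.20, inclusive = FALSE))
  expect_error(call_expressed(0.5, 1.2), "threshold")
})

test_that("interaction calling equals a brute-force triple loop", {
  set.seed(31)
  genes <- c("L1", "L2", "L3", "L4a", "L4b", "R1", "R2", "R3", "C3", "R4")
  frac <- matrix(round(runif(5 * length(genes)), 2), 5,
                 dimnames = list(paste0("ct", 1:5), genes))
  md <- data.frame(species = "spA", cell_type = rownames(frac),
                   compartment = c("fetal", "fetal", "maternal", "maternal",
                                   "maternal"),
                   cell_class = paste0("cl", 1:5), n_cells = 30,
                   stringsAsFactors = FALSE)
  tpm <- matrix(1e6 / length(genes), 5, length(genes),
                dimnames = dimnames(frac))
  atlas <- suppressWarnings(pseudobulk_atlas(md, list(spA = tpm),
                                             list(spA = frac)))
  cat10 <- rbind_cat <- tiny_catalog()
  calls <- score_interactions(atlas, cat10, 0.2)
  brute <- brute_interaction_calls(frac, cat10, 0.2)
  key <- function(d) paste(d$sender, d$receiver, d$interaction_id)
  expect_equal(calls$called[order(key(calls))], brute$called[order(key(brute))])
  # all-subunit rule and autocrine labelling
  expect_true(all(calls$called == (calls$ligand_on & calls$receptor_on)))
  expect_true(all((calls$sender == calls$receiver) == calls$autocrine))
})

test_that("interaction calls are monotone in the threshold", {
  sim <- simulate_atlas(seed = 5, config = list(cells_per_type = 20,
                                                n_interactions = 25,
                                                n_genes = 120))
  h <- humanize_atlas(sim$atlas, sim$ortho_maps, cells = sim$cells)
  lo <- suppressMessages(score_interactions(h, sim$catalog, 0.1))
  hi <- suppressMessages(score_interactions(h, sim$catalog, 0.4))
  expect_true(all(lo$called[hi$called]))  # calls at t2 >= t1 are a subset
  expect_lte(sum(hi$called), sum(lo$called))
})

test_that("ALC follows its defining formula on a hand example", {
  # catalog {(L1,R1),(L2,R2),(L3,R3)}; cell expresses L1, L2, R2 -> ALC 1
  cat3 <- lr_catalog(c("a", "b", "c"), list("L1", "L2", "L3"),
                     list("R1", "R2", "R3"), rep(TRUE, 3),
                     c("f1", "f2", "f3"))
  counts <- matrix(0, 2, 6, dimnames = list(c("c1", "c2"),
                                            c("L1", "L2", "L3", "R1", "R2", "R3")))
  counts["c1", c("L1", "L2", "R2")] <- 1
  counts["c2", "R1"] <- 5  # expresses no ligand -> 0
  cells <- cell_level_matrix(counts, data.frame(cell_id = c("c1", "c2"),
                                                species = "s", cell_type = "T"))
  alc <- compute_alc(cells, cat3)
  expect_equal(alc$alc, c(1L, 0L))
})

test_that("ALC equals the brute-force double loop on a 200-cell fixture", {
  set.seed(13)
  genes <- c(paste0("L", 1:8), paste0("R", 1:8), "HK")
  counts <- matrix(rbinom(200 * length(genes), 3, 0.25), 200,
                   dimnames = list(paste0("c", 1:200), genes))
  counts[, "HK"] <- counts[, "HK"] + 1L
  cat8 <- lr_catalog(paste0("I", 1:8), as.list(paste0("L", 1:8)),
                     as.list(paste0("R", 1:8)), rep(TRUE, 8),
                     paste0("f", 1:8))
  cells <- cell_level_matrix(counts,
                             data.frame(cell_id = rownames(counts),
                                        species = "s",
                                        cell_type = rep_len(c("A", "B"), 200)))
  alc <- compute_alc(cells, cat8)
  expect_equal(alc$alc, brute_alc(counts, cat8))
})

test_that("a cell's ALC is invariant to how other cells are clustered", {
  set.seed(14)
  cells <- rand_cells(40, 12, 4, seed = 14)
  colnames(cells$counts) <- c(paste0("L", 1:6), paste0("R", 1:6))
  cat6 <- lr_catalog(paste0("I", 1:6), as.list(paste0("L", 1:6)),
                     as.list(paste0("R", 1:6)), rep(TRUE, 6), paste0("f", 1:6))
  a1 <- compute_alc(cells, cat6)
  relabeled <- cells
  relabeled$cell_meta$cell_type <- rep_len(c("X", "Y", "Z"), 40)
  a2 <- compute_alc(relabeled, cat6)
  expect_equal(a1$alc, a2$alc)
})

test_that("ALC ANOVA reproduces the textbook two-class example", {
  # class means {1,2,3} and {4,5,6} -> F = 13.5, p ~ 0.0213
  alc_tab <- data.frame(cell_id = paste0("c", 1:6), species = "s",
                        cell_type = paste0("ct", 1:6),
                        replicate = "rep1", alc = 1:6,
                        stringsAsFactors = FALSE)
  class_of <- setNames(rep(c("A", "B"), each = 3), paste0("ct", 1:6))
  res <- alc_anova(alc_tab, class_of)
  expect_equal(res$F, 13.5)
  expect_equal(res$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  # all group means equal -> F = 0, p = 1
  flat <- alc_tab; flat$alc <- 2
  res0 <- alc_anova(flat, class_of)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
})

test_that("ALC ANOVA matches a from-first-principles ANOVA on random data", {
  set.seed(17)
  for (rep in 1:5) {
    n_ct <- 8
    alc_tab <- data.frame(cell_id = paste0("c", 1:(n_ct * 5)), species = "s",
                          cell_type = rep(paste0("ct", 1:n_ct), each = 5),
                          replicate = "rep1",
                          alc = rpois(n_ct * 5, 6), stringsAsFactors = FALSE)
    class_of <- setNames(rep(c("A", "B", "C"), length.out = n_ct),
                         paste0("ct", 1:n_ct))
    res <- alc_anova(alc_tab, class_of)
    means <- tapply(alc_tab$alc, alc_tab$cell_type, mean)
    brute <- brute_anova(as.numeric(means),
                         class_of[names(means)])
    expect_equal(res$F, brute$F, tolerance = 1e-10)
    expect_equal(res$p, brute$p, tolerance = 1e-10)
  }
})

test_that("signalling graph edges carry ligand x receptor products", {
  mean_ln <- matrix(c(2, 0, 0, 3), 2, 2,
                    dimnames = list(c("A", "B"), c("L1", "R1")))
  cat1 <- lr_catalog("I1", list("L1"), list("R1"), TRUE, "f")
  g <- build_signaling_graph(mean_ln, cat1)
  e <- igraph::as_data_frame(g)
  expect_equal(nrow(e), 1)
  expect_equal(e$from, "A"); expect_equal(e$to, "B")
  expect_equal(e$weight, 6)  # 2 x 3
  # either side zero -> edge absent (only the A->B edge exists)
  expect_equal(igraph::ecount(g), 1)
})

test_that("graph edge enumeration matches brute force on a fixture", {
  set.seed(19)
  genes <- c("L1", "L2", "R1", "R2", "C3")
  mean_ln <- matrix(round(rexp(4 * 5), 2), 4,
                    dimnames = list(paste0("ct", 1:4), genes))
  mean_ln[sample(20, 6)] <- 0
  cat2 <- lr_catalog(c("I1", "I2"), list("L1", "L2"),
                     list("R1", c("R2", "C3")), c(TRUE, TRUE), c("f1", "f2"),
                     list(TRUE, c(TRUE, FALSE)))
  g <- build_signaling_graph(mean_ln, cat2)
  n_expected <- 0
  for (s in 1:4) for (r in 1:4) for (i in 1:2) {
    lig <- min(mean_ln[s, cat2$ligand_subunits[[i]]])
    rec <- min(mean_ln[r, cat2$receptor_subunits[[i]]])
    if (lig * rec > 0) n_expected <- n_expected + 1
  }
  expect_equal(igraph::ecount(g), n_expected)
})

test_that("HITS scores behave on canonical small graphs", {
  # single edge A -> B
  W <- matrix(c(0, 0, 5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  hs <- hits_scores(W)
  expect_equal(hs$hub, c(1, 0))
  expect_equal(hs$authority, c(0, 1))
  # symmetric reciprocal two-node graph: all scores equal
  W2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  hs2 <- hits_scores(W2)
  expect_equal(hs2$hub, c(1, 1))
  expect_equal(hs2$authority, c(1, 1))
})

test_that("HITS matches the eigen-decomposition oracle and igraph", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 6
    W <- matrix(rexp(n * n) * rbinom(n * n, 1, 0.5), n,
                dimnames = list(paste0("ct", 1:n), paste0("ct", 1:n)))
    hs <- hits_scores(W)
    orc <- oracle_hits(W)
    expect_equal(hs$hub, orc$hub, tolerance = 1e-8)
    expect_equal(hs$authority, orc$authority, tolerance = 1e-8)
    # invariant (up to normalization) under uniform weight scaling
    hs_scaled <- hits_scores(W * 7.3)
    expect_equal(hs$hub, hs_scaled$hub, tolerance = 1e-10)
    expect_true(all(hs$hub >= 0 & hs$authority >= 0))
  }
  # cross-check against igraph on a graph built by the package
  mean_ln <- matrix(rexp(12), 3, 4,
                    dimnames = list(c("A", "B", "C"),
                                    c("L1", "L2", "R1", "R2")))
  cat2 <- lr_catalog(c("I1", "I2"), list("L1", "L2"), list("R1", "R2"),
                     c(TRUE, TRUE), c("f1", "f2"))
  g <- build_signaling_graph(mean_ln, cat2)
  hs <- hits_scores(g)
  ig <- igraph::hits_scores(
    igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE,
                     edge.attr.comb = list(weight = "sum", "ignore")),
    scale = TRUE)
  expect_equal(hs$hub, unname(ig$hub[hs$cell_type]), tolerance = 1e-6)
  expect_equal(hs$authority, unname(ig$authority[hs$cell_type]),
               tolerance = 1e-6)
})
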
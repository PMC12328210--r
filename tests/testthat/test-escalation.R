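test_that("zTPM maps zeroes to the floor and is monotone above it", {
  set.seed(83)
  tpm <- c(0, rexp(200, 0.01))
  z <- ztpm_transform(tpm)
  expect_equal(unname(z[1]), -3)
  ord <- order(tpm)
  expect_true(all(diff(z[ord]) >= 0))
  expect_true(all(z >= -3))
  # plain mean/sd fit centres the fitted mean at zero
  z2 <- ztpm_transform(tpm, fit = "mean_sd")
  mu <- attr(z2, "mu")
  expect_equal(unname(ztpm_transform(c(tpm, 2^mu), fit = "mean_sd")[202]), 0,
               tolerance = 1e-10)
  expect_error(ztpm_transform(c(-1, 2)), "non-negative")
})

test_that("representative traits take the compartment maximum with lexicographic ties", {
  vals <- matrix(c(-1, 2, 2, 2), 2, 2,
                 dimnames = list(c("TB2", "TB1"), c("g1", "g2")))
  md <- data.frame(species = "s", cell_type = c("TB2", "TB1"),
                   compartment = "fetal", cell_class = "Troph", n_cells = 10)
  rt <- representative_trait(vals, md, "g1", "fetal")
  expect_equal(rt$value, 2)
  expect_equal(rt$cell_type, "TB1")
  # tie broken by name
  rt2 <- representative_trait(vals, md, "g2", "fetal")
  expect_equal(rt2$cell_type, "TB1")
  expect_error(representative_trait(vals, md, "g1", "maternal"),
               "no cell types")
})

test_that("contrasts reproduce the hand-worked three-taxon example", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  pc <- pic_contrasts(tr, c(A = 2, B = 0, C = 1))
  expect_equal(unname(pc), c(0, sqrt(2)), tolerance = 1e-12)
  expect_length(pc, 2)  # n - 1 contrasts
  # constant trait -> all contrasts zero
  expect_equal(unname(pic_contrasts(tr, c(A = 1, B = 1, C = 1))), c(0, 0))
  # linearity: pic(aX) = a pic(X)
  set.seed(87)
  for (i in 1:20) {
    tr2 <- rand_bin_tree(sample(4:8, 1))
    x <- setNames(rnorm(length(tr2$tip.label)), tr2$tip.label)
    a <- rnorm(1)
    expect_equal(pic_contrasts(tr2, a * x), a * pic_contrasts(tr2, x),
                 tolerance = 1e-10)
  }
})

test_that("regression through the origin matches lm and flags degeneracy", {
  x <- c(1, 2, -1)
  reg <- pic_regression(x, 2 * x)
  expect_equal(reg$slope, 2)
  expect_true(reg$degenerate)
  expect_equal(reg$p, 0)
  # orthogonal contrasts give slope zero
  reg0 <- pic_regression(c(1, -1), c(1, 1))
  expect_equal(reg0$slope, 0)
  # sum(x^2) = 0 -> undefined
  regu <- pic_regression(c(0, 0), c(1, 2))
  expect_true(regu$undefined)
  # general agreement with lm(y ~ x + 0)
  set.seed(89)
  for (i in 1:10) {
    xx <- rnorm(5); yy <- rnorm(5)
    reg2 <- pic_regression(xx, yy)
    fit <- summary(lm(yy ~ xx + 0))
    expect_equal(reg2$slope, unname(coef(fit)[1, 1]), tolerance = 1e-10)
    expect_equal(reg2$p, unname(coef(fit)[1, 4]), tolerance = 1e-10)
  }
})

test_that("the OLS slope matches its closed form", {
  expect_equal(ols_slope(c(0, 1, 2), c(0, 1, 2))$slope, 1)
  expect_equal(ols_slope(c(0, 1, 2), c(5, 5, 5))$slope, 0)
  expect_true(ols_slope(c(1, 1, 1), c(0, 1, 2))$undefined)
  set.seed(91)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(ols_slope(x, y)$slope, cov(x, y) / var(x), tolerance = 1e-10)
  }
})

test_that("direction flag swaps predictor and response", {
  set.seed(93)
  x <- rnorm(5); y <- rnorm(5)
  a <- pic_regression(x, y, "receptor_on_ligand")
  b <- pic_regression(x, y, "ligand_on_receptor")
  expect_equal(a$slope, sum(x * y) / sum(x^2))
  expect_equal(b$slope, sum(x * y) / sum(y^2))
})

test_that("coupled-trait simulation with zero noise recovers beta exactly", {
  tree <- fixed_six_species_tree()
  sim <- simulate_coupled_traits(tree, beta = 0.7, noise_sd = 0, n_pairs = 5,
                                 seed = 11)
  for (k in 1:5) {
    lc <- pic_contrasts(tree, sim$ligand[, k])
    rc <- pic_contrasts(tree, sim$receptor[, k])
    expect_equal(rc, 0.7 * lc, tolerance = 1e-10)
    expect_equal(pic_regression(lc, rc)$slope, 0.7, tolerance = 1e-10)
  }
})

test_that("branch trait changes are descendant minus ancestor", {
  tr <- ape::read.tree(text = "((A:1,B:1)E:1,(C:1,D:1)F:1)R;")
  leaf <- matrix(c(1.5, 0.5, 0, 0), 4, 1,
                 dimnames = list(c("A", "B", "C", "D"), "g"))
  bm <- brownian_asr(tr, leaf)
  d <- branch_trait_changes(tr, leaf, bm$node_values)
  rowA <- d[d$child == "A", ]
  expect_equal(rowA$delta, 1.5 - bm$node_values["E", "g"])
  expect_true(rowA$terminal)
  # constant trait -> all deltas zero
  leaf0 <- matrix(2, 4, 1, dimnames = list(c("A", "B", "C", "D"), "g"))
  bm0 <- brownian_asr(tr, leaf0)
  expect_true(all(abs(branch_trait_changes(tr, leaf0, bm0$node_values)$delta)
                  < 1e-12))
  # deltas match an independent recomputation from the joined table
  full <- rbind(leaf, bm$node_values)
  labs <- c("A", "B", "C", "D", "R", "E", "F")
  for (e in seq_len(nrow(tr$edge))) {
    p <- labs[tr$edge[e, 1]]; ch <- labs[tr$edge[e, 2]]
    expect_equal(d$delta[d$parent == p & d$child == ch],
                 unname(full[ch, "g"] - full[p, "g"]))
  }
})

test_that("the end-to-end escalation table filters and annotates pairs", {
  sim <- simulate_atlas(seed = 21, config = list(cells_per_type = 25,
                                                 n_interactions = 30,
                                                 n_genes = 140))
  h <- humanize_atlas(sim$atlas, sim$ortho_maps, cells = sim$cells)
  esc <- test_escalation(h, sim$catalog, sim$tree)
  expect_true(all(esc$n_contrasts == 5))  # six species -> five contrasts
  expect_true(all(esc$interaction_id %in%
                    sim$catalog$interaction_id[sim$catalog$is_secreted]))
  expect_true(all(esc$q_bh >= esc$pic_p - 1e-12, na.rm = TRUE))
  expect_equal(esc$p_bonferroni,
               pmin(1, esc$pic_p * sum(!is.na(esc$pic_p))))
})
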
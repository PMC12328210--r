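test_that("compartment classification assigns the four categories", {
  frac <- matrix(c(0.30, 0.05, 0.10,   # L1: fetal-only
                   0.25, 0.30, 0.00,   # L2: both
                   0.05, 0.25, 0.10,   # L3: maternal-only
                   0.01, 0.02, 0.03),  # L4: off
                 3, 4, dimnames = list(c("TB", "STR", "EPI"),
                                       paste0("L", 1:4)))
  md <- data.frame(species = "spA", cell_type = c("TB", "STR", "EPI"),
                   compartment = c("fetal", "maternal", "maternal"),
                   cell_class = c("Troph", "Stromal", "Epithelial"),
                   n_cells = 40, stringsAsFactors = FALSE)
  tpm <- matrix(2.5e5, 3, 4, dimnames = dimnames(frac))
  atlas <- pseudobulk_atlas(md, list(spA = tpm), list(spA = frac))
  cat4 <- lr_catalog(paste0("I", 1:4), as.list(paste0("L", 1:4)),
                     as.list(paste0("R", 1:4)), rep(TRUE, 4),
                     rep("famX", 4))
  calls <- classify_compartment_expression(atlas, cat4, threshold = 0.2)
  expect_equal(calls$category, c("fetal_only", "both", "maternal_only", "off"))
  expect_equal(calls$n_fetal_on, c(1L, 1L, 0L, 0L))
  expect_equal(calls$n_maternal_on, c(0L, 1L, 1L, 0L))
})

test_that("homologue expansion scores species paralogues separately", {
  frac <- matrix(c(0.30, 0.05,
                   0.05, 0.30), 2, 2,
                 dimnames = list(c("TB", "STR"), c("spA:L1a", "spA:L1b")))
  md <- data.frame(species = "spA", cell_type = c("TB", "STR"),
                   compartment = c("fetal", "maternal"),
                   cell_class = c("Troph", "Stromal"), n_cells = 40,
                   stringsAsFactors = FALSE)
  tpm <- matrix(5e5, 2, 2, dimnames = dimnames(frac))
  atlas <- pseudobulk_atlas(md, list(spA = tpm), list(spA = frac))
  cat1 <- lr_catalog("I1", list("L1"), list("R1"), TRUE, "famX")
  om <- list(spA = data.frame(species_gene = c("spA:L1a", "spA:L1b"),
                              human_gene = "L1"))
  calls <- classify_compartment_expression(atlas, cat1, threshold = 0.2,
                                           expand_homologues = TRUE,
                                           ortho_maps = om)
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$category, c("fetal_only", "maternal_only"))
})

test_that("family null expectations follow the printed formulas", {
  fc <- data.frame(family = "famX", category = c("both", "both"),
                   n_fetal_on = c(1, 1), n_maternal_on = c(1, 1))
  nullm <- family_null_expectation(fc, n_fetal = 2, n_maternal = 2)
  expect_equal(nullm$P_on, 0.5)                 # 4 / (2 * 4)
  expect_equal(unname(nullm$probs["fetal_only"]), (1 - 0.25) * 0.25)  # 0.1875
  expect_equal(unname(nullm$expected["fetal_only"]), 0.375)
  # probability quadruple sums to one on random parameters
  set.seed(71)
  for (i in 1:20) {
    S <- sample(2:30, 1); nf <- sample(1:8, 1); nm <- sample(1:8, 1)
    nfo <- rbinom(S, nf, runif(1)); nmo <- rbinom(S, nm, runif(1))
    fc2 <- data.frame(family = "f",
                      category = ifelse(nfo > 0 & nmo > 0, "both",
                                        ifelse(nfo > 0, "fetal_only",
                                               ifelse(nmo > 0, "maternal_only",
                                                      "off"))),
                      n_fetal_on = nfo, n_maternal_on = nmo)
    nl <- family_null_expectation(fc2, nf, nm)
    expect_equal(sum(nl$probs) + nl$P_off, 1, tolerance = 1e-12)
    # unconditioned expected counts sum to S * (1 - P_off)
    expect_equal(sum(nl$expected), nl$S_pathway * (1 - nl$P_off),
                 tolerance = 1e-12)
  }
  # zero expression collapses every expectation
  fc0 <- data.frame(family = "f", category = c("off", "off"),
                    n_fetal_on = 0, n_maternal_on = 0)
  nl0 <- family_null_expectation(fc0, 2, 2)
  expect_equal(nl0$P_on, 0)
  expect_equal(unname(nl0$expected), c(0, 0, 0))
  # impossible call counts are an integrity error
  bad <- data.frame(family = "f", category = "both", n_fetal_on = 9,
                    n_maternal_on = 9)
  expect_error(family_null_expectation(bad, 2, 2), "integrity")
})

test_that("the goodness-of-fit statistic matches hand computation", {
  res <- family_gof_test(observed = c(both = 4, fetal_only = 0,
                                      maternal_only = 0),
                         expected = c(both = 2, fetal_only = 1,
                                      maternal_only = 1), mc = FALSE)
  expect_equal(res$chi2, 4)        # 2 + 1 + 1
  expect_equal(res$df, 2)
  expect_equal(res$p, exp(-2))     # chi2 survival at 4 with 2 df
  same <- family_gof_test(observed = c(both = 2, fetal_only = 1,
                                       maternal_only = 1),
                          expected = c(both = 2, fetal_only = 1,
                                       maternal_only = 1), mc = FALSE)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
})

test_that("BH over a single family leaves q equal to the inference p", {
  fc <- simulate_family_calls(10, 3, 3, p_on = 0.3, seed = 73)
  md <- data.frame(species = "sim", cell_type = paste0("ct", 1:6),
                   compartment = rep(c("fetal", "maternal"), each = 3),
                   cell_class = "cl", n_cells = 30, stringsAsFactors = FALSE)
  res <- test_disambiguation(fc, md, mc = FALSE)
  expect_equal(res$q, res$p)
  res_mc <- test_disambiguation(fc, md, mc = TRUE, B = 199, seed = 5)
  expect_equal(res_mc$q, res_mc$p_mc)
})

test_that("transition counting matches a brute-force branch scan", {
  tr <- ape::read.tree(text = "((A:1,B:1)E:1,(C:1,D:1)F:1)R;")
  labs <- c("A", "B", "C", "D", "R", "E", "F")
  set.seed(79)
  fet <- matrix(rbinom(7 * 6, 1, 0.5), 7, 6,
                dimnames = list(labs, paste0("L", 1:6)))
  mat <- matrix(rbinom(7 * 6, 1, 0.5), 7, 6,
                dimnames = list(labs, paste0("L", 1:6)))
  tt <- disambiguation_transitions(tr, fet, mat)
  # row-normalized percentages sum to 100 where defined
  rs <- rowSums(tt$percent)
  expect_true(all(abs(rs[!is.na(rs)] - 100) < 1e-9))
  # brute-force recount
  lev <- c("0/0", "1/0", "0/1", "1/1")
  brute <- matrix(0, 4, 4, dimnames = list(lev, lev))
  for (e in seq_len(nrow(tr$edge))) {
    p <- labs[tr$edge[e, 1]]; ch <- labs[tr$edge[e, 2]]
    for (l in 1:6) {
      from <- paste(fet[p, l], mat[p, l], sep = "/")
      to <- paste(fet[ch, l], mat[ch, l], sep = "/")
      brute[from, to] <- brute[from, to] + 1
    }
  }
  expect_equal(unname(tt$counts), unname(brute))
  expect_equal(tt$n_changes, sum(brute) - sum(diag(brute)))
})

test_that("a parent (0,1) to child (1,0) branch is a disambiguated outcome", {
  tr <- ape::read.tree(text = "(A:1,B:1)R;")
  fet <- matrix(c(1, 0, 0), 3, 1, dimnames = list(c("A", "B", "R"), "L1"))
  mat <- matrix(c(0, 1, 1), 3, 1, dimnames = list(c("A", "B", "R"), "L1"))
  tt <- disambiguation_transitions(tr, fet, mat)
  expect_equal(unname(tt$counts["0/1", "1/0"]), 1)
  expect_equal(tt$n_disambiguated, 1)
  expect_equal(unname(tt$fetal_only_double), 1)
  # gain-vs-loss decomposition of fetal-only arrivals
  fet2 <- matrix(c(1, 1, 0), 3, 1, dimnames = dimnames(fet))
  mat2 <- matrix(c(0, 0, 0), 3, 1, dimnames = dimnames(mat))
  tt2 <- disambiguation_transitions(tr, fet2, mat2)
  expect_equal(unname(tt2$fetal_only_from_gain), 2)  # placental gains
  expect_equal(unname(tt2$fetal_only_from_loss), 0)
})
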
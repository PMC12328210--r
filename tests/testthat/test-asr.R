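quartet <- function() {
  tr <- ape::read.tree(text = "((A:1,B:1)E:1,(C:1,D:1)F:1)R;")
  tr
}

test_that("class collapsing applies the any-cell-type-passes rule", {
  frac <- matrix(c(0.10, 0.25, 0.0,
                   0.05, 0.00, 0.0), 2, 3, byrow = TRUE,
                 dimnames = list(c("TB1", "TB2"), c("g1", "g2", "g3")))
  md <- data.frame(species = "spA", cell_type = c("TB1", "TB2"),
                   compartment = "fetal", cell_class = "Trophoblastic",
                   n_cells = 30, stringsAsFactors = FALSE)
  tpm <- matrix(1e6 / 3, 2, 3, dimnames = dimnames(frac))
  atlas <- pseudobulk_atlas(md, list(spA = tpm), list(spA = frac))
  cc <- collapse_to_classes(atlas, threshold = 0.2)
  # {0.10, 0.05} < 0.2 everywhere for g1? no: g1 has 0.10 and 0.05 -> 0
  expect_equal(unname(cc$binary["spA", "Trophoblastic|g1"]), 0)
  # g2: one cell type at 0.25 passes -> 1, proportion = max
  expect_equal(unname(cc$binary["spA", "Trophoblastic|g2"]), 1)
  expect_equal(unname(cc$proportion["spA", "Trophoblastic|g2"]), 0.25)
  # all fractions 0 -> 0
  expect_equal(unname(cc$binary["spA", "Trophoblastic|g3"]), 0)
})

test_that("class collapsing equals brute-force max-then-threshold", {
  sim <- simulate_atlas(seed = 9, config = list(cells_per_type = 20,
                                                n_interactions = 20,
                                                n_genes = 100))
  h <- humanize_atlas(sim$atlas, sim$ortho_maps, cells = sim$cells)
  genes <- unique(unlist(sim$catalog$ligand_subunits))[1:10]
  cc <- collapse_to_classes(h, genes = genes, threshold = 0.2)
  md <- h$metadata
  for (sp in c("human", "opossum")) {
    for (cl in unique(md$cell_class[md$species == sp])) {
      cts <- md$cell_type[md$species == sp & md$cell_class == cl]
      for (g in genes) {
        mx <- max(h$frac_expr[[sp]][cts, g])
        expect_equal(unname(cc$binary[sp, paste(cl, g, sep = "|")]),
                     as.numeric(mx >= 0.2))
        expect_equal(unname(cc$proportion[sp, paste(cl, g, sep = "|")]), mx)
      }
    }
  }
})

test_that("Sankoff reconstruction solves the quartet under both cost schemes", {
  tr <- quartet()
  x <- c(A = 1, B = 1, C = 0, D = 0)
  # gains cost 2, losses 1: unique optimum root=1, E=1, F=0, cost 1
  res21 <- sankoff_asr(tr, x, cost_matrix(gain = 2, loss = 1))
  expect_equal(unname(res21$min_cost), 1)
  expect_equal(unname(res21$node_states["R", 1]), "1")
  expect_equal(unname(res21$node_states["E", 1]), "1")
  expect_equal(unname(res21$node_states["F", 1]), "0")
  # equal costs: cost 1, root ambiguous
  res11 <- sankoff_asr(tr, x, cost_matrix(1, 1))
  expect_equal(unname(res11$min_cost), 1)
  expect_equal(unname(res11$node_states["R", 1]), "ambiguous")
  expect_equal(unname(res11$node_states["E", 1]), "1")
  expect_equal(unname(res11$node_states["F", 1]), "0")
  # constant characters are free
  res_const <- sankoff_asr(tr, c(A = 1, B = 1, C = 1, D = 1), cost_matrix(2, 1))
  expect_equal(unname(res_const$min_cost), 0)
  expect_true(all(res_const$node_states == "1"))
})

test_that("Sankoff agrees with exhaustive enumeration on random trees", {
  set.seed(41)
  schemes <- list(cost_matrix(1, 1), cost_matrix(2, 1))
  for (trial in 1:40) {
    tr <- rand_bin_tree(sample(4:8, 1))
    x <- setNames(rbinom(length(tr$tip.label), 1, 0.5), tr$tip.label)
    if (length(unique(x)) == 1) x[1] <- 1 - x[1]
    for (costs in schemes) {
      res <- sankoff_asr(tr, x, costs)
      orc <- oracle_parsimony(tr, x, costs)
      expect_equal(unname(res$min_cost), orc$min_cost)
      expect_equal(unname(res$node_states[, 1]), orc$sets)
    }
  }
})

test_that("equal-cost Sankoff state sets equal Fitch bottom-up/top-down sets", {
  set.seed(43)
  for (trial in 1:40) {
    tr <- rand_bin_tree(sample(4:8, 1))
    x <- setNames(rbinom(length(tr$tip.label), 1, 0.5), tr$tip.label)
    res <- sankoff_asr(tr, x, cost_matrix(1, 1))
    expect_equal(unname(res$node_states[, 1]), oracle_fitch_sets(tr, x))
  }
})

test_that("Wagner MPR matches equal-cost Sankoff on binary characters", {
  tr <- quartet()
  # all leaves 1 -> all nodes 1
  all1 <- wagner_mpr(tr, c(A = 1, B = 1, C = 1, D = 1), outgroup = "A")
  expect_true(all(all1$node_states == "1"))
  expect_error(wagner_mpr(tr, c(A = 1, B = 1, C = 1, D = 1), "nope"),
               "outgroup")
  # quartet: non-root nodes match the exhaustive sets
  x <- c(A = 1, B = 1, C = 0, D = 0)
  wag <- wagner_mpr(tr, x, outgroup = "A")
  orc <- oracle_parsimony(tr, x, cost_matrix(1, 1))
  expect_equal(unname(wag$node_states["F", 1]), orc$sets[3])
  # random trees: shared (non-root) nodes agree with equal-cost Sankoff
  set.seed(47)
  for (trial in 1:100) {
    tr2 <- rand_bin_tree(sample(4:8, 1))
    x2 <- setNames(rbinom(length(tr2$tip.label), 1, 0.5), tr2$tip.label)
    wag2 <- wagner_mpr(tr2, x2, outgroup = tr2$tip.label[1])
    san2 <- sankoff_asr(tr2, x2, cost_matrix(1, 1))
    shared <- setdiff(rownames(san2$node_states),
                      rownames(san2$node_states)[1])  # root is row 1
    expect_equal(wag2$node_states[shared, 1], san2$node_states[shared, 1])
  }
})

test_that("Brownian ancestral values solve the small closed-form cases", {
  # two-leaf symmetric tree: root is the midpoint
  t2 <- ape::read.tree(text = "(A:1,B:1)R;")
  bm2 <- brownian_asr(t2, matrix(c(4, 0), 2, 1, dimnames = list(c("A", "B"), "tr")))
  expect_equal(unname(bm2$node_values["R", "tr"]), 2)
  # constant trait: every node takes the same value
  tr <- quartet()
  bmc <- brownian_asr(tr, matrix(3.5, 4, 1, dimnames = list(LETTERS[1:4], "tr")))
  expect_true(all(abs(bmc$node_values - 3.5) < 1e-12))
  # three-leaf star: root equals the GLS phylogenetic mean
  star <- ape::read.tree(text = "(A:1,B:1,C:2)R;")
  y <- c(A = 0, B = 0, C = 3)
  bms <- brownian_asr(star, matrix(y, 3, 1, dimnames = list(names(y), "tr")))
  expect_equal(unname(bms$node_values["R", "tr"]),
               as.numeric(oracle_gls_root(star, y)))
})

test_that("Brownian ancestral values match independent reconstructions", {
  set.seed(53)
  for (trial in 1:20) {
    tr <- rand_bin_tree(sample(4:6, 1))
    y <- setNames(rnorm(length(tr$tip.label), 0, 2), tr$tip.label)
    bm <- brownian_asr(tr, matrix(y, length(y), 1,
                                  dimnames = list(names(y), "tr")))
    expect_equal(unname(bm$node_values[, "tr"]), oracle_fastanc(tr, y),
                 tolerance = 1e-8)
  }
  # ape's REML states agree to the precision of its rate optimizer
  tr <- rand_bin_tree(6)
  y <- setNames(rnorm(6), tr$tip.label)
  bm <- brownian_asr(tr, matrix(y, 6, 1, dimnames = list(names(y), "tr")))
  expect_equal(unname(bm$node_values[, "tr"]),
               suppressWarnings(oracle_reml_asr(tr, y)), tolerance = 1e-4)
})

test_that("Brownian reconstruction is affine-equivariant", {
  set.seed(59)
  tr <- rand_bin_tree(6)
  y <- setNames(rnorm(6), tr$tip.label)
  m <- matrix(y, 6, 1, dimnames = list(names(y), "tr"))
  a <- 2.7; b <- -1.3
  expect_equal(brownian_asr(tr, a * m + b)$node_values,
               a * brownian_asr(tr, m)$node_values + b)
})

test_that("binarization is inclusive at the cutoff and idempotent", {
  v <- c(0.21, 0.2, 0.19, 0)
  expect_equal(unname(binarize_states(v, 0.2)), c(1, 1, 0, 0))
  expect_equal(binarize_states(binarize_states(v, 0.2), 0.2),
               binarize_states(v, 0.2))
})

test_that("method agreement counts identical node configurations", {
  tr <- quartet()
  chars <- matrix(c(1, 1, 0, 0,
                    1, 0, 1, 0,
                    1, 1, 1, 0,
                    0, 0, 0, 1), 4, 4,
                  dimnames = list(LETTERS[1:4], paste0("k", 1:4)))
  a <- sankoff_asr(tr, chars, cost_matrix(1, 1))
  expect_equal(compare_methods(a, a)$agreement, 1.0)
  b <- a
  b$node_states[1, "k2"] <- if (b$node_states[1, "k2"] == "1") "0" else "1"
  cm <- compare_methods(a, b)
  expect_equal(cm$agreement, 0.75)  # one of four characters altered
  expect_equal(compare_methods(b, a)$agreement, cm$agreement)  # symmetric
})

test_that("branch events are gains and losses relative to the parent", {
  tr <- quartet()
  states <- matrix(c(1, 1, 0, 0,  # tips A B C D
                     0, 1, 0),    # R E F
                   7, 1, dimnames = list(c("A", "B", "C", "D", "R", "E", "F"),
                                         "k1"))
  ev <- branch_changes(tr, states)
  expect_true(any(ev$parent == "R" & ev$child == "E" & ev$event == "gain"))
  # E(1) -> A(1): no event on that branch
  expect_false(any(ev$child == "A"))
  # brute-force total over a random state assignment
  set.seed(61)
  st <- matrix(rbinom(7 * 5, 1, 0.5), 7, 5,
               dimnames = list(c("A", "B", "C", "D", "R", "E", "F"),
                               paste0("k", 1:5)))
  ev2 <- branch_changes(tr, st)
  labs <- c("A", "B", "C", "D", "R", "E", "F")
  n_expected <- 0
  for (e in seq_len(nrow(tr$edge))) {
    p <- labs[tr$edge[e, 1]]; ch <- labs[tr$edge[e, 2]]
    n_expected <- n_expected + sum(st[p, ] != st[ch, ])
  }
  expect_equal(nrow(ev2), n_expected)
})

test_that("ancestral networks obey the all-subunit rule", {
  states <- c("Trophoblastic|L1" = 1, "Stromal|R1" = 1, "Stromal|L1" = 0,
              "Trophoblastic|R1" = 0,
              "Trophoblastic|L2" = 1, "Stromal|R2" = 1, "Stromal|C2" = 0,
              "Trophoblastic|R2" = 0, "Trophoblastic|C2" = 0,
              "Stromal|L2" = 0)
  cat2 <- lr_catalog(c("I1", "I2"), list("L1", "L2"),
                     list("R1", c("R2", "C2")), c(TRUE, TRUE), c("f1", "f2"),
                     list(TRUE, c(TRUE, FALSE)))
  net <- ancestral_network(states, cat2)
  expect_true(any(net$sender_class == "Trophoblastic" &
                    net$receiver_class == "Stromal" &
                    net$interaction_id == "I1"))
  # heterodimeric receptor with C2 off nowhere satisfied
  expect_false("I2" %in% net$interaction_id)
  # monotone: switching a state on never removes edges
  states2 <- states; states2["Stromal|C2"] <- 1
  net2 <- ancestral_network(states2, cat2)
  key <- function(n) paste(n$sender_class, n$receiver_class, n$interaction_id)
  expect_true(all(key(net) %in% key(net2)))
  expect_true("I2" %in% net2$interaction_id)
})

test_that("network edge ages find the oldest continuous ancestor", {
  tr <- quartet()
  cat1 <- lr_catalog("I1", list("L1"), list("R1"), TRUE, "f1")
  # edge present at R and E and A; absent at F
  chars <- c("X|L1", "X|R1")
  full <- matrix(0, 7, 2, dimnames = list(c("A", "B", "C", "D", "R", "E", "F"),
                                          chars))
  full[c("A", "E", "R"), ] <- 1
  net <- network_edge_ages(tr, full, "E", cat1)
  expect_equal(net$age_node, "R")  # present at E and continuously at R
  full2 <- full; full2["R", 1] <- 0
  net2 <- network_edge_ages(tr, full2, "E", cat1)
  expect_equal(net2$age_node, "E")
})
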
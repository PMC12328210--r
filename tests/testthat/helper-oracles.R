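# Independent oracles and small fixtures used across the suite.
# Each oracle is a deliberately naive reimplementation (enumeration,
# double loops, closed forms) kept separate from the package's code paths.

# ---- trees -----------------------------------------------------------------

rand_bin_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1  # keep lengths well above zero
  tr$tip.label <- paste0("sp", seq_len(n))
  tr
}

# ---- parsimony by exhaustive enumeration ----------------------------------

# Min total cost and per-internal-node sets of states attainable in some
# minimum-cost labelling, by brute force over all 2^Nnode labellings.
oracle_parsimony <- function(tree, x, costs) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  labellings <- as.matrix(expand.grid(rep(list(0:1), nnode)))
  states <- matrix(NA_integer_, nrow(labellings), ntip + nnode)
  states[, seq_len(ntip)] <- matrix(rep(x[tree$tip.label], each = nrow(labellings)),
                                    nrow(labellings))
  states[, (ntip + 1):(ntip + nnode)] <- labellings
  cost <- numeric(nrow(labellings))
  for (e in seq_len(nrow(tree$edge))) {
    p <- states[, tree$edge[e, 1]]; ch <- states[, tree$edge[e, 2]]
    cost <- cost + costs[cbind(p + 1, ch + 1)]
  }
  mc <- min(cost)
  best <- labellings[cost <= mc + 1e-9, , drop = FALSE]
  sets <- apply(best, 2, function(col) {
    u <- unique(col)
    if (length(u) == 2) "ambiguous" else as.character(u)
  })
  list(min_cost = mc, sets = unname(sets))
}

# Fitch/Hartigan bottom-up/top-down state sets for uniform-cost binary
# parsimony (sets encoded as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}).
# Upward pass: U = states attaining the max child-support count K,
# UU = states at count K-1. Downward: F(root) = U(root); F(child) =
# F(parent) when F(parent) is within U(child), else U(child) plus any
# parent state one step short of optimal (in UU).
oracle_fitch_sets <- function(tree, x) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  U <- integer(ntip + nnode); UU <- integer(ntip + nnode)
  U[seq_len(ntip)] <- x[tree$tip.label] + 1L
  post <- ape::reorder.phylo(tree, "postorder")$edge
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  for (v in unique(post[, 1])) {
    ch <- kids[[as.character(v)]]
    cnt <- c(sum(vapply(ch, function(c2) bitwAnd(U[c2], 1L) > 0, TRUE)),
             sum(vapply(ch, function(c2) bitwAnd(U[c2], 2L) > 0, TRUE)))
    K <- max(cnt)
    U[v] <- sum(c(1L, 2L)[cnt == K])
    UU[v] <- sum(c(1L, 2L)[cnt == K - 1L])
  }
  Fset <- integer(ntip + nnode)
  root <- ntip + 1L
  Fset[root] <- U[root]
  for (e in rev(seq_len(nrow(post)))) {
    v <- post[e, 2]
    if (v <= ntip) next
    p <- post[e, 1]
    Fset[v] <- if (bitwAnd(Fset[p], U[v]) == Fset[p]) Fset[p]
    else bitwOr(U[v], bitwAnd(Fset[p], UU[v]))
  }
  code <- c("0", "1", "ambiguous")
  code[Fset[(ntip + 1L):(ntip + nnode)]]
}

# ---- Brownian ancestral states via independent tools ----------------------

# exact ancestral expectations (phytools re-rooting algorithm)
oracle_fastanc <- function(tree, y) {
  unname(phytools::fastAnc(tree, y[tree$tip.label]))
}

# ape's REML reconstruction (optimizer-limited precision ~1e-5)
oracle_reml_asr <- function(tree, y) {
  fit <- ape::ace(y[tree$tip.label], tree, type = "continuous",
                  method = "REML")
  unname(fit$ace)
}

# GLS root estimate on an arbitrary (possibly multifurcating) tree by
# direct matrix inversion of the Brownian covariance.
oracle_gls_root <- function(tree, y) {
  V <- ape::vcv(tree)[names(y), names(y)]
  one <- rep(1, length(y))
  solve(t(one) %*% solve(V) %*% one) %*% t(one) %*% solve(V) %*% y
}

# ---- HITS via eigen decomposition -----------------------------------------

oracle_hits <- function(W) {
  hub <- abs(eigen(W %*% t(W))$vectors[, 1])
  auth <- abs(eigen(t(W) %*% W)$vectors[, 1])
  list(hub = hub / max(hub), authority = auth / max(auth))
}

# ---- brute-force statistics ------------------------------------------------

brute_fraction_expressing <- function(counts, cell_type) {
  cts <- sort(unique(cell_type))
  out <- matrix(0, length(cts), ncol(counts),
                dimnames = list(cts, colnames(counts)))
  for (ct in cts) {
    rows <- which(cell_type == ct)
    for (g in seq_len(ncol(counts))) {
      out[ct, g] <- sum(counts[rows, g] > 0) / length(rows)
    }
  }
  out
}

brute_alc <- function(counts, catalog) {
  alc <- integer(nrow(counts))
  for (c in seq_len(nrow(counts))) {
    v <- counts[c, ]
    total <- 0L
    for (i in seq_len(nrow(catalog))) {
      lig <- catalog$ligand_subunits[[i]]
      rec <- catalog$receptor_subunits[[i]]
      L <- all(lig %in% colnames(counts)) && all(v[lig] > 0)
      R <- all(rec %in% colnames(counts)) && all(v[rec] > 0)
      if (L && !R) total <- total + 1L
    }
    alc[c] <- total
  }
  alc
}

brute_interaction_calls <- function(frac, catalog, threshold) {
  calls <- list()
  for (s in rownames(frac)) for (r in rownames(frac)) {
    for (i in seq_len(nrow(catalog))) {
      lig <- catalog$ligand_subunits[[i]]
      rec <- catalog$receptor_subunits[[i]]
      l_on <- all(lig %in% colnames(frac)) && all(frac[s, lig] >= threshold)
      r_on <- all(rec %in% colnames(frac)) && all(frac[r, rec] >= threshold)
      calls[[length(calls) + 1L]] <- data.frame(
        sender = s, receiver = r, interaction_id = catalog$interaction_id[i],
        called = l_on && r_on, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, calls)
}

# one-way ANOVA from first principles
brute_anova <- function(values, groups) {
  grand <- mean(values)
  k <- length(unique(groups))
  n <- length(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# ---- fixtures --------------------------------------------------------------

tiny_catalog <- function() {
  lr_catalog(
    interaction_id = c("I1", "I2", "I3", "I4"),
    ligand_subunits = list("L1", "L2", "L3", c("L4a", "L4b")),
    receptor_subunits = list("R1", "R2", c("R3", "C3"), "R4"),
    is_secreted = c(TRUE, TRUE, TRUE, FALSE),
    family = c("famA", "famA", "famB", "famC"),
    binding_subunits = list(TRUE, TRUE, c(TRUE, FALSE), TRUE))
}

# 3-cell-type single-species pseudobulk atlas over a small gene set
tiny_atlas <- function(genes = c("L1", "L2", "L3", "L4a", "L4b",
                                 "R1", "R2", "R3", "C3", "R4"),
                       frac = NULL) {
  md <- data.frame(species = "spA",
                   cell_type = c("TB", "STR", "EPI"),
                   compartment = c("fetal", "maternal", "maternal"),
                   cell_class = c("Trophoblastic", "Stromal", "Epithelial"),
                   n_cells = 50, replicate = "rep1",
                   stringsAsFactors = FALSE)
  if (is.null(frac)) {
    set.seed(99)
    frac <- matrix(round(runif(3 * length(genes)), 2), 3,
                   dimnames = list(md$cell_type, genes))
  }
  tpm <- matrix(stats::rexp(3 * length(genes)), 3,
                dimnames = list(md$cell_type, genes))
  tpm <- sweep(tpm, 1, rowSums(tpm), "/") * 1e6
  pseudobulk_atlas(md, tpm = list(spA = tpm), frac_expr = list(spA = frac))
}

rand_cells <- function(n_cells = 50, n_genes = 20, n_types = 4, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_cells * n_genes, 0.7), n_cells,
                   dimnames = list(paste0("c", seq_len(n_cells)),
                                   paste0("g", seq_len(n_genes))))
  counts[, 1] <- counts[, 1] + 1L  # keep every cell total positive
  meta <- data.frame(cell_id = rownames(counts), species = "spA",
                     cell_type = rep_len(paste0("ct", seq_len(n_types)), n_cells),
                     replicate = "rep1", stringsAsFactors = FALSE)
  cell_level_matrix(counts, meta)
}
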
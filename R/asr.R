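#' Collapse cell-type expression to cell-class characters
#'
#' Builds the species x character matrices used for ancestral state
#' reconstruction. A character is a (cell class, gene) pair such as
#' `"Trophoblastic|IGF1"`: its binary state in a species is 1 iff at least
#' one cell type of that class passes the fraction-expressing threshold,
#' and its companion proportion value is the maximum fraction over the
#' class's cell types (the leading cluster). A class absent from a species
#' yields `NA` for all its characters in that species.
#'
#' @param atlas A humanized [pseudobulk_atlas()].
#' @param genes Genes to build characters for (default: union of atlas
#'   genes).
#' @param threshold On-call threshold (default 0.2, inclusive).
#' @param classes Cell classes to use (default: all in the metadata).
#' @return List with `binary` and `proportion` matrices (species x
#'   character) and the `characters` data frame (`character`, `cell_class`,
#'   `gene`).
#' @export
collapse_to_classes <- function(atlas, genes = NULL, threshold = 0.2,
                                classes = NULL) {
  md <- atlas$metadata
  if (is.null(classes)) classes <- sort(unique(md$cell_class))
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(atlas$frac_expr, colnames))))
  }
  species <- names(atlas$frac_expr)
  chars <- expand.grid(gene = genes, cell_class = classes,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  chars$character <- paste(chars$cell_class, chars$gene, sep = "|")
  prop <- matrix(NA_real_, length(species), nrow(chars),
                 dimnames = list(species, chars$character))
  for (sp in species) {
    fr <- atlas$frac_expr[[sp]]
    sp_md <- md[md$species == sp, , drop = FALSE]
    for (cl in classes) {
      cts <- sp_md$cell_type[sp_md$cell_class == cl]
      if (!length(cts)) next  # class absent in this species -> NA
      sub <- fr[cts, intersect(genes, colnames(fr)), drop = FALSE]
      mx <- apply(sub, 2, max)
      cols <- paste(cl, colnames(sub), sep = "|")
      prop[sp, cols] <- mx
      # genes absent from this species' universe: fraction 0
      absent <- setdiff(genes, colnames(fr))
      if (length(absent)) prop[sp, paste(cl, absent, sep = "|")] <- 0
    }
  }
  binary <- (prop >= threshold) * 1
  list(binary = binary, proportion = prop,
       characters = chars[, c("character", "cell_class", "gene")])
}

#' Transition cost matrix for binary parsimony
#'
#' @param gain Cost of a 0 to 1 transition (expression gain).
#' @param loss Cost of a 1 to 0 transition (expression loss).
#' @return 2x2 matrix with zero diagonal, dimnames `c("0","1")`,
#'   `costs["0","1"] = gain`.
#' @export
cost_matrix <- function(gain = 1, loss = 1) {
  if (gain < 0 || loss < 0) stop("costs must be non-negative")
  matrix(c(0, loss, gain, 0), 2, 2, dimnames = list(c("0", "1"), c("0", "1")))
}

#' Sankoff parsimony ancestral state reconstruction
#'
#' Weighted-parsimony dynamic programming for binary characters on a
#' rooted bifurcating tree. For each character, computes the minimum total
#' transition cost and, for every internal node, the set of states
#' attainable in at least one minimum-cost labelling (a bottom-up cost
#' pass followed by a top-down pass over the outside-subtree costs). The
#' root state is chosen by minimum cost with no prior. Deterministic.
#'
#' The gain-penalising scheme of the pipeline uses
#' `cost_matrix(gain = 2, loss = 1)` (expression gains cost twice as much
#' as losses); the equal-weights scheme uses `cost_matrix(1, 1)`.
#'
#' @param tree Rooted bifurcating `phylo`.
#' @param chars Binary matrix, species x characters (values 0/1; a
#'   character with any `NA` leaf state is skipped with a warning).
#' @param costs A [cost_matrix()].
#' @return An `asr_result`: list with `method`, `node_states` (internal
#'   node x character matrix with entries `"0"`, `"1"`, `"ambiguous"`),
#'   `min_cost` (per character), `tree`.
#' @export
sankoff_asr <- function(tree, chars, costs = cost_matrix(1, 1)) {
  validate_species_tree(tree)
  chars <- as_char_matrix(chars, tree)
  keep <- !apply(chars, 2, anyNA)
  if (!all(keep)) {
    warning("sankoff_asr: skipping ", sum(!keep), " character(s) with missing leaf states")
    chars <- chars[, keep, drop = FALSE]
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  edge <- tree$edge
  # children list per internal node
  kids <- split(edge[, 2], edge[, 1])
  porder <- postorder_nodes(tree)
  nlab <- node_labels(tree)
  inf <- .Machine$double.xmax / 4
  n_char <- ncol(chars)
  node_states <- matrix(NA_character_, nnode, n_char,
                        dimnames = list(nlab, colnames(chars)))
  min_cost <- numeric(n_char)
  names(min_cost) <- colnames(chars)
  for (k in seq_len(n_char)) {
    x <- chars[tree$tip.label, k]
    # S[node, s]: min cost of subtree of node given node has state s (0/1)
    S <- matrix(inf, ntip + nnode, 2)
    S[cbind(seq_len(ntip), x + 1L)] <- 0
    for (v in porder) {
      for (s in 1:2) {
        S[v, s] <- sum(vapply(kids[[as.character(v)]], function(ch) {
          min(costs[s, 1] + S[ch, 1], costs[s, 2] + S[ch, 2])
        }, numeric(1)))
      }
    }
    mc <- min(S[root, ])
    min_cost[k] <- mc
    # T[node, s]: min cost outside node's subtree given node state s,
    # including the edge into node. T[root, ] = 0.
    Tm <- matrix(inf, ntip + nnode, 2)
    Tm[root, ] <- 0
    for (v in rev(porder)) {
      ch_v <- kids[[as.character(v)]]
      for (ch in ch_v) {
        sib <- setdiff(ch_v, ch)
        for (t in 1:2) {
          best <- Inf
          for (s in 1:2) {
            sib_cost <- sum(vapply(sib, function(sb) {
              min(costs[s, 1] + S[sb, 1], costs[s, 2] + S[sb, 2])
            }, numeric(1)))
            best <- min(best, Tm[v, s] + costs[s, t] + sib_cost)
          }
          Tm[ch, t] <- best
        }
      }
    }
    tol <- 1e-9 * max(1, mc)
    sets <- vapply((ntip + 1L):(ntip + nnode), function(v) {
      ok <- which(S[v, ] + Tm[v, ] <= mc + tol)
      if (length(ok) == 2L) "ambiguous" else as.character(ok - 1L)
    }, character(1))
    node_states[, k] <- sets
  }
  structure(list(method = sprintf("sankoff_gain%g_loss%g",
                                  costs["0", "1"], costs["1", "0"]),
                 node_states = node_states, min_cost = min_cost, tree = tree),
            class = "asr_result")
}

# Internal nodes in postorder (children before parents).
postorder_nodes <- function(tree) {
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  unique(edge[, 1])
}

as_char_matrix <- function(chars, tree) {
  if (is.null(dim(chars))) chars <- matrix(chars, ncol = 1,
                                           dimnames = list(names(chars), "char1"))
  if (is.null(rownames(chars))) stop("character matrix needs species rownames")
  missing <- setdiff(tree$tip.label, rownames(chars))
  if (length(missing)) stop("no character states for: ",
                            paste(missing, collapse = ", "))
  chars[tree$tip.label, , drop = FALSE]
}

#' Wagner parsimony ancestral states (MPR)
#'
#' Most-parsimonious-reconstruction intervals for ordered (Wagner)
#' characters on the unrooted tree with a designated outgroup, via
#' [ape::MPR()]. For binary characters the interval collapses to `"0"`,
#' `"1"` or `"ambiguous"`. The rooted tree's root node has no counterpart
#' on the unrooted tree; its state is set to the outgroup's observed tip
#' state (the outgroup defines the ancestral condition, so gains on the
#' outgroup's own branch are disallowed under this model).
#'
#' @param tree Rooted bifurcating `phylo` with at least 4 tips.
#' @param chars Binary species x character matrix.
#' @param outgroup Tip label used to root the reconstruction.
#' @return An `asr_result` (same layout as [sankoff_asr()], `min_cost`
#'   absent).
#' @export
wagner_mpr <- function(tree, chars, outgroup) {
  validate_species_tree(tree)
  if (!outgroup %in% tree$tip.label) stop("outgroup not found: ", outgroup)
  chars <- as_char_matrix(chars, tree)
  keep <- !apply(chars, 2, anyNA)
  if (!all(keep)) {
    warning("wagner_mpr: skipping ", sum(!keep), " character(s) with missing leaf states")
    chars <- chars[, keep, drop = FALSE]
  }
  ntip <- length(tree$tip.label)
  utree <- ape::unroot(tree)
  map <- match_unrooted_nodes(tree, utree)
  nlab <- node_labels(tree)
  root <- ntip + 1L
  node_states <- matrix(NA_character_, tree$Nnode, ncol(chars),
                        dimnames = list(nlab, colnames(chars)))
  for (k in seq_len(ncol(chars))) {
    x <- chars[utree$tip.label, k]
    mpr <- ape::MPR(unname(x), utree, outgroup)
    st <- ifelse(mpr[, "lower"] == mpr[, "upper"],
                 as.character(mpr[, "lower"]), "ambiguous")
    # MPR names rows by node number, or by node label when present
    rn <- rownames(mpr)
    unrooted_nodes <- if (all(grepl("^[0-9]+$", rn))) as.integer(rn)
    else ntip + match(rn, utree$node.label)
    rooted_nodes <- map[as.character(unrooted_nodes)]
    node_states[rooted_nodes - ntip, k] <- st
    node_states[root - ntip, k] <- as.character(chars[outgroup, k])
  }
  structure(list(method = sprintf("wagner_mpr_outgroup_%s", outgroup),
                 node_states = node_states, min_cost = NULL, tree = tree),
            class = "asr_result")
}

# Map internal node numbers of unroot(tree) back to rooted node numbers by
# matching descendant tip sets; the one unrooted node whose set is not a
# rooted clade (the basal node absorbing the old root) is matched by
# elimination.
match_unrooted_nodes <- function(tree, utree) {
  ntip <- length(tree$tip.label)
  tipset <- function(tr, node) {
    sort(ape::extract.clade(tr, node)$tip.label)
  }
  rooted_nodes <- (ntip + 2L):(ntip + tree$Nnode)  # all but the root
  rkeys <- vapply(rooted_nodes, function(v) paste(tipset(tree, v), collapse = ";"), "")
  unrooted_nodes <- (ntip + 1L):(ntip + utree$Nnode)
  ukeys <- vapply(unrooted_nodes, function(v) {
    desc <- unrooted_clade_tips(utree, v)
    paste(sort(desc), collapse = ";")
  }, "")
  map <- integer(0)
  hit <- match(ukeys, rkeys)
  map[as.character(unrooted_nodes[!is.na(hit)])] <- rooted_nodes[hit[!is.na(hit)]]
  left_u <- unrooted_nodes[is.na(hit)]
  left_r <- setdiff(rooted_nodes, map)
  if (length(left_u) != length(left_r) || length(left_u) > 1) {
    stop("internal error: cannot match unrooted nodes to rooted tree")
  }
  map[as.character(left_u)] <- left_r
  map
}

# Tips below a node of a tree stored with a basal multifurcation.
unrooted_clade_tips <- function(tr, node) {
  ntip <- length(tr$tip.label)
  out <- integer(0); stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    ch <- tr$edge[tr$edge[, 1] == v, 2]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  tr$tip.label[out]
}

#' Brownian-motion ancestral trait expectations (GLS / REML)
#'
#' Ancestral values of continuous characters (here, 0-1 expression
#' proportions) under Brownian motion. The root value is the generalised
#' least squares phylogenetic mean and every internal node takes its
#' conditional expectation given the tip values; these expectations are
#' identical for any positive rate, so the REML rate estimate (reported as
#' `sigma2`, from the mean squared independent contrast) affects only
#' uncertainty, not the reconstructed states. Vectorised over characters.
#'
#' @param tree Rooted bifurcating `phylo` with positive branch lengths.
#' @param values Numeric species x character matrix.
#' @return List with `node_values` (internal node x character),
#'   `root` (row of `node_values`), and `sigma2` (per character).
#' @export
brownian_asr <- function(tree, values) {
  # GLS expectations need neither bifurcation nor a basal dichotomy;
  # the stored basal node acts as the root
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    stop("all branch lengths must be present and > 0")
  }
  values <- as_char_matrix(values, tree)
  storage.mode(values) <- "double"
  ntip <- length(tree$tip.label)
  V <- ape::vcv(tree)[tree$tip.label, tree$tip.label]
  Vi <- solve(V)
  one <- rep(1, ntip)
  Y <- values[tree$tip.label, , drop = FALSE]
  denom <- sum(Vi)
  root_hat <- as.vector((one %*% Vi %*% Y) / denom)
  resid <- sweep(Y, 2, root_hat, "-")
  ViR <- Vi %*% resid
  # shared path length between each internal node and each tip
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  tips <- seq_len(ntip)[match(tree$tip.label, tree$tip.label)]
  Cmat <- matrix(depth[mr[nodes, tips, drop = FALSE]], nrow = length(nodes))
  node_values <- sweep(Cmat %*% ViR, 2, root_hat, "+")
  dimnames(node_values) <- list(node_labels(tree), colnames(values))
  # contrasts-based REML rate (needs a fully dichotomous tree)
  sigma2 <- if (ape::is.binary(tree) && ape::is.rooted(tree)) {
    vapply(seq_len(ncol(Y)), function(k) {
      mean(ape::pic(stats::setNames(Y[, k], tree$tip.label), tree)^2)
    }, numeric(1))
  } else rep(NA_real_, ncol(Y))
  names(sigma2) <- colnames(values)
  list(node_values = node_values, root = node_values[1, ], sigma2 = sigma2)
}

#' Binarize continuous node values
#'
#' @param values Numeric vector/matrix of reconstructed proportions.
#' @param cutoff Inclusive cutoff (default 0.2): `value >= cutoff` is 1.
#' @return Same shape, values in \{0, 1\}.
#' @export
binarize_states <- function(values, cutoff = 0.2) {
  (values >= cutoff) * 1
}

#' Agreement between ancestral reconstruction methods
#'
#' The fraction of characters whose full internal-node state configuration
#' is identical across all supplied methods (`"ambiguous"` counts as its
#' own state). Symmetric in argument order.
#'
#' @param ... Two or more `asr_result` objects (or a list of them) on the
#'   same tree and characters.
#' @return List with `agreement` (fraction), `n_char`, and `discordant`
#'   (per-character logical vector).
#' @export
compare_methods <- function(...) {
  results <- list(...)
  if (length(results) == 1L && !inherits(results[[1]], "asr_result")) {
    results <- results[[1]]
  }
  if (length(results) < 2) stop("need at least two asr_result objects")
  chars <- colnames(results[[1]]$node_states)
  nodes <- rownames(results[[1]]$node_states)
  for (r in results[-1]) {
    if (!identical(colnames(r$node_states), chars) ||
        !identical(rownames(r$node_states), nodes)) {
      stop("asr_result objects cover different characters or nodes")
    }
  }
  configs <- vapply(results, function(r) {
    apply(r$node_states, 2, paste, collapse = "/")
  }, character(length(chars)))
  if (is.null(dim(configs))) configs <- matrix(configs, nrow = 1,
                                               dimnames = list(chars, NULL))
  same <- apply(configs, 1, function(z) all(z == z[1]))
  list(agreement = mean(same), n_char = length(chars),
       discordant = !same)
}

#' Resolve ambiguous node states
#'
#' Downstream event counting needs unambiguous states; ambiguity resolves
#' to absence (0) by default - conservative about inferring ancestral
#' expression - or to presence.
#'
#' @param asr An `asr_result`.
#' @param to `"0"` (default) or `"1"`.
#' @return Numeric internal node x character matrix of 0/1 states.
#' @export
resolve_ambiguity <- function(asr, to = c("0", "1")) {
  to <- match.arg(to)
  st <- asr$node_states
  st[st == "ambiguous"] <- to
  out <- matrix(as.numeric(st), nrow(st), ncol(st), dimnames = dimnames(st))
  out
}

#' Per-branch gain and loss events
#'
#' Compares the resolved binary state of every character across each
#' branch: a gain is 0 in the immediate ancestor and 1 in the descendant,
#' a loss the reverse.
#'
#' @param tree Rooted bifurcating `phylo`.
#' @param states Full binary state matrix, (tips + internal nodes) x
#'   characters; rownames must cover all tip and node labels.
#' @return Data frame: `parent`, `child`, `character`, `event`
#'   (`"gain"`/`"loss"`).
#' @export
branch_changes <- function(tree, states) {
  labs <- all_node_labels(tree)
  missing <- setdiff(labs, rownames(states))
  if (length(missing)) stop("states missing for node(s): ",
                            paste(missing, collapse = ", "))
  edge <- tree$edge
  out <- list()
  for (e in seq_len(nrow(edge))) {
    p <- labs[edge[e, 1]]; ch <- labs[edge[e, 2]]
    d <- states[ch, ] - states[p, ]
    gained <- colnames(states)[d > 0]
    lost <- colnames(states)[d < 0]
    if (length(gained)) out[[length(out) + 1L]] <-
        data.frame(parent = p, child = ch, character = gained, event = "gain",
                   stringsAsFactors = FALSE)
    if (length(lost)) out[[length(out) + 1L]] <-
        data.frame(parent = p, child = ch, character = lost, event = "loss",
                   stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(parent = character(0), child = character(0),
                      character = character(0), event = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reconstructed cell-cell signalling network at one node
#'
#' Applies the all-subunit rule to the binary (cell class, gene) character
#' states of one (ancestral or extant) node: an edge sender class ->
#' receiver class exists for an interaction iff every ligand subunit
#' character is 1 in the sender class and every receptor subunit character
#' is 1 in the receiver class. Class self-pairs are included. Genes with
#' no character are treated as absent (0) and reported once.
#'
#' @param states Named numeric vector of binary states for characters
#'   `"Class|GENE"` at one node.
#' @param catalog An [lr_catalog()].
#' @param classes Cell classes to enumerate (default: classes present in
#'   `names(states)`).
#' @return Data frame: `sender_class`, `receiver_class`, `interaction_id`.
#' @export
ancestral_network <- function(states, catalog, classes = NULL) {
  parts <- strsplit(names(states), "|", fixed = TRUE)
  st_class <- vapply(parts, `[`, "", 1)
  st_gene <- vapply(parts, `[`, "", 2)
  if (is.null(classes)) classes <- sort(unique(st_class))
  gene_on <- function(cl, genes) {
    idx <- match(paste(cl, genes, sep = "|"), names(states))
    vals <- states[idx]
    vals[is.na(vals)] <- 0
    all(vals == 1)
  }
  missing <- setdiff(unique(unlist(c(catalog$ligand_subunits,
                                     catalog$receptor_subunits))),
                     unique(st_gene))
  if (length(missing)) {
    message("ancestral_network: ", length(missing),
            " catalog gene(s) without characters, treated as absent")
  }
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    lig_ok <- vapply(classes, gene_on, TRUE, genes = catalog$ligand_subunits[[i]])
    rec_ok <- vapply(classes, gene_on, TRUE, genes = catalog$receptor_subunits[[i]])
    if (!any(lig_ok) || !any(rec_ok)) next
    grid <- expand.grid(sender_class = classes[lig_ok],
                        receiver_class = classes[rec_ok],
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$interaction_id <- catalog$interaction_id[i]
    out[[length(out) + 1L]] <- grid
  }
  if (!length(out)) {
    return(data.frame(sender_class = character(0),
                      receiver_class = character(0),
                      interaction_id = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Phylogenetic age labels for ancestral network edges
#'
#' Labels each signalling edge present at a focal node with the oldest
#' ancestor (the focal node included) at which the edge is already
#' present and has remained present along every node down to the focal
#' node - i.e. the node where this ligand-receptor channel was
#' established.
#'
#' @param tree Rooted bifurcating `phylo`.
#' @param full_states Full binary state matrix (tips + internal nodes) x
#'   characters.
#' @param node Label of the focal node.
#' @param catalog An [lr_catalog()].
#' @return The [ancestral_network()] table at `node` with an extra
#'   `age_node` column.
#' @export
network_edge_ages <- function(tree, full_states, node, catalog) {
  labs <- all_node_labels(tree)
  path <- node_path_to_root(tree, node)  # node first, root last
  nets <- lapply(path, function(v) {
    net <- ancestral_network(full_states[v, ], catalog)
    paste(net$sender_class, net$receiver_class, net$interaction_id, sep = "\r")
  })
  net0 <- ancestral_network(full_states[node, ], catalog)
  keys <- paste(net0$sender_class, net0$receiver_class, net0$interaction_id,
                sep = "\r")
  age <- vapply(keys, function(k) {
    j <- 1L
    while (j < length(path) && k %in% nets[[j + 1L]]) j <- j + 1L
    path[j]
  }, "")
  net0$age_node <- unname(age)
  net0
}

node_path_to_root <- function(tree, node) {
  labs <- all_node_labels(tree)
  v <- match(node, labs)
  if (is.na(v)) stop("unknown node: ", node)
  root <- length(tree$tip.label) + 1L
  path <- labs[v]
  while (v != root) {
    v <- tree$edge[tree$edge[, 2] == v, 1]
    path <- c(path, labs[v])
  }
  path
}
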
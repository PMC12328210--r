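#' Threshold an expression fraction into an on/off call
#'
#' A gene is "on" in a cell type when the fraction of cells expressing it
#' reaches the threshold (20% by default throughout the pipeline,
#' inclusive: a fraction of exactly 0.20 is on).
#'
#' @param frac Numeric fraction(s) in \[0, 1\].
#' @param threshold Threshold in \[0, 1\] (default 0.2).
#' @param inclusive If `TRUE` (default), `frac >= threshold` is on;
#'   otherwise strict.
#' @return Logical vector.
#' @export
call_expressed <- function(frac, threshold = 0.2, inclusive = TRUE) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  stopifnot(all(frac >= 0 & frac <= 1))
  if (inclusive) frac >= threshold else frac > threshold
}

# Per-cell-type x interaction logical matrices: is every ligand (receptor)
# subunit on? Genes absent from the matrix are treated as off and reported
# once via attribute "missing_genes".
subunit_on_matrix <- function(frac, subunit_list, threshold, inclusive = TRUE) {
  genes <- colnames(frac)
  on <- call_expressed(frac, threshold, inclusive)
  missing <- unique(setdiff(unlist(subunit_list), genes))
  res <- vapply(subunit_list, function(su) {
    hit <- su %in% genes
    if (!all(hit)) return(rep(FALSE, nrow(frac)))
    if (length(su) == 1L) on[, su] else apply(on[, su, drop = FALSE], 1, all)
  }, logical(nrow(frac)))
  if (nrow(frac) == 1L) res <- matrix(res, nrow = 1,
                                      dimnames = list(rownames(frac), NULL))
  rownames(res) <- rownames(frac)
  attr(res, "missing_genes") <- missing
  res
}

#' Call ligand-receptor interactions between all cell-type pairs
#'
#' For every ordered (sender, receiver) pair of cell types within each
#' species and every catalog interaction, the interaction is called iff
#' every ligand subunit is on (per [call_expressed()]) in the sender and
#' every receptor subunit is on in the receiver (the all-subunit rule).
#' Autocrine pairs (sender == receiver) are included and labelled. Catalog
#' genes absent from the atlas are treated as off and reported once per
#' species via a message.
#'
#' @param atlas A humanized [pseudobulk_atlas()].
#' @param catalog An [lr_catalog()].
#' @param threshold On-call threshold (default 0.2).
#' @return Data frame: `species`, `sender`, `receiver`, `interaction_id`,
#'   `ligand_on`, `receptor_on`, `called`, `autocrine`.
#' @export
score_interactions <- function(atlas, catalog, threshold = 0.2) {
  out <- vector("list", length(atlas$frac_expr))
  names(out) <- names(atlas$frac_expr)
  for (sp in names(atlas$frac_expr)) {
    fr <- atlas$frac_expr[[sp]]
    lig_on <- subunit_on_matrix(fr, catalog$ligand_subunits, threshold)
    rec_on <- subunit_on_matrix(fr, catalog$receptor_subunits, threshold)
    miss <- union(attr(lig_on, "missing_genes"), attr(rec_on, "missing_genes"))
    if (length(miss)) {
      message("score_interactions [", sp, "]: ", length(miss),
              " catalog gene(s) absent from atlas, treated as off")
    }
    cts <- rownames(fr)
    grid <- expand.grid(sender = cts, receiver = cts,
                        interaction = seq_len(nrow(catalog)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    l_on <- lig_on[cbind(match(grid$sender, cts), grid$interaction)]
    r_on <- rec_on[cbind(match(grid$receiver, cts), grid$interaction)]
    out[[sp]] <- data.frame(
      species = sp, sender = grid$sender, receiver = grid$receiver,
      interaction_id = catalog$interaction_id[grid$interaction],
      ligand_on = l_on, receptor_on = r_on, called = l_on & r_on,
      autocrine = grid$sender == grid$receiver,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Allocrine ligand count (ALC) per cell
#'
#' The ALC of a cell is the number of catalog ligand-receptor pairs for
#' which the cell expresses the ligand (every ligand subunit captured with
#' at least one count) but not the cognate receptor (not every receptor
#' subunit non-zero): `ALC = sum_i L_i * (1 - R_i)` over the N catalog
#' pairs, with "on" defined as non-zero expression. It measures a cell's
#' intrinsic non-autocrine signalling potential and depends only on the
#' cell's own expression vector, not on how other cells are clustered. A
#' ligand participating in k catalog pairs contributes up to k
#' (`unique_ligands = TRUE` counts each distinct ligand at most once).
#'
#' @param cells A humanized [cell_level_matrix()].
#' @param catalog An [lr_catalog()].
#' @param unique_ligands Count each distinct ligand subunit set at most
#'   once (default `FALSE`, matching the sum over pairs).
#' @return Data frame: `cell_id`, `species`, `cell_type`, `replicate`,
#'   `alc` (non-negative integer, at most the number of catalog pairs).
#' @export
compute_alc <- function(cells, catalog, unique_ligands = FALSE) {
  stopifnot(nrow(catalog) > 0)
  expressed <- methods::as(cells$counts > 0, "CsparseMatrix") * 1
  genes <- colnames(expressed)
  all_on <- function(su) {
    hit <- su %in% genes
    if (!all(hit)) return(rep(FALSE, nrow(expressed)))
    if (length(su) == 1L) expressed[, su] > 0
    else Matrix::rowSums(expressed[, su, drop = FALSE]) == length(su)
  }
  lig_on <- vapply(catalog$ligand_subunits, all_on, logical(nrow(expressed)))
  rec_on <- vapply(catalog$receptor_subunits, all_on, logical(nrow(expressed)))
  allo <- lig_on & !rec_on
  if (unique_ligands) {
    lig_key <- vapply(catalog$ligand_subunits, paste, "", collapse = ";")
    alc <- rowSums(vapply(split(seq_len(nrow(catalog)), lig_key),
                          function(j) apply(allo[, j, drop = FALSE], 1, any),
                          logical(nrow(expressed))))
  } else {
    alc <- rowSums(allo)
  }
  data.frame(cell_id = rownames(expressed),
             species = cells$cell_meta$species,
             cell_type = cells$cell_meta$cell_type,
             replicate = cells$cell_meta$replicate,
             alc = as.integer(alc), stringsAsFactors = FALSE)
}

#' One-way ANOVA of mean ALC across cell-type classes
#'
#' Averages ALC over each unique (species, cell type, replicate) group and
#' runs a classical one-way ANOVA of those group means against cell-type
#' class, within one species (the pipeline reports one F per species; pass
#' pooled data and `species = NULL` for a pooled fit). Classes with no
#' groups are dropped with a warning.
#'
#' @param alc_table Output of [compute_alc()].
#' @param class_of Named character vector mapping cell type to cell-type
#'   class.
#' @param species Species to subset to, or `NULL` to use all rows.
#' @return List with `F`, `p`, `df`, and the group-mean table.
#' @export
alc_anova <- function(alc_table, class_of, species = NULL) {
  tab <- alc_table
  if (!is.null(species)) tab <- tab[tab$species == species, , drop = FALSE]
  if (!nrow(tab)) stop("no ALC rows for species ", species)
  grp <- aggregate(alc ~ species + cell_type + replicate, data = tab, FUN = mean)
  grp$cell_class <- unname(class_of[grp$cell_type])
  if (anyNA(grp$cell_class)) {
    warning("dropping ", sum(is.na(grp$cell_class)),
            " group(s) with no cell_class label")
    grp <- grp[!is.na(grp$cell_class), , drop = FALSE]
  }
  if (length(unique(grp$cell_class)) < 2) {
    stop("alc_anova needs at least two cell-type classes")
  }
  fit <- stats::aov(alc ~ cell_class, data = grp)
  s <- summary(fit)[[1]]
  f <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
  class_means <- tapply(grp$alc, grp$cell_class, mean)
  if (stats::var(as.numeric(class_means)) == 0) { f <- 0; p <- 1 }
  list(F = f, p = p, df = c(s[["Df"]][1], s[["Df"]][2]), groups = grp)
}

#' Build the weighted directed cell-cell signalling multigraph
#'
#' Nodes are cell types; one edge per (sender, receiver, interaction) with
#' weight equal to the product of the ligand and receptor mean
#' log-normalized CP10K values (minimum over subunits for multi-subunit
#' complexes, limiting-subunit logic). Zero-weight edges are omitted.
#' Autocrine self-loops are included.
#'
#' @param mean_ln Matrix of per-cell-type mean log-normalized expression
#'   ([mean_lognorm_by_celltype()]) for one species, on human genes.
#' @param catalog An [lr_catalog()].
#' @return An [igraph::graph_from_data_frame()] directed multigraph with
#'   edge attributes `interaction_id` and `weight`.
#' @export
build_signaling_graph <- function(mean_ln, catalog) {
  genes <- colnames(mean_ln)
  side_val <- function(su) {
    if (!all(su %in% genes)) return(rep(0, nrow(mean_ln)))
    if (length(su) == 1L) mean_ln[, su]
    else apply(mean_ln[, su, drop = FALSE], 1, min)
  }
  lig <- vapply(catalog$ligand_subunits, side_val, numeric(nrow(mean_ln)))
  rec <- vapply(catalog$receptor_subunits, side_val, numeric(nrow(mean_ln)))
  cts <- rownames(mean_ln)
  grid <- expand.grid(sender = seq_along(cts), receiver = seq_along(cts),
                      interaction = seq_len(nrow(catalog)),
                      KEEP.OUT.ATTRS = FALSE)
  w <- lig[cbind(grid$sender, grid$interaction)] *
    rec[cbind(grid$receiver, grid$interaction)]
  keep <- w > 0
  edges <- data.frame(from = cts[grid$sender[keep]], to = cts[grid$receiver[keep]],
                      weight = w[keep],
                      interaction_id = catalog$interaction_id[grid$interaction[keep]],
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = cts))
}

#' Kleinberg hub and authority scores of a signalling graph
#'
#' Parallel edges are collapsed by summing their weights, then HITS
#' hub/authority scores are computed on the weighted adjacency by
#' deterministic power iteration (hub update `h <- W a`, authority update
#' `a <- W' h`, i.e. the principal eigenvectors of `W W'` and `W' W`),
#' started from a uniform vector, converged to `tol` in the max norm or
#' `max_iter` iterations, and max-normalized to 1.
#'
#' @param graph A directed [igraph] graph with edge `weight`s, or a
#'   non-negative weighted adjacency matrix.
#' @param tol Convergence tolerance (default 1e-12).
#' @param max_iter Iteration cap (default 1000).
#' @return Data frame: `cell_type`, `hub`, `authority`.
#' @export
hits_scores <- function(graph, tol = 1e-12, max_iter = 1000) {
  if (inherits(graph, "igraph")) {
    if (igraph::ecount(graph) == 0) stop("hits_scores: graph has no edges")
    g <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = FALSE,
                          edge.attr.comb = list(weight = "sum", "ignore"))
    W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  } else {
    W <- as.matrix(graph)
    if (all(W == 0)) stop("hits_scores: graph has no edges")
  }
  n <- nrow(W)
  a <- rep(1, n); h <- rep(1, n)
  for (i in seq_len(max_iter)) {
    h_new <- as.vector(W %*% a)
    if (max(h_new) > 0) h_new <- h_new / max(h_new)
    a_new <- as.vector(crossprod(W, h_new))
    if (max(a_new) > 0) a_new <- a_new / max(a_new)
    if (max(abs(h_new - h)) < tol && max(abs(a_new - a)) < tol) {
      h <- h_new; a <- a_new
      break
    }
    h <- h_new; a <- a_new
  }
  data.frame(cell_type = rownames(W), hub = h, authority = a,
             stringsAsFactors = FALSE)
}
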
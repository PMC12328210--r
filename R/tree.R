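#' Time-calibrated six-species mammal phylogeny
#'
#' Returns the rooted, strictly bifurcating phylogeny of the six study
#' species (opossum, tenrec, guinea pig, mouse, macaque, human) with branch
#' lengths in millions of years (Myr) and named internal nodes. Only the
#' tenrec--human (crown Placentalia) divergence of 99 Myr is treated as a
#' fixed calibration; the remaining node ages are conventional
#' TimeTree-style defaults and can be overridden.
#'
#' @param ages Named numeric vector of crown node ages in Myr with elements
#'   `theria`, `placentalia`, `euarchontoglires`, `rodentia`, `catarrhini`.
#'   Ages must be strictly decreasing root-to-tip.
#' @return An [ape::read.tree()] `phylo` object with 6 tips and 5 labelled
#'   internal nodes (`Theria`, `Placentalia`, `Euarchontoglires`,
#'   `Rodentia`, `Catarrhini`).
#' @export
fixed_six_species_tree <- function(ages = c(theria = 160, placentalia = 99,
                                            euarchontoglires = 90,
                                            rodentia = 73, catarrhini = 29)) {
  need <- c("theria", "placentalia", "euarchontoglires", "rodentia", "catarrhini")
  if (!all(need %in% names(ages))) {
    stop("ages must name: ", paste(need, collapse = ", "))
  }
  a <- ages[need]
  if (any(diff(c(a[["theria"]], a[["placentalia"]], a[["euarchontoglires"]])) >= 0) ||
      a[["rodentia"]] >= a[["euarchontoglires"]] ||
      a[["catarrhini"]] >= a[["euarchontoglires"]]) {
    stop("node ages must decrease from root towards the tips")
  }
  txt <- sprintf(
    "(opossum:%g,(tenrec:%g,((guinea_pig:%g,mouse:%g)Rodentia:%g,(macaque:%g,human:%g)Catarrhini:%g)Euarchontoglires:%g)Placentalia:%g)Theria;",
    a[["theria"]],
    a[["placentalia"]],
    a[["rodentia"]], a[["rodentia"]], a[["euarchontoglires"]] - a[["rodentia"]],
    a[["catarrhini"]], a[["catarrhini"]], a[["euarchontoglires"]] - a[["catarrhini"]],
    a[["placentalia"]] - a[["euarchontoglires"]],
    a[["theria"]] - a[["placentalia"]])
  tree <- ape::read.tree(text = txt)
  validate_species_tree(tree)
  tree
}

#' Validate a species tree against an atlas
#'
#' Checks that a phylogeny is rooted, strictly bifurcating, has strictly
#' positive branch lengths and (optionally) that its tips match a set of
#' species identifiers exactly.
#'
#' @param tree A `phylo` object.
#' @param species Optional character vector of species identifiers the tips
#'   must match (order-insensitively).
#' @return The tree, invisibly. Errors on violation.
#' @export
validate_species_tree <- function(tree, species = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be strictly bifurcating")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    stop("all branch lengths must be present and > 0")
  }
  if (!is.null(species) && !setequal(tree$tip.label, species)) {
    stop("tree tips do not match atlas species: expected {",
         paste(sort(species), collapse = ", "), "}, got {",
         paste(sort(tree$tip.label), collapse = ", "), "}")
  }
  invisible(tree)
}

# Internal node labels, generating stable fallbacks where absent.
node_labels <- function(tree) {
  n_node <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab) || !length(lab)) lab <- rep("", n_node)
  empty <- is.na(lab) | lab == ""
  lab[empty] <- paste0("node", seq_len(n_node) + length(tree$tip.label))[empty]
  lab
}

# Map every node number (tips then internals) to a printable label.
all_node_labels <- function(tree) {
  c(tree$tip.label, node_labels(tree))
}
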
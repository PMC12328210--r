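#' Standardized log2 expression (zTPM)
#'
#' Standardizes TPM values within one species so that expression levels
#' are comparable across species with different dynamic ranges:
#' `zTPM = (log2(TPM) - mu) / sigma`, floored at `floor` (default -3, the
#' conventional lower bound for biologically relevant expression);
#' `TPM = 0` maps to the floor. The Gaussian parameters are fitted over
#' the positive entries of the species' matrix (the gene universe, not
#' per gene). The default `fit = "half_gaussian"` follows the zFPKM-style
#' procedure: `mu` is the kernel-density mode of the log2 values and
#' `sigma` is estimated from the right tail as
#' `(mean(x[x > mu]) - mu) * sqrt(pi/2)`, robust to the zero-inflated
#' left flank; `fit = "mean_sd"` uses the plain sample mean and SD.
#'
#' @param tpm Numeric vector or matrix of TPM values for one species.
#' @param floor Lower bound on the z-score (default -3).
#' @param fit `"half_gaussian"` (default) or `"mean_sd"`.
#' @return Object of the same shape with attributes `mu` and `sigma`.
#'   Strictly increasing in TPM above the floor.
#' @export
ztpm_transform <- function(tpm, floor = -3, fit = c("half_gaussian", "mean_sd")) {
  fit <- match.arg(fit)
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  pos <- log2(tpm[tpm > 0])
  if (length(pos) < 2) stop("need at least two positive TPM values to fit")
  if (fit == "half_gaussian") {
    d <- stats::density(pos)
    mu <- d$x[which.max(d$y)]
    upper <- pos[pos > mu]
    if (!length(upper)) stop("degenerate fit: no values above the mode")
    sigma <- (mean(upper) - mu) * sqrt(pi / 2)
  } else {
    mu <- mean(pos)
    sigma <- stats::sd(pos)
  }
  if (!is.finite(sigma) || sigma <= 0) stop("sigma estimate is not positive")
  z <- tpm
  z[] <- ifelse(tpm > 0, pmax((log2(pmax(tpm, .Machine$double.xmin)) - mu) / sigma,
                              floor), floor)
  attr(z, "mu") <- mu
  attr(z, "sigma") <- sigma
  z
}

#' Representative trait value of a gene in a compartment
#'
#' The cell types with the greatest ligand (fetal side) and receptor
#' (maternal side) expression are taken as the representative,
#' co-evolving trait carriers: returns the maximum value over the
#' compartment's cell types, ties broken lexicographically by cell-type
#' name.
#'
#' @param values Matrix cell types x genes (typically zTPM) for one
#'   species.
#' @param metadata Atlas metadata rows for that species.
#' @param gene Gene identifier.
#' @param compartment `"fetal"` or `"maternal"`.
#' @return List with `value` and `cell_type`.
#' @export
representative_trait <- function(values, metadata, gene, compartment) {
  cts <- metadata$cell_type[metadata$compartment == compartment]
  cts <- intersect(rownames(values), cts)
  if (!length(cts)) stop("no cell types in compartment ", compartment)
  if (!gene %in% colnames(values)) {
    return(list(value = NA_real_, cell_type = NA_character_))
  }
  v <- values[cts, gene]
  names(v) <- cts
  v <- v[order(names(v))]
  best <- names(v)[which.max(v)]  # first max after lexicographic sort
  list(value = unname(v[best]), cell_type = best)
}

#' Phylogenetic independent contrasts
#'
#' Felsenstein contrasts of a trait on a bifurcating tree via
#' [ape::pic()]: at each internal node the contrast is the difference of
#' the two daughter values scaled by the square root of their (extended)
#' branch lengths; n tips yield n - 1 contrasts that are i.i.d. under
#' Brownian motion.
#'
#' @param tree Rooted bifurcating `phylo` (polytomies are an error).
#' @param trait Named numeric vector of per-leaf values.
#' @return Numeric vector of n - 1 contrasts (named by internal node
#'   label).
#' @export
pic_contrasts <- function(tree, trait) {
  validate_species_tree(tree)
  if (!all(tree$tip.label %in% names(trait))) {
    stop("trait values missing for some tips")
  }
  out <- ape::pic(trait[tree$tip.label], tree)
  num <- suppressWarnings(as.integer(names(out)))
  if (!anyNA(num)) names(out) <- node_labels(tree)[num - length(tree$tip.label)]
  out
}

#' Regression through the origin on contrasts
#'
#' Fits `y = slope * x` on ligand/receptor contrast pairs (slope =
#' sum(xy)/sum(x^2)) and returns the two-sided t-test of the slope with
#' n - 1 degrees of freedom. By convention the receptor contrasts are the
#' response and the ligand contrasts the predictor
#' (`direction = "receptor_on_ligand"`); the flag swaps them. Degenerate
#' fits are flagged: `sum(x^2) = 0` yields an undefined slope, an exact
#' linear relation yields `p = 0` with `degenerate = TRUE`.
#'
#' @param ligand,receptor Numeric contrast vectors of equal length >= 2.
#' @param direction `"receptor_on_ligand"` (default) or
#'   `"ligand_on_receptor"`.
#' @return List: `slope`, `se`, `t`, `df`, `p`, `n`, `direction`,
#'   `degenerate`, `undefined`.
#' @export
pic_regression <- function(ligand, receptor,
                           direction = c("receptor_on_ligand",
                                         "ligand_on_receptor")) {
  direction <- match.arg(direction)
  stopifnot(length(ligand) == length(receptor), length(ligand) >= 2)
  if (direction == "receptor_on_ligand") { x <- ligand; y <- receptor }
  else { x <- receptor; y <- ligand }
  n <- length(x)
  sxx <- sum(x^2)
  # contrasts of a constant trait (e.g. every species at the zTPM floor)
  # carry only rounding residue; treat them as no variation
  if (max(abs(x)) < 1e-10) sxx <- 0
  if (sxx == 0) {
    return(list(slope = NA_real_, se = NA_real_, t = NA_real_, df = n - 1,
                p = NA_real_, n = n, direction = direction,
                degenerate = FALSE, undefined = TRUE))
  }
  slope <- sum(x * y) / sxx
  rss <- sum((y - slope * x)^2)
  df <- n - 1
  if (rss <= .Machine$double.eps * sum(y^2) || df == 0) {
    return(list(slope = slope, se = 0, t = Inf, df = df, p = 0, n = n,
                direction = direction, degenerate = TRUE, undefined = FALSE))
  }
  se <- sqrt(rss / df / sxx)
  tval <- slope / se
  list(slope = slope, se = se, t = tval, df = df,
       p = 2 * stats::pt(-abs(tval), df), n = n, direction = direction,
       degenerate = FALSE, undefined = FALSE)
}

#' Ordinary least squares slope (with intercept)
#'
#' Raw cross-species association of receptor on ligand zTPM (direction as
#' in [pic_regression()]); plotted against the contrast-based p-value in
#' the escalation volcano.
#'
#' @param ligand,receptor Numeric per-species zTPM vectors.
#' @inheritParams pic_regression
#' @return List: `slope`, `intercept`, `n`, `undefined`.
#' @export
ols_slope <- function(ligand, receptor,
                      direction = c("receptor_on_ligand", "ligand_on_receptor")) {
  direction <- match.arg(direction)
  keep <- is.finite(ligand) & is.finite(receptor)
  x <- ligand[keep]; y <- receptor[keep]
  if (direction == "ligand_on_receptor") { tmp <- x; x <- y; y <- tmp }
  if (length(x) < 3) stop("ols_slope needs at least 3 species with data")
  if (stats::var(x) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_, n = length(x),
                undefined = TRUE))
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(x), undefined = FALSE)
}

#' Escalation test over all candidate ligand-receptor pairs
#'
#' For each secreted interaction (after [filter_escalation_pairs()]):
#' extract per-species representative traits (fetal ligand, maternal
#' receptor) on the zTPM scale, keep pairs whose ligand and receptor both
#' have non-zero TPM in at least `min_species` species, compute
#' phylogenetic independent contrasts on the species tree, regress
#' through the origin, and report the two-sided slope p-value with
#' Bonferroni (0.05 / n pairs handled by the caller via `p_bonferroni`)
#' and Benjamini-Hochberg adjustments across tested pairs, plus the raw
#' OLS slope.
#'
#' Multi-subunit sides use their limiting subunit (minimum zTPM per cell
#' type) as the complex value.
#'
#' @param atlas Humanized [pseudobulk_atlas()].
#' @param catalog An [lr_catalog()]; filtered internally.
#' @param tree Species tree covering the atlas species.
#' @param threshold Unused here (calls are not thresholded); kept for
#'   config symmetry.
#' @param min_species Minimum species with non-zero representative TPM
#'   for both sides (default 4).
#' @param direction Regression direction, see [pic_regression()].
#' @param floor zTPM floor (default -3).
#' @param fit zTPM fit method.
#' @return Data frame: one row per tested pair with `interaction_id`,
#'   `ligand`, `receptor`, `pic_slope`, `pic_p`, `p_bonferroni`, `q_bh`,
#'   `ols_slope`, `n_contrasts`, `n_species`, `direction`, `degenerate`,
#'   `undefined`.
#' @export
test_escalation <- function(atlas, catalog, tree, min_species = 4,
                            direction = c("receptor_on_ligand",
                                          "ligand_on_receptor"),
                            floor = -3, fit = "half_gaussian",
                            threshold = NULL) {
  direction <- match.arg(direction)
  pairs <- filter_escalation_pairs(catalog)
  md <- atlas$metadata
  species <- names(atlas$tpm)
  validate_species_tree(tree, species)
  ztpm <- lapply(atlas$tpm, ztpm_transform, floor = floor, fit = fit)
  side_trait <- function(sp, subunits, compartment) {
    vals <- vapply(subunits, function(g) {
      representative_trait(ztpm[[sp]], md[md$species == sp, ], g, compartment)$value
    }, numeric(1))
    if (anyNA(vals)) NA_real_ else min(vals)  # limiting subunit
  }
  side_tpm_pos <- function(sp, subunits, compartment) {
    cts <- md$cell_type[md$species == sp & md$compartment == compartment]
    tp <- atlas$tpm[[sp]]
    all(subunits %in% colnames(tp)) &&
      all(vapply(subunits, function(g) max(tp[cts, g]) > 0, TRUE))
  }
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    lig_su <- pairs$ligand_subunits[[i]]
    rec_su <- pairs$receptor_subunits[[i]]
    lig_ok <- vapply(species, side_tpm_pos, TRUE, subunits = lig_su,
                     compartment = "fetal")
    rec_ok <- vapply(species, side_tpm_pos, TRUE, subunits = rec_su,
                     compartment = "maternal")
    if (sum(lig_ok) < min_species || sum(rec_ok) < min_species) next
    lig <- vapply(species, side_trait, numeric(1), subunits = lig_su,
                  compartment = "fetal")
    rec <- vapply(species, side_trait, numeric(1), subunits = rec_su,
                  compartment = "maternal")
    if (anyNA(lig) || anyNA(rec)) next
    lc <- pic_contrasts(tree, lig)
    rc <- pic_contrasts(tree, rec)
    reg <- pic_regression(lc, rc, direction)
    ols <- ols_slope(lig, rec, direction)
    rows[[length(rows) + 1L]] <- data.frame(
      interaction_id = pairs$interaction_id[i],
      ligand = paste(lig_su, collapse = ";"),
      receptor = paste(rec_su, collapse = ";"),
      pic_slope = reg$slope, pic_p = reg$p,
      ols_slope = ols$slope,
      n_contrasts = reg$n, n_species = length(species),
      direction = direction,
      degenerate = reg$degenerate, undefined = reg$undefined,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("no ligand-receptor pair passes the ", min_species, "-species filter")
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_bonferroni <- pmin(1, res$pic_p * sum(!is.na(res$pic_p)))
  res$q_bh <- stats::p.adjust(res$pic_p, method = "BH")
  res
}

#' Per-branch evolutionary changes of reconstructed traits
#'
#' Joins tip values and Brownian ancestral node values and returns, per
#' branch, the change `descendant - ancestor` (a gain of expression is
#' positive) for each character. The terminal-branch rows support the
#' escalation/de-escalation quadrant reading: escalation on a branch is a
#' ligand increase paired with a receptor decrease.
#'
#' @param tree Rooted bifurcating `phylo`.
#' @param leaf_values Species x character matrix of trait values.
#' @param node_values Internal node x character matrix
#'   ([brownian_asr()]`$node_values`).
#' @return Data frame: `parent`, `child`, `character`, `delta`,
#'   `terminal`.
#' @export
branch_trait_changes <- function(tree, leaf_values, node_values) {
  full <- rbind(leaf_values[tree$tip.label, , drop = FALSE],
                node_values[node_labels(tree), , drop = FALSE])
  labs <- all_node_labels(tree)
  rownames(full) <- labs
  edge <- tree$edge
  out <- lapply(seq_len(nrow(edge)), function(e) {
    p <- labs[edge[e, 1]]; ch <- labs[edge[e, 2]]
    data.frame(parent = p, child = ch, character = colnames(full),
               delta = full[ch, ] - full[p, ],
               terminal = edge[e, 2] <= length(tree$tip.label),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
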
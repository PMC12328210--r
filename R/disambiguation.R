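#' Classify ligand expression by fetal/maternal compartment
#'
#' Per species, each ligand is "on" in a compartment iff at least one cell
#' type of that compartment passes the fraction-expressing threshold on
#' every ligand subunit, yielding a category `fetal_only`,
#' `maternal_only`, `both` or `off`. With `expand_homologues`, species
#' paralogues mapping to a catalog (single-subunit) human ligand are
#' scored as separate potential ligands on the species-native atlas.
#'
#' @param atlas A [pseudobulk_atlas()]; humanized unless
#'   `expand_homologues = TRUE`, in which case species-native with
#'   `ortho_maps` supplied.
#' @param catalog An [lr_catalog()] (typically secreted-filtered).
#' @param threshold On-call threshold (default 0.2).
#' @param expand_homologues Score species paralogues of a human ligand as
#'   separate ligands (default `FALSE`).
#' @param ortho_maps Named list of orthologue maps (needed when
#'   expanding).
#' @return Data frame: `species`, `ligand`, `human_ligand`, `family`,
#'   `category`, `n_fetal_on`, `n_maternal_on` (per-cell-type on-call
#'   counts feeding the null model).
#' @export
classify_compartment_expression <- function(atlas, catalog, threshold = 0.2,
                                            expand_homologues = FALSE,
                                            ortho_maps = NULL) {
  md <- atlas$metadata
  lig_key <- vapply(catalog$ligand_subunits, paste, "", collapse = ";")
  uniq <- !duplicated(lig_key)
  ligands <- catalog$ligand_subunits[uniq]
  families <- catalog$family[uniq]
  names(families) <- lig_key[uniq]
  out <- list()
  for (sp in names(atlas$frac_expr)) {
    fr <- atlas$frac_expr[[sp]]
    sp_md <- md[md$species == sp, , drop = FALSE]
    fet <- sp_md$cell_type[sp_md$compartment == "fetal"]
    mat <- sp_md$cell_type[sp_md$compartment == "maternal"]
    if (!length(fet) || !length(mat)) {
      stop("species ", sp, " lacks a fetal or maternal compartment")
    }
    units <- lapply(seq_along(ligands), function(i) {
      list(ligand = paste(ligands[[i]], collapse = ";"),
           human = paste(ligands[[i]], collapse = ";"),
           subunits = ligands[[i]])
    })
    if (expand_homologues) {
      if (is.null(ortho_maps[[sp]])) stop("expand_homologues needs ortho_maps for ", sp)
      om <- ortho_maps[[sp]]
      expanded <- list()
      for (u in units) {
        if (length(u$subunits) > 1L) { expanded[[length(expanded) + 1L]] <- u; next }
        paras <- om$species_gene[om$human_gene == u$subunits]
        if (!length(paras)) { expanded[[length(expanded) + 1L]] <- u; next }
        for (p in paras) {
          expanded[[length(expanded) + 1L]] <-
            list(ligand = p, human = u$human, subunits = p)
        }
      }
      units <- expanded
    }
    on <- call_expressed(fr, threshold)
    res <- lapply(units, function(u) {
      present <- u$subunits %in% colnames(fr)
      if (!all(present)) {
        nf <- 0L; nm <- 0L
      } else {
        su_on <- if (length(u$subunits) == 1L) on[, u$subunits] else
          apply(on[, u$subunits, drop = FALSE], 1, all)
        nf <- sum(su_on[fet]); nm <- sum(su_on[mat])
      }
      data.frame(species = sp, ligand = u$ligand, human_ligand = u$human,
                 family = unname(families[u$human]),
                 category = if (nf > 0 && nm > 0) "both"
                 else if (nf > 0) "fetal_only"
                 else if (nm > 0) "maternal_only" else "off",
                 n_fetal_on = nf, n_maternal_on = nm,
                 stringsAsFactors = FALSE)
    })
    out[[sp]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Null-model expectations for a ligand family
#'
#' Under random assignment of a family's observed per-cell-type "on" calls
#' across cell types regardless of compartment, each (ligand, cell type)
#' slot is on with probability
#' `P_on = L_expressed / (S_pathway * (N_fetal + N_maternal))`, giving
#' \deqn{P_{fetal\ only} = (1 - (1-P_{on})^{N_f}) (1-P_{on})^{N_m}}
#' and symmetrically for maternal-only; `P_both` and `P_off` follow by
#' complement (the four probabilities sum to 1). Expected category counts
#' multiply these by the family size `S_pathway` (the unconditioned
#' expectation, `expected`); for the goodness-of-fit test
#' the three expressed-category probabilities are conditioned on
#' expression (divided by `1 - P_off`) and scaled to the observed number
#' of expressed ligands so observed and expected totals match
#' (`expected_conditioned`).
#'
#' @param family_calls Rows of [classify_compartment_expression()] for one
#'   family in one species (or pooled).
#' @param n_fetal,n_maternal Numbers of fetal and maternal cell types.
#' @return List of class `family_null` with the counts, probabilities and
#'   both expectation triples (`both`, `fetal_only`, `maternal_only`).
#' @export
family_null_expectation <- function(family_calls, n_fetal, n_maternal) {
  stopifnot(n_fetal >= 1, n_maternal >= 1)
  S <- nrow(family_calls)
  if (S < 1) stop("family has no ligands")
  L <- sum(family_calls$n_fetal_on + family_calls$n_maternal_on)
  slots <- S * (n_fetal + n_maternal)
  if (L > slots) stop("integrity error: L_expressed exceeds available slots")
  p_on <- L / slots
  p_off <- (1 - p_on)^(n_fetal + n_maternal)
  p_f <- (1 - (1 - p_on)^n_fetal) * (1 - p_on)^n_maternal
  p_m <- (1 - (1 - p_on)^n_maternal) * (1 - p_on)^n_fetal
  p_both <- 1 - p_off - p_f - p_m
  obs <- c(both = sum(family_calls$category == "both"),
           fetal_only = sum(family_calls$category == "fetal_only"),
           maternal_only = sum(family_calls$category == "maternal_only"))
  n_expr <- sum(obs)
  probs <- c(both = p_both, fetal_only = p_f, maternal_only = p_m)
  expected <- probs * S
  cond <- if (p_off < 1) probs / (1 - p_off) else probs * 0
  structure(list(family = family_calls$family[1], S_pathway = S,
                 n_fetal = n_fetal, n_maternal = n_maternal,
                 L_expressed = L, P_on = p_on, P_off = p_off,
                 probs = probs, observed = obs,
                 expected = expected,
                 expected_conditioned = cond * n_expr,
                 n_expressed = n_expr),
            class = "family_null")
}

#' Chi-squared goodness-of-fit test of a family against its null
#'
#' One-way chi-squared test of the observed (co-expressed, fetal-only,
#' maternal-only) counts against the conditioned null expectations, df =
#' retained categories - 1. Categories with zero expectation are dropped
#' (with a warning if their observed count is non-zero, reducing df).
#' The Bonferroni-style adjustment multiplies p by the number of ligands
#' in the family (capped at 1); Benjamini-Hochberg q-values are computed
#' across families by [test_disambiguation()].
#'
#' @param null A `family_null` (or an observed/expected pair via
#'   `observed`/`expected` arguments).
#' @param observed,expected Optional explicit triples overriding `null`.
#' @param mc Also compute a Monte-Carlo (parametric bootstrap) p-value
#'   `p_mc` for the same chi-squared statistic by resimulating `B` null
#'   families at the fitted `P_on` and re-estimating the null in each
#'   (default `TRUE` when `null` is supplied). The analytic chi-squared
#'   reference is conservative here because `P_on` is estimated from the
#'   same on-calls being categorized; the simulated reference restores
#'   the nominal error rate.
#' @param B Bootstrap replicates (default 999).
#' @return Data frame row: `family`, observed and expected counts,
#'   `chi2`, `df`, `p`, `p_mc`, `p_bonferroni`.
#' @export
family_gof_test <- function(null = NULL, observed = NULL, expected = NULL,
                            mc = !is.null(null), B = 999) {
  if (is.null(observed)) observed <- null$observed
  if (is.null(expected)) expected <- null$expected_conditioned
  S <- if (!is.null(null)) null$S_pathway else sum(observed)
  fam <- if (!is.null(null)) null$family else NA_character_
  chi_df <- gof_statistic(observed, expected, warn = TRUE)
  p <- if (chi_df[["df"]] > 0) {
    stats::pchisq(chi_df[["chi2"]], chi_df[["df"]], lower.tail = FALSE)
  } else 1
  p_mc <- NA_real_
  if (mc) {
    if (is.null(null)) stop("Monte-Carlo p-value needs the family_null object")
    sims <- vapply(seq_len(B), function(b) {
      nf <- stats::rbinom(null$S_pathway, null$n_fetal, null$P_on)
      nm <- stats::rbinom(null$S_pathway, null$n_maternal, null$P_on)
      sim_calls <- data.frame(family = fam,
                              category = ifelse(nf > 0 & nm > 0, "both",
                                                ifelse(nf > 0, "fetal_only",
                                                       ifelse(nm > 0, "maternal_only",
                                                              "off"))),
                              n_fetal_on = nf, n_maternal_on = nm,
                              stringsAsFactors = FALSE)
      sim_null <- family_null_expectation(sim_calls, null$n_fetal,
                                          null$n_maternal)
      gof_statistic(sim_null$observed, sim_null$expected_conditioned)[["chi2"]]
    }, numeric(1))
    p_mc <- (1 + sum(sims >= chi_df[["chi2"]])) / (B + 1)
  }
  data.frame(family = fam,
             obs_both = observed[["both"]],
             obs_fetal_only = observed[["fetal_only"]],
             obs_maternal_only = observed[["maternal_only"]],
             exp_both = expected[["both"]],
             exp_fetal_only = expected[["fetal_only"]],
             exp_maternal_only = expected[["maternal_only"]],
             chi2 = chi_df[["chi2"]], df = chi_df[["df"]], p = p, p_mc = p_mc,
             p_bonferroni = min(1, p * S),
             stringsAsFactors = FALSE)
}

gof_statistic <- function(observed, expected, warn = FALSE) {
  keep <- expected > 0
  if (warn && any(!keep & observed > 0)) {
    warning("family_gof_test: observed counts in zero-expectation categories; ",
            "categories dropped, df reduced")
  }
  o <- observed[keep]; e <- expected[keep]
  if (length(o) < 2 || sum(e) == 0) {
    c(chi2 = 0, df = 0)
  } else {
    c(chi2 = sum((o - e)^2 / e), df = length(o) - 1)
  }
}

#' Disambiguation test over all ligand families
#'
#' Runs [family_null_expectation()] and [family_gof_test()] for every
#' family of a species' compartment calls and adds Benjamini-Hochberg
#' q-values across families (on the inference p-value: `p_mc` when
#' Monte-Carlo is on, the analytic `p` otherwise).
#'
#' @param calls Output of [classify_compartment_expression()].
#' @param metadata Atlas metadata (for fetal/maternal cell-type counts).
#' @param species Species to test (default: each in turn).
#' @param min_ligands Families smaller than this are skipped (default 2).
#' @param mc,B Monte-Carlo settings, see [family_gof_test()].
#' @param seed Optional seed making the Monte-Carlo p-values
#'   reproducible (local to this call).
#' @return Data frame with one row per (species, family).
#' @export
test_disambiguation <- function(calls, metadata, species = NULL,
                                min_ligands = 2, mc = TRUE, B = 999,
                                seed = NULL) {
  if (is.null(species)) species <- unique(calls$species)
  with_seed(seed, {
    rows <- list()
    for (sp in species) {
      sp_calls <- calls[calls$species == sp, , drop = FALSE]
      md <- metadata[metadata$species == sp, , drop = FALSE]
      nf <- sum(md$compartment == "fetal")
      nm <- sum(md$compartment == "maternal")
      for (fam in sort(unique(sp_calls$family))) {
        fc <- sp_calls[sp_calls$family == fam, , drop = FALSE]
        if (nrow(fc) < min_ligands) next
        nullm <- family_null_expectation(fc, nf, nm)
        row <- family_gof_test(nullm, mc = mc, B = B)
        row <- cbind(data.frame(species = sp, stringsAsFactors = FALSE), row)
        row$S_pathway <- nullm$S_pathway
        row$L_expressed <- nullm$L_expressed
        row$P_on <- nullm$P_on
        rows[[length(rows) + 1L]] <- row
      }
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res$q <- stats::p.adjust(if (mc) res$p_mc else res$p, method = "BH")
    res
  })
}

#' Joint fetal/maternal expression transitions on the tree
#'
#' Codes each ligand at every node (tips and resolved internal nodes) as
#' a joint binary state (F, M) of fetal and maternal expression, counts
#' one parent-to-child transition per branch per ligand, and returns the
#' 4x4 transition-count matrix together with its row-normalized
#' percentage form. Transitions into a disambiguated state - fetal-only
#' (1,0) or maternal-only (0,1) from a different state - are totalled,
#' and fetal-only outcomes are decomposed into gains of placental (fetal)
#' expression (from (0,0)), losses of maternal expression (from (1,1))
#' and simultaneous double changes (from (0,1)).
#'
#' @param tree Rooted bifurcating `phylo`.
#' @param fetal_states,maternal_states Full binary state matrices
#'   (tips + internal nodes) x ligands, same dimnames, same tree.
#' @return List with `counts` (4x4), `percent` (rows summing to 100 where
#'   defined), `n_changes` (off-diagonal transition total),
#'   `n_disambiguated`, `fetal_only_from_gain`, `fetal_only_from_loss`,
#'   `fetal_only_double`.
#' @export
disambiguation_transitions <- function(tree, fetal_states, maternal_states) {
  if (!identical(dimnames(fetal_states), dimnames(maternal_states))) {
    stop("fetal and maternal state matrices must share dimnames")
  }
  labs <- all_node_labels(tree)
  if (!all(labs %in% rownames(fetal_states))) {
    stop("state matrices do not cover this tree's nodes")
  }
  lev <- c("0/0", "1/0", "0/1", "1/1")  # F/M
  joint <- matrix(paste(fetal_states, maternal_states, sep = "/"),
                  nrow(fetal_states), dimnames = dimnames(fetal_states))
  counts <- matrix(0L, 4, 4, dimnames = list(lev, lev))
  edge <- tree$edge
  for (e in seq_len(nrow(edge))) {
    p <- joint[labs[edge[e, 1]], ]
    ch <- joint[labs[edge[e, 2]], ]
    tab <- table(factor(p, lev), factor(ch, lev))
    counts <- counts + tab
  }
  percent <- sweep(counts, 1, rowSums(counts), "/") * 100
  percent[rowSums(counts) == 0, ] <- NA
  off <- counts; diag(off) <- 0L
  n_disamb <- sum(off[, c("1/0", "0/1")])
  list(counts = counts, percent = percent,
       n_changes = sum(off),
       n_disambiguated = n_disamb,
       fetal_only_from_gain = counts["0/0", "1/0"],
       fetal_only_from_loss = counts["1/1", "1/0"],
       fetal_only_double = counts["0/1", "1/0"])
}
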
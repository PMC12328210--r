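#' Construct / load a ligand-receptor interaction catalog
#'
#' The catalog models multi-subunit ligand-receptor interactions in the
#' style of CellPhoneDB complex tables: each interaction has a non-empty
#' set of (human) ligand subunit genes, a non-empty set of receptor subunit
#' genes with a per-subunit flag separating cognate ligand-binding subunits
#' from co-receptors, a secreted/membrane flag and exactly one
#' ligand-family label. Families must partition ligands: a ligand subunit
#' set may not appear under two families.
#'
#' On disk the catalog is a TSV with columns `interaction_id`,
#' `ligand_subunits` and `receptor_subunits` (semicolon-joined gene lists),
#' `is_secreted` (`TRUE`/`FALSE`), `family`, and `binding_subunits`
#' (semicolon-joined `1`/`0` flags aligned with `receptor_subunits`).
#'
#' @param interaction_id,family Character vectors.
#' @param ligand_subunits,receptor_subunits Lists of character vectors.
#' @param is_secreted Logical vector.
#' @param binding_subunits List of logical vectors aligned with
#'   `receptor_subunits`.
#' @return A data frame of class `lr_catalog` with list-columns for the
#'   subunit sets.
#' @export
lr_catalog <- function(interaction_id, ligand_subunits, receptor_subunits,
                       is_secreted, family, binding_subunits = NULL) {
  if (is.null(binding_subunits)) {
    binding_subunits <- lapply(receptor_subunits, function(r) rep(TRUE, length(r)))
  }
  cat <- data.frame(interaction_id = interaction_id,
                    is_secreted = is_secreted, family = family,
                    stringsAsFactors = FALSE)
  cat$ligand_subunits <- ligand_subunits
  cat$receptor_subunits <- receptor_subunits
  cat$binding_subunits <- binding_subunits
  class(cat) <- c("lr_catalog", "data.frame")
  validate_catalog(cat)
}

#' @rdname lr_catalog
#' @param path TSV file path.
#' @export
load_lr_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("interaction_id", "ligand_subunits", "receptor_subunits",
            "is_secreted", "family", "binding_subunits")
  if (!all(need %in% names(tab))) {
    stop("catalog format error: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  lr_catalog(tab$interaction_id,
             strsplit(tab$ligand_subunits, ";", fixed = TRUE),
             strsplit(tab$receptor_subunits, ";", fixed = TRUE),
             as.logical(tab$is_secreted), tab$family,
             lapply(strsplit(tab$binding_subunits, ";", fixed = TRUE),
                    function(x) x == "1"))
}

#' @rdname lr_catalog
#' @param catalog An `lr_catalog`.
#' @export
write_lr_catalog <- function(catalog, path) {
  join <- function(l) vapply(l, paste, "", collapse = ";")
  tab <- data.frame(interaction_id = catalog$interaction_id,
                    ligand_subunits = join(catalog$ligand_subunits),
                    receptor_subunits = join(catalog$receptor_subunits),
                    is_secreted = catalog$is_secreted,
                    family = catalog$family,
                    binding_subunits = join(lapply(catalog$binding_subunits,
                                                   function(x) as.integer(x))),
                    stringsAsFactors = FALSE)
  write_tsv(tab, path)
}

#' Validate an interaction catalog
#'
#' @param catalog An `lr_catalog`.
#' @return The catalog, invisibly. Errors on empty subunit lists, duplicate
#'   interaction ids, ligand/receptor subunit overlap within an
#'   interaction, flag misalignment, or a ligand assigned to two families.
#' @export
validate_catalog <- function(catalog) {
  if (anyDuplicated(catalog$interaction_id)) {
    stop("catalog integrity error: duplicate interaction_id")
  }
  n_l <- lengths(catalog$ligand_subunits)
  n_r <- lengths(catalog$receptor_subunits)
  if (any(n_l == 0) || any(n_r == 0) ||
      any(vapply(catalog$ligand_subunits, function(x) any(!nzchar(x)), TRUE)) ||
      any(vapply(catalog$receptor_subunits, function(x) any(!nzchar(x)), TRUE))) {
    stop("catalog format error: empty ligand or receptor subunit list")
  }
  if (any(n_r != lengths(catalog$binding_subunits))) {
    stop("catalog format error: binding_subunits flags do not align with receptor subunits")
  }
  overlap <- mapply(function(l, r) length(intersect(l, r)) > 0,
                    catalog$ligand_subunits, catalog$receptor_subunits)
  if (any(overlap)) {
    stop("catalog integrity error: ligand and receptor subunits overlap in ",
         paste(catalog$interaction_id[overlap], collapse = ", "))
  }
  lig_key <- vapply(catalog$ligand_subunits, paste, "", collapse = ";")
  fam_by_lig <- tapply(catalog$family, lig_key, function(f) length(unique(f)))
  if (any(fam_by_lig > 1)) {
    stop("catalog integrity error: ligand(s) assigned to more than one family: ",
         paste(names(fam_by_lig)[fam_by_lig > 1], collapse = ", "))
  }
  invisible(catalog)
}

#' Reduce a catalog to escalation-testable pairs
#'
#' Keeps only secreted-ligand interactions and prunes each receptor side to
#' its cognate ligand-binding subunits, excluding co-receptors.
#' Interactions whose receptor side becomes empty are dropped (their ids
#' are attached as attribute `dropped`).
#'
#' @param catalog An `lr_catalog`.
#' @return A filtered `lr_catalog`; idempotent.
#' @export
filter_escalation_pairs <- function(catalog) {
  out <- catalog[catalog$is_secreted, , drop = FALSE]
  out$receptor_subunits <- mapply(function(r, b) r[b],
                                  out$receptor_subunits, out$binding_subunits,
                                  SIMPLIFY = FALSE)
  out$binding_subunits <- lapply(out$receptor_subunits,
                                 function(r) rep(TRUE, length(r)))
  empty <- lengths(out$receptor_subunits) == 0
  dropped <- out$interaction_id[empty]
  if (length(dropped)) {
    message("filter_escalation_pairs: dropping ", length(dropped),
            " interaction(s) with no binding subunit: ",
            paste(dropped, collapse = ", "))
  }
  out <- out[!empty, , drop = FALSE]
  attr(out, "dropped") <- dropped
  class(out) <- c("lr_catalog", "data.frame")
  out
}

#' Read an orthologue map
#'
#' A many-to-one map from species-native gene identifiers to human gene
#' identifiers, as a TSV with columns `species_gene` and `human_gene`
#' (an optional `score` column is carried along).
#'
#' @param path TSV file path.
#' @return Data frame with columns `species_gene`, `human_gene`.
#' @export
read_orthologue_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_gene", "human_gene") %in% names(tab))) {
    stop("orthologue map format error: need columns species_gene, human_gene")
  }
  if (anyDuplicated(tab$species_gene)) {
    stop("orthologue map integrity error: a species gene maps to several human genes")
  }
  tab
}

#' Pool a species expression matrix onto human gene identifiers
#'
#' Counts/TPM of all paralogues mapping to the same human gene are summed
#' (many-to-one orthology pooling). Unmapped genes are kept under their
#' native identifiers and recorded in attribute `unmapped`, so column sums
#' (and hence per-cell totals or TPM row sums) are preserved exactly.
#'
#' @param m Matrix (dense or sparse) with genes as columns.
#' @param ortho Orthologue map data frame (`species_gene`, `human_gene`).
#' @return Matrix with pooled human gene columns followed by unmapped
#'   native columns.
#' @keywords internal
pool_gene_columns <- function(m, ortho) {
  if (nrow(ortho) == 0) stop("orthologue map is empty")
  target <- ortho$human_gene[match(colnames(m), ortho$species_gene)]
  unmapped <- colnames(m)[is.na(target)]
  target[is.na(target)] <- unmapped
  tg <- factor(target, levels = unique(target))
  proj <- Matrix::sparseMatrix(i = seq_along(tg), j = as.integer(tg), x = 1,
                               dims = c(ncol(m), nlevels(tg)),
                               dimnames = list(NULL, levels(tg)))
  out <- m %*% proj
  if (is.matrix(m)) out <- as.matrix(out)
  rownames(out) <- rownames(m)
  attr(out, "unmapped") <- unmapped
  out
}

#' Convert a species atlas / cell matrix to the human gene universe
#'
#' Implements the "human-equivalent transcriptome" transform: species
#' genes are mapped to their top human orthologue, and in many-to-one
#' cases the TPM (or counts) of all paralogues are pooled by summation.
#' The pooled fraction-expressing of a human gene is recomputed from cell
#' level when `cells` are supplied (fraction of cells with a non-zero
#' count in any contributing paralogue); with pseudo-bulk input only, the
#' maximum of the paralogue fractions is used and flagged as an
#' upper-bound-biased approximation (attribute `frac_method`).
#'
#' @param atlas A [pseudobulk_atlas()].
#' @param ortho_maps Named list (per species) of orthologue map data
#'   frames; species absent from the list are passed through unchanged.
#' @param cells Optional named list (per species) of [cell_level_matrix()]
#'   objects used to recompute pooled fractions exactly.
#' @return A `pseudobulk_atlas` on (partially) human gene columns.
#' @export
humanize_atlas <- function(atlas, ortho_maps, cells = NULL) {
  tpm <- atlas$tpm; frac <- atlas$frac_expr
  method <- character(0)
  for (sp in names(tpm)) {
    om <- ortho_maps[[sp]]
    if (is.null(om)) next
    tpm[[sp]] <- pool_gene_columns(tpm[[sp]], om)
    if (!is.null(cells[[sp]])) {
      hcells <- humanize_cells(cells[[sp]], om)
      fr <- fraction_expressing(hcells)
      frac[[sp]] <- fr[rownames(tpm[[sp]]), colnames(tpm[[sp]]), drop = FALSE]
      method[sp] <- "cell_level"
    } else {
      fr <- frac[[sp]]
      target <- om$human_gene[match(colnames(fr), om$species_gene)]
      unmapped <- colnames(fr)[is.na(target)]
      target[is.na(target)] <- unmapped
      out <- vapply(split(seq_along(target), factor(target, unique(target))),
                    function(j) apply(fr[, j, drop = FALSE], 1, max),
                    numeric(nrow(fr)))
      if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                           dimnames = list(rownames(fr), unique(target)))
      frac[[sp]] <- out[, colnames(tpm[[sp]]), drop = FALSE]
      method[sp] <- "max_of_fractions"
    }
  }
  out <- pseudobulk_atlas(atlas$metadata, tpm, frac)
  attr(out, "frac_method") <- method
  out
}

#' @rdname humanize_atlas
#' @param x A [cell_level_matrix()] for one species.
#' @param ortho An orthologue map data frame.
#' @export
humanize_cells <- function(x, ortho) {
  pooled <- pool_gene_columns(x$counts, ortho)
  out <- cell_level_matrix(pooled, x$cell_meta)
  attr(out, "unmapped") <- attr(pooled, "unmapped")
  out
}
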
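#' Pipeline configuration
#'
#' Assembles the effective configuration of a full analysis run. With no
#' input paths, the pipeline generates its own synthetic atlas via
#' [simulate_atlas()] (seeded); supply `atlas_dir`, `catalog_path`,
#' `ortho_dir`, `tree_path` and `cells_dir` to analyse data on disk
#' instead.
#'
#' @param out_dir Output directory for the report tables.
#' @param seed Integer seed driving every stochastic step.
#' @param threshold On-call fraction threshold (default 0.2).
#' @param parsimony Headline parsimony scheme for reported states:
#'   `"equal"` (default, equal gain/loss weights) or `"weighted21"`
#'   (gains cost twice losses).
#' @param ambiguity Ambiguous ancestral states resolve to `"0"` (default)
#'   or `"1"` for event counting.
#' @param direction Escalation regression direction (see
#'   [pic_regression()]).
#' @param network_node Node whose ancestral signalling network is
#'   reported (default `"Placentalia"`).
#' @param outgroup Outgroup species for Wagner parsimony (default
#'   `"opossum"`).
#' @param ztpm_floor zTPM lower bound (default -3).
#' @param atlas_dir,catalog_path,ortho_dir,tree_path,cells_dir Optional
#'   input paths (all or none).
#' @param sim_config List of [simulate_atlas()] overrides.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, threshold = 0.2,
                            parsimony = c("equal", "weighted21"),
                            ambiguity = c("0", "1"),
                            direction = c("receptor_on_ligand",
                                          "ligand_on_receptor"),
                            network_node = "Placentalia",
                            outgroup = "opossum", ztpm_floor = -3,
                            atlas_dir = NULL, catalog_path = NULL,
                            ortho_dir = NULL, tree_path = NULL,
                            cells_dir = NULL, sim_config = list()) {
  structure(list(out_dir = out_dir, seed = seed, threshold = threshold,
                 parsimony = match.arg(parsimony),
                 ambiguity = match.arg(ambiguity),
                 direction = match.arg(direction),
                 network_node = network_node, outgroup = outgroup,
                 ztpm_floor = ztpm_floor,
                 atlas_dir = atlas_dir, catalog_path = catalog_path,
                 ortho_dir = ortho_dir, tree_path = tree_path,
                 cells_dir = cells_dir, sim_config = sim_config),
            class = "pipeline_config")
}

#' Run the full co-evolution analysis pipeline
#'
#' Executes every stage in dependency order: atlas acquisition
#' (simulation or disk) -> orthologue pooling onto human genes ->
#' interaction calling / ALC + ANOVA / HITS scores -> cell-class and
#' compartment characters -> four-model ancestral state reconstruction
#' with method agreement, per-branch gain/loss events and the ancestral
#' signalling network -> disambiguation classification, family tests and
#' tree-wide transition matrix -> escalation test and per-branch trait
#' changes. All tables are written as TSV under `config$out_dir` together
#' with an md5 `manifest.tsv` and the effective `run_config.txt`; reruns
#' with an identical config are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   vector of written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- c(config$atlas_dir, config$catalog_path, config$ortho_dir,
              config$tree_path)
  if (length(inputs) && length(inputs) < 4) {
    stop("pipeline configuration error: supply all of atlas_dir, ",
         "catalog_path, ortho_dir, tree_path, or none")
  }
  for (p in inputs) {
    if (!file.exists(p)) stop("pipeline configuration error: missing input ", p)
  }
  # -- stage: inputs ------------------------------------------------------
  if (is.null(config$atlas_dir)) {
    sim <- simulate_atlas(config = config$sim_config, seed = config$seed)
    atlas <- sim$atlas; catalog <- sim$catalog; ortho <- sim$ortho_maps
    tree <- sim$tree; cells <- sim$cells; truth <- sim$truth
  } else {
    atlas <- read_pseudobulk_atlas(config$atlas_dir)
    catalog <- load_lr_catalog(config$catalog_path)
    ortho_files <- list.files(config$ortho_dir, "\\.tsv$", full.names = TRUE)
    ortho <- lapply(ortho_files, read_orthologue_map)
    names(ortho) <- sub("\\.tsv$", "", basename(ortho_files))
    tree <- ape::read.tree(config$tree_path)
    cells <- NULL
    if (!is.null(config$cells_dir)) {
      dirs <- list.dirs(config$cells_dir, recursive = FALSE)
      cells <- lapply(dirs, read_cell_matrix)
      names(cells) <- basename(dirs)
    }
    truth <- NULL
  }
  validate_species_tree(tree, unique(atlas$metadata$species))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    f <- file.path(config$out_dir, name)
    write_tsv(df, f)
    files <<- c(files, f)
  }
  md <- atlas$metadata

  # -- stage: humanize ----------------------------------------------------
  hatlas <- humanize_atlas(atlas, ortho, cells = cells)
  hcells <- if (!is.null(cells)) {
    lapply(names(cells), function(sp) humanize_cells(cells[[sp]], ortho[[sp]]))
  }
  if (!is.null(hcells)) names(hcells) <- names(cells)

  # -- stage: interaction calls ------------------------------------------
  calls <- score_interactions(hatlas, catalog, config$threshold)
  emit(calls, "interaction_calls.tsv")

  # -- stage: ALC + ANOVA -------------------------------------------------
  alc <- anova_tab <- NULL
  if (!is.null(hcells)) {
    alc <- do.call(rbind, lapply(hcells, compute_alc, catalog = catalog))
    rownames(alc) <- NULL
    emit(alc, "alc.tsv")
    class_of <- stats::setNames(md$cell_class, md$cell_type)
    anova_tab <- do.call(rbind, lapply(unique(md$species), function(sp) {
      a <- alc_anova(alc, class_of, species = sp)
      data.frame(species = sp, F = a$F, p = a$p, df1 = a$df[1], df2 = a$df[2],
                 stringsAsFactors = FALSE)
    }))
    emit(anova_tab, "alc_anova.tsv")
  }

  # -- stage: signalling graph + HITS ------------------------------------
  hits <- NULL
  if (!is.null(hcells)) {
    hits <- do.call(rbind, lapply(names(hcells), function(sp) {
      g <- build_signaling_graph(mean_lognorm_by_celltype(hcells[[sp]]), catalog)
      cbind(species = sp, hits_scores(g))
    }))
    emit(hits, "hits_scores.tsv")
  }

  # -- stage: characters --------------------------------------------------
  cat_genes <- unique(unlist(c(catalog$ligand_subunits,
                               catalog$receptor_subunits)))
  chars <- collapse_to_classes(hatlas, genes = cat_genes,
                               threshold = config$threshold)
  char_tab <- data.frame(species = rep(rownames(chars$binary),
                                       ncol(chars$binary)),
                         character = rep(colnames(chars$binary),
                                         each = nrow(chars$binary)),
                         state = as.vector(chars$binary),
                         proportion = as.vector(chars$proportion),
                         stringsAsFactors = FALSE)
  emit(char_tab, "characters.tsv")

  # -- stage: ancestral state reconstruction ------------------------------
  usable <- !apply(chars$binary, 2, anyNA)
  bin <- chars$binary[, usable, drop = FALSE]
  prop <- chars$proportion[, usable, drop = FALSE]
  asr_equal <- sankoff_asr(tree, bin, cost_matrix(1, 1))
  asr_w21 <- sankoff_asr(tree, bin, cost_matrix(gain = 2, loss = 1))
  asr_wag <- wagner_mpr(tree, bin, config$outgroup)
  bm <- brownian_asr(tree, prop)
  asr_reml <- structure(list(method = "brownian_reml_20pc",
                             node_states = matrix(
                               as.character(binarize_states(bm$node_values,
                                                            config$threshold)),
                               nrow(bm$node_values),
                               dimnames = dimnames(bm$node_values)),
                             min_cost = NULL, tree = tree),
                        class = "asr_result")
  methods_list <- list(equal = asr_equal, weighted21 = asr_w21,
                       wagner = asr_wag, reml = asr_reml)
  agree <- compare_methods(methods_list)
  asr_tab <- do.call(rbind, lapply(names(methods_list), function(m) {
    ns <- methods_list[[m]]$node_states
    data.frame(method = m, node = rep(rownames(ns), ncol(ns)),
               character = rep(colnames(ns), each = nrow(ns)),
               state = as.vector(ns), stringsAsFactors = FALSE)
  }))
  emit(asr_tab, "asr_states.tsv")

  headline <- if (config$parsimony == "equal") asr_equal else asr_w21
  node_bin <- resolve_ambiguity(headline, config$ambiguity)
  full_states <- rbind(bin[tree$tip.label, , drop = FALSE], node_bin)
  events <- branch_changes(tree, full_states)
  emit(events, "branch_events.tsv")

  # -- stage: ancestral network ------------------------------------------
  net <- network_edge_ages(tree, full_states, config$network_node, catalog)
  emit(net, "ancestral_network.tsv")

  # -- stage: disambiguation ---------------------------------------------
  secreted <- catalog[catalog$is_secreted, , drop = FALSE]
  class(secreted) <- c("lr_catalog", "data.frame")
  calls_cmp <- classify_compartment_expression(hatlas, secreted,
                                               threshold = config$threshold)
  disamb <- test_disambiguation(calls_cmp, md, seed = config$seed + 1L)
  emit(disamb, "disambiguation_families.tsv")

  cmp_atlas <- atlas_with_compartment_classes(hatlas)
  lig_genes <- unique(unlist(secreted$ligand_subunits))
  cmp_chars <- collapse_to_classes(cmp_atlas, genes = lig_genes,
                                   threshold = config$threshold)
  usable2 <- !apply(cmp_chars$binary, 2, anyNA)
  cbin <- cmp_chars$binary[, usable2, drop = FALSE]
  casr <- sankoff_asr(tree, cbin,
                      if (config$parsimony == "equal") cost_matrix(1, 1)
                      else cost_matrix(2, 1))
  cfull <- rbind(cbin[tree$tip.label, , drop = FALSE],
                 resolve_ambiguity(casr, config$ambiguity))
  pick <- function(prefix) {
    sel <- startsWith(colnames(cfull), paste0(prefix, "|"))
    m <- cfull[, sel, drop = FALSE]
    colnames(m) <- sub("^[^|]*\\|", "", colnames(m))
    m
  }
  fet <- pick("fetal"); mat <- pick("maternal")
  common <- intersect(colnames(fet), colnames(mat))
  trans <- disambiguation_transitions(tree, fet[, common, drop = FALSE],
                                      mat[, common, drop = FALSE])
  trans_tab <- data.frame(from = rep(rownames(trans$counts), 4),
                          to = rep(colnames(trans$counts), each = 4),
                          count = as.vector(trans$counts),
                          percent = as.vector(trans$percent),
                          stringsAsFactors = FALSE)
  emit(trans_tab, "disambiguation_transitions.tsv")

  # -- stage: escalation --------------------------------------------------
  esc <- test_escalation(hatlas, catalog, tree, direction = config$direction,
                         floor = config$ztpm_floor)
  emit(esc, "escalation.tsv")
  ztpm <- lapply(hatlas$tpm, ztpm_transform, floor = config$ztpm_floor)
  traits <- representative_trait_matrix(ztpm, md, esc)
  bm_l <- brownian_asr(tree, traits$ligand)
  bm_r <- brownian_asr(tree, traits$receptor)
  dl <- branch_trait_changes(tree, traits$ligand, bm_l$node_values)
  dr <- branch_trait_changes(tree, traits$receptor, bm_r$node_values)
  deltas <- data.frame(dl[, c("parent", "child", "terminal")],
                       interaction_id = dl$character,
                       delta_ligand = dl$delta, delta_receptor = dr$delta,
                       stringsAsFactors = FALSE)
  emit(deltas, "branch_trait_deltas.tsv")

  # -- stage: summary + manifest -----------------------------------------
  summary_tab <- data.frame(
    quantity = c("n_species", "n_interactions", "n_called_interactions",
                 "n_characters", "asr_method_agreement", "n_branch_events",
                 "n_ancestral_network_edges", "n_disambiguation_transitions",
                 "n_escalation_pairs"),
    value = c(length(unique(md$species)), nrow(catalog), sum(calls$called),
              ncol(bin), agree$agreement, nrow(events), nrow(net),
              trans$n_changes, nrow(esc)),
    stringsAsFactors = FALSE)
  emit(summary_tab, "summary.tsv")
  cfg_lines <- vapply(setdiff(names(config), "sim_config"), function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = ";"))
  }, "")
  cfg_file <- file.path(config$out_dir, "run_config.txt")
  writeLines(sort(cfg_lines), cfg_file)
  files <- c(files, cfg_file)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(list(files = c(files, file.path(config$out_dir, "manifest.tsv")),
                 calls = calls, alc = alc, anova = anova_tab, hits = hits,
                 characters = chars, asr = methods_list, agreement = agree,
                 events = events, network = net, disambiguation = disamb,
                 transitions = trans, escalation = esc, truth = truth))
}

# Recast compartment as the cell-class label so class-level collapsing
# yields fetal/maternal characters.
atlas_with_compartment_classes <- function(atlas) {
  md <- atlas$metadata
  md$cell_class <- md$compartment
  out <- atlas
  out$metadata <- md
  out
}

# Species x interaction matrices of representative ligand / receptor zTPM
# traits for the interactions listed in an escalation result table.
representative_trait_matrix <- function(ztpm, metadata, esc) {
  species <- names(ztpm)
  get <- function(side, compartment) {
    m <- vapply(seq_len(nrow(esc)), function(i) {
      su <- strsplit(esc[[side]][i], ";", fixed = TRUE)[[1]]
      vapply(species, function(sp) {
        vals <- vapply(su, function(g) {
          representative_trait(ztpm[[sp]],
                               metadata[metadata$species == sp, ],
                               g, compartment)$value
        }, numeric(1))
        min(vals)
      }, numeric(1))
    }, numeric(length(species)))
    m <- matrix(m, nrow = length(species),
                dimnames = list(species, esc$interaction_id))
    m
  }
  list(ligand = get("ligand", "fetal"), receptor = get("receptor", "maternal"))
}
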
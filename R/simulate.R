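# Run code with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is left untouched. seed = NULL runs on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulate binary expression characters on a species tree
#'
#' A two-state continuous-time Markov chain (gain rate 0 to 1, loss rate
#' 1 to 0, per Myr) is simulated from the root down each branch; the true
#' internal-node states are recorded so that ancestral reconstruction can
#' be scored against the planted truth.
#'
#' @param tree Rooted bifurcating `phylo` (branch lengths in the same
#'   time unit as the rates).
#' @param gain_rate,loss_rate Transition rates (>= 0).
#' @param n_chars Number of independent characters.
#' @param root_prob Probability that a character is in state 1 at the
#'   root.
#' @param seed Optional integer seed (local to this call).
#' @return List: `leaf_states` (species x character), `truth` with
#'   `node_states` (internal node x character) and the parameters.
#' @export
simulate_binary_characters <- function(tree, gain_rate = 0.0008,
                                       loss_rate = 0.0008, n_chars = 100,
                                       root_prob = 0.5, seed = NULL) {
  stopifnot(gain_rate >= 0, loss_rate >= 0)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nn <- ntip + tree$Nnode
    states <- matrix(NA_integer_, nn, n_chars)
    root <- ntip + 1L
    states[root, ] <- stats::rbinom(n_chars, 1, root_prob)
    edge <- ape::reorder.phylo(tree, "cladewise")$edge
    el <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edge))) {
      p <- states[edge[e, 1], ]
      prob1 <- ctmc_p1(p, gain_rate, loss_rate, el[e])
      states[edge[e, 2], ] <- stats::rbinom(n_chars, 1, prob1)
    }
    chn <- paste0("char", seq_len(n_chars))
    leaf <- states[seq_len(ntip), , drop = FALSE]
    dimnames(leaf) <- list(tree$tip.label, chn)
    node <- states[(ntip + 1L):nn, , drop = FALSE]
    dimnames(node) <- list(node_labels(tree), chn)
    list(leaf_states = leaf,
         truth = list(node_states = node, gain_rate = gain_rate,
                      loss_rate = loss_rate, root_prob = root_prob,
                      seed = seed))
  })
}

# P(state 1 after time t | start state), two-state CTMC.
ctmc_p1 <- function(start, gain, loss, t) {
  tot <- gain + loss
  if (tot == 0) return(as.numeric(start))
  pi1 <- gain / tot
  decay <- exp(-tot * t)
  ifelse(start == 1, pi1 + (1 - pi1) * decay, pi1 * (1 - decay))
}

#' Simulate coupled ligand/receptor traits under Brownian motion
#'
#' The ligand trait evolves by Brownian motion; per branch, the receptor
#' increment is `beta` times the ligand increment plus independent
#' Brownian noise. With `noise_sd = 0` the receptor contrasts are exactly
#' `beta` times the ligand contrasts; regression through the origin on
#' contrasts recovers `beta` in expectation.
#'
#' @param tree Rooted bifurcating `phylo`.
#' @param beta True coupling slope.
#' @param noise_sd Receptor-specific Brownian rate (SD per unit sqrt
#'   branch length; default 0.1).
#' @param n_pairs Number of independent ligand/receptor pairs.
#' @param sigma_ligand Ligand Brownian rate (SD per unit sqrt branch
#'   length; default 0.1).
#' @param root_value Trait value at the root (default 0).
#' @param seed Optional integer seed (local to this call).
#' @return List: `ligand`, `receptor` (species x pair matrices), `truth`.
#' @export
simulate_coupled_traits <- function(tree, beta, noise_sd = 0.1, n_pairs = 1,
                                    sigma_ligand = 0.1, root_value = 0,
                                    seed = NULL) {
  stopifnot(noise_sd >= 0, sigma_ligand > 0)
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nn <- ntip + tree$Nnode
    lig <- matrix(NA_real_, nn, n_pairs)
    rec <- matrix(NA_real_, nn, n_pairs)
    lig[ntip + 1L, ] <- root_value
    rec[ntip + 1L, ] <- root_value
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      t <- ord$edge.length[e]
      dl <- stats::rnorm(n_pairs, 0, sigma_ligand * sqrt(t))
      dr <- beta * dl + stats::rnorm(n_pairs, 0, noise_sd * sqrt(t))
      lig[ord$edge[e, 2], ] <- lig[ord$edge[e, 1], ] + dl
      rec[ord$edge[e, 2], ] <- rec[ord$edge[e, 1], ] + dr
    }
    pn <- paste0("pair", seq_len(n_pairs))
    out_l <- lig[seq_len(ntip), , drop = FALSE]
    out_r <- rec[seq_len(ntip), , drop = FALSE]
    dimnames(out_l) <- dimnames(out_r) <- list(tree$tip.label, pn)
    list(ligand = out_l, receptor = out_r,
         truth = list(beta = beta, noise_sd = noise_sd,
                      sigma_ligand = sigma_ligand, seed = seed))
  })
}

#' Simulate per-cell-type "on" calls for one ligand family
#'
#' Lightweight generator for calibrating the disambiguation test. Under
#' the null, every (ligand, cell type) slot is on independently with
#' probability `p_on` regardless of compartment. A planted exclusive
#' family restricts on-calls to one compartment, inflating that
#' compartment's per-slot probability so the expected total number of
#' on-calls is preserved.
#'
#' @param S Number of ligands in the family.
#' @param n_fetal,n_maternal Numbers of fetal/maternal cell types.
#' @param p_on Per-slot on probability under the null (default 0.2).
#' @param exclusive `"none"` (null), `"fetal"` or `"maternal"`.
#' @param family Family label.
#' @param seed Optional integer seed (local to this call).
#' @return Data frame compatible with [family_null_expectation()].
#' @export
simulate_family_calls <- function(S, n_fetal, n_maternal, p_on = 0.2,
                                  exclusive = c("none", "fetal", "maternal"),
                                  family = "FAM", seed = NULL) {
  exclusive <- match.arg(exclusive)
  with_seed(seed, {
    p_f <- p_on; p_m <- p_on
    if (exclusive == "fetal") {
      p_f <- min(1, p_on * (n_fetal + n_maternal) / n_fetal); p_m <- 0
    } else if (exclusive == "maternal") {
      p_m <- min(1, p_on * (n_fetal + n_maternal) / n_maternal); p_f <- 0
    }
    nf <- stats::rbinom(S, n_fetal, p_f)
    nm <- stats::rbinom(S, n_maternal, p_m)
    data.frame(species = "sim", ligand = paste0("L", seq_len(S)),
               human_ligand = paste0("L", seq_len(S)), family = family,
               category = ifelse(nf > 0 & nm > 0, "both",
                                 ifelse(nf > 0, "fetal_only",
                                        ifelse(nm > 0, "maternal_only", "off"))),
               n_fetal_on = nf, n_maternal_on = nm,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic multi-subunit ligand-receptor catalog
#'
#' @param n_interactions Number of interactions (default 120).
#' @param n_families Number of ligand families (default 10).
#' @param p_secreted Fraction of secreted interactions (default 0.7).
#' @param p_heterodimer Fraction of interactions with a two-subunit
#'   receptor (one binding subunit plus one co-receptor; default 0.15).
#' @param seed Optional integer seed (local to this call).
#' @return An [lr_catalog()]; one distinct ligand gene per interaction,
#'   families of contiguous ligand blocks.
#' @export
make_synthetic_catalog <- function(n_interactions = 120, n_families = 10,
                                   p_secreted = 0.7, p_heterodimer = 0.15,
                                   seed = NULL) {
  with_seed(seed, {
    lig <- sprintf("LIG%03d", seq_len(n_interactions))
    rec <- sprintf("REC%03d", seq_len(n_interactions))
    corec <- sprintf("COR%03d", seq_len(n_interactions))
    hetero <- stats::runif(n_interactions) < p_heterodimer
    secreted <- stats::runif(n_interactions) < p_secreted
    fam <- sprintf("FAM%02d", rep_len(seq_len(n_families), n_interactions)[
      order(rep_len(seq_len(n_families), n_interactions))])
    receptor_subunits <- lapply(seq_len(n_interactions), function(i) {
      if (hetero[i]) c(rec[i], corec[i]) else rec[i]
    })
    binding <- lapply(seq_len(n_interactions), function(i) {
      if (hetero[i]) c(TRUE, FALSE) else TRUE
    })
    lr_catalog(sprintf("INT%03d", seq_len(n_interactions)),
               as.list(lig), receptor_subunits, secreted, fam, binding)
  })
}

#' Simulate a six-species fetal-maternal expression atlas
#'
#' End-to-end generator with planted ground truth: a catalog
#' ([make_synthetic_catalog()]), per-(cell class, gene) binary expression
#' characters evolved on the tree ([simulate_binary_characters()]),
#' planted single-compartment ligand families, negative-binomial
#' cell-level counts with per-cell library-size variation, and the
#' derived pseudo-bulk atlas. Species gene identifiers are native
#' (`<species>:<gene>`), with a configurable number of duplicated
#' paralogues per species exercising many-to-one orthologue pooling.
#'
#' Default scale: 6 species x 12 cell types (6 fetal in 3 classes, 6
#' maternal in 3 classes) x 60 cells x ~600 genes x 120 catalog
#' interactions.
#'
#' @param tree Species tree (default [fixed_six_species_tree()]).
#' @param config Named list overriding any of the defaults in
#'   `default_atlas_config()`.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return List: `cells` (per-species [cell_level_matrix()]), `atlas`
#'   (native-gene [pseudobulk_atlas()]), `catalog`, `ortho_maps`, `tree`,
#'   `truth` (planted node states, planted families, parameters, seed).
#' @export
simulate_atlas <- function(tree = fixed_six_species_tree(), config = list(),
                           seed = 1) {
  cfg <- utils::modifyList(default_atlas_config(), config)
  with_seed(seed, {
    catalog <- make_synthetic_catalog(cfg$n_interactions, cfg$n_families,
                                      cfg$p_secreted, cfg$p_heterodimer)
    cat_genes <- unique(unlist(c(catalog$ligand_subunits,
                                 catalog$receptor_subunits)))
    n_hk <- max(cfg$n_genes - length(cat_genes), 20)
    hk <- sprintf("HK%03d", seq_len(n_hk))
    genes <- c(cat_genes, hk)
    classes <- c(cfg$fetal_classes, cfg$maternal_classes)
    # class-level binary characters evolved on the tree
    nchar_total <- length(classes) * length(cat_genes)
    sim <- simulate_binary_characters(tree, cfg$gain_rate, cfg$loss_rate,
                                      n_chars = nchar_total,
                                      root_prob = cfg$root_prob)
    char_names <- paste(rep(classes, each = length(cat_genes)),
                        rep(cat_genes, times = length(classes)), sep = "|")
    colnames(sim$leaf_states) <- char_names
    colnames(sim$truth$node_states) <- char_names
    # plant compartment exclusivity for selected ligand families
    lig_genes_of <- function(fams) {
      unique(unlist(catalog$ligand_subunits[catalog$family %in% fams]))
    }
    silence <- function(states, genes_off, classes_off) {
      cols <- as.vector(outer(genes_off, classes_off,
                              function(g, cl) paste(cl, g, sep = "|")))
      cols <- intersect(cols, colnames(states))
      states[, cols] <- 0
      states
    }
    force_on <- function(states, genes_on, classes_on) {
      cols <- as.vector(outer(genes_on, classes_on,
                              function(g, cl) paste(cl, g, sep = "|")))
      cols <- intersect(cols, colnames(states))
      states[, cols][states[, cols] == 0] <-
        stats::rbinom(sum(states[, cols] == 0), 1, cfg$planted_on_prob)
      states
    }
    fet_lig <- lig_genes_of(cfg$planted_fetal_families)
    mat_lig <- lig_genes_of(cfg$planted_maternal_families)
    sim$leaf_states <- silence(sim$leaf_states, fet_lig, cfg$maternal_classes)
    sim$leaf_states <- force_on(sim$leaf_states, fet_lig, cfg$fetal_classes)
    sim$leaf_states <- silence(sim$leaf_states, mat_lig, cfg$fetal_classes)
    sim$leaf_states <- force_on(sim$leaf_states, mat_lig, cfg$maternal_classes)
    sim$truth$node_states <- silence(sim$truth$node_states, fet_lig,
                                     cfg$maternal_classes)
    sim$truth$node_states <- silence(sim$truth$node_states, mat_lig,
                                     cfg$fetal_classes)
    # per-species cell-level counts
    species <- tree$tip.label
    md <- list(); cells <- list(); ortho <- list()
    for (sp in species) {
      ct_f <- paste0(sp, "_F", seq_len(cfg$cell_types_per_compartment))
      ct_m <- paste0(sp, "_M", seq_len(cfg$cell_types_per_compartment))
      cls_f <- rep_len(cfg$fetal_classes, length(ct_f))
      cls_m <- rep_len(cfg$maternal_classes, length(ct_m))
      sp_md <- data.frame(
        species = sp, cell_type = c(ct_f, ct_m),
        compartment = rep(c("fetal", "maternal"),
                          each = cfg$cell_types_per_compartment),
        cell_class = c(cls_f, cls_m),
        n_cells = cfg$cells_per_type,
        replicate = "rep1", stringsAsFactors = FALSE)
      # duplicate the first `n_paralogues` catalog genes into two paralogues
      dup <- utils::head(cat_genes, cfg$n_paralogues)
      native_of <- function(g) {
        if (g %in% dup) paste0(sp, ":", g, letters[1:2]) else paste0(sp, ":", g)
      }
      native <- lapply(genes, native_of)
      native_genes <- unlist(native)
      human_of <- rep(genes, lengths(native))
      ortho[[sp]] <- data.frame(species_gene = native_genes,
                                human_gene = human_of,
                                stringsAsFactors = FALSE)
      n_cells_sp <- nrow(sp_md) * cfg$cells_per_type
      dn <- list(paste0(sp, "_cell", seq_len(n_cells_sp)), native_genes)
      cell_type <- rep(sp_md$cell_type, each = cfg$cells_per_type)
      cell_class <- rep(sp_md$cell_class, each = cfg$cells_per_type)
      lib <- exp(stats::rnorm(n_cells_sp, 0, cfg$lib_sd))
      triplets <- list()
      for (j in seq_along(native_genes)) {
        hg <- human_of[j]
        if (hg %in% hk) {
          q <- if (match(hg, hk) <= 10) 1 else cfg$hk_on_prob
          on_cells <- stats::runif(n_cells_sp) < q
        } else {
          key <- paste(cell_class, hg, sep = "|")
          st <- sim$leaf_states[sp, key]
          q <- ifelse(st == 1, cfg$detect_prob, cfg$leak_prob)
          on_cells <- stats::runif(n_cells_sp) < q
        }
        if (!any(on_cells)) next
        n_on <- sum(on_cells)
        cnt <- 1L + stats::rnbinom(n_on, mu = cfg$nb_mu * lib[on_cells],
                                   size = cfg$nb_size)
        triplets[[length(triplets) + 1L]] <-
          cbind(which(on_cells), j, cnt)
      }
      tr <- do.call(rbind, triplets)
      counts <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                                     dims = c(n_cells_sp, length(native_genes)),
                                     dimnames = dn)
      cm <- data.frame(cell_id = rownames(counts), species = sp,
                       cell_type = cell_type, replicate = "rep1",
                       stringsAsFactors = FALSE)
      cells[[sp]] <- cell_level_matrix(counts, cm)
      md[[sp]] <- sp_md
    }
    metadata <- do.call(rbind, md)
    rownames(metadata) <- NULL
    tpm <- lapply(cells, pseudobulk_tpm)
    frac <- lapply(cells, fraction_expressing)
    frac <- lapply(names(frac), function(sp) {
      frac[[sp]][rownames(tpm[[sp]]), colnames(tpm[[sp]]), drop = FALSE]
    })
    names(frac) <- names(tpm)
    atlas <- pseudobulk_atlas(metadata, tpm, frac)
    truth <- list(seed = seed, config = cfg,
                  node_states = sim$truth$node_states,
                  leaf_states = sim$leaf_states,
                  planted_fetal_families = cfg$planted_fetal_families,
                  planted_maternal_families = cfg$planted_maternal_families)
    list(cells = cells, atlas = atlas, catalog = catalog,
         ortho_maps = ortho, tree = tree, truth = truth)
  })
}

#' @rdname simulate_atlas
#' @export
default_atlas_config <- function() {
  list(
    cell_types_per_compartment = 6,
    fetal_classes = c("Trophoblastic", "FetalMesenchyme", "FetalVascular"),
    maternal_classes = c("Stromal", "Epithelial", "Myeloid"),
    cells_per_type = 60,
    n_genes = 600,
    n_interactions = 120,
    n_families = 10,
    p_secreted = 0.7,
    p_heterodimer = 0.15,
    n_paralogues = 8,
    gain_rate = 0.0015,
    loss_rate = 0.0015,
    root_prob = 0.35,
    planted_fetal_families = "FAM01",
    planted_maternal_families = "FAM02",
    planted_on_prob = 0.6,
    detect_prob = 0.6,
    leak_prob = 0.02,
    hk_on_prob = 0.9,
    nb_mu = 1.5,
    nb_size = 2,
    lib_sd = 0.3
  )
}

#' Write / read a simulation truth record
#'
#' Plain-text serialization of the planted ground truth: `params.txt`
#' (key = value lines), `node_states.tsv` and `leaf_states.tsv`.
#'
#' @param truth The `truth` element of [simulate_atlas()] (or of the
#'   character/trait simulators, wrapped in a list).
#' @param path Directory.
#' @export
write_simulation_truth <- function(truth, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  flat <- truth$config
  flat$seed <- truth$seed
  flat$planted_fetal_families <- paste(truth$planted_fetal_families, collapse = ";")
  flat$planted_maternal_families <- paste(truth$planted_maternal_families, collapse = ";")
  lines <- vapply(names(flat), function(k) {
    paste0(k, " = ", paste(flat[[k]], collapse = ";"))
  }, "")
  writeLines(sort(lines), file.path(path, "params.txt"))
  for (nm in c("node_states", "leaf_states")) {
    m <- truth[[nm]]
    df <- data.frame(node = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(df, file.path(path, paste0(nm, ".tsv")))
  }
  invisible(path)
}
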
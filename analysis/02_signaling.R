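#!/usr/bin/env Rscript
# Stage 2 — ligand-receptor interaction calling and signalling statistics.
#
# Loads the stage-1 data, pools species genes onto the human catalog,
# calls interactions between all cell-type pairs (20% threshold, all
# subunits), computes the per-cell allocrine ligand count (ALC) with its
# per-species one-way ANOVA against cell-type class, and the Kleinberg
# hub/authority scores of each species' weighted signalling multigraph.

suppressMessages(library(coevocell))

data_dir <- "results/data"
out_dir <- "results/signaling"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

atlas <- read_pseudobulk_atlas(file.path(data_dir, "atlas"))
catalog <- load_lr_catalog(file.path(data_dir, "catalog.tsv"))
ortho <- lapply(list.files(file.path(data_dir, "ortho"), full.names = TRUE),
                read_orthologue_map)
names(ortho) <- sub("\\.tsv$", "",
                    list.files(file.path(data_dir, "ortho")))
cells <- lapply(list.dirs(file.path(data_dir, "cells"), recursive = FALSE),
                read_cell_matrix)
names(cells) <- basename(list.dirs(file.path(data_dir, "cells"),
                                   recursive = FALSE))

hatlas <- humanize_atlas(atlas, ortho, cells = cells)
hcells <- lapply(names(cells),
                 function(sp) humanize_cells(cells[[sp]], ortho[[sp]]))
names(hcells) <- names(cells)

calls <- score_interactions(hatlas, catalog, threshold = 0.2)
coevocell:::write_tsv(calls, file.path(out_dir, "interaction_calls.tsv"))
message(sprintf("Called %d of %d possible (sender, receiver, interaction) triples.",
                sum(calls$called), nrow(calls)))

alc <- do.call(rbind, lapply(hcells, compute_alc, catalog = catalog))
rownames(alc) <- NULL
coevocell:::write_tsv(alc, file.path(out_dir, "alc.tsv"))

md <- atlas$metadata
class_of <- setNames(md$cell_class, md$cell_type)
anova_tab <- do.call(rbind, lapply(unique(md$species), function(sp) {
  a <- alc_anova(alc, class_of, species = sp)
  data.frame(species = sp, F = a$F, p = a$p)
}))
coevocell:::write_tsv(anova_tab, file.path(out_dir, "alc_anova.tsv"))
message("ALC varies across cell-type classes in every species:")
for (i in seq_len(nrow(anova_tab))) {
  message(sprintf("  %-10s F = %7.2f  p = %.3g", anova_tab$species[i],
                  anova_tab$F[i], anova_tab$p[i]))
}

hits <- do.call(rbind, lapply(names(hcells), function(sp) {
  g <- build_signaling_graph(mean_lognorm_by_celltype(hcells[[sp]]), catalog)
  cbind(species = sp, hits_scores(g))
}))
coevocell:::write_tsv(hits, file.path(out_dir, "hits_scores.tsv"))
top <- hits[order(-hits$hub), ][1, ]
message(sprintf("Strongest signalling hub: %s (%s), hub score %.2f.",
                top$cell_type, top$species, top$hub))
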
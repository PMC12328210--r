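#!/usr/bin/env Rscript
# Stage 5 — escalation test on ligand/receptor expression magnitude.
#
# Standardizes pseudo-bulk TPM to zTPM within each species, extracts
# representative fetal-ligand and maternal-receptor traits, regresses
# receptor on ligand phylogenetic independent contrasts through the
# origin for every secreted binding pair, and derives per-branch
# expression changes from Brownian ancestral values (the human terminal
# branch gives the escalation/de-escalation quadrants).

suppressMessages(library(coevocell))

data_dir <- "results/data"
out_dir <- "results/escalation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

atlas <- read_pseudobulk_atlas(file.path(data_dir, "atlas"))
catalog <- load_lr_catalog(file.path(data_dir, "catalog.tsv"))
ortho <- lapply(list.files(file.path(data_dir, "ortho"), full.names = TRUE),
                read_orthologue_map)
names(ortho) <- sub("\\.tsv$", "", list.files(file.path(data_dir, "ortho")))
tree <- ape::read.tree(file.path(data_dir, "tree.nwk"))
hatlas <- humanize_atlas(atlas, ortho)

esc <- test_escalation(hatlas, catalog, tree)
coevocell:::write_tsv(esc, file.path(out_dir, "escalation.tsv"))
message(sprintf("Tested %d secreted ligand/binding-receptor pairs (>= 4 of 6 species expressed).",
                nrow(esc)))
message(sprintf("Nominally coupled (PIC p < 0.05): %d; after Bonferroni: %d; negative-slope (escalation-consistent): %d.",
                sum(esc$pic_p < 0.05, na.rm = TRUE),
                sum(esc$p_bonferroni < 0.05, na.rm = TRUE),
                sum(esc$pic_p < 0.05 & esc$pic_slope < 0, na.rm = TRUE)))

# per-branch expression changes of the tested traits
ztpm <- lapply(hatlas$tpm, ztpm_transform)
traits <- coevocell:::representative_trait_matrix(ztpm, atlas$metadata, esc)
bm_l <- brownian_asr(tree, traits$ligand)
bm_r <- brownian_asr(tree, traits$receptor)
dl <- branch_trait_changes(tree, traits$ligand, bm_l$node_values)
dr <- branch_trait_changes(tree, traits$receptor, bm_r$node_values)
deltas <- data.frame(dl[, c("parent", "child", "terminal")],
                     interaction_id = dl$character,
                     delta_ligand = dl$delta, delta_receptor = dr$delta)
coevocell:::write_tsv(deltas, file.path(out_dir, "branch_trait_deltas.tsv"))

hum <- deltas[deltas$child == "human", ]
message(sprintf("Human terminal branch: %d pairs escalating (ligand up, receptor down), %d de-escalating, %d coordinated-up.",
                sum(hum$delta_ligand > 0 & hum$delta_receptor < 0),
                sum(hum$delta_ligand < 0 & hum$delta_receptor > 0),
                sum(hum$delta_ligand > 0 & hum$delta_receptor > 0)))
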
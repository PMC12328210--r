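---
title: "Models and methods behind coevocell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coevocell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`coevocell` traces how ligand–receptor signalling between fetal
(placental) and maternal (uterine) cell types evolves across a mammal
phylogeny. This vignette documents the models, the defaults and why they
were chosen, the numerical decisions, and what the synthetic-data
validation does and does not establish.

## Expression calls and the 20% threshold

All discrete analyses rest on one primitive: a gene is *on* in a cell
type when the fraction of that type's cells with a non-zero count is at
least the threshold (default 0.20, inclusive — a fraction of exactly
20% counts as on, and the same inclusive convention is used wherever a
20% cutoff appears, including the binarization of reconstructed
continuous states). An interaction is *called* between a sender and a
receiver cell type only if every ligand subunit is on in the sender and
every receptor subunit is on in the receiver (the all-subunit rule);
co-receptors participate in calling but are excluded from the
escalation analysis, which keeps only secreted ligands and their
cognate binding subunits.

Cross-species comparability is obtained by mapping each species'
transcriptome onto the human-referenced catalog before interaction
analysis ("human-equivalent transcriptome"). Many-to-one orthologue
pooling sums counts/TPM over paralogues; the pooled
fraction-expressing is recomputed from cell level (fraction of cells
with any contributing paralogue detected) when cell-level counts are
available, and otherwise falls back to the maximum of the paralogue
fractions, which is biased upward and flagged as such on the returned
object. Gene identifiers stay species-native until this explicit
transform, so nothing is silently renamed at load time.

## Allocrine ligand count

The ALC of a cell is the number of catalog ligand–receptor pairs for
which the cell expresses every ligand subunit (non-zero count) but not
the full receptor: a per-cell measure of non-autocrine signalling
potential. Because it depends only on the cell's own expression vector,
it is invariant to how the remaining cells are clustered — the property
that motivates using it instead of network out-degree, which inflates
when a partner population is split into more clusters. A ligand that
occurs in k catalog pairs can contribute up to k; a variant counting
each distinct ligand once is available (`unique_ligands = TRUE`).
Class-level structure is assessed by a one-way ANOVA of
(species, cell type, replicate) mean ALCs against cell-type class,
fitted per species; the degenerate all-equal-means case is reported as
F = 0, p = 1 rather than the 0/0 ratio a direct fit produces.

## Signalling graphs and HITS

Per species, a directed multigraph connects cell types with one edge
per (sender, receiver, interaction), weighted by the product of the
mean log-normalized CP10K values of ligand and receptor (natural log,
`log(1 + 1e4·count/total)`; the limiting — minimum — subunit represents a
complex; zero-weight edges are dropped). Kleinberg hub and authority
scores are computed on the collapsed weighted adjacency (parallel edges
summed) by deterministic power iteration from a uniform start,
converged to 1e-12 in the max norm or 1,000 iterations, max-normalized
to 1. Power iteration was chosen over an ARPACK eigensolver solely for
bit-reproducibility of pipeline reruns; the tests verify agreement with
an eigen-decomposition oracle to 1e-8.

## Characters and ancestral state reconstruction

Characters live at cell-class resolution: `(class, gene)` is 1 in a
species if any cell type of that class passes the threshold, with a
companion continuous character equal to the leading cell type's
expressed fraction. A class absent from a species leaves its characters
missing; such characters are excluded from reconstruction rather than
imputed. Four reconstructions are compared:

* **Sankoff parsimony, equal weights** (`cost_matrix(1, 1)`) — the
  headline model for reported states;
* **Sankoff parsimony, gain-penalising** (`cost_matrix(gain = 2,
  loss = 1)`), encoding the view that novel expression gains are rarer
  than losses;
* **Wagner MPR** on the unrooted tree with the opossum as outgroup.
  The rooted root has no unrooted counterpart, so its state is taken
  from the outgroup tip — the outgroup defines the ancestral condition,
  which also means gains on the outgroup's own terminal branch cannot
  be inferred under this model;
* **Brownian GLS/REML** on the proportion characters, binarized at the
  20% cutoff. Ancestral expectations under Brownian motion are
  independent of the rate, so the REML rate (mean squared contrast)
  affects only uncertainty, never the states; the implementation is the
  exact matrix GLS conditional expectation, vectorised over characters.

The Sankoff implementation returns, per internal node, the set of
states attainable in at least one minimum-cost labelling (bottom-up
subtree costs plus a top-down outside-subtree pass), with ties reported
as `ambiguous`. Costs are compared with an absolute-plus-relative
tolerance of 1e-9 so weighted schemes are tie-stable. For event
counting and network reconstruction, ambiguity resolves to absence (0)
by default — conservative about asserting ancestral expression — and can
be switched to presence. Method agreement is the fraction of characters
whose full internal-node configuration (ambiguity included as its own
state) is identical across all four models.

Ancestral signalling networks re-apply the all-subunit rule to one
node's reconstructed states over all ordered class pairs (self-pairs
included). Each edge is aged by walking rootward while the edge remains
present at every intermediate node; the oldest such ancestor labels the
edge, so the age marks where that channel was established without
interruption.

## Disambiguation null model and test

Per species and ligand family: `S_pathway` ligands, `N_f` fetal and
`N_m` maternal cell types, and `L_expressed` observed per-cell-type
on-calls give `P_on = L_expressed / (S_pathway (N_f + N_m))`, the
per-slot on-probability under random assignment of calls to cell types
regardless of compartment. Then

$$P_{\text{fetal only}} = \left(1 - (1-P_{on})^{N_f}\right)(1-P_{on})^{N_m},$$

symmetrically for maternal-only, with co-expression and off by
complement (the quadruple sums to 1; an invariant tested to 1e-12).
Multi-subunit ligands are scored as units; when species paralogues are
expanded (`expand_homologues`), each paralogue of a single-subunit
human ligand becomes its own potential ligand on the species-native
atlas.

The test statistic is the usual `Σ (obs − exp)²/exp` over the three
expressed categories. Two decisions matter here:

1. **Conditioning.** The three category probabilities printed above do
   not sum to the observed number of expressed ligands, so the raw
   expectations cannot feed a goodness-of-fit test directly. The test
   conditions on expression: probabilities are divided by `1 − P_off`
   and scaled to the observed expressed count, so observed and expected
   totals match. The unconditioned expectations are also reported for
   transparency.
2. **Reference distribution.** Because `P_on` is estimated from the
   same on-calls being categorized, the statistic is stochastically
   smaller than chi-squared with 2 df (it falls between 1 and 2 df, the
   classical estimated-parameter effect), and the analytic p-value is
   conservative — the test suite measures its null rejection rate well
   below the nominal 5%. The function therefore reports both the
   analytic `p` (df = retained categories − 1) and a seeded Monte-Carlo
   `p_mc` obtained by resimulating B = 999 null families at the fitted
   `P_on` and re-estimating the null in each replicate; `p_mc` is the
   inference default and holds the nominal size in the calibration
   tests. Benjamini–Hochberg q-values are computed across families on
   the inference p-value; a per-family Bonferroni adjustment
   (p × family size, capped at 1) is reported alongside.

Calibration simulations use families of 24 ligands over 6 + 6 cell
types at `P_on = 0.2` — sizes chosen so the conditioned expected counts
stay near or above the classical chi-squared validity range — and
planted single-compartment families of 8 ligands for power, with the
per-slot probability inflated to preserve the expected total number of
calls.

Tree-wide disambiguation dynamics are summarized by coding each ligand
at every node as a joint (fetal, maternal) binary state — compartment
characters reconstructed by equal-weights parsimony with ambiguity
resolved to 0 — and counting one transition per branch per ligand into a
4×4 matrix (row-normalized percentages). Transitions into fetal-only
are decomposed into gains of fetal expression (from 0/0), losses of
maternal expression (from 1/1) and simultaneous double changes (from
0/1).

## zTPM, contrasts and the escalation test

Pseudo-bulk TPM is standardized within each species over the positive
entries of its matrix: `zTPM = (log2 TPM − μ)/σ`, floored at −3
(zeroes map to the floor). The default fit is the half-Gaussian,
mode-based procedure: μ is the kernel-density mode of the log2 values
and σ is estimated from the right tail as `(mean(x[x > μ]) − μ)·√(π/2)`,
which is robust to the zero-inflated left flank of expression
distributions; a plain mean/SD fit is available. Note the reference
point is the *expressed* population: genes far below the bulk of
expressed genes can land at the floor in every species even with
non-zero TPM.

Each pair's traits are the maximum zTPM over fetal cell types (ligand)
and maternal cell types (receptor) — the representative, putatively
co-evolving carriers — with ties broken lexicographically by cell-type
name so reruns are stable. Pairs must have non-zero representative TPM
in at least 4 of the 6 species on both sides. Felsenstein contrasts are
computed on the time-calibrated tree (n − 1 contrasts for n species;
polytomies are an error, resolve upstream), and the regression through
the origin `slope = Σxy/Σx²` is tested two-sided with n − 1 df. The
function regresses receptor contrasts on ligand contrasts by default —
change in the ligand predicts change in the receptor — with a flag to
swap the direction; the direction is recorded in the output because the
two conventions do not give the same slope. The raw OLS slope (with
intercept, same direction) accompanies each pair.

Degenerate cases are flagged, not dropped silently: predictor contrasts
that are numerically zero (absolute value below 1e-10 — e.g. a trait at
the floor in every species, where exact contrasts are zero up to
rounding residue) give `undefined = TRUE` with NA slope; an exactly
linear relation gives `p = 0` with `degenerate = TRUE`. Per-branch
expression changes are descendant minus ancestor (a gain is positive)
using the Brownian ancestral values, so escalation on a branch reads as
Δligand > 0 with Δreceptor < 0.

## The synthetic atlas generator

The generator exists so that every stage can be validated against known
truth. Defaults: 6 species on the fixed tree below, 12 cell types per
species (6 fetal in 3 classes, 6 maternal in 3 classes), 60 cells per
type, ~600 genes, 120 catalog interactions in 10 families (70%
secreted, 15% heterodimeric receptors), 8 genes duplicated into species
paralogue pairs to exercise orthologue pooling. Class-level binary
characters evolve by a two-state Markov chain (gain = loss =
0.0015/Myr, root probability 0.35); within a species, a cell of an
expressing cell type detects the gene with probability 0.6 (leak 0.02
otherwise), with counts 1 + NB(μ = 1.5, size = 2) scaled by lognormal
(sd 0.3) per-cell library factors. One ligand family is planted
fetal-exclusive and one maternal-exclusive. Coupled traits for the
escalation calibration evolve with ligand Brownian rate 0.1 and
receptor increments β × ligand increments plus independent noise (rate
0.1).

The species tree is
`(opossum,(tenrec,((guinea_pig,mouse),(macaque,human))))` with the
tenrec–human split fixed at 99 Myr and the remaining crown ages
(Theria 160, Euarchontoglires 90, Rodentia 73, Catarrhini 29 Myr) set
to conventional TimeTree-style values; all ages are overridable.

What the generator deliberately does not model: real cluster
substructure, batch effects, ambient RNA, dropout that varies by
expression level, unequal cell-type sizes, or biological correlation
between genes beyond the class-level characters. Consequently, passing
tests establish that the statistics are implemented correctly and
calibrated under their stated assumptions — not that those assumptions
hold in any particular real atlas. One instructive artefact is kept on
purpose: the generator's cell types come in class pairs that share an
expression state, so per-cell-type on-calls are positively correlated
within a species, and the disambiguation null (which assumes
independent slots) is mildly anticonservative on the synthetic atlas
itself, while remaining exactly calibrated on the slot-independent
null simulations. Real cell-type atlases share this kind of
correlation, so family-level rejections should be read as deviation
from the independent-slot null, not as proof of compartment-driven
selection.

## Problem sizes and determinism

Validation uses: exhaustive-enumeration parsimony oracles on 500 random
trees of up to 8 leaves (both cost schemes); 100-tree cross-checks of
Wagner-vs-Sankoff and of the Brownian GLS against an independent
reconstruction (1e-8); 1,000-replicate Brownian simulations on the
six-species tree for the escalation test (nominal size at β = 0, slope
recovery at β = 1); 2,000 null families plus 200 planted families for
the disambiguation test; 3,000 low-rate characters (about one expected
event per character) for ancestral-state recovery against the planted
truth, where gain-penalising parsimony must beat the per-character
majority-state baseline. That last margin is real but thin: the
recovery simulation uses symmetric gain/loss rates, which do not reward
the 2:1 gain penalty's premise that gains are rarer than losses, so the
two reconstructions agree on the many near-constant characters and
differ mainly on topologically informative patterns; under strongly
asymmetric rates the parsimony advantage widens. Every stochastic step takes an explicit seed;
generators restore the caller's RNG state, and a pipeline rerun with
the same configuration is byte-identical (verified by md5 manifest in
the tests).

## Known limitations

* Expression is the only evidence: post-transcriptional antagonism
  (decoy receptors, binding-affinity changes, peptide half-life) is out
  of scope.
* Parsimony state sets are exact, but downstream event counts depend on
  the ambiguity policy; the default (resolve to absence) undercounts
  gains near ambiguous nodes.
* With six species the contrast regressions have four residual degrees
  of freedom; power to detect moderate coupling is intrinsically low,
  and Bonferroni-significant pairs will be rare.
* The Wagner model's root convention ties the root state to the
  outgroup; discordance with the other models concentrates on the
  outgroup's branch.
* The pseudo-bulk-only fraction-pooling fallback is upper-bound biased;
  supply cell-level counts where exactness matters.
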
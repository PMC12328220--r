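---
title: "Structure-aware conservation analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-aware conservation analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Orthologous enzymes accumulate amino-acid substitutions unevenly: residues
buried in the core, lining small-molecule binding sites, or mediating
protein--protein contacts tolerate fewer changes than solvent-exposed
surface. `strucons` quantifies this structure-dependence at residue
resolution. Given an *orthogroup* -- a set of orthologous (possibly
paralogous) structures anchored to one or more reference members -- it
derives 1:1 residue correspondences by structural superposition, summarises
them as a **mapping ratio** (MR, the fraction of a member's residues placed
in correspondence with the reference, $M/(M+N)$) and a **conservation
ratio** (CR, the fraction of mapped residues whose amino acid matches the
reference, $C/M$), partitions the reference into structural elements, and
asks which elements, costs and metabolic properties co-vary with
conservation.

# The alignment model

Pairwise member-to-reference alignment follows the matchmaker idiom of
structure viewers:

1. a global sequence alignment (BLOSUM62, affine gaps, opening 10 /
   extension 1) seeds candidate C$\alpha$ pairs;
2. a Kabsch least-squares superposition (SVD with reflection correction)
   fits the candidates;
3. pairs farther than `prune_cutoff` (2.0 Å) after superposition are
   removed and the fit repeated until stable (at most 20 iterations);
4. the final 1:1 mapping keeps sequence-aligned pairs within `map_cutoff`
   (5.0 Å) of their partner after the converged superposition.

The pruning loop makes the superposition robust to divergent loops and
termini; the looser map cutoff retains residues that move with breathing
motions but are clearly homologous. Both cutoffs are exposed because they
trade mapped coverage (MR) against mapping confidence.

Structural similarity is scored with the TM-score,
$\mathrm{TM} = L^{-1} \sum_i 1/(1 + (d_i/d_0)^2)$ with
$d_0 = \max(0.5,\ 1.24\,(L-15)^{1/3} - 1.8)$, floored at 0.5 Å so toy
chains below 21 residues remain scored. Because the score depends on which
length normalises it, the package symmetrises the two normalisations; the
*bidirectional* score defaults to the arithmetic mean (minimum and maximum
are available by flag -- the choice matters only for length-mismatched
pairs, and the mean is the least extreme symmetrisation). Orthogroup
refinement clusters $1 - \mathrm{TM}_{bidir}$ with average linkage and cuts
the dendrogram at 0.2; identical structures (distance 0) can never be
separated by that cut.

# Conservation bookkeeping

M, N and C are counted on the *member* side (so $M + N$ is the member's
chain length), while per-residue tallies (`n_mapped`, `n_identical`,
`fully_conserved`) accumulate on the reference side. Ratios are computed
per member and averaged unweighted over members -- the "mean conservation
ratio per protein" convention -- rather than pooling residues, which would
weight long members more. A species-deduplication helper collapses
paralogues to their best-mapping representative before averaging, since
the averaging universe (structures vs species) is a genuine ambiguity;
both modes are exposed. `'X'` residues may map but never count as
identical, and are excluded from class-CR denominators.

A residue is *fully conserved* when every aligned member maps it and
matches it; a relaxed quorum (e.g. 0.95) is available for large noisy
orthogroups, with 1.0 the default because the cluster analysis is defined
on strict conservation.

# Residue features

* **Accessibility.** Shrake--Rupley SASA with a 1.4 Å probe and a
  960-point deterministic spherical (golden-spiral) lattice per atom;
  element radii from a packaged table. rSASA divides by Tien-style
  theoretical maxima, and residues are *surface* at rSASA $\ge$ 0.25 (a
  common convention; configurable, and the studies are insensitive between
  0.20 and 0.30 because the toy folds have few boundary residues).
* **Secondary structure.** Kabsch--Sander hydrogen bonds (electrostatic
  energy below $-0.5$ kcal/mol, amide H rebuilt from the previous
  residue's carbonyl): consecutive $i \to i{+}4$ (or $i{+}3$/$i{+}5$)
  turns make helix, bridge patterns make extended (with ladder fill, since
  antiparallel ladders hydrogen-bond only every second residue), isolated
  $i \to i{+}3$ bends make turn, everything else coil. Four exclusive
  classes, priority helix > extended > turn. A C$\alpha$-only geometric
  fallback (distance windows on $d_{i,i+3}$/$d_{i,i+4}$) is flagged in the
  output when backbones are incomplete.
* **Binding sites.** Two orthogonal definitions: curated per-residue
  annotation joined through author numbering (UPb; site types substrate /
  cofactor / metal), and heavy-atom proximity (5.0 Å) to retained ligands
  after excluding waters and common crystallisation additives (CSb).
  Annotations detected on a holo homologue transfer onto the reference
  through the residue mapping, dropping (and counting) unmapped residues.

# Conserved clusters

Fully conserved residues form a contact graph (C$\alpha$ within 10 Å);
*clusters* are its connected components of at least 3 residues. Connected
components were chosen over community detection because the planted
structures of interest (binding pockets) are compact and the graph is
sparse; a community-detection alternative can be swapped in behind the same
interface. A *site* in the overlap statistics is a spatially connected set
of flagged residues on the same contact graph (annotated sites need not be
contiguous in sequence), covered when any of its residues falls in any
cluster. The enrichment ratio compares the binding fraction among fully
conserved residues to the binding fraction overall.

The cluster classifier is a histogram-based gradient-boosted tree
(xgboost, `tree_method = "hist"`, depth 3, 50 rounds) on a declared
feature vector: size, contact density, mean rSASA, surface fraction,
secondary-structure composition, mean residue cost, mean hydrophobicity,
physicochemical-class composition, mean pLDDT. Evaluation is ten repeats
of stratified fivefold cross-validation; two baselines reuse the same
folds and seed -- labels reassigned to random clusters within size tertiles,
and fully permuted labels.

# Costs and composition

Two packaged per-residue cost metrics: Akashi--Gojobori biosynthetic cost
(high-energy phosphate-bond equivalents) and molecular weight; each is
median-normalised so metrics on different scales can sit in one figure,
and external tables load through the same two-column TSV interface.
Composition excludes `'X'` from numerator and denominator. Element reports
(all mapped / core / surface / UPb / CSb / four secondary-structure
classes) leave empty elements missing rather than zero.

# Statistics layer

Rank correlations (Spearman, Kendall tau-b, Pearson) on pairwise-complete
data with exact small-sample p-values where available; Wilcoxon--Mann--Whitney
and signed-rank tests with Cliff's $\Delta$ as effect size; quartile
enrichment by two-sided Fisher's exact test with tail ties included (a
deterministic tail beats an exactly-25% tail); ROC/AUC through the
Mann--Whitney identity with midranked ties; Benjamini--Hochberg adjustment
for every reported family. The "adjusted" Cliff's $\Delta$ operates on
per-orthogroup means rather than pooled residues, removing
pseudo-replication; the pooled variant stays available
(`delta_mode = "pooled"`).

# The synthetic generator

The generator is the ground-truth substrate for every end-to-end claim.
A fold blueprint lists segments (helix / strand / coil) and a pocket; the
default is a 72-residue three-helix bundle whose pocket is three inward
mid-helix triplets, chosen so all pocket pairs sit on adjacent helices.
Structured segments are built with full idealised backbones from canonical
dihedrals ($\varphi,\psi$ of $-57,-47$ for helix and $-139,135$ for
strand) so hydrogen-bond-based secondary-structure assignment sees real
geometry; helices pack on a bundle circle (pocket faces rotated inward,
bundle shrunk until pocket residues approach mutual contact under a clash
guard), consecutive strands pair antiparallel with the axial registry that
maximises inter-strand hydrogen bonds, and coils are self-avoiding walks
with 3.8 Å virtual bonds routed over the bundle.

Evolution plants the conservation hierarchy: per member, each site
substitutes independently with class probability 0.02 (binding), 0.2
(core) or 0.5 (surface); replacements are uniform over the 19 other amino
acids so expected identity is exactly $1-p$; C$\alpha$ noise
($\sigma = 0.5$ Å) is applied rigidly per residue; terminal deletions
(probability 0.5 per terminus, 1--6 residues) concentrate unmapped
residues at the ends, as in real predicted models. Orthogroups draw 5--30
members by default. Across a corpus, per-orthogroup multipliers
(uniform 0.5--2 on the core/surface rates) spread conservation the way
real orthogroups spread; property tables then couple abundance positively
($\alpha + \beta\,\mathrm{CR} + \varepsilon$, $\beta = 6$, $\sigma = 1$ on
a log2 scale) and flux variability and $k_\mathrm{cat}$ variability
negatively to true CR, with auxiliary columns (flux median, species
count, inhibitor count, PPI degree, EC class, pathway) completing the
standard table shape. Members are independent (star phylogeny) because the
downstream statistics do not model the tree; a phenotype-multiplier hook
halves the substitution rate of "yes" species for subgroup simulations.

What the generator does *not* emulate: side chains beyond the backbone,
force-field-quality packing, tree-structured covariance between members,
insertions (only terminal deletions), and compositional biases of real
proteomes (ancestor sequences are uniform over the 20 amino acids).
Passing the planted-truth studies therefore demonstrates that the pipeline
measures what it claims on data whose answer is known -- not that real
orthogroups obey the planted model.

# Validation studies and problem sizes

The packaged studies (also run by `scripts/acceptance.R`) use: 100
simulated orthogroups of 10 members for hierarchy recovery (pooled class
CR checked against $1-p$ within 3 binomial standard errors) and for
pocket-cluster recovery (background rate 0.4, Jaccard of the best cluster
against the pocket); 200 null replicates for rank-test calibration and BH
false-positive rates; 1000 label permutations for the AUC null; 50 runs
of 20 orthogroups for coupling sign recovery; 20 seeds of ~21 clusters
(pocket-derived positives vs random connected subsets) for the
classifier; and a 3-orthogroup "small" preset, run twice, for bit-identical
determinism of the file-based pipeline. The separable classifier check
uses 150 synthetic clusters: with much smaller sets, cross-validated AUC
under permuted labels sits systematically *below* 0.5 (training folds
absorb label noise that anti-correlates with the held-out folds -- the
finite-population "anti-learning" effect), and only at this size does the
permutation null centre on chance. That small-sample bias is a known
limitation to keep in mind when reading per-seed baseline AUCs from the
planted-cluster study.

# Degenerate inputs and numerical choices

Residues without C$\alpha$ are dropped and counted at parse; altlocs
resolve to highest occupancy (ties toward 'A'); insertion codes flatten
into sequential indices with author numbering kept for annotation joins;
modified residues map to parent amino acids via a packaged table, anything
else to `'X'`. Chains shorter than 5 residues are all coil; collinear
point sets superpose with a degeneracy flag; empty conserved networks are
valid output; empty residue subsets yield missing values, never zeros.
Every stochastic path is seeded, and the pipeline derives stage seeds from
one master seed so a rerun with the same configuration is bit-identical.

# Known limitations

MR/CR depend on the reference choice; with paralogous references the
package computes one profile per reference and leaves the comparison to
the caller. The conservation statistics ignore phylogenetic
non-independence between members, matching the analysis layer they
implement; with a real species tree, correlations across orthogroups
should be read as descriptive. The pocket-packing step is best-effort:
helix geometry wraps consecutive pocket residues around the helix axis, so
the "mutually within 8 Å" target is reached between inward-facing
residues but not across every pocket pair. CSb detection requires ligands
in the input structure or a mapped holo homologue; it cannot invent
pockets from geometry alone.
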
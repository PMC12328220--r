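# strucons — structure-aware conservation analysis of enzyme orthogroups

Orthologous enzymes do not diverge uniformly: substitutions concentrate on
the solvent-exposed surface, while cores and especially small-molecule
binding sites stay conserved. `strucons` measures this at residue
resolution for *orthogroups* — sets of orthologous structures anchored to a
reference member. It is written for structural bioinformaticians who have
per-species predicted (or experimental) structures and want
conservation-by-structural-context analyses without a heavyweight external
alignment stack.

## What it computes

For each member aligned onto the reference (sequence-seeded Kabsch
superposition with iterative pruning, matchmaker-style):

* **Mapping ratio** `MR = M / (M + N)` — the fraction of the member's
  residues placed in 1:1 structural correspondence with the reference;
* **Conservation ratio** `CR = C / M` — the fraction of mapped residues
  identical to the reference, averaged unweighted over members;
* bidirectional TM-scores
  (`TM = L⁻¹ Σᵢ 1/(1 + (dᵢ/d₀)²)`, `d₀ = max(0.5, 1.24(L−15)^⅓ − 1.8)`)
  and average-linkage orthogroup refinement at a 0.2 linkage cutoff;
* per-residue features: Shrake–Rupley rSASA with a surface/core split at
  0.25, hydrogen-bond secondary structure, binding sites from curated
  annotation (UPb) or ligand proximity at 5 Å (CSb);
* clusters of fully conserved residues on the 10 Å Cα contact graph,
  their overlap with binding sites, and a gradient-boosted classifier
  (ten fivefold cross-validations, two null baselines) for whether a
  cluster contains a known site;
* amino-acid biosynthetic cost and composition per structural element;
* a statistics layer: rank correlations, Wilcoxon tests with Cliff's Δ,
  quartile Fisher enrichment, ROC/AUC enrichment, BH adjustment,
  phenotype subgrouping.

A synthetic-orthogroup generator with planted class-dependent substitution
rates (binding 0.02 < core 0.2 < surface 0.5 per site and member),
coordinate noise, terminal indels and property tables coupled to true
conservation provides ground truth for every end-to-end claim; see
`vignettes/methods.Rmd` for the models and design decisions.

## Worked example

The numbered drivers under `analysis/` run the full study on a simulated
corpus (10 orthogroups × 8 members of a 72-residue three-helix bundle with
a planted pocket), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_align_conserve.R
Rscript analysis/03_features_clusters.R
Rscript analysis/04_cost.R
Rscript analysis/05_associations.R
```

which prints, stage by stage:

```
simulated 10 orthogroups (90 structures), mean pLDDT 90.8
true CR range across orthogroups: 0.47 - 0.82
aligned 10 orthogroups: median MR 0.996, median CR 0.597
measured vs true CR: Spearman rho = 0.99 over 10 orthogroups
features: 720 residues annotated; surface fraction 0.42
clusters per orthogroup: median 1.0, median size 10.0
UPb sites covered by a cluster: 100% of orthogroups at 100%
associations with orthogroup CR (estimate / adjusted p):
  abundance_log2     0.64  0.112
  flux_cv           -0.43  0.273
  kcat_log_sd       -0.73  0.106
planted hierarchy recovered in 100% of 20 seeds (class CR: binding 0.976, core 0.807, surface 0.500)
```

Reading this: members map almost completely (the only unmapped residues
are the planted terminal deletions), the measured orthogroup CR tracks the
generator's true conservation almost perfectly, every planted pocket is
recovered by a conserved cluster, and the class-restricted CRs land on the
planted substitution rates (1 − p = 0.98 / 0.80 / 0.50). The association
signs (abundance positive, flux and kcat variability negative) recover the
generator couplings; with only 10 orthogroups the adjusted p-values are,
as expected, not significant.

The same machinery is exposed as functions
(`read_structure`, `align_and_map`, `conservation_profile`,
`residue_features`, `find_clusters`, `classify_clusters`,
`element_cost_report`, `correlate`, …) and as a config-driven
`run_pipeline()` whose stages communicate through files and are
bit-identical under a fixed seed.

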
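Package: strucons
Title: Structure-Aware Conservation Analysis of Enzyme Orthogroups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Residue-level conservation analysis of enzyme orthogroups from
    protein structures. Superposes members of an orthogroup onto a reference
    structure, derives 1:1 residue mappings, and computes mapping ratios (MR)
    and conservation ratios (CR) per member, per orthogroup and per structural
    element (core, surface, binding sites, secondary-structure classes).
    Annotates residues with relative solvent accessibility, secondary
    structure and binding-site flags, detects clusters of fully conserved
    residues on the 10 Angstrom C-alpha contact graph, quantifies their
    overlap with annotated binding sites, and classifies clusters with a
    gradient-boosted tree. Includes amino-acid biosynthetic cost and
    composition profiling, a nonparametric statistics layer (correlations,
    rank tests with Cliff's delta, quartile and ROC enrichment, BH
    adjustment), and a synthetic-orthogroup generator with planted
    class-dependent substitution rates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    xgboost,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
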
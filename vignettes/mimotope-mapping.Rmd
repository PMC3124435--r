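---
title: "Mapping phage-display mimotopes onto antigen surfaces"
author: "mimomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping phage-display mimotopes onto antigen surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimomap)
```

## The problem

Most B-cell epitopes are conformational: the residues an antibody contacts
sit close together on the folded antigen surface but far apart in sequence.
Phage display panning against a monoclonal antibody yields mimotopes —
short peptides (typically ≤ 15 residues) that bind the same paratope and
therefore tend to resemble the epitope in sequence. `mimomap` treats
epitope localisation as a constrained alignment problem: find, among
spatially plausible residue paths on the antigen surface, those that the
mimotope set collectively matches best, and report the surface
neighbourhood that accumulates the strongest evidence.

The model makes three assumptions worth keeping in mind. First, that
mimotope similarity to the epitope is sequential and positional, so a
substitution matrix is an appropriate measure. Second, that epitope
residues are mutually close at the Cβ level, so simple paths in a
residue-contact graph can represent the physical footprint. Third, that
one patch (15 Å radius) suffices to contain the epitope; epitopes split
across distant surface regions will at best be partially recovered.

## Pipeline and parameters

### Solvent accessibility

Per-atom accessible surface area uses the Shrake–Rupley construction: each
atom's van der Waals sphere (C 1.70, N 1.55, O 1.52, S 1.80 Å) is expanded
by the probe radius (default 1.4 Å, water) and sampled with a
**deterministic golden-spiral lattice** of `n_sphere_points` (default 960)
points; the accessible fraction is the share of points outside every
neighbouring expanded sphere. The deterministic lattice makes areas
reproducible without a seed; at 960 points an isolated sphere's area is
exact to the lattice discretisation, and areas on small structures change
by under 2 % when the density is quadrupled (this is tested).

A residue is a **surface residue** when RSA = ASA / maxASA exceeds
`rsa_threshold` (default 0.05, dimensionless). The maxASA denominators are
the published theoretical maxima of Tien et al. (2013); the table is an
explicit argument (`max_area_table()`) because several such scales exist
and downstream counts shift slightly with the choice. Accessibility is
computed on the antigen chain alone: prediction never sees the antibody.

### Patches and compactness-regulated graphs

Each surface residue centres a candidate patch containing every surface
residue whose side-chain anchor lies within `patch_radius` (15 Å — large
enough to encompass typical conformational epitopes). The anchor is Cβ,
falling back to Cα for glycine; side chains mediate antibody contact, so
Cβ–Cβ distance represents functional closeness better than Cα–Cα.
Patches with more than `max_patch_size` (50) residues mark dense, concave
regions where epitopes are unlikely and path search cost explodes; they
are discarded (and counted).

A patch graph connects residue pairs within a distance threshold. Its
compactness factor is

$$CF = \frac{e}{a\,k}, \qquad a = 4,$$

the observed edge count over an expected count that grows linearly with
the vertex count \(k\) — linear rather than \(k(k-1)/2\) because a residue
only contacts its spatial neighbours. The **adaptive distance threshold**
starts at 6.5 Å and moves in 0.01 Å steps, up when CF is below the band
\(0.73 \pm 0.06\), down when above, stopping when CF enters the closed
interval \([0.67, 0.79]\). Numerical details decided here:

* **Tie at the edge rule**: edges use ≤ threshold. The alternative strict
  inequality differs only when a pairwise distance ties the grid exactly.
* **Unreachable band**: small patches have a CF ceiling below 0.67 (two
  vertices cap at 1/8), so thresholds are clamped to
  `threshold_bounds = c(3, 20)` Å and the closest-CF graph is returned
  with `band_reached = FALSE` — never an error, because patch sets always
  contain a few tiny patches.
* **Band jump**: when one 0.01 Å step crosses the band (many equal
  distances entering at once), the side with CF closer to 0.73 is kept.
  The adaptive walk is verified against an independent grid-scan oracle in
  the tests.

### Path alignment

A mimotope \(Q(k) = (q_1,\dots,q_k)\) is aligned to simple paths by
dynamic programming over states \((m, S)\) — the path's end vertex and its
visited set (patch graphs are capped at 50 vertices, so \(S\) is a 64-bit
mask in the compiled kernel). Transitions are replacement (advance path
and query, score \(h(q_i, p_j)\)), deletion (advance query only, penalty
\(\delta_D\)), and insertion (advance path only, \(\delta_D\)); paths
ending at the same vertex with the same visited set keep only their best
score. End gaps are free: alignments may start and end anywhere in both
the query and the path, and the returned score is the maximum over all
states and query positions, floored at zero. Because leading path
vertices are free, every optimal alignment can start at a matched vertex,
so state seeding matches \(q_i\) at every vertex for every \(i\); raw
scores are exactly reproducible from the reported alignment columns.

\(\delta_D\) defaults to −5 (configurable): deep enough that a gap costs
about as much as a good match gains, so paths do not skip freely, yet
shallow enough that a single mismatch-bridge is affordable. Both gap
directions are enabled by default and can be disabled individually.

**Branch and bound.** A state is expanded only if its score plus an
admissible completion bound reaches the best complete alignment found so
far (seeded by a greedy single-match pass). The bound sums, over
unconsumed query positions, each position's best achievable score against
any amino acid present in the graph (never larger than
remaining × max entry). Pruning is strict-inequality, so exactness is
preserved; the tests assert score equality with pruning on and off, and
equality with exhaustive path enumeration on hundreds of random
instances. An optional beam limit exists for pathological dense graphs
and is off by default; with it off, results are exact.

### The NNK-adjusted substitution matrix

Phage libraries built on NNK codons (N = A/C/G/T, K = G/T; 32 codons, one
stop) encode amino acids with frequencies \(f_i = c_i/32\) where \(c_i\)
counts codons (Leu/Arg/Ser 3; Met/Trp 1; …). BLOSUM62's log-odds assume
natural background on both sides; the default matrix here replaces the
query-side background:

$$s'_{ij} = \operatorname{round}\!\left(2\log_2\frac{q_{ij}}{f_i\,p_j}\right),$$

with target frequencies \(q_{ij} = p_i p_j 2^{s_{ij}/2}\) implied by the
integer BLOSUM62 scores \(s_{ij}\) and published background \(p\). The
result is asymmetric (rows index the mimotope side) and is shipped as a
plain NCBI-format text file, regenerated by `derive_nnk_matrix()`, so any
other matrix can be substituted via `read_score_matrix()`.

### Extreme-value calibration and patch ranking

Raw path scores are length-dependent, so each (graph, query length) pair
is calibrated: `evd_samples` (default 1000; ≥ 200 enforced) random
peptides with NNK amino-acid frequencies are aligned to the graph and a
Gumbel distribution fitted by the **method of moments**
(\(\beta = s\sqrt{6}/\pi\), \(\mu = \bar{x} - \gamma\beta\)) — closed
form, deterministic given the seed, and testable against exact
expectations; maximum likelihood is available behind `method = "mle"`.
Zero-variance samples (degenerate single-vertex graphs) get a flagged
scale floor rather than an error. The calibration distribution must match
the query distribution: P-values are near-uniform for NNK-drawn peptides,
and would be anti-conservative for, e.g., uniformly drawn ones, because
rare-in-NNK letters score high under the adjusted matrix.

A patch aggregates \(\sum_i -\log_{10} P_i\) over its mimotope
alignments. Summing raw P-values would reward bad alignments, so the
log-evidence sum — under which "highest score wins" is coherent — is
used. Ties rank smaller patches first (more specific), then lower centre
residue numbers (deterministic output). Calibrating per graph is the
default; `evd_scope = "antigen"` calibrates once per query length on a
median-size graph and reuses it, trading calibration sharpness for a
large constant-factor speedup.

No multiple-testing correction is applied across patches: patches overlap
heavily and the method reports a ranking, not significance claims.

## Synthetic structures: what they do and do not show

`make_toy_structure()` builds two deterministic geometries with ideal
backbone pseudo-atoms (N, Cα, C, O) and a Cβ at a 1.53 Å tetrahedral
offset:

* **helix** — an ideal α-helix (1.5 Å rise, 100°/residue). Everything is
  solvent-exposed and consecutive Cβ anchors sit 5–6 Å apart, so planted
  epitope paths are graph-connected at the 6.5 Å scale. CF at 6.5 Å is
  typically below the band: the sparse regime.
* **coil** — a jittered compact lattice globule (~4 Å neighbour spacing,
  snake-ordered chain) at protein-interior density. CF at 6.5 Å sits above
  the band: the dense regime that makes the adaptive threshold contract.

`plant_epitope_path()` relabels a connected run of surface residues to
spell a chosen epitope (coordinates untouched), and `sample_mimotopes()`
mutates the epitope per position at `mutation_rate` with NNK-frequency
replacements — emulating the high sequence similarity of affinity-selected
peptides.

These fixtures validate the machinery — surface flags, graph regulation,
exact search, calibration, ranking — under fully known ground truth. They
do **not** emulate real side-chain packing, discontinuous multi-segment
epitopes, mimotopes with register shifts or motif rearrangements, or
antigens with buried cores shaping the surface non-trivially. A passing
planted-recovery suite therefore demonstrates correctness of the
algorithmic chain, not field performance on crystal structures; real
antigens should be evaluated against curated epitope annotations.

## Problem sizes

The shipped tests and the acceptance script size their simulations for a
single CPU: oracle comparisons use 200 random graphs of ≤ 8 vertices with
3–6-mer queries (the exhaustive oracle is factorial and guarded at 12
vertices); planted-epitope recovery runs 20 replicates on 24-residue
helices with 10 mimotopes at 20 % mutation; examples and tests calibrate
with `evd_samples = 300` (above the 200-sample floor) rather than the
1000-sample default; Gumbel recovery uses \(10^5\) draws. Each replicate
of the recovery experiment takes a few seconds; the full acceptance run
about two minutes.

## Known limitations

* Only the first PDB model and a single chain are consumed; mmCIF,
  assemblies and ligands are out of scope. Nonstandard residues with a
  clear parent (MSE → M, etc.) are mapped; others are dropped.
* The alignment is linear-gap; affine gaps are not offered.
* An "AHA atom" anchoring convention mentioned in parts of the literature
  is not implemented; anchoring is Cβ (Cα fallback) only.
* Patch scores are comparable within one run, not across antigens:
  calibration is per graph.
* The ADT walk's 0.01 Å grid interacts with discretised coordinates:
  exactly tied distances are resolved by the ≤ rule and band-jump policy
  above, which can leave a graph marked `band_reached = FALSE` even when
  its CF is near the band edge.
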
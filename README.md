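# mimomap

Conformational B-cell epitopes are discontinuous clusters of residues on an
antigen's surface. Phage display experiments yield *mimotopes* — short
affinity-selected peptides that mimic the native epitope's binding behaviour
and usually resemble it in sequence. `mimomap` projects a set of mimotopes
back onto an antigen's 3D structure to locate the epitope they mimic: it is
aimed at structural immunologists and vaccine designers who have an antigen
crystal structure plus panning results, and want a ranked candidate epitope
before committing to experiments.

## Method

1. **Surface extraction.** Per-atom solvent-accessible surface area is
   computed with a native Shrake–Rupley implementation (1.4 Å probe,
   deterministic golden-spiral point lattice). A residue with relative
   accessibility RSA = ASA / maxASA > 0.05 is a surface residue.
2. **Patches.** Every surface residue centres a patch: all surface residues
   whose Cβ anchors (Cα for glycine) lie within 15 Å. Patches larger than
   50 residues are discarded.
3. **Compactness-regulated graphs.** Patch residues become vertices; pairs
   within a distance threshold become edges. The *compactness factor*

   CF = e / (a·k),  a = 4

   (observed over expected edge count, k vertices) regulates an *adaptive
   distance threshold* (ADT): starting from 6.5 Å the threshold moves in
   0.01 Å steps until CF ∈ 0.73 ± 0.06, so dense and loose surface regions
   yield comparably connected graphs. A fixed threshold (FDT) mode is
   available for comparison.
4. **Path alignment.** Each mimotope Q(k) = (q₁,…,q_k) is aligned against
   simple paths of each graph by dynamic programming over
   (end vertex m, visited set S) states, with substitution scores h(qᵢ, pⱼ),
   a linear gap penalty δ_D for internal insertions/deletions, free end
   gaps, and deduplication of permuted paths sharing (m, S). Admissible
   branch-and-bound pruning accelerates the search without changing
   scores. The default substitution matrix is BLOSUM62 re-derived with the
   query-side background replaced by NNK-library codon frequencies
   (f_aa = codons/32), reflecting the amino-acid bias of phage libraries.
5. **Scoring.** Per graph and query length, raw scores of random
   NNK-frequency peptides are fitted to a Gumbel (extreme value)
   distribution; each alignment gets P = 1 − exp(−exp(−(x−μ)/β)). A patch
   scores Σ −log₁₀ P over its mimotope alignments; the top-ranked patch is
   the candidate epitope.
6. **Evaluation.** Against a known epitope, sensitivity TP/(TP+FN),
   precision TP/(TP+FP) and the Matthews correlation coefficient are
   reported over the surface-residue universe.

## Worked example

A synthetic 24-residue helix with the 5-mer epitope `YGVKN` planted as a
connected surface path, and six mimotopes mutated from it at rate 0.2:

```r
library(mimomap)
planted <- plant_epitope_path(make_toy_structure(toy_spec(24, seed = 3)),
                              "YGVKN", seed = 3)
mims <- sample_mimotopes("YGVKN", 6, 0.2, seed = 3)
fit <- mimomap(planted$model, mims, evd_samples = 300, seed = 3)
summary(fit)
```

```
Ranked patches (adt; mean CF 0.721):
 rank patch size aggregate
    1  A:13   17 11.589620
    2  A:12   17 10.963255
    3  A:11   17 10.680405
    4   A:3   11 10.428399
    5   A:8   16  9.969055

Candidate epitope (patch A:13): A:5, A:6, A:7, A:8, A:9, A:10, ... A:21

Mimotope alignments on the candidate patch:
 label sequence raw_score p_value                  path
    m1    VGVKN      24.0  0.0141       A:6 A:7 A:8 A:9
    m2    AGVKN      25.0  0.0107 A:11 A:10 A:7 A:8 A:9
    m5    YGVKN      31.0 0.00208   A:5 A:6 A:7 A:8 A:9
    ...
```

The patch score (`aggregate`) is summed −log₁₀ P evidence over all six
mimotopes; the unmutated copy `YGVKN` aligns along the planted path
A:5–A:9 with the best raw score (31, the diagonal sum of its
substitution-matrix entries) and the smallest P-value. The candidate patch
contains the full planted epitope:

```r
evaluate_prediction(fit, planted$planted_keys)
#> TP=5 FP=12 TN=7 FN=0  Se=1.000 Pr=0.294 MCC=0.329
```

For real antigens, point `mimomap()` (or the CLI) at a PDB file and chain:

```sh
inst/cli/mimomap run --pdb antigen.pdb --chain A --mimotopes peps.txt \
    --out-dir out           # JSON + TSV results, run log
inst/cli/mimomap compare --pdb antigen.pdb --chain A --mimotopes peps.txt
inst/cli/mimomap simulate --epitope YGVKN --n-residues 30
inst/cli/mimomap evaluate --predicted pred.txt --truth truth.txt --universe uni.txt
```

## Scope

The package predicts from the antigen chain alone (no antibody modelling),
does not fetch structures or mimotope databases, and applies no
multiple-testing correction across patches. See the methods vignette
(`vignettes/mimotope-mapping.Rmd`) for modelling assumptions, parameter
choices and limitations.
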
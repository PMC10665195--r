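# scrapseek

Cross-reactivity scoring and antigen prioritization for peptide-centric
immunotherapies (PC-CARs, TCR-mimic antibodies, affinity-enhanced TCRs).

Peptide-centric receptors see only the solvent-exposed face of a short
peptide presented by an MHC class I molecule. A normal self-peptide that
matches the tumour target at the receptor-facing positions can therefore be
co-recognized — the failure mode behind fatal off-tumour toxicities — and
has to be screened for *before* a receptor is built. `scrapseek` implements
that screen and the antigen-discovery pipeline around it:

* **Cross-reactivity scan** — compares a query tumour pMHC against every
  same-length window of the normal proteome. Per scored (non-anchor)
  position a candidate earns **5** for an identical residue, **2** for a
  different residue of the same chemical class, **−2** otherwise; the
  positional sum ΣP is combined with the candidate's predicted binding
  affinity *b* (IC50, nM) and its parent genes' maximum normal-tissue
  expression *E*<sub>max</sub> as

  overall = ΣP / (*b* × *E*<sub>max</sub>)

  and candidates are reported ranked, with flags for exact self-matches and
  for peptides empirically observed in the normal immunopeptidome. An
  alternative expression-weighted orientation (ΣP · *E*<sub>max</sub> / *b*)
  is available; see the methods vignette for why both exist.
* **Discovery funnel** — filters immunopeptidomics hit tables through
  predicted binding (IC50 ≤ 500 nM), per-tissue differential expression of
  the parent gene versus every normal tissue (log2 FC ≥ 1 and p < 0.01 as a
  conjunction), and gene-level exclusion against a benign-tissue
  immunopeptidome; then ranks survivors by a transparent composite
  (expression, allele frequency, abundance, affinity, recurrence).
* **Companion screens** — cross-HLA presentation scans through a pluggable
  binding-predictor contract, MS1 matched-peptide search (theoretical
  monoisotopic m/z within a ppm tolerance, ±1 min retention-time window),
  and alanine-scan contact-residue calling.
* **Synthetic data** — deterministic generators with planted ground truth
  (cross-reactors with arithmetically known ΣP, tumour-specific genes,
  per-stage funnel labels, jittered MS1 features), so the entire pipeline
  is testable without external databases or binding engines.

External binding predictors (NetMHC-class tools) are deliberately not
reimplemented: anything satisfying the
`function(peptides, allele) -> (ic50, rank)` contract plugs in, and
`cache_predictions()` / `table_predictor()` let you run an engine once and
replay it.

## Worked example

Build a small synthetic proteome, plant a near-identical cross-reactive
peptide (two different-class substitutions at positions 4 and 6 of the
PHOX2B-derived query QYNPIRTTF), index it, and scan:

```r
library(scrapseek)

prot    <- synth_proteome(30, seed = 42)
planted <- plant_cross_reactor(prot, "QYNPIRTTF", at_positions = c(4, 6),
                               ic50 = 25, seed = 42)
pred    <- toy_predictor(42, overrides = data.frame(
             peptide = planted$truth$peptide, allele = "HLA-A24:02",
             ic50 = 25, rank = 0.2))
ex      <- synth_expression(c(prot$gene, "PLANTED1"), seed = 42)
idx     <- build_index(planted$proteome, 9, "HLA-A24:02", pred,
                       normal_tissue_max(ex$expr, ex$sample_map))
lig     <- synth_normal_ligandome(prot, 25, seed = 42)
scrap_scan("QYNPIRTTF", "HLA-A24:02", idx, normal_ligandome = lig, top_k = 5)
```

```
sCRAP scan: QYNPIRTTF on HLA-A24:02 | mode: printed | 1959 candidates scored
    rank   peptide    genes sum_p      b_nM     E_max overall_score
1:     1 QYNQIATTF PLANTED1    21  25.00000 11.813916   0.071102586
2:     2 QAYNFHTYC    G0006     4  41.11070  1.426219   0.068221124
3:     3 GINGGRFAT    G0006     8 615.57747  1.426219   0.009112153
4:     4 TVNPMDQFC    G0007    12 152.36655 17.074733   0.004612514
5:     5 CAAPGLRGC    G0001     1  24.72951 10.242710   0.003947931
   in_normal_ligandome   self
1:               FALSE  FALSE
...
```

Reading the top row: the planted mimic `QYNQIATTF` matches the query at all
scored positions except 4 and 6 (ΣP = 35 − 2×5 − 2×2 = 21, exactly the
generator's recorded ground truth), binds strongly (25 nM) and its host
gene is expressed in normal tissue (E_max ≈ 11.8 RPKM), so it tops the
risk ranking — it is the peptide you would counter-screen a receptor
against before committing to the target. The `self` column flags the
query's own proteome occurrence; `in_normal_ligandome` marks candidates
actually observed on normal tissue (rendered `T`/`F` in the TSV report).

The same operations are available from the shell via the installed
`scrapseek` script (`synth`, `scan`, `funnel`, `prioritize`, `crosshla`,
`ms1match`, `alascan`, `validate` subcommands); every run writes a JSON
manifest with parameters, input digests and the seed.

## Package layout

* `R/aa-table.R` — amino-acid classes, peptide validation, positional
  scoring primitives, monoisotopic mass / m/z arithmetic
* `R/proteome.R`, `R/predictor.R` — proteome windowing, expression
  annotation, index construction, binding-predictor contract
* `R/scrap.R` — the cross-reactivity engine and report I/O
* `R/discovery.R` — funnel stages, prioritization, cross-HLA and MS1 screens
* `R/alascan.R` — alanine-scan contact-residue analysis
* `R/synthetic.R` — seeded generators with planted ground truth
* `R/cli.R`, `exec/scrapseek` — command-line entry point and run manifests
* `vignettes/cross-reactivity-methods.Rmd` — model, assumptions, design
  decisions and limitations
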
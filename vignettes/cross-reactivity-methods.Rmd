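---
title: "Cross-reactivity scoring and antigen prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-reactivity scoring and antigen prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrapseek)
```

## The problem

Peptide-centric receptors (PC-CARs and affinity-enhanced TCRs) recognize a
short tumour peptide presented on an MHC class I molecule. Because the
receptor only contacts the solvent-exposed face of an 8–14-mer, a normal
self-peptide that resembles the target at the receptor-facing positions can
be recognized too — with potentially fatal consequences when the mimicking
gene is expressed in an essential tissue. `scrapseek` provides the two
computational halves of a safety-aware antigen program:

1. a **discovery funnel** that filters immunopeptidomics hits down to
   tumour-specific candidates, and
2. a **cross-reactivity scan** that ranks every same-length window of the
   normal proteome by its predicted risk of being co-recognized with a given
   query pMHC.

## The cross-reactivity score

For a query peptide $q$ and a normal candidate $c$ of equal length $n$, each
scored position $i$ contributes

$$P_i = \begin{cases} 5 & q_i = c_i \\ 2 & q_i \ne c_i,\ \mathrm{class}(q_i) = \mathrm{class}(c_i) \\ -2 & \text{otherwise} \end{cases}$$

using five chemical classes (aliphatic-nonpolar `G A V L I P M`, aromatic
`F W Y`, polar-uncharged `S T C N Q`, positive `K R H`, negative `D E`). The
class table is deliberately a loadable TSV (`read_aa_table()`), not a
constant: alternative groupings drop in without code changes. The
three-outcome rule folds "different class, same polarity" into the residual
−2 case, since only three score levels exist; the polarity flag is retained
in the table for users who want to build finer-grained schemes.

MHC **anchor residues** are buried in the groove and masked from scoring.
Two masking conventions are implemented because the natural-language rule
("positions one and three through eight") and the index range of the score
sum ($\sum_{i=3}^{n} P_i$) disagree for class I peptides:

* `convention = "text"` (default): positions $\{1\} \cup \{3 \dots n-1\}$,
  excluding the P2 and C-terminal anchors. For a 9-mer this is positions
  1, 3–8 — seven scored positions, so $\Sigma P \in [-14, 35]$.
* `convention = "equation"`: positions $\{3 \dots n\}$, the literal sum
  range, which scores the C-terminal anchor and skips position 1.

The text reading is the default because it matches the stated biology
(anchors face the MHC, not the receptor); the convention used is recorded in
every report.

The positional sum is combined with the candidate's predicted binding
affinity $b$ (IC50, nM — lower is stronger) and the maximum expression of
its parent genes across normal tissues $E_{\max}$ (RPKM/FPKM):

$$\mathrm{overall} = \frac{\Sigma P}{b \times E_{\max}} \quad (\texttt{mode = "printed"})$$

Note the direction of the expression term: under this formula high normal
expression *lowers* the risk score, while the intuition behind the method —
a cross-reactive peptide is more dangerous when its source gene is highly
expressed in normal tissue — suggests the opposite. Both orientations are
shipped: `mode = "expression_weighted"` computes $\Sigma P \cdot E_{\max} / b$.
The printed form is the default for fidelity to the published formula, the
mode is always logged in report metadata, and tests cover both.

Two numerical guards: $b \le 0$ is an error, and $E_{\max}$ is floored at a
configurable 0.01 RPKM so unexpressed or unannotated genes cannot produce
infinite scores; under the printed mode the floor preserves the
"unexpressed gene ⇒ very high score" behaviour. Ranking ties are broken
deterministically ($\Sigma P$ descending, then $b$ ascending, then peptide
lexicographically in the C locale), so scans are bit-reproducible under
input permutation. Exact self-matches (the query's own occurrence in the
proteome) are flagged `self`, never removed. Each candidate also carries a
`T`/`F` flag for presence of the exact peptide in the supplied normal-tissue
immunopeptidome.

## The normal-peptidome index

`build_index()` windows a gene-annotated proteome into all substrings of the
query length, merges identical peptides across proteins (gene-set union —
the scan scores peptides, not loci), annotates each with predictions from a
pluggable binding predictor and with $E_{\max}$. Windows containing
non-canonical residues are skipped and counted; predictor failures drop rows
with a count, never silently. $E_{\max}$ is computed as the maximum over
normal tissues of the per-tissue *mean* FPKM (tissue-level summary first,
then the max), with samples mapped to tissues by a `sample, tissue, cohort`
table; the tumour cohort is excluded. At full scale this index is the
~86-million-peptide normal peptidome across 84 HLA allotypes; the package
builds the identical structure at any scale.

Binding prediction itself is out of scope: NetMHC-class engines satisfy the
`function(peptides, allele) -> (ic50, rank)` contract, are run once and
replayed via `cache_predictions()`/`table_predictor()`. The bundled
`toy_predictor()` is a deterministic position-weight scheme (anchor
positions weighted 5×, full weight for the allele's preferred residue, half
for its class) mapped monotonically to IC50 ∈ [1, 50000] nM and percentile
rank ∈ [0, 100]; it exists to make the whole pipeline testable, not to
approximate real affinities.

## The discovery funnel

`run_funnel()` applies three filters in order, and reports per-stage record,
unique-peptide and unique-gene counts:

1. **Binding**: predicted IC50 ≤ 500 nM, boundary inclusive (the
   conventional strong-binder threshold; strictness is not specified in the
   published rule, so the inclusive reading was fixed here).
2. **Differential expression**: the parent gene must be higher in tumour
   than in *every* normal tissue — a conjunction, not a pooled test. Per
   tissue: fold change of mean $\log_2(\mathrm{FPKM}+1)$ ≥ 1 (log2 chosen
   as the field convention for "one log fold"; the base is an argument) AND
   a two-group p-value < 0.01. The test is Mann–Whitney rank-sum by
   default (`wilcox.test`, normal approximation with continuity and tie
   correction, for determinism and speed at GTEx-scale group sizes); Welch's
   t is available. No multiple-testing correction is applied by default
   because the rule is stated on raw p-values; a Benjamini–Hochberg option
   exists. Tissues with fewer than 2 samples are excluded with a warning.
3. **Benign-ligandome exclusion**: a record is dropped if its parent *gene*
   is represented anywhere in the normal-tissue immunopeptidome, even by a
   different peptide. This gene-level rule is deliberately conservative for
   receptor safety (it can discard genuinely tumour-restricted peptides)
   and is labelled as gene-level in the funnel parameters.

`prioritize()` then aggregates survivors to unique peptides and ranks them
by an equally-weighted composite of per-factor z-scores: differential
expression (minimum per-tissue fold change), HLA allele population
frequency, peptide abundance (percentile rank, lower better), binding
affinity (log10 IC50, lower better) and recurrence (distinct tumours
presenting the identical sequence). The published shortlist additionally
involved literature-based biological judgement, which is not implementable;
the composite is therefore decision support with all factor columns emitted
for re-ranking, not a reproduction of any particular shortlist. Missing
factors are imputed to the cohort median and flagged.

Two companion screens support candidate follow-up. `cross_hla_scan()` asks
which other HLA allotypes are predicted to present a candidate (percentile
rank ≤ threshold, default 2%), excluding the discovery allele from the
"additional" set and listing unscorable alleles rather than dropping them.
`match_ms1_features()` checks whether a peptide's theoretical m/z (residue
monoisotopic masses + water, protonated) appears in MS1 feature tables
within a ppm tolerance (default 10) and ±1 min of a reference retention
time; no RT prediction is attempted, and when features carry a charge column
the observed charge is used (restricted to the allowed set) rather than
trying every charge. Modified residues and isotope envelopes are out of
scope — matching is unmodified-monoisotopic only.

## Alanine-scan contact mapping

`contact_residues()` turns alanine-scan binding data into a receptor
contact-residue call: relative binding is the background-subtracted fraction
of wild-type signal (clipped at 0), and positions below a threshold —
default 0.5, i.e. loss of more than half the binding, since no quantitative
cutoff is standard — are called contacts after excluding anchors. The
threshold is a parameter and is printed in every report. Mapping contacts
onto crystal-structure coordinates is visualization and out of scope.

## The synthetic-data generators

Every generator is a pure function of (parameters, seed); a root seed fans
out into independent substreams (`derive_seed()`), so any fixture is
regenerable in isolation and byte-identical across runs. Amino-acid
composition is near-uniform rather than human-like: the tests need coverage
of all five chemical classes more than compositional realism.

What the generators emulate, and what they do not:

* `synth_proteome()` — gene-annotated protein sequences. Real proteomes have
  length and composition biases, homologous families and repeated domains;
  none of that is modelled, so passing tests say nothing about, e.g., scan
  behaviour on paralog-rich gene families.
* `plant_cross_reactor()` — inserts a variant of the query differing at
  chosen positions by same-class or different-class residues. The expected
  positional sum is computed arithmetically from the construction (5/2/−2
  per position), independent of the scoring engine, which is what makes
  planted-recovery tests meaningful. With zero substitutions, minimum IC50
  (override) and floor-level expression, the plant provably dominates the
  printed-mode ranking.
* `synth_expression()` — log2-normal baselines (mean 3, SD 1 in log2 FPKM)
  with SD-1 sample noise; planted genes shifted by `effect_log2` in tumour
  only. The defaults for power analysis are 20 tumour vs 20 samples per
  tissue and a 3-log2 effect. Real GTEx-style data has correlated samples,
  batch structure and heavy tails, none of which is simulated, so the DE
  power estimates are upper bounds for clean effects.
* `make_funnel_fixture()` — the one place determinism is forced onto a
  statistical stage: tumour-specific genes get fully separated expression
  (constant levels with small ordered jitter, no overlap), so the rank-sum
  outcome — hence the per-record stage label — is fixed by construction
  and label-agreement checks are exact rather than probabilistic.
* `synth_ms1_features()` — features at theoretical m/z with *uniform* ppm
  and RT jitter (half-widths as parameters), so the expected recovery
  fraction under a tolerance has the closed form
  $\min(1, \mathrm{tol}/\mathrm{jitter})$, which the tests check against a
  binomial envelope.

## Problem sizes and verification

The test suite verifies the scan against an independently written naive
double-loop reference (its own 20×20 score matrix, base-R ordering) on 50
random indexes of 200–1,200 peptides with both score modes; planted
cross-reactor recovery on 100 seeded builds; funnel-vs-label agreement on
100 random fixtures; DE power (recall ≥ 95% at 3 log2 units, 20 vs 20) and
null false-pass behaviour over 100 simulated cohorts of 30 genes × 3
tissues; exhaustive single-substitution score perturbations (all 20 residues
at every scored and anchor position of a 9-mer); and byte-identity of
repeated CLI runs. These sizes keep the full suite under a minute while
exercising every code path; the same checks hold at larger index sizes, at
proportionally higher cost. `scripts/acceptance.R` recomputes the same
quantities from scratch against the installed package at any seed.

## Known limitations

* Only canonical, unspliced proteome windows are indexed; spliced and
  non-canonical peptides are invisible to the scan.
* No gapped or length-mismatched comparison: a 10-mer mimic of a 9-mer query
  is out of reach by design.
* The similarity score is sequence-only; structural surface similarity
  across different HLA contexts is not modelled.
* Whether deployed cross-reactivity portals use IC50 or percentile rank for
  $b$ is not publicly specified; this implementation takes nM IC50 and
  records units in its reports.
* The benign-ligandome flag and exclusion are only as complete as the
  supplied normal immunopeptidome table; absence of evidence of normal
  presentation is not evidence of absence.
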
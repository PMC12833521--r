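---
title: "Phosphosite-centric co-regulation analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphosite-centric co-regulation analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large compendia of published phosphoproteomic datasets record, for thousands
of proteins, which phosphosites were detected (qualitative *profile*
datasets) and how each site responded to a perturbation relative to control
(quantitative *differential* datasets, with per-site fold changes and
p-values). For a kinase of interest, such a compendium supports three
questions that `phoscoreg` answers in sequence:

1. **Which phosphosite on the protein is predominant?** Sites are ranked by
   detection frequency across profile datasets and by differential-regulation
   frequency across differential datasets.
2. **Which phosphosites in other proteins (PsOPs) are co-regulated with that
   anchor site?** For each candidate site on another protein, the differential
   datasets are cross-tabulated by the joint behaviour of the two sites, and
   a one-sided Fisher's exact test asks whether concordant (or discordant)
   regulation occurs more often than chance given how often each site is
   seen at all.
3. **Does the network around the anchor make biological sense?** Binary
   interactors and known/predicted kinase-substrate relations are overlaid,
   and candidate substrate windows are scanned for the kinase's recognition
   motif — aspartate and proline flanking the S/T acceptor at −1/+1 in
   either order, `D(S/T)P` or `P(S/T)D`.

## Data model and confidence filtering

A catalog is two tables. Observations: one row per (dataset, phosphosite)
with accession, residue (S/T/Y), 1-based position, a ±7 sequence window
(15-mer, `_`-padded at termini), localization evidence, and — in
differential datasets — fold change and p-value. Datasets: id, kind
(PROFILE/DIFFERENTIAL), PubMed ID, experimental-condition code, and
enrichment chemistry (STY/ST/Y).

**Class-1 filter.** An observation is confidently localized when its
localization probability is ≥ 0.75 *or* its A-score exceeds 13. The two
criteria are alternatives (`OR`) because a given source study typically
reports only one of the two scores; an observation carrying neither score is
unclassifiable and is dropped. The filter is monotone in the probability
threshold, which the test suite checks as a property.

**Regulation calls.** In a differential dataset a detected site is called
`UP` when fold change ≥ 1.3 with p < 0.05, `DOWN` when fold change ≤ 0.76
with p < 0.05, and `UNREGULATED` otherwise. Boundaries are implemented
exactly as stated: the fold-change bounds are inclusive, the p-value and
A-score bounds strict. Fold changes are linear-scale; a `log_fc` loader flag
converts log2 input once, at load time. Note 0.76 ≈ 1/1.3, so the rule is
symmetric on the log scale.

**Window validation.** Where reference FASTA sequences are available, each
observation's 15-mer is recomputed from the sequence at the claimed position
and must match exactly (padding included). Mismatching observations are
excluded rather than remapped — isoform remapping is out of scope and
silently "fixing" coordinates would corrupt site identity.

## Predominant-site selection

The strict rule keeps sites detected in more than 50% of profile datasets
*and* regulated in more than 50% of differential datasets. In practice a
frequently studied protein often has exactly one site clearing both bars
while several others are still clearly recurrent; the field's de-facto usage
is rank-based. `predominant_sites()` therefore implements the strict rule
*and* a `top_k` mode (default k = 6, by differential frequency), and always
attaches the full ranked table so the caller sees the evidence either way.
Ties break by profile frequency, then position, for determinism.

## The co-regulation statistic

For an anchor site *c* and a candidate PsOP *o*, every differential dataset
falls in exactly one of nine cells by the pair of calls
(U/D/absent for each site). The 2×2 contingency collapses these to

- `a = n_0c0o` — neither site regulated,
- `b = n_Uc0 + n_Dc0 + n_0Uo + n_0Do` — exactly one site regulated,
- `c = n_UcDo + n_DcUo` — discordant co-regulation,
- `d = n_UcUo + n_DcDo` — concordant co-regulation,

and the one-sided Fisher's exact p-value is the hypergeometric tail
probability of a table at least as extreme in the direction of larger `d`
(positive sign) or larger `c` (negative sign), margins fixed. The
implementation sums `exp(lchoose(...))` point masses over the support
explicitly — deliberately *not* `fisher.test()` — so the tests can verify it
against three independent routes: a brute-force factorial enumeration, the
`phyper` closed form (exhaustively, on all 135,751 tables with total ≤ 40,
to 1e-12), and `fisher.test` on sampled tables.

**Sign and selection.** Each pair is assigned the sign of its larger
directional cell (`d ≥ c` → positive; ties are positive with a flag) and
tested in that direction only. Because the direction is chosen after seeing
the data, the null rate of `p < 0.05` is a union of two tails and can exceed
0.05; discreteness of the exact test pulls it back down. On 1,000 simulated
independent null pairs the realized rate is ≈ 0.05–0.085 depending on seed
(0.064 at the default benchmark seed). This inflation is inherent to the
procedure being reproduced and is documented rather than corrected; a
Benjamini–Hochberg column (`bh_q`) is emitted for transparency but is not
used in filtering, since the procedure applies per-pair p < 0.05.

**Four confidence filters.** A PsOP is high-confidence when (1) p < 0.05;
(2) the ratio `d/c` (positive) or `c/d` (negative) is at least 10% of the
anchor's total differential frequency — a zero denominator yields `Inf`,
which passes any finite threshold; (3) the co-regulated datasets span ≥ 2
distinct PubMed IDs; and (4) ≥ 2 distinct experimental-condition codes. The
ratio rule is the one reading of the stated "10% of the anchor's total
frequency" criterion that yields a concrete monotone threshold; both the
fraction and an absolute override are exposed in `confidence_config()`.

**Unregulated co-detections.** Cells are defined over up/down/absent, so a
detected-but-unregulated observation is treated as absent by default; a
config switch (`unregulated = "detected"`) instead counts such datasets into
`b`. The co-regulation frequency reported per pair is `d` for positive sign
and `c` for negative sign; the table carries all nine cells so the
alternative bookkeeping (`d + c`) can be recovered by the reader.

## Motif scanning

Windows are 15-mers centred on the acceptor. The adjacent-mode match
(default) requires D at −1 and P at +1 (`DSP_TYPE`) or P at −1 and D at +1
(`PSD_TYPE`); the acceptor must be S or T (tyrosine windows never match — the
motif belongs to an S/T kinase). This −1/+1 adjacency is the only reading
consistent with a window centred on the acceptor; a window-wide substring
mode is available behind a flag for the looser interpretation. Under
uniform-random flanks the chance match rate is 2 × (1/20)² = 0.005, which
the generator reproduces and the acceptance suite verifies binomially.

## The synthetic world

The generator emulates the statistical structure the analysis assumes; its
defaults were fixed once, from the stated benchmark conditions and
realistic values, and are not revisited:

| parameter | default | rationale |
|---|---|---|
| differential / profile datasets | 150 / 100 | stated benchmark size |
| PMIDs / experimental codes | 20 / 30 | stated benchmark diversity; round-robin with 20% jitter |
| anchor detection (differential) | 0.55 | a real predominant site is regulated in ~56% of differential datasets |
| anchor detection (profile) | 0.74 | ~74% profile detection for the same site |
| planted partners (+/−) | 30 / 5 | stated benchmark |
| partner concordance | 0.95 | stated benchmark effect size |
| partner detection | 0.6 | recurrent but not ubiquitous sites |
| background site detection | 0.25 | typical sparse coverage of any one site |
| P(regulated \| detected, differential) | 0.9 | differential tables mostly list regulated sites |
| P(Class-1 evidence) | 0.9 | most deposited sites are confidently localized |
| within-protein co-occurrence concordance | 0.9 | matches the ~13/15 positive split seen for a real site pair |
| motif plant rate | 0.5 | roughly half of co-regulated predicted-substrate sites carry the motif |

Draws are hierarchical — detect, then direction, then fold-change magnitude,
then p-value — so each filter is independently exercisable. Regulated events
draw fold changes strictly beyond the thresholds (threshold × e^{|N(0,0.35)|})
with p uniform below 0.049; unregulated detections draw fold changes centred
at 1 with p ≥ 0.05. The combined fold-change distribution therefore
straddles the 1.3/0.76 thresholds while keeping planted ground truth crisp.
A single master seed drives everything through derived sub-seeds;
identical seeds give byte-identical files.

**What a green test does and does not establish.** The generator plants
correlation through a shared anchor trajectory with independent detection —
it does not model mass-spectrometry intensities, missingness that depends on
abundance (missing-not-at-random biology), batch structure within studies,
or correlated detection between interacting proteins. Recovery of planted
partners therefore validates the statistical machinery and its thresholds,
not robustness to those real-data pathologies. At the default world the
pipeline recovers ≥ 90% of planted partners with ~1% null false positives;
because the expected false-positive count is ≈ 1–2 out of 200 nulls, the
realized rate fluctuates between 0.5% and 3% across seeds. The bundled
acceptance checks use the generator's default seed.

## Numerical and degenerate-input choices

- FET p-values are clamped to (0, 1]; an all-zero table is an error
  ("empty contingency"), not p = 1.
- `d = 0` with positive sign gives p = 1 (the tail spans the whole support).
- Pairs never co-called in any dataset are dropped, not reported with
  undefined statistics.
- An anchor with no differential call is an error naming the site.
- Ranking ties and output row orders are fully deterministic so that
  identical inputs give byte-identical outputs; the run manifest records
  config, input MD5 digests, per-stage row counts and version, and reruns
  differ only in the timestamp.

## Known limitations

- Cross-protein co-occurrence is computed only against the anchor; no joint
  modeling across anchors.
- No multiple-testing correction is applied in filtering (by design, to
  reproduce the procedure); `bh_q` is informational.
- Annotation matching assumes gene symbols already harmonized to the
  catalog's accession namespace.
- The post-hoc sign selection inflates the per-pair type-I rate above the
  nominal 0.05 (see above); consumers wanting strict calibration should
  filter on `bh_q` or pre-register the sign.
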
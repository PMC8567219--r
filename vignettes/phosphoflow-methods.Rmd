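---
title: "Methods: ratio normalization, site assembly and proximity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratio normalization, site assembly and proximity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoflow)
```

phosphoflow turns evidence-style peptide quantification tables from SILAC
phosphoproteomics experiments into normalized phosphorylation-site ratios,
fold-change classifications, sequence-motif enrichments, and
proximity-assay statistics. This vignette describes the statistical model
behind each stage, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was open.

## The ratio model

Every evidence row carries a heavy/light SILAC ratio for one peptide
quantification event. On the log2 scale the pipeline models the observed
ratio of a peptide as

$$
r = m + n_P \, c + \beta_{\text{site}} + \varepsilon,
$$

where

* $m$ is a per-(experiment, replicate) **mixing offset** caused by unequal
  amounts of heavy- and light-labeled cells,
* $c$ is a per-proline **conversion factor**: metabolic conversion of heavy
  arginine into heavy proline removes signal from the heavy channel of
  proline-containing peptides, so $c$ is typically negative and scales with
  the number of prolines $n_P$ in the peptide,
* $\beta_{\text{site}}$ is the biological effect of the condition on the
  peptide's phosphosite (0 for unphosphorylated peptides), and
* $\varepsilon$ is measurement noise, taken Normal on the log2 scale
  (lognormal on the ratio scale), the standard error model for SILAC
  ratios.

Orientation precedes everything: ratios are log2-transformed and negated
for replicates whose labels were swapped, so a positive value always means
higher abundance in the perturbed condition.

### Estimating m and c

Both factors are estimated independently per (experiment, replicate)
group, from **unphosphorylated peptides only**, in a fixed order:

1. $\hat m$ = mean oriented log2 ratio of proline-free unphosphorylated
   peptides; it is subtracted from every record of the group.
2. $\hat c$ = mean over the pooled set of (i) residuals of one-proline
   unphosphorylated peptides and (ii) residuals of two-proline
   unphosphorylated peptides divided by two.

Every record, phosphorylated or not, is then corrected as
`oriented − m − n_P · c`. Peptides with three or more prolines never enter
the $\hat c$ estimate (their per-proline information is weaker and they
are rare) but are corrected with their full $n_P \, c$ term.

Two readings of the pooled average are possible: weighting each *record*
equally, or weighting the one- and two-proline *classes* equally. We
average per record — the simplest reading — and note the two agree
whenever the class means agree. By construction the corrected proline-free
unphosphorylated records average exactly 0 in every group, and refitting
on corrected data returns $m = c = 0$; both properties are tested to
1e-12.

For affinity-purification (pull-down) experiments where the bait protein's
abundance itself differs between conditions, `normalize_protein_level()`
additionally subtracts the median corrected log2 ratio of the protein's
unphosphorylated peptides from all of its records. The global datasets are
deliberately *not* protein-level adjusted, since unmodified-peptide data
are not available for every phosphosite.

## Localization filtering and site assembly

Phosphosite localization within a peptide is uncertain; each candidate
residue carries a probability. The **isoform probability** of a record is
the product of the highest individual site probabilities of its assigned
residues; records below 0.70 are discarded. The wording "below 70% ...
discarded" makes the boundary inclusive: exactly 0.70 is retained. When a
record admits several position sets, the highest-probability assignment is
used (mirroring the search engine's best-scoring isoform).

A **phosphorylation site** is the set of phosphorylated residues of a
protein; peptide variants from missed cleavages or secondary modifications
(oxidation, N-terminal acetylation, deamidation) merge into the same site.
Ratios aggregate in two unweighted levels: evidence entries average into a
per-replicate ratio, and replicate ratios average into the final site
ratio. Unweighted means are used at both levels because no replicate- or
evidence-level weights are defined in this design.

**Phosphoislands** are connected components of the graph whose nodes are
phosphopeptides and whose edges join peptides sharing at least one
phosphorylated residue — sequence overlap alone is not an edge. Each
island's **unphosphorylated counter group** (UCG) collects the
unphosphorylated peptides whose interval covers at least one island
position, aggregated with the same two-level mean; an empty UCG is flagged
rather than imputed. Islands are built per run; building them across
experiments is possible by concatenating records first.

## Integration and fold-change classification

Site tables from different experimental setups are outer-joined on site
identity. Missing cells stay missing: with data-dependent acquisition,
absence of quantification is not evidence of absence, so the pipeline
never imputes and instead compares defined groups of sites.

Classification uses a **twofold cutoff** with inclusive bounds: induced
when fold change ≥ 2 (log2 ≥ 1), decreased when ≤ 0.5 (log2 ≤ −1), static
otherwise. Dependency of a site on a kinase or phosphatase is defined as
|log2| ≥ 1 in the corresponding perturbation setup. A site is
Hog1-dependent when it is stress-induced (SR log2 ≥ 1) and reduced at
least twofold by kinase-analog inhibition (log2 ≤ −1).

Within the universe of sites induced both under stress and upon
phosphatase-subunit deletion, the stress response in the
endosulfine-deletion background splits sites into **Set1** (strong loss,
log2 ≤ −1) and **Set2** (moderate loss, −1 < log2 < 0). The Set2 lower
bound is not printed in the source analysis; we take the dependency bound
−1 as the natural split (consistent with the motif-analysis foreground
definition "≥ 2-fold induced and ≤ 0.5-fold with endosulfines deleted"
being the strong set) and expose it as `class_rules(set2_lower = )`.

Enrichment between site sets uses Fisher's exact test. The reported odds
ratio is the sample odds ratio $(a d)/(b c)$ — the quantity conventionally
printed alongside such tests — not the conditional MLE; the p-value is the
exact two-sided hypergeometric value. Distribution shifts between groups
of log2 ratios use the rank-sum (Wilcoxon) test or Welch's t-test.

## Motif enrichment

Windows of 13 residues (±6 around the phosphorylated residue) are
extracted per phosphorylated position, padded with `_` past protein
termini; serine- and threonine-centered windows are analyzed separately.
Extraction is the iterative motif-x procedure: for every (offset, residue)
pair the binomial tail probability of the foreground count given the
background frequency at that offset is computed; the most significant pair
with p ≤ 0.01 whose restricted foreground keeps at least 20 windows is
fixed, pools are restricted, and the step repeats; the finished motif's
matches are removed and extraction restarts. Defaults (min 20 sequences,
p-cutoff 0.01) match the settings of the original analysis. The binomial
approximation with the background frequency as success probability follows
the original algorithm. Ties are broken deterministically by smaller
signed offset, then alphabetical residue. The padding character counts as
an ordinary symbol in background frequencies. Reported scores are the
summed −log10 p over accepted pairs; no multiplicity correction is applied
across motifs.

The threonine-enrichment analysis restricts both pools to S/T-P windows
(proline at +1, the proline-directed kinase motif and preferred
PP2A-Cdc55 context) and tests central T versus S against set membership
with Fisher's exact test.

## M-Track proximity statistics

Each Western blot carries a four-point dilution series of a control
sample, quantified in both the trimethylation readout (me3K9H3) and the HA
loading control. A polynomial in log2 signal versus log2 loading — degree
2 for assay series 1, degree 1 for series 2 — is fitted per blot and
channel with least squares.

The source description states the purpose of the curve ("correct for
unequal loading, normalize between blots") but not the algebra. We invert
the fitted curve, mapping each lane's log2 signal to an **equivalent
loading**; the proximity signal is the me3 equivalent loading minus the HA
equivalent loading. This interpolation reading makes proximity exactly
invariant under common loading changes when both channels' curves share a
degree-1 slope, and recovers planted effects exactly on noise-free data.
Inversion requires monotonicity over the dilution range; a non-monotone
degree-2 fit falls back to degree 1 with a warning.

Proximities are rescaled by subtracting the mean of the negative control
(prey-tagged strain without the methyltransferase fusion), so the control
mean is exactly 0. Each bait with at least 3 replicates is compared
against all control replicates with a one-tailed (greater) Welch t-test; a
variance floor of 1e-8 keeps the statistic defined on degenerate
(zero-variance) inputs. Benjamini–Hochberg q-values are computed over the
bait family of one analysis series — series are never pooled, because the
methylation antibody batches differ between them — and reported in tiers
q < 0.01 and q < 0.05.

## The synthetic-data generator

The generator exists so that every downstream stage is testable against
planted ground truth without any external download. It emulates:

* a random proteome (uniform residue usage, ≥ 2 K/R per protein) digested
  with Trypsin/P specificity and up to 2 missed cleavages;
* evidence rows whose log2 ratio follows exactly the ratio model above,
  with configurable $m$, $c$, per-site per-setup effects, and Normal
  log2 noise;
* label-swapped replicates (the written ratio is negated, and the swap map
  records it);
* localization probabilities drawn so that a configurable fraction of
  phospho rows falls below the 0.70 filter — confident probabilities
  concentrate near 1 via a Beta draw, low-confidence ones are uniform
  below the threshold;
* densitometry tables with planted dilution curves (slope 1, optional
  small quadratic term), per-lane loading variation, per-bait proximity
  effects and a zero-effect negative control.

It does **not** emulate retention-time or intensity structure, spectra,
decoys, contaminants, protein-inference ambiguity beyond razor-protein
rows, correlated (batch) noise, or missingness that depends on abundance.
Passing tests therefore demonstrate the *computational* correctness of the
pipeline under its stated model, not robustness to every artifact of real
evidence tables.

Defaults the source design does not fix are configuration, not claims:
log2 noise SD 0.3, 2–8 replicates per setup (3 in the demo), a 10%
low-localization fraction, and demo effect sizes of ±1.6–2.0 log2 units
placed well clear of the twofold boundary. Densitometry noise is placed on
the me3 channel (SD 0.3 by default in the statistical checks) with the HA
loading control treated as exact, so the planted proximity noise SD equals
the parameter directly; in practice the methylation readout dominates
blot-to-blot variation.

## Numerical choices and degenerate inputs

* Thresholds are inclusive at their printed bounds (fold exactly 2 is
  induced; isoform probability exactly 0.70 is retained).
* A group without proline-free unphosphorylated peptides cannot be
  normalized (hard error); a group without 1–2-proline unphosphorylated
  peptides gets $c = 0$ with a warning.
* A protein without unphosphorylated peptides cannot be protein-level
  centered (hard error).
* Residue letters come from the FASTA when one is supplied; disagreement
  with the peptide sequence, or a non-S/T/Y letter, is a hard error — this
  catches off-by-one coordinate bugs early.
* Motif extraction errors when the background pool becomes smaller than
  the foreground during restriction.
* Fisher's odds ratio is flagged undefined on zero margins and infinite on
  zero off-diagonal cells; the p-value is still exact.
* All simulation entry points take a single integer seed; identical seed
  and configuration give byte-identical outputs, including the written
  tables.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make the statistical guarantees sharp while staying quick
on one CPU: 5,000-record simulations across 200 seeds for
normalization-factor recovery; 100 random instances of up to 30 peptides
against brute-force island and isoform oracles; all 46,371 2×2 tables with
total count ≤ 30 against full hypergeometric enumeration; 50 planted-motif
seeds at the default motif settings; 200 null families and 200
planted-effect families of 10 baits × 4 replicates for the proximity
statistics; and a 220-site planted matrix for classification recovery.

## Known limitations

* The "simple" evidence dialect is the primary interchange format; the
  maxquant-like reader maps the common columns but does not reproduce
  every quirk of real search-engine output (e.g., multi-isoform
  probability strings spanning several proteins).
* Motif significance is reported as raw per-step p-values; no FDR across
  motifs.
* Phosphoislands are built within one run; cross-experiment islands
  require concatenating records first.
* The Welch variance floor (1e-8) makes zero-variance comparisons
  conservative rather than undefined; with real replicate noise it never
  binds.
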
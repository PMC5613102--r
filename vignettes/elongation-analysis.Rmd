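---
title: "Quantifying very long-chain fatty-acid elongation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying very long-chain fatty-acid elongation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elovlkit)
library(dplyr)
```

elovlkit analyzes the heterologous-expression experiments used to
characterize Elovl elongases: yeast expressing a candidate elongase are
grown with a supplemented fatty-acid substrate, total lipids are
transmethylated, and FAME peak areas are read off a GC(-MS) chromatogram.
The package starts where peak integration ends — its raw input is a table
of peak areas per sample — and carries the analysis through to the
publication-style outputs: step-wise conversion tables, VLC-SFA group
comparisons with compact letters, absolute qPCR tissue-expression
summaries, and Elovl motif diagnostics.

## Shorthand nomenclature and elongation cascades

Fatty acids are named in GC shorthand `C:Dn-x` (carbons : double bonds,
n-x series counted from the methyl end), `C:0` for saturates. `parse_fa()`
accepts the printed dialects (`"22:5n-3"`, `"22:5 n-3"`, `"22:5(n-3)"`)
and canonicalizes them; `format_fa()` inverts it exactly. Supported
fatty acids have even chain lengths of 12–40 carbons and up to 6 double
bonds — generous headroom around the C18–C36 range elongase assays
actually produce — and series n-3, n-6, n-9 or saturated. Double-bond
*positions* beyond the series, geometric isomers and odd/branched chains
are out of scope.

Each condensation cycle adds two carbons at the carboxyl end, so the
double-bond count and methyl-end series are invariant:

```{r}
elongate_fa("22:5n-3")
build_cascade("18:4n-3", max_carbons = 36)$fatty_acid
```

A *cascade* is the ordered chain substrate, +2C, +4C, … up to a ceiling.
The default ceiling of C36 matches the longest products seen for PUFA
substrates; assays whose product range demonstrably stops earlier (e.g.
22:6n-3 cascades ending at C32) should pass their observed ceiling. We
treat the ceiling as data-driven — what the chromatogram supports — rather
than a claim about the enzyme's mechanistic limit.

## The step-wise conversion statistic

For cascade areas $A_0, A_1, \dots, A_n$ (substrate at index 0), the
step-$k$ conversion is

$$\mathrm{conv}_k \;=\; 100 \times
  \frac{\sum_{i \ge k} A_i}{A_{k-1} + \sum_{i \ge k} A_i},$$

the fraction of the pool that reached chain length $k-1$ and was elongated
at least once more. The substrate is *redefined at every step*: step 1
measures elongation of the supplemented substrate, step 2 measures
elongation of the first product, and so on.

The statistic has a clean estimand. Under a sequential irreversible model
in which a fraction $e_k$ of the material arriving at node $k-1$ moves on
to node $k$, the terminal amounts are
$A_k = A_0 \prod_{j \le k} e_j \,(1 - e_{k+1})$ (with $e$ past the last
step equal to 0). Both sums telescope:
$\sum_{i \ge k} A_i = A_0 \prod_{j \le k} e_j$, so
$\mathrm{conv}_k = 100\,e_k$ exactly. `simulate_cascade_areas()`
implements exactly this model, which is why the recovery identity is
testable to machine precision:

```{r}
tab <- simulate_cascade_areas("18:4n-3", c(0.5, 0.25), a0 = 100, seed = 1)
tab$area
stepwise_conversions(tab, "18:4n-3", max_carbons = 22)$conversion
```

Because the statistic is a ratio of areas it is invariant to uniform
rescaling — areas are relative quantities, and no response-factor
(mole) correction is applied, matching how such assays are routinely
reported. Conversions are always in $[0, 100]$.

**Detection and edge semantics.** Real tables contain censored entries.
The rules are:

* a step whose substrate *and* entire downstream tail are below the
  detection limit is *not detected* (the denominator is empty) — printed
  `N.D.`;
* a step whose substrate is absent while downstream products are present
  reports 100 — the pool was fully elongated onward.

This is why 100-rows and N.D.-rows can coexist within one cascade. The
detection limit `lod` is configurable and defaults to 0 because
integration thresholds differ per instrument and are rarely reported;
areas strictly below it are zeroed before the statistic. Censoring can
only push a step toward 0, toward 100, or into N.D. — never to a spurious
interior value above its uncensored conversion (a property the test suite
exercises). Endogenous background in control samples is flagged with a
warning but never subtracted: the statistic is reported raw.

When replicate cultures exist, conversions are computed per sample and
averaged by `conversion_table()`; a step is N.D. only if it is N.D. in
every replicate. Computing per replicate (rather than pooling areas) keeps
replicate-to-replicate variation visible.

## VLC-SFA profiles and group comparison

Endogenous saturate elongation is assessed without supplemented substrate
by comparing saturated profiles of control and transgenic yeast.
`sfa_percentages()` expresses each saturate with $\ge$ 24 carbons as a
percentage of the total qualifying saturated area per sample (the
percentages sum to 100 by construction). `compare_groups()` then runs,
per fatty acid, a one-way ANOVA followed by Tukey's HSD at
$\alpha = 0.05$ and renders the pairwise decisions as a compact letter
display using the insert-and-absorb algorithm: start with one letter
covering all groups; for every significantly different pair, split each
letter column containing both members; absorb columns that became subsets.
Groups sharing a letter do not differ (Tukey $p > \alpha$); groups sharing
none do. Letters are assigned in descending order of group mean — purely
presentational, so the largest mean carries "a". The comparison runs on
area percentages, not raw areas, and applies no transformation.

## Absolute qPCR quantification

Tissue expression is quantified absolutely. A linearized plasmid carrying
the amplicon is converted to copies using the double-stranded DNA
convention of 660 g/mol per base pair:

$$\mathrm{copies} = \frac{\mathrm{mass}}{660 \times \mathrm{length}}
  \times N_A, \qquad N_A = 6.02214076 \times 10^{23}.$$

Serial dilutions of known copies give a standard curve
$C_q = b + m \log_{10}(\mathrm{copies})$ fitted per gene by least squares
(`fit_standard_curve()`; cross-gene fits are rejected). A valid assay has
$m < 0$; the amplification efficiency $10^{-1/m} - 1$ equals 1 at the
ideal slope $-1/\log_{10} 2 \approx -3.32$. Quantification inverts the
curve, $\mathrm{copies} = 10^{(C_q - b)/m}$.

Design choices worth stating:

* **Duplicates** are averaged on the $C_q$ scale before quantification.
  Averaging on the copy scale differs by a factor
  $\cosh(\ln 10\,\Delta/2|m|)$ for duplicates $\Delta$ apart — negligible
  for well-behaved duplicates — and the $C_q$ scale is where replicate
  noise is closest to Gaussian.
* **Normalization** divides target copies by reference-gene (28S rRNA)
  copies from the same sample, so constant factors such as the fixed cDNA
  dilution cancel; copies are per reaction, not per µg RNA.
* Reactions where neither duplicate amplified are treated as no-template
  flags and dropped with a warning, never quantified.

`tissue_summary()` reports per-tissue mean ratios ± SE over fish
(`n = 4` by default, sexes pooled with sex retained as metadata) and
reuses the ANOVA + Tukey + letters machinery across tissues.

## Motif diagnostics

Elovl condensing enzymes are recognizable from conserved sequence
features: the histidine box `HXXHH`, the C-terminal di-basic ER retrieval
signal `RXKXX`, and conserved regions `KXXEXXDT`, `QXXFLHXXHH`,
`NXXXHXXMYXYY`, `TXXQXXQ`. `translate_orf()` translates complete ORFs
(triplet length, ATG start, single terminal stop) with the standard code;
ambiguous `N` codons become `X` with a warning rather than an error, so
sequencing ambiguity never silently changes coordinates. `scan_motifs()`
reports every — possibly overlapping — match of X-wildcard patterns in
1-based inclusive coordinates; `X` is the only wildcard (bracket classes
are not needed for this motif family). `check_er_signal()` anchors
`RXKXX` to the carboxyl terminus. The scanner reports hits without
classifying a sequence as Elovl-like: the motif panel is diagnostic, not
a decision rule.

## The synthetic-data generators

Raw chromatograms and plate files from published assays are rarely
available, so every pipeline stage has a generator with known ground
truth; all generators require an explicit seed and are bit-reproducible.

* **Cascade areas** follow the sequential irreversible steady-state model
  above. A kinetic ODE model would add rate constants that end-point
  areas after a two-day culture cannot identify; terminal partitioning is
  the most parsimonious model for which the conversion statistic is a
  consistent estimator. Noise is multiplicative lognormal
  (median-unbiased, `sdlog = noise_sigma`) because chromatographic areas
  are positive with roughly constant CV; a detection limit then zeroes
  sub-threshold areas.
* **SFA profiles** scatter control replicates around a baseline profile
  (defaults follow a typical yeast VLC-SFA profile dominated by 26:0)
  and multiply chosen saturates by boost factors in transgenic groups,
  with lognormal replicate noise at CV 0.05 and 4 cultures per group.
* **qPCR** computes dilution-series $C_q$ exactly from each gene's true
  curve and draws per-fish duplicate $C_q$ values with Gaussian noise
  (sd 0.2 — a typical inter-replicate spread — around the curve value at
  the tissue's true copy number), 4 fish per tissue.

What the generators deliberately do *not* emulate: FAME response factors
varying with chain length, β-oxidation/chain-shortening fluxes, substrate
competition between cascades, yeast growth dynamics, pipetting-level
correlation between duplicates, and biological between-fish variance
beyond measurement noise. Passing recovery tests therefore demonstrates
that the estimators are correct for the measurement model they assume,
not that real chromatography or plates are this well behaved.

## Verification performed by the package

The test suite and `scripts/acceptance.R` recompute, from scratch:

* exact recovery of generating step fractions from 500 random noiseless
  cascades (lengths 2–10), to $10^{-10}$;
* per-step mean absolute conversion error under 5% area noise across 200
  simulated cascades (stays below 2 percentage points on a 9-step
  cascade);
* ORF length arithmetic (945 bp → 314 aa, 915 bp → 304 aa) on synthetic
  ORFs of those lengths;
* a noiseless qPCR round trip (relative error $\approx 10^{-15}$) and a
  calibration study: with $C_q$ noise 0.2 and 4 fish, recovered tissue
  means fall within 3 SE of truth in well over 95% of 500 replicates.
  Coverage is measured against the estimator's sampling SE (its sd across
  the 500 replicates): with only 4 fish, a per-replicate estimated SE
  would turn a 3-SE statement into a 3-df $t$ statement with ~94%
  nominal coverage, conflating small-sample $t$ behaviour with pipeline
  miscalibration;
* agreement of compact letters with the pairwise Tukey decisions on 100
  random datasets, and exact mass conservation of SFA percentages;
* equality of the motif scanner with an exhaustive-window comparator on
  1000 random proteins.

These problem sizes are the package's chosen verification scale; all run
in well under a minute each on a single core.

## Known limitations

The conversion statistic inherits the assumptions of its model:
irreversible forward elongation only, no parallel consumption of cascade
intermediates, raw (not mole-corrected) areas. The N.D. rule cannot
distinguish "no enzymatic activity" from "activity below the detection
limit". Tukey's HSD assumes approximately normal within-group errors and
homoscedasticity; with 3–4 replicates these are untestable, which is the
standard situation for such assays, not a defect specific to this
implementation.
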
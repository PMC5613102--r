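# elovlkit

Analytics for functional characterization of **Elovl fatty-acid
elongases** — the ER-membrane condensing enzymes that extend very
long-chain (>C24) saturated and polyunsaturated fatty acids. The package
is aimed at lipid biochemists running yeast heterologous-expression
assays (and the qPCR tissue surveys that accompany them) who need to get
from integrated GC peak areas and Cq exports to publication-grade tables
and statistics.

Everything is tidyverse-native: functions take a data frame first and
return tibbles, fitted objects support `tidy()` / `glance()` /
`autoplot()`, and results chain with the pipe.

## What it computes

**Step-wise elongation conversions.** For an elongation cascade
A₀ → A₁ → … → Aₙ of +2C products of a supplemented substrate, the step-k
conversion from FAME peak areas is

```
conv_k = 100 × Σ_{i≥k} A_i / (A_{k−1} + Σ_{i≥k} A_i)
```

with the substrate redefined at every step. Steps with no detectable
substrate or products are `N.D.`; an absent substrate with detected
products is 100%. Under the package's sequential-elongation generative
model this statistic recovers the true per-step conversion fraction
exactly (see the methods vignette for the telescoping argument).

**VLC-SFA profiles.** Saturates ≥C24 as area percentages of the total
qualifying saturated area, compared across control/transgenic groups with
one-way ANOVA + Tukey HSD and compact letter displays (insert-and-absorb).

**Absolute qPCR quantification.** Plasmid copies via the 660 g/mol·bp
convention, per-gene standard curves `Cq = b + m·log10(copies)`,
amplification efficiency `10^(−1/m) − 1`, duplicate averaging on the Cq
scale, reference-gene (28S rRNA) normalization, and per-tissue mean ± SE
summaries with Tukey letters.

**Elovl motif diagnostics.** ORF translation (standard code) and
X-wildcard scanning for the family's signature motifs — the histidine box
`HXXHH`, `KXXEXXDT`, `QXXFLHXXHH`, `NXXXHXXMYXYY`, `TXXQXXQ` — plus the
C-terminal ER retrieval signal `RXKXX`.

**Synthetic data with known truth** for every stage
(`simulate_cascade_areas()`, `simulate_sfa_profiles()`,
`simulate_qpcr()`), so the whole pipeline is verifiable end to end
without access to raw instrument files.

## Worked example

Simulate three replicate cultures of an `elovl4a`-expressing yeast fed
22:5n-3, with known per-step conversion fractions and 5% area noise, and
recover the conversion table:

```r
library(elovlkit)
library(dplyr)

tab <- simulate_cascade_areas(
  "22:5n-3", step_fractions = c(0.14, 0.51, 0.83, 0.98, 0.96, 0.90, 0.34),
  noise_sigma = 0.05, seed = 7, n_samples = 3, treatment = "elovl4a"
)
conv <- stepwise_conversions(tab, "22:5n-3", max_carbons = 36)
conversion_table(conv)
#> # A tibble: 7 × 8
#>   treatment  step substrate product elongation     n not_detected conversion
#>   <chr>     <int> <chr>     <chr>   <chr>      <int> <lgl>             <dbl>
#> 1 elovl4a       1 22:5n-3   24:5n-3 C22 → 36       3 FALSE              14.0
#> 2 elovl4a       2 24:5n-3   26:5n-3 C24 → 36       3 FALSE              51.4
#> 3 elovl4a       3 26:5n-3   28:5n-3 C26 → 36       3 FALSE              83.6
#> 4 elovl4a       4 28:5n-3   30:5n-3 C28 → 36       3 FALSE              98.0
#> 5 elovl4a       5 30:5n-3   32:5n-3 C30 → 36       3 FALSE              96.0
#> 6 elovl4a       6 32:5n-3   34:5n-3 C32 → 36       3 FALSE              90.3
#> 7 elovl4a       7 34:5n-3   36:5n-3 C34 → 36       3 FALSE              32.2
```

Each row is one +2C step: 14.0% of the supplemented 22:5n-3 pool was
elongated at least once (truth: 14%), 51.4% of the resulting 24:5n-3
pool was elongated further (truth: 51%), and so on — the estimates sit
within noise of the generating fractions. `write_conversion_table()`
renders the same table with one-decimal conversions and `N.D.` entries.

A matching qPCR tissue survey (two genes, three tissues, 4 fish, Cq
noise 0.2):

```r
curves <- tibble(gene = c("elovl4a", "28S"),
                 slope = c(-3.4, -3.2), intercept = c(37, 30))
truth <- tidyr::expand_grid(tissue = c("pituitary", "brain", "liver"),
                            gene = c("elovl4a", "28S")) |>
  mutate(copies = ifelse(gene == "28S", 4e7,
                         c(2e5, 1e5, 5e2)[match(tissue, c("pituitary", "brain", "liver"))]))
sim <- simulate_qpcr(curves, truth, cq_sd = 0.2, n_fish = 4, seed = 11)

glance(fit_standard_curve(filter(sim$dilutions, gene == "elovl4a")))
#> # A tibble: 1 × 6
#>   gene    slope intercept r_squared efficiency n_points
#>   <chr>   <dbl>     <dbl>     <dbl>      <dbl>    <int>
#> 1 elovl4a  -3.4        37         1      0.968        7

ratios <- qpcr_quantify(sim$measurements, sim$dilutions, reference = "28S")
tidy(tissue_summary(ratios))
#> # A tibble: 3 × 6
#>   gene    group         n      mean         se letters
#>   <chr>   <chr>     <int>     <dbl>      <dbl> <chr>  
#> 1 elovl4a pituitary     4 0.00531   0.000323   a      
#> 2 elovl4a brain         4 0.00257   0.000246   b      
#> 3 elovl4a liver         4 0.0000128 0.00000119 c
```

The recovered normalized ratios track the simulated truth (pituitary
2e5/4e7 = 5e-3, brain 2.5e-3, liver 1.25e-5), and the three tissues are
statistically separable, each carrying its own letter. `autoplot()` on
either result draws the corresponding figure.

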
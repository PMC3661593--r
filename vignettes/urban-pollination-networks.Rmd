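---
title: "Methods: quantitative pollination webs along an urbanisation gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative pollination webs along an urbanisation gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollweb)
```

## The analysis pollweb implements

`pollweb` analyses flower-visitation field data collected on replicated
experimental plant communities placed along an urbanisation gradient. The
design it targets has four landscape contexts (semi-natural, agricultural,
suburban, urban), three sites per context, and at each site four plots (two
per plant spatial configuration, systematic or random) observed in four
rounds of 10-minute sessions. Each observation cell is a count of visits by
one insect morphotype (a morphological functional group; nine are
distinguished, from bumblebees to Heteroptera "bugs") on one of five plant
species. The five plants split into two floral functional groups: *tubular*
flowers (*L. corniculatus*, *M. sativa*, *C. regalis*), whose rewards are
hidden from short-mouthpart visitors, and *open* flowers (*M. inodora*,
*S. arvensis*) with accessible rewards.

Visits are cumulated over rounds, and over the two plots sharing a spatial
configuration, into one quantitative bipartite web per site and
configuration — a plant x morphotype count matrix `A` in which `A[i, j]` is
the number of visits of morphotype `j` on plant `i`. The full design yields
24 webs. Cumulation over rounds removes the effect of asynchronous flowering
between species; pooling the two like-configured plots reflects that they are
replicates of one treatment within a site.

## Indices

**Interaction evenness.** With `p_ij = A_ij / total` computed over the `L`
*realised* links only (zero cells are excluded by construction, with
`0·log 0 := 0`), evenness is `H / ln L` where `H = -sum p_ij ln p_ij`. It is
1 exactly when visits are spread uniformly over realised links. For `L <= 1`
the normaliser `ln L` vanishes and the index is undefined; `pollweb` raises
an error rather than imposing a convention (the per-web summary table reports
`NA` there). Natural logarithms are used throughout; the normalised evenness
is base-invariant.

**Generalism.** Qualitative generalism of a morphotype is its degree — the
number of plant species it visits. Weighted generalism is the Shannon index
(in nats) of its visit distribution over plants, `-sum_f P(p,f) ln P(p,f)`
with `P(p,f) = A[f,p] / V_p`: 0 for a perfect specialist, `ln k` for a
uniform k-plant visitor, and always at most `ln(degree)`. Both are undefined
for a morphotype with zero visits in a web; such morphotypes are excluded
from per-web generalism tables with a message. Because raw Shannon values
depend on the logarithm base, cross-study numerical comparison of weighted
generalism should only be attempted when the base is known to match; all
within-package comparisons are internally consistent.

**Reproductive-success index.** Conspecific pollen transfer requires flower
constancy — consecutive visits to the same plant species. Treating each
morphotype's plant choices as independent draws from `P(p, .)`, the
probability of an immediate same-plant repeat on plant `f` is `P(p,f)^2`, and
scaling by the morphotype's observed visit total `V_p` estimates its number
of potentially pollinating events. Per plant:

```
R_f = sum over morphotypes p with V_p > 0 of P(p,f)^2 * V_p
    = sum_p A[f,p]^2 / V_p
```

and per floral functional group the sum of its members' `R_f`. Zero-visit
morphotypes contribute exactly 0 (rather than erroring), keeping sparse urban
webs computable. Useful identities, all tested: a perfect specialist on `f`
contributes its whole `V_p` (`R = V`); each morphotype's total contribution
is at most `V_p` (Cauchy–Schwarz), with equality only for specialists; and
for `N` i.i.d. choices the sequential expectation `(N-1)·sum P^2` and the
index's `N·sum P^2` agree relatively as `N` grows. The index is computed per
cumulated web (site x configuration) and then compared across landscape
contexts; computing it on context-pooled webs instead would weight sites by
their visit totals, which the per-web choice deliberately avoids. No
within-sequence autocorrelation is modelled: the index is a proxy for
potential, not measured, reproduction, and should be validated against fruit
or seed set before being interpreted quantitatively.

## Statistics

* **Pearson chi-squared homogeneity tests** on plant x landscape-context
  visit tables, one per morphotype (`sum (O-E)^2/E`, `df = (r-1)(c-1)`,
  asymptotic p, no continuity correction). A full 5-plant x 4-context table
  has `df = 12`; all-zero rows/columns of rare morphotypes are dropped before
  testing, and degenerate tables are skipped with a message.
* **Spatial autocorrelation**: Bray-Curtis similarity
  (`1 - sum|u-v| / sum(u+v)`) on raw per-site morphotype visit totals
  (per-morphotype totals rather than the 45 plant x morphotype cells — the
  coarser vector is the community composition the similarity is meant to
  capture; the cell-level alternative is available by passing your own matrix
  to `bray_curtis_matrix()`), turned into a dissimilarity matrix and tested
  against geographic distance with a **Mantel permutation test**. The
  correlation flavour is Pearson on upper triangles (Spearman available via
  an argument), the test is two-sided on `|r|` — both choices documented
  because the convention is not universal — and the p-value uses the
  `(1 + hits) / (1 + n_perm)` convention so it can never be 0. For designs
  small enough that `n! - 1 <= n_perm`, all `n!` relabellings are enumerated
  and the p-value is exact.
* **Context comparisons.** Field analyses of such designs typically use
  mixed models with site and configuration random effects. `pollweb`
  deliberately does not reimplement that machinery; instead
  `permutation_context_compare()` provides a clearly labelled *permutation
  surrogate*: for each context pair, the difference of means under random
  relabelling of per-web values, exact (all `choose(n, n1)` relabellings)
  when that is cheaper than the permutation budget. It ignores the site
  random effect, so its p-values are not the mixed-model p-values and every
  output row says so in its `method` field.

## The synthetic-data generator

No visitation dataset ships with the package, so `default_presets()` +
`generate_study()` produce one with the statistical structure the analysis
assumes, making every pipeline stage testable end to end:

* **Visit rates** per 10-minute session are Poisson with per-context means of
  16.10, 12.73, 4.08 and 4.23 visits/min (semi-natural, agricultural,
  suburban, urban) — the field means for this design — times 10 minutes.
* **Morphotype mix**: each visit is assigned a morphotype with probabilities
  proportional to the study-wide interaction shares of the nine groups
  (bumblebees 31.1%, solitary bees 28.2%, Syrphidae 27%, ...). The mix is
  held constant across contexts: per-context group compositions are not
  published as a table, so the presets are calibrated to the overall shares
  only and documented as illustrative.
* **Plant choice**: each morphotype has a baseline preference row over the
  five plants, with at least 70% of mass on tubular plants for long-mouthpart
  groups (bumblebees, Lepidoptera) and at least 70% on open flowers for
  short-mouthpart groups (solitary bees, Coleoptera, Syrphidae, other flies,
  bugs), honey bees being intermediate generalists. Site-level realised
  preferences are drawn once per site from a Dirichlet whose mean is the
  baseline row *tempered* by the sharpness parameter `kappa`:
  `m(kappa) ∝ base^(kappa/(1+kappa))`, with concentration `tau0 + kappa`
  (`tau0 = 200` supplies realistic between-site replication noise). Small
  `kappa` flattens choices towards uniform — more generalism — while
  `kappa → ∞` converges on the baseline row, so measured weighted generalism
  approaches the Shannon index of the baseline. This parameterisation was
  chosen over a plain `Dirichlet(kappa · base)` because the latter couples
  sharpness to noise in the wrong direction: its low-`kappa` draws are
  *spikier*, not flatter, and could not express the urban generalism
  increase. In the default presets `kappa` falls from 30 (semi-natural,
  agricultural) through 8 (suburban) to 3 (urban) for short-mouthpart groups
  and stays at 30 for the rest.
* **Seeding**: one root seed governs everything; each site's stream derives
  from `(seed + 7919 * site_index) mod (2^31 - 1)`, so single sites can be
  regenerated in isolation and identical configurations are byte-identical.
* **Geography**: sites sit on a shuffled 1-km grid, so landscape context is
  not spatially clustered and the Mantel test is a true null on default data.

What the generator does *not* emulate: temporal flower constancy
(within-sequence autocorrelation of plant choices — deliberately, because the
reproductive-success index approximates exactly that, and simulating it would
make the index's recovery test circular), weather and flowering-phenology
covariates, plot-level heterogeneity beyond Poisson noise, and context
differences in morphotype composition. Tests passing on synthetic data
therefore validate the arithmetic and the direction of built-in effects, not
the field realism of any particular magnitude.

## Numerical and design choices

* Evenness on single-link webs: error, not 0 or 1 (no defensible convention;
  summaries show `NA`).
* `0 · log 0 := 0` wherever Shannon sums appear, matching the exclusion of
  absent links.
* Permutation p-values: `+1` correction in numerator and denominator for
  Monte-Carlo tests; exact enumeration (identity included, minimum p
  `2/choose(n, n1)` two-sided for balanced groups) whenever the full
  relabelling set fits the permutation budget.
* Matrix label order is fixed by the canonical community lists, so webs from
  the same study align and all outputs are deterministic; labels outside the
  canonical sets are accepted, appended after the canonical ones, and
  reported via messages rather than errors (numeric fields are validated
  strictly).
* Flowering quality (the 0–6 per-species indicator) is parsed, validated and
  carried through, but used in no computation: its analytical role belongs to
  the mixed-model layer that is out of scope here.
* Test problem sizes: the simulation-backed properties use 100 seeded studies
  for the effect-direction checks, 20 seeds per sharpness value for the
  generalism recovery, and 500 replicates for the chi-squared and Mantel
  calibrations — enough for the binomial/simulation error of each check to
  sit well inside its tolerance.

## A worked example

```{r example}
study <- generate_study(default_presets(seed = 1))
webs <- build_all_networks(study$records, study$sites)
length(webs)

summ <- do.call(rbind, lapply(webs, network_summary))
summarize_by_context(summ, "total_interactions")

M <- webs[["SN1:systematic"]]
interaction_evenness(M)
weighted_generalism(M, "Syrphidae")
rs_report(M)$per_group
```

## Known limitations

* The reproductive-success index assumes i.i.d. plant choices; real foraging
  sequences are autocorrelated, so the index is a lower-variance proxy, not
  an estimate of realised constancy.
* The permutation context comparison ignores the site random effect and will
  be anti-conservative when sites differ strongly within contexts; it is a
  screening surrogate, not a replacement for mixed models.
* Generator presets are calibrated to study-wide totals and qualitative
  gradient patterns only; per-context morphotype mixes are illustrative.
* Weighted generalism values are in nats and not comparable to figures
  computed in other logarithm bases.
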
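# pollweb

Quantitative plant–pollinator network analysis for urbanisation-gradient
field experiments.

`pollweb` is for ecologists who record flower visitation on replicated
experimental plant communities — here, five plant species spanning two floral
functional groups ("open" vs "tubular" corollas), visited by insects scored
into nine morphotypes — across a gradient of landscape contexts
(semi-natural, agricultural, suburban, urban). From tabular visitation
records it:

* cumulates visits into one quantitative bipartite web per site and plot
  spatial configuration (a plant × morphotype count matrix *A*, where
  *A(i, j)* is the number of visits of morphotype *j* on plant *i*);
* computes network and morphotype indices: total interactions, realised link
  count, **interaction evenness** *H*/ln *L* over realised links only
  (*H* = −Σ *p*ᵢⱼ ln *p*ᵢⱼ, *L* = number of nonzero cells), qualitative
  generalism (degree) and Shannon-**weighted generalism** of each visitor
  group;
* computes a flower-constancy based **reproductive-success index** per plant
  and floral group,
  *R_f* = Σₚ *P*(p, f)² · *V*ₚ = Σₚ *A*(f, p)²/*V*ₚ,
  the expected number of visits preceded by a visit to the same plant species
  (the visits most likely to deliver conspecific pollen);
* runs the supporting statistics: per-morphotype plant × context Pearson
  chi-squared homogeneity tests, Bray–Curtis similarity and a Mantel
  permutation test for spatial autocorrelation, and permutation comparisons
  of per-web metrics between landscape contexts;
* ships a calibrated synthetic visitation generator
  (`default_presets()` / `generate_study()`) so the entire pipeline is
  testable without field data.

## Worked example

```r
library(pollweb)

study <- generate_study(default_presets(seed = 1))
webs  <- build_all_networks(study$records, study$sites)
length(webs)
#> [1] 24

summ <- do.call(rbind, lapply(webs, network_summary))
summarize_by_context(summ, "total_interactions")
#>   landscape_context             metric     mean       sd n
#> 1      semi-natural total_interactions 1288.667 24.06380 6
#> 2      agricultural total_interactions 1024.833 40.86767 6
#> 3          suburban total_interactions  334.500 15.29379 6
#> 4             urban total_interactions  344.500 23.03693 6

M <- webs[["SN1:systematic"]]
interaction_evenness(M)
#> [1] 0.7950337
weighted_generalism(M, "Syrphidae")
#> [1] 1.278117
rs_report(M)$per_group
#>  tubular     open
#> 142.3645 272.4186
```

Each web carries on average visit-rate × 10 min × 4 rounds × 2 plots
interactions, so semi-natural webs (~1289) dwarf urban ones (~345); evenness
is the uniformity of visit spread over that web's 33 realised links; the
Syrphidae Shannon value of 1.28 nats sits between a specialist (0) and a
uniform five-plant generalist (ln 5 ≈ 1.61); and the reproductive-success
sums say most potentially pollinating (same-plant-in-a-row) visits at this
semi-natural site accrue to the open-flower group.

A packaged fixture holds the nine study-wide morphotype interaction totals:

```r
f <- system.file("extdata", "overall_morphotype_totals.csv", package = "pollweb")
recs <- read_visitation_table(f)
sum(recs$visit_count)
#> [1] 17857
```

A thin command-line front end over the same functions lives at
`inst/cli/pollweb.R` (subcommands `generate`, `analyze`, `fixture`).

## Documentation

The methods vignette (`vignettes/urban-pollination-networks.Rmd`) documents
the model, every index, the permutation conventions, the synthetic
generator's assumptions and the package's known limitations.
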
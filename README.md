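# magbias

Incomplete metagenome-assembled genomes (MAGs) systematically underestimate
the metabolic capabilities of the organisms they represent: when a bin misses
part of a chromosome, genes vanish at random with respect to function, and
the *fullness* of metabolic modules — the proportion of a module's enzymatic
steps enabled by the genes present — drops with genome completeness. If the
bias is ignored, artifactual functional deficits are easily mistaken for
biology. `magbias` is for microbiome researchers who infer function from
MAGs and want to quantify, visualise and correct this completeness bias.

## The model

For genome *g* (phylum *p*, completeness *c* as a proportion) and module *m*
with *S* steps, the satisfied-step count is modelled per module with a
weighted binomial GLM (logit link, step count as weights):

```
k ~ Binomial(S, invlogit(alpha_mp + beta_mp * c))        fullness f = k / S
```

so each module gets a phylum-specific completeness slope `beta_mp`. Modules
present in fewer than `floor(0.05 * n_genomes)` genomes are excluded. The
slopes are then meta-analysed with a linear mixed model,

```
beta_mp ~ phylum + domain + S + (1 | module)
```

fitted by REML (lme4), with percentile confidence intervals from a
999-simulation parametric bootstrap. Finally, an incomplete genome's profile
is corrected module-by-module by adding the model-predicted fullness deficit,

```
f* = clamp(f + invlogit(a + b) - invlogit(a + b*c), 0, 1)
```

and the correction is validated by contig-subsampling complete genomes at
70/80/90% retention (10 replicates each; 240 subsamples for 8 genomes),
re-estimating completeness from single-copy core genes, and comparing raw
vs. corrected profiles to the complete genomes in a joint PCoA.

A synthetic-data module generates KEGG-like module catalogs, complete
genomes, mechanistic incompleteness (random contig dropout) and parametric
cohorts drawn from a known logit-linear model, so every stage is testable
against ground truth.

## Worked example

```r
library(magbias)
library(dplyr)

catalog <- simulate_catalog(n_modules = 60, seed = 1)
model   <- default_parametric_model(catalog, seed = 2)
cohort  <- simulate_parametric_fullness(model, n_genomes = 1000, seed = 3) |>
  filter_modules(min_prevalence = 0.05)

fits <- fit_module_glms(cohort)
glance(fits)
#> # A tibble: 1 × 4
#>   n_modules n_phyla n_converged prop_positive_slope
#>       <int>   <int>       <int>               <dbl>
#> 1        60       4          60                   1

fullness_change(fits) |>
  summarise(mean_pp = mean(change_pp), sd_pp = sd(change_pp))
#> # A tibble: 1 × 2
#>   mean_pp sd_pp
#>     <dbl> <dbl>
#> 1    14.0  7.77
```

Every fitted module shows a positive fullness-completeness slope, and raising
completeness from 70% to 100% is predicted to add on average 14 percentage
points of module fullness (s.d. 7.8 across module-phylum pairs). The slope
meta-analysis with bootstrap intervals:

```r
slopes <- extract_slopes(fits, catalog)
meta   <- fit_slope_lmm(slopes)
cis    <- bootstrap_slope_cis(meta, n_sim = 199, seed = 4)
marginal_predictions(meta, "phylum")
#> # A tibble: 4 × 2
#>   level            predicted
#>   <chr>                <dbl>
#> 1 Proteobacteria        3.69
#> 2 Firmicutes            3.63
#> 3 Actinobacteriota      3.07
#> 4 Bacteroidota          2.71
```

Proteobacteria show the steepest fullness-completeness relationship and
Bacteroidota the shallowest, matching how this cohort was generated.
`evaluate_hypotheses(cis)` turns the intervals into overlap verdicts, and
`correct_profile()` / `run_validation()` apply and benchmark the correction
(see the methods vignette in `vignettes/completeness-bias.Rmd`).

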
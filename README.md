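# allelometa

Phylogenetic Bayesian meta-analysis of grass allelopathy experiments.

Allelopathy studies expose a recipient plant to material from a potentially
allelopathic grass and report control/treatment group summaries (means,
SDs or SEs, sample sizes) for germination or growth. `allelometa` is for
ecologists compiling such studies who want to test the classic
invasion-biology hypotheses on the pooled evidence:

* **Novel Weapons** — non-native grasses suppress native recipients more
  than native grasses do;
* **Biotic Resistance** — native grasses suppress non-native recipients
  more than native recipients;
* **Phylogenetic Distance** — allelopathic impact grows with the
  evolutionary distance between grass and recipient.

## The model

Each control/treatment pair becomes a small-sample-corrected ("delta") log
response ratio

$$d = \ln\frac{\bar m_T}{\bar m_C} + \frac12\Big[\tfrac{s_T^2}{n_T \bar m_T^2} - \tfrac{s_C^2}{n_C \bar m_C^2}\Big],$$

with its second-order sampling variance, screened by the Geary criterion
$(\bar m/s)\sqrt{n} \ge 3$ (a pair is dropped only when **both** groups
fail). Missing doses are completed by predictive-mean-matching multiple
imputation (m = 25, median-aggregated). Effect sizes are then modelled as

$$y_i \sim \mathrm{Student}\text{-}t\big(\nu,\ \mu_i,\ \sqrt{\sigma^2 + se_i^2}\big), \qquad \mu_i = \text{study}_i + \text{species}_i,$$

where the *study* component carries random effects for study, nested
sub-study and trait, method, nested duration, and dose category, and the
*species* component carries grass/recipient origin fixed effects, a
penalized smooth of log-scaled patristic distance (its linear coefficient
is the Phylogenetic Distance test), plain species random effects, and
tree-linked species effects with covariance $\tau^2 A$ built from the
phylogeny. Posterior contrasts, variance decomposition, PSIS-LOO/WAIC
comparison against an intercept-only model, Egger and publication-year
bias diagnostics, and an a-priori random-effects power calculator complete
the pipeline. See `vignette("allelometa-methods")` for every modelling
choice and caveat.

## Worked example

Real compiled data enter through `read_study_table()` (CSV/TSV, one row
per comparison) plus a user-supplied Newick tree. The bundled generator
produces a realistic stand-in with known truth, so the example is fully
reproducible:

```r
library(allelometa)

cfg <- synthetic_config(seed = 42)       # 23 studies, ~500 comparisons
sim <- simulate_dataset(cfg)
rep <- run_all(run_config(input = sim$records, tree = sim$tree,
                          seed = 1, chains = 2, iter = 1500, warmup = 750,
                          run_year_trend = FALSE))
print(rep)
```

```
Allelopathy meta-analysis run
  records: 465 in = 464 analyzed + 1 Geary-dropped + 0 rejected
  dose imputed for 120 records (26%)
  component intercepts (intercept model):
             mean   2.5% 97.5%
b0_study   -0.160 -1.582 1.252
b0_species -0.185 -1.555 1.255
b0_sum     -0.345 -0.728 0.054
  hypotheses (full model):
                             name     estimate     ci_low    ci_high supported
         Novel Weapons Hypothesis  0.061772796 -0.2134410 0.34787020     FALSE
     Biotic Resistance Hypothesis  0.001782623 -0.2373939 0.25298486     FALSE
 Phylogenetic Distance Hypothesis -0.085360468 -0.2304693 0.06683533     FALSE
  a-priori power: 86% (k = 23)
```

Reading the output: the run's bookkeeping always balances (465 = 464 + 1
+ 0); 26% of records had their dose imputed. Only the *sum* of the two
component intercepts is identified by data — here −0.35 with a 95%
interval just reaching 0, i.e. an overall suppressive tendency (a `d` of
−0.35 is a 30% suppression via `percent_change()`) — while the wide
intervals on the individual intercepts show their prior-dependence. The
hypothesis contrasts are species-level quantities: with only ~15 grass
species in the pool, their intervals are wide, and in this particular
draw the Novel Weapons estimate lands on the wrong side of zero while its
interval comfortably covers the generating value (−0.14). That is the
honest behaviour of a species-level contrast at this scale, and it is why
the package ships `recovery_experiment()`, which confirms nominal
interval coverage over replicated datasets.

The same report also carries `rep$decomposition` (variance shares per
random-effect factor), `rep$comparison` (elpd differences full vs
intercept: here LOO +5.2 ± 2.5 in favour of the full model),
`rep$egger` (funnel-asymmetry intercept 0.015, 95% CI [−0.031, 0.061]:
no bias signal, as expected for the generator), and `rep$power`.

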
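# sharknet

Movement networks and ontogenetic space use from passive acoustic
telemetry.

`sharknet` is for movement ecologists working with array-based acoustic
telemetry of large mobile fishes — the kind of study in which a few dozen
tiger sharks carry coded transmitters past two island receiver arrays for
several years. It turns raw detection exports into quality-controlled
residency statistics, growth-corrected life stages, and per-individual
movement networks, and then asks the ontogenetic question: how does
motility scale with body size, and differently between the sexes?

## The core quantities

With receivers as nodes and subsequent detections of a shark at two
different stations as directed edges, each individual's space use within an
array reduces to two densities on [0, 1]:

- **node density** = |stations visited| / |stations active during the
  shark's monitoring window|,
- **edge density** = |distinct ordered station pairs traversed| /
  n(n − 1), the fraction of possible movements realized ("motility").

Alongside: residency index RI = detection days / monitoring period; station
residency (consecutive detection days at a station before detection
elsewhere or a > 24 h absence); occupancy (group-mean total detection
days); degree and unnormalized Brandes betweenness per station, tested
against directed Erdős–Rényi G(n, m) nulls with a one-sample Wilcoxon
signed-rank test.

Because sharks grow between tagging and detection, fork length at first
detection is integrated from a piecewise size-class growth schedule
(4–40 cm FL yr⁻¹) and life stage — YOY < 110 cm FL, juvenile < 180,
sub-adult ≥ 180, adult > 255 (M) / > 265 (F) — is re-assigned at detection.
Motility is then modelled against fork length, sex and island with a
nine-model candidate set of penalized-spline GAMs (`mgcv`), compared by AIC
with Akaike weights; among models within ΔAIC < 2 the default rule selects
the highest percent deviance explained.

A synthetic telemetry generator (continuous-time Markov movement over the
stations with a known, sex-specific motility-versus-length effect,
imperfect detection and injected false detections) makes the entire chain
testable end to end with no field data.

## Worked example

```r
library(sharknet)

# growth-correct the bundled synthetic cohort (aggregates match the
# published attribute summaries of a 39-shark Bahamas cohort)
cohort  <- synthetic_staged_cohort()
staging <- restage_cohort(cohort$tags, cohort$detections)
table(staging$staged$stage_first_detection)
#>     adult  juvenile sub-adult       YOY
#>        10         6        22         1
nrow(staging$reclassified)   # sub-adults that matured before detection
#> [1] 5

# model-selection arithmetic on the bundled reference AIC table
ref <- edge_density_aic_reference()
tab <- aic_selection_table(ref$model_id, ref$aic,
                           ref$deviance_explained_pct)
head(tab[c("model_id", "aic", "delta_aic", "akaike_weight")], 3)
#>   model_id                        aic    delta_aic akaike_weight
#> 1 s(FL) + Island                -81.0   0            0.227
#> 2 s(FL)                         -80.9   0.130        0.213
#> 3 s(FL, by = Sex) + Sex + Island-80.2   0.820        0.151
select_model(tab)$model_id
#> [1] "s(FL, by = Sex) + Sex + Island"
```

The first call reproduces the growth-correction result that five sharks
tagged as sub-adults had crossed the female maturity threshold (265 cm FL)
by their first detection; the second shows that although a shared-smooth
model has the lowest AIC, the sex-specific smooth is selected for its
deviance explained among the closely supported (ΔAIC < 2) models.

A full simulated pipeline run:

```r
out <- run_pipeline(run_config(
  simulate = sim_config(seed = 1, cohort_size = 40,
                        study_end = "2019-03-01",
                        tagging_end = "2018-04-30",
                        prob_never_detected = 0),
  seed = 1), outdir = "results/run1")
summary(out$residency$ri)    # residency indices, all in (0, 1]
out$model_table              # AIC table over the nine candidates
```

See `vignettes/movement-networks.Rmd` for the model, its assumptions, and
every design choice.

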
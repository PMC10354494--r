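# colonynet

Do animal groups have repeatable "personalities" at the level of their
social network structure — or do apparent between-group differences just
reflect group size, composition, weather, housing and observation effort?
`colonynet` is an R toolkit for answering that question with automated
tracking data from replicated captive groups (it was built around
barcode-tracked zebra finch colonies, but any per-frame co-detection
stream fits the schema). It takes per-frame detection records, builds two
kinds of daily social network per group, computes seven colony-level
metrics, and partitions the day-to-day variance of each metric into
external drivers versus consistent colony identity.

## What it computes

**Daily networks, two social contexts.** From perch-camera frames, an
*interaction network*: birds "clump" when their barcodes are detected less
than 80 px (one body-width) apart in a frame, and the edge weight is a
strict simple ratio index,

    w_ij = (frames i and j clumped) / (frames i and j detected on the same perch),

which isolates the *choice* to interact from mere co-presence. From
feeding-table frames, an *association network* with the usual simple ratio
index,

    w_ij = (frames both on the same table) / (frames at least one at any table).

**Seven metrics per colony-day** (local → global scale): mean weighted
degree, mean binary degree, mean edge weight, CV of edge weights (social
differentiation), edge density, mean path length and diameter. The two
path-based metrics are computed on the weighted network (weights as
traversal costs) and, when a network is disconnected, corrected by a
randomized augmentation: 100 times, one bird sampled per component is
linked into a chain with the study-wide smallest positive edge weight, and
the mean excess of the joined-network value over the largest-component
value is added back.

**Variance partitioning.** Per metric, network type and season the package
fits Gaussian random-intercept models by REML (`lme4`):

* *uninformed*: `metric ~ 1 + (1 | colony)` — baseline colony
  repeatability `R = σ²_colony / (σ²_colony + σ²_resid)`;
* *informed*: `metric ~ group size + age + temperature + humidity + cloud
  + aviary aspect + aviary size + daily detections + (1 | colony) +
  (1 | date)` — repeatability after controlling for external drivers,
  `R = σ²_colony / (σ²_colony + σ²_date + σ²_resid)`, plus marginal and
  conditional R² and driver VIFs.

Confidence intervals come from a parametric bootstrap (default 1000
refits, bias-corrected percentile interval). Partial residuals
("corrected" metric values) visualize single-driver effects.

**Synthetic studies with ground truth.** A generator emulates the whole
observation process — latent colony / date / individual / dyad effects on
a log-odds scale, covariate effects, feeder bout joining, camera dropout —
so every stage can be validated against known truth.

## Worked example

```r
library(colonynet)

cfg <- synthetic_config(n_years = 1, colonies_per_year = 4,
                        birds_per_colony = 12, days_pre = 10,
                        days_post_by_year = 0, frames_per_day = 300,
                        seed = 42)
sim  <- simulate_study(cfg)
nets <- build_study_networks(sim$detections)
length(nets)
#> [1] 80                       # 4 colonies x 10 days x 2 network types
nets[[1]]
#> <daily_network> 2017-C01 2017-03-01 [interaction]: 12 nodes, 57 edges

met <- metric_table(nets, n_reps = 100, seed = 1)
round(head(met[met$net_type == "interaction",
               c("mean_weighted_degree", "mean_binary_degree",
                 "mean_edge_weight", "cv_edge_weight", "edge_density",
                 "mean_path_length", "diameter")], 3), 3)
#>   mean_weighted_degree mean_binary_degree mean_edge_weight cv_edge_weight
#> 1                2.353                9.5            0.214          0.771
#> 3                3.614                9.0            0.329          0.763
#> 5                4.784                9.5            0.435          0.651
#>   edge_density mean_path_length diameter
#> 1        0.864            0.171    0.287
#> 3        0.818            0.315    0.511
#> 5        0.864            0.475    1.000

met$season <- "pre"
res <- fit_study_models(met, impute_humidity(sim$covariates),
                        summarize_detections(sim$detections),
                        bootstrap_reps = 1000, seed = 9)
res[res$metric == "mean_weighted_degree" & res$net_type == "interaction",
    c("model", "R", "ci_low", "ci_high", "r2_marginal", "r2_conditional")]
#>        model     R ci_low ci_high r2_marginal r2_conditional
#> 1 uninformed 0.246  0.000   0.652       0.000          0.246
#> 2   informed 0.371  0.027   0.828       0.569          0.963
```

Read: day-to-day mean weighted degree varies a lot, and colony identity
alone explains ~25% of it; after the drivers (which here explain 57% of
the variance on their own) and a shared date effect soak up environmental
noise, the *remaining* variance is still 37% attributable to which colony
it is — consistent colony identity, not just circumstance.

The same pipeline runs end to end from a single config
(`run_pipeline()`, or `inst/scripts/run_pipeline.R` from a shell), writes
every intermediate table as CSV plus a run manifest, and accepts real
detection/covariate CSVs in place of the generator.

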
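# homingnav

Analysis of the initial homing phase of GPS-tracked pigeon releases.

Release experiments ask what a pigeon knows about its position at an
unfamiliar site: two treatment groups (e.g. birds previously exposed to
the release site's cues versus birds exposed elsewhere) are released
individually at two sites in a 2 x 2 design, each bird carrying a 1 Hz
GPS logger, with the home loft tens of kilometres away. The informative
part of each track is the section between leaving a 500 m escape radius
and leaving a 2 km (and 5 km) radius of the release site for the final
time. `homingnav` implements the full analysis chain for such data:

* **Ingest**: CSV (`bird_id,datetime,lat,lon,speed_kmh`) or GPX 1.1,
  with a bird-to-design manifest; invalid fixes are rejected with a
  logged count.
* **Preprocessing**: 500 m escape strip, < 5 km/h stop filter,
  final-exit segmentation at each analysis radius, and detection of
  birds following each other with the group-dependent exclusion rule
  (same group: one excluded at random; different groups: both).
* **Metrics** per bird and radius: virtual vanishing time *t*(exit) −
  *t*(release); mean vector length of home-relative step directions
  (each step's bearing minus the bearing to home, averaged as unit
  vectors); efficiency index *g*(first, exit)/*L*; homing efficiency
  index [*g*(first, home) − *g*(exit, home)]/*L*, where *g* is
  great-circle distance and *L* the path length.
* **Directional inference**: per-bird mean-vector points, second-order
  (group) mean vectors, and two-sample Hotelling's T² comparisons with
  the exact F transform on (2, n−3) df.
* **Linear models**: `metric ~ group + release_site` by OLS with Type II
  sums of squares (vanishing times log-transformed), reporting F, df, p,
  partial η², fitted mean differences with 95% CIs, and Cohen's
  d = t·√(1/n₁+1/n₂) with noncentral-t CIs, plus Shapiro–Wilk/Q-Q
  residual diagnostics.
* **Power**: analytic noncentral-F power for the 1-df treatment term,
  f² = η²p/(1−η²p), λ = f²·N, df = (1, N−3).
* **Simulator**: a biased correlated random walk generator
  (`simulate_study()`) emitting complete synthetic studies — escape
  phase, stops, site-specific orientation bias, optional treatment
  effect, follower dyads, GPS noise — with a per-bird truth table, so
  the whole pipeline is testable and calibratable offline.

## Worked example

```r
library(homingnav)

study <- simulate_study(sim_config(seed = 11))   # 49 synthetic birds
res   <- homing_analysis(study$tracks, config = homing_config(seed = 11))
print(res)
#> Homing-pigeon release analysis
#>   birds in: 49
#>   radius 2000 m: 38 analysed (11 exclusions)
#>   radius 5000 m: 38 analysed (11 exclusions)
#>   2000 m directional tests: group T2 = 3.32 (p = 0.214), site T2 = 41.2 (p = 1.58e-06)
#>   5000 m directional tests: group T2 = 2.13 (p = 0.365), site T2 = 163 (p = 9.77e-14)
#>   mean release-site eta2p across models: 0.55
```

49 birds went in; 11 were excluded (followers, plus any track that never
left a radius), leaving 38 per model. The treatment comparison is null by
construction (`treatment_effect = 0` is the generator default) and the
directional tests agree (p = 0.21, 0.37); the built-in release-site
handicap produces the strong site effect (T² = 41.2, p < 1e-5).

The per-model effect reports:

```r
rep <- model_report_table(res)
rep[rep$metric == "efficiency_index",
    c("radius_m", "term", "n", "F", "p", "partial_eta_sq",
      "mean_difference", "cohens_d")]
#>  radius_m         term  n        F        p partial_eta_sq mean_difference cohens_d
#>      2000        group 38   0.0600 8.08e-01       0.001713         0.01241   0.0796
#>      2000 release_site 38  20.2807 7.12e-05       0.366867        -0.22770  -1.4611
#>      5000        group 38   0.0251 8.75e-01       0.000716        -0.00416  -0.0515
#>      5000 release_site 38 104.3807 4.82e-12       0.748889        -0.26780  -3.3147
```

Negative site differences mean site 2 underperforms site 1, the direction
the handicap injects. `plot(res)` draws the circular mean-vector panels
(home at the top); `run_full_analysis("out/")` writes the metric table,
exclusion log, model reports, Hotelling JSON, power grid, figures and a
run manifest for a fully reproducible run.

The analytic power grid at the conventional effect sizes:

```r
power_table(c(0.26, 0.14, 0.06, 0.01), c(31, 34))[, 1:3]
#>   partial_eta_sq n_total power_percent
#> 1           0.26      31     88.974996
#> 2           0.14      31     58.280564
#> 3           0.06      31     27.425867
#> 4           0.01      31      8.409889
#> 5           0.26      34     91.734283
#> 6           0.14      34     62.528303
#> 7           0.06      34     29.761098
#> 8           0.01      34      8.771269
```

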
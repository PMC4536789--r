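# chromhelix

Polymer-physics models of chromatin contact-frequency decay within
topologically associating domains (TADs), for people who analyse 3C-qPCR
profiles or binned Hi-C maps and want quantitative parameters of local and
higher-order chromatin dynamics rather than pictures.

Contact frequency between two sites separated by *s* kb is modelled with
the combined freely-jointed-chain / worm-like-chain law

    X(s) = K · 0.53 · β^(−3/2) · exp(−2/β²) · (L·S)^(−3)

where *K* is a cross-linking efficiency scale, *L* the linear mass density
(nm of fiber per kb of DNA, derivable from the nucleosome repeat length)
and *S* the Kuhn statistical segment (kb; chromatin flexibility). The
reduced separation β is either *s/S* (unconstrained chain) or the
statistical-helix form in which constrained supranucleosomal dynamics is
summarized by a mean helix diameter *D* and pitch *P* (nm); one helix turn
contains Sh = √((πD)² + P²)/L kb of DNA and sets the period of the
high/low modulation of contact frequencies. Globule power laws
X(s) = k·s^α (α = −3/2 equilibrium, −1 crumpled) are included for model
discrimination.

The package provides:

* closed-form model evaluation (`model_curve`, `helix_turn_length`,
  `linear_density_from_nrl`, …);
* weighted nonlinear least-squares fitting with multi-start search and
  asymptotic standard errors (`fit_unconstrained`, `fit_helix`,
  `fit_powerlaw`, `compare_fits`);
* supranucleosomal separation-distance domains with Mann–Whitney tests
  between adjacent windows (`domain_scheme`, `adjacent_domain_tests`);
* virtual 3C: per-anchor decay profiles from 5-kb binned contact maps,
  TAD-containment filtering, epigenetic-domain classification (D1–D4),
  batch fitting and per-domain summaries (`build_virtual_profiles`,
  `filter_within_tad`, `classify_profiles`, `fit_virtual_profiles`,
  `domain_parameter_summary`);
* a synthetic-data generator with known ground truth for profiles,
  TAD/epigenetic annotation tracks and sampled contact maps
  (`simulate_3c_profile`, `simulate_genome`, `simulate_contact_map`);
* plain-text I/O: profile TSVs, BED4 tracks, sparse/dense contact maps,
  fit tables and JSON manifests.

## Worked example

Simulate a gene-rich-style quantitative-3C profile (truth: K = 1070,
S = 2.7 kb, D = 255 nm, P = 201 nm, L fixed at 9.70 nm/kb, 10 %
replicate noise) and fit both models:

```r
library(chromhelix)

s  <- seq(5, 250, 5)
pr <- simulate_3c_profile(s, K = 1.07e3, L = 9.70, S = 2.7,
                          D = 255, P = 201,
                          noise = noise_spec(0.1), seed = 42)
fit_helix(pr, L = 9.70)
#> <chromatin_fit: helix model>
#>   estimate std.error
#> K 1033.920    58.300
#> S    2.611     0.090
#> D  254.706     0.639
#> P  202.188     1.760
#> fixed: L = 9.7
#> helix turn Sh = 85.1 kb
#> R^2 = 0.9992 | weighted SSR = 75.7425 | n = 50 | converged = TRUE (32 starts)
```

All four truth parameters are recovered within their standard errors, and
the fitted turn length (85.1 kb) matches √((π·255)² + 201²)/9.70. The
unconstrained chain cannot follow the modulation on the same data
(R² = −0.30 vs 0.9992), which is exactly the model contrast the fits are
meant to expose. The modulation itself shows up as alternating
adjacent-domain means:

```r
adjacent_domain_tests(pr, domain_scheme("gene_rich_poor"))
#>     pair       mean_a       mean_b n_a n_b      p_value stars
#> 1   I-II 0.0029877203 0.0010012813   6   7 0.0034052358   ***
#> 2 II-III 0.0010012813 0.0011574522   7   9 0.2442767438
#> 3 III-IV 0.0011574522 0.0005503001   9   9 0.0004122948   ***
#> 4   IV-V 0.0005503001 0.0004583696   9   9 0.0171182397    **
#> 5   V-VI 0.0004583696 0.0003094679   9   9 0.0004122948   ***
```

For Hi-C-style input, `simulate_genome()` + `simulate_contact_map()` build
a TAD-tiled chromosome with per-epigenetic-class truth, and the virtual-3C
chain recovers the per-class flexibility medians; see the methods vignette
(`vignettes/chromhelix-methods.Rmd`) for the model assumptions, fitting
choices, identifiability caveats and generator design.

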
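---
title: "Polymer models of chromatin contact-frequency decay: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polymer models of chromatin contact-frequency decay: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromhelix)
```

## The scientific problem

Chromosome-conformation-capture assays (quantitative 3C, Hi-C) measure how
often two genomic sites touch, averaged over millions of cells. Within a
topologically associating domain (TAD), the decay of contact frequency
$X(s)$ with genomic separation $s$ carries quantitative information about
the chromatin fiber: how compact it is, how stiff it is, and whether its
supranucleosomal dynamics is constrained. `chromhelix` implements a family
of closed-form polymer models for $X(s)$, weighted nonlinear least-squares
estimation of their parameters, rank statistics for the alternating
"supranucleosomal domains" the constrained model predicts, and a
virtual-3C stage that turns binned Hi-C maps into thousands of per-anchor
decay profiles stratified by TADs and epigenetic domains. A fully synthetic
data generator with known ground truth makes every stage testable offline.

## The models

The core law combines the freely jointed chain with the Kratky–Porod
worm-like chain:

$$X(s) = K \cdot 0.53 \cdot \beta^{-3/2} \, e^{-2/\beta^2} \, (L S)^{-3}$$

with $s$ in kb and three local parameters: $K$, a dimensionless
cross-linking efficiency absorbing all experimental scale; $L$, the linear
mass density in nm of fiber per kb of DNA (smaller $L$ = more compact); and
$S$, the Kuhn statistical segment in kb (smaller $S$ = more flexible). The
constants $0.53$, $-3/2$ and $-2$ are part of the law and are never fitted.
The reduced separation $\beta$ encodes the higher-order organization:

* **Unconstrained chain**: $\beta = s/S$.
* **Statistical helix**: constrained supranucleosomal dynamics behaves *as
  if* the fiber were, on average, folded into a helix of mean diameter $D$
  and mean pitch $P$ (both nm):
  $$\beta = \frac{\sqrt{D^2\sin^2\!\left[\frac{\pi L s}{\sqrt{\pi^2D^2+P^2}}\right]
  + \frac{P^2L^2s^2}{\pi^2D^2+P^2}}}{L S}.$$
  One helix turn contains $S_h = \sqrt{(\pi D)^2 + P^2}/L$ kb of DNA; the
  $\sin^2$ modulation has genomic period $S_h$, which is why contact
  frequencies alternate between high and low across consecutive
  separation-distance windows. With $D = 0$ the helix degenerates exactly
  to the unconstrained chain.
* **Globule power laws**: $X(s) = k\,s^{\alpha}$, with $\alpha = -3/2$ for
  the equilibrium globule and $\alpha = -1$ for the crumpled (fractal)
  globule, used to test whether globule ensembles can describe intra-TAD
  dynamics at all.

$L$ is normally not fitted but derived from the nucleosome repeat length
via a packing ratio of 6 nucleosomes per 11 nm of fiber:
$L = (1000/\mathrm{NRL}) \times 11/6$, giving 9.45 nm/kb at NRL 194 bp
(mouse liver) and 9.70 nm/kb at NRL 189 bp (mESC). At NRL 174 bp the exact
value is $10.536$ nm/kb; published tables print 10.53, and
`linear_density_from_nrl()` deliberately returns the exact value rather
than reproducing the rounding.

Two numerical notes. First, as $\beta \to 0$ the law tends to 0 but the
naive product underflows to `0 * Inf`; `contact_frequency()` returns exactly
0 below $\beta = 10^{-3}$, matching the analytic limit. Second, the local
*maxima* of the helix curve are not spaced exactly $S_h$ apart: the
quadratic drift term shifts them to $S_h\,(\pi D)^2/((\pi D)^2+P^2)$ to
first order (about 6% below $S_h$ for mESC gene-rich parameters). The
$\sin^2$ term itself has exact period $S_h$; tests verify both statements
in their own regimes.

## Fitting

All fits minimize $\sum_i w_i\,(X_i - X(s_i;\theta))^2$ with bounded
Levenberg–Marquardt local searches. Choices that the data alone do not
dictate, fixed as follows:

* **Weights.** If every observation carries a positive SEM,
  $w_i = 1/\mathrm{sem}_i^2$ (inverse variance); otherwise uniform. The
  switch is explicit (`weights = "auto" / "sem" / "uniform"`).
* **Multi-start.** The helix objective is oscillatory in $(D, P)$, so
  `fit_helix()` starts from the grid $D \in \{100,200,300,400\}$ nm,
  $P \in \{50,150,250,400\}$ nm, $S \in \{2,4\}$ kb, with $K$ started from
  a closed-form scale match at the smallest separation, and keeps the
  lowest-SSR converged solution. Unconstrained and power-law fits use
  smaller grids over $S$ (and $L$ when free) and over $\alpha$.
* **Tolerances.** Relative SSR tolerance $10^{-10}$, at most 1000
  iterations per start. Fits are deterministic: identical input and
  options give bit-identical results.
* **Standard errors.** Asymptotic, from $(J^\top W J)^{-1}$ scaled by the
  weighted residual variance, with the Jacobian evaluated numerically at
  the optimum. Published "±" values are interpreted the same way.
* **Model comparison.** `compare_fits()` ranks by $R^2$
  ($1 - SS_{res}/SS_{tot}$, computed unweighted), descending, with ties
  broken by model id.

**Identifiability.** In the unconstrained model $K$ and $L$ enter only
through the product $K(LS)^{-3}$: their Jacobian columns are exactly
parallel, so with $L$ free only $S$ and the overall amplitude are
estimable. `fit_unconstrained(L = "free")` and the virtual-3C batch fit
therefore report an $L$ that stays near its starting value, flag its
standard error as `NA`, and all recovery claims are made on $S$ and on the
amplitude $K(LS)^{-3}$. Mouse-style analyses avoid the issue by fixing $L$
from the NRL; per-domain contrasts from virtual-3C fits are meaningful for
$S$ (and for amplitude combinations), not for $K$ and $L$ separately.

## Supranucleosomal domains

Separations are binned into consecutive windows — gene-rich/gene-poor
scheme 0–35–70–115–160–205–250 kb (domains I–VI), gene-desert scheme in
25-kb steps to 150 kb — under a left-closed right-open convention: a
boundary value belongs to the upper domain (the printed schemes leave the
boundary membership unresolved; one convention is fixed and documented).
Adjacent windows are compared with a two-sided Mann–Whitney U test, exact
by enumeration when the combined sample is at most 12 without ties, else
the normal approximation with tie and continuity correction; two samples
with all pooled values identical give $p = 1$. P-values are reported raw
(five adjacent comparisons; no multiplicity correction, matching how such
panels are annotated), with two star conventions: `two_level`
(`**` for $0.01<p<0.05$, `***` for $p<0.01$) and `three_level`
(`*`/`**`/`***` at 0.05/0.01/0.001). Whether the original tests were
two-sided is not stated; two-sided is the default and a flag.

## Virtual 3C

A binned map (5-kb bins) is scanned with a 25-kb anchor window in 5-kb
steps over a one-sided 400-kb downstream span ("surrounding 400 kb from
the start of the 25-kb bin" is read as one-sided; the centered alternative
is noted but not implemented). The profile value at separation $d$ is the
**mean of the five contact values at exactly that separation**, pairing
anchor bin $a{+}k$ with bin $a{+}k{+}d/5$. A fixed-target alternative
(all five anchor bins against the single bin at $d$ downstream of the
anchor start) mixes separations $d{-}20 \dots d$ kb and, on model-generated
maps, flattens the decay enough to push fitted $S$ far off truth; the
constant-separation rule makes the noiseless profile equal the model curve
exactly and was adopted for that reason. On a gap-free chromosome the
number of profiles is $n_{bins} - 80 + 1$.

Profiles are kept when the anchor window plus `min_span_kb` of downstream
sequence lies within a single TAD (default 65 kb, the filter used when the
published profile set was assembled). The batch fit uses the first 70 kb —
all 14 bins, including small separations, which are genuine bin pairs
under the constant-separation rule and are precisely the points that
identify $S$; restricting to $d \ge 25$ kb leaves $S$ nearly unidentified
because $e^{-2S^2/s^2} \approx 1$ there. For strict containment of every
fitted pair (reach = 25 kb + 70 kb), pass `min_span_kb = 70`; the 65/70
mismatch mirrors how the published profile sets were assembled and is
documented rather than hidden. Anchors are classified by majority base-pair overlap of the anchor
window with the epigenetic track (D1 red/active, D2 black/unmarked, D3
blue/Polycomb, D4 green/HP1); exact ties and zero overlap are left
unassigned. Fits are retained when converged with $0 < R^2 < 1$, the
fraction with $R^2 > 0.5$ is reported, and per-domain medians of
$K, L, S$ are compared with pairwise two-sided rank-sum tests. For
dosage-compensation reasons an X chromosome should simply not be passed
in; the package does not special-case chromosome names.

## The synthetic-data generator

The generator emulates every input the pipeline consumes, with known truth:

* `simulate_3c_profile()` mirrors the replicate structure "three
  independent assays, each in triplicate": observation = mean of assay
  means, SEM = SE across assay means, multiplicative log-normal noise
  (3C-qPCR error is scale-proportional).
* `simulate_genome()` tiles chromosomes with TADs drawn from a log-normal
  size distribution (fly-like median 70 kb by default; mouse-like TADs are
  an order of magnitude larger), rounded to whole 5-kb bins, minimum two
  bins, each TAD carrying one epigenetic class. Default class proportions
  (23/57/14/6 % for D1–D4) follow the observed share of fitted profiles
  per class on fly chromosome 2L, and default per-class $(K, L, S)$ truths
  are that chromosome's published medians. The TAD size spread
  (`sdlog = 0.5`) is a realistic choice not pinned by any printed value.
* `simulate_contact_map()` gives each in-TAD bin pair the model-expected
  value under its TAD's class truth; pairs crossing a border are
  multiplied by an attenuation factor (default 0.1, reflecting strongly
  depleted cross-border contacts), then log-normal noise (default 10 %) or
  Poisson counts are applied. TAD borders are hard multipliers — no loop
  or boundary elements, no bead–spring dynamics, no read-level simulation.

Everything is seed-deterministic, and `write_simulation_manifest()` dumps
the truth parameters and seed as JSON.

What passing tests on these data do **not** show: real Hi-C bins carry
correlated noise, coverage and mappability artifacts, and normalization
residue; real TADs have fuzzy borders, nested structure and loops; real
epigenetic domains are not in 1:1 correspondence with TADs. Recovery on
the generator demonstrates the estimator and pipeline are correct, not
that the biological model is true.

## Problem sizes used in the shipped tests

The test-suite simulations are sized to exercise every claim at desk
scale: helix Monte-Carlo recovery uses 25 separations over three helix
turns and 100 replicates at 10 % noise; slope recovery uses 50 separations
and 200 replicates per exponent at 5 % noise; the end-to-end virtual-3C
check uses one 6-Mb chromosome (1200 bins, two epigenetic classes with
distinct flexibility truths, ≥ 50 retained profiles per class, 10 %
noise). These sizes are the package's chosen reference experiments; all
scale linearly if larger runs are wanted.

## Known limitations

* $K$/$L$ non-identifiability in the unconstrained model (above) is a
  property of the law, not of the optimizer; treat per-profile $K$ and $L$
  from free-$L$ fits as coordinates on a ridge.
* Asymptotic standard errors only; no bootstrap or Bayesian intervals.
* The helix fit fixes $L$; jointly free $L$ with helix parameters is not
  supported (it would inherit the same degeneracy).
* One-sided downstream virtual-3C windows; upstream/centered windows are
  not implemented.
* Contact maps are per-chromosome and in-memory sparse; binary Hi-C
  containers (cooler/hic) are out of scope, as are read mapping, matrix
  balancing and TAD calling.
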
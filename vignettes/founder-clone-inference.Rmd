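---
title: "Inferring founder-clone numbers from multicolor lineage tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring founder-clone numbers from multicolor lineage tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecount)
```

## The problem

Multicolor lineage tracing (brainbow in mouse, flybow in *Drosophila*)
stochastically marks each independently induced cell lineage — each *founder
clone* — with one of four fluorophores: GFP (G), mCherry (R), mCitrine (Y),
mTurquoise2 (B). An image of a tumor or clone field then displays some
non-empty subset of the four colors, one of $2^4 - 1 = 15$ categories. A
monoclonal tumor can only ever show one color; a tumor assembled from many
founder clones shows more. The number of *distinct colors* per image is,
however, a heavily censored readout of the number of *clones*: two clones
share a color with appreciable probability, and the color palette is far from
uniform (un-recombined flybow defaults to GFP, so G dominates, especially at
short induction). `clonecount` turns the 15-category image counts into a
maximum-likelihood estimate of the mean number of founder clones per image,
with profile-likelihood confidence intervals.

## The model

Per image, the number of founder clones $k$ is Poisson($\mu$). Each clone is
independently assigned color $c$ with frequency $p_c$,
$p = (p_G, p_R, p_Y, p_B)$ on the simplex. Images with no clone are never
recorded, so $k$ is zero-truncated:
$P(k \mid k \ge 1) = \frac{\mu^k e^{-\mu}/k!}{1 - e^{-\mu}}$.
Given $k$ clones, the probability that exactly the color set $S$ is displayed
follows by inclusion–exclusion,

$$f_S(p, k) = \sum_{T \subseteq S} (-1)^{|S| - |T|}
  \Big(\sum_{c \in T} p_c\Big)^{k},$$

and the observable category frequencies mix $f$ over the truncated clone
number:

$$F(\mu, p) = \frac{1}{1 - P(0, \mu)} \sum_{k > 0} P(k, \mu)\, f(p, k).$$

The data vector $n$ of counts over the 15 categories is multinomial with cell
probabilities $F(\theta)$, $\theta = (\mu, p)$, and
$\ell(\theta \mid n) = \log M(n, F(\theta))$ is maximized numerically.

Two computational identities matter. First, by Poisson thinning, clones of
color $c$ arrive as independent Poisson($\mu p_c$) streams, so

$$F_S = \frac{\prod_{c \in S} (1 - e^{-\mu p_c})
  \prod_{c \notin S} e^{-\mu p_c}}{1 - e^{-\mu}}$$

exactly. The package evaluates this closed form as the production path and
keeps the explicit series (`mixture_category_probs()`) for fidelity to the
defining equation; their agreement to $10^{-10}$ is one of the central oracle
tests, alongside exhaustive enumeration of all $4^k$ color assignments as the
oracle for $f$. Second, the product form makes the log-likelihood a function
of the data only through the total image count and the four per-color
presence counts, which yields cheap analytic gradients.

## Estimation

Parameters are transformed for optimization: $\log \mu$, and
additive-log-ratio coordinates $\log(p_c / p_B)$ for the three free simplex
components (a smooth bijection onto the open simplex — the back-transform of
any finite point is a valid parameter, so the optimizer cannot leave the
feasible set; the fourth frequency is recovered as
$p_B = 1 - p_G - p_R - p_Y$). `fit_mle()` runs BFGS with analytic gradients
from one deterministic start (`initial_guess()`) plus four seeded jittered
starts (normal jitter, SD 0.5 in the unconstrained space), keeps the best
optimum (ties within $10^{-9}$ go to the lowest start index), and finishes
with Newton polishing so that convergence can be declared at gradient norm
$< 10^{-6}$. Estimates of $\hat\mu$ or $\hat p_c$ within $10^{-4}$ of the
boundary are flagged rather than silently clamped, with $\mu$ floored at
$10^{-8}$ against underflow of the truncation factor $1 - e^{-\mu}$.

The starting point is deterministic: $p_0$ is the per-color occurrence share
(pseudo-count 0.5 per color), and $\mu_0$ solves the method-of-moments
equation matching the expected number of distinct colors per retained image,
$\sum_c (1 - e^{-\mu p_{0c}})/(1 - e^{-\mu})$, to its observed value, clamped
to $[0.1, 20]$.

Two degenerate regimes are handled explicitly. If no image shows more than
one color, the likelihood supremum sits on the $\mu \to 0$ boundary (where it
attains the saturated multinomial bound with $p$ at the empirical singleton
frequencies); `fit_mle()` returns that boundary fit, flagged, instead of
letting the optimizer chase it. Conversely, heavily saturated data — many
four-color images under a skewed palette — can make the likelihood monotone
in $\mu$ beyond some point (the profile deviance plateaus at zero), in which
case $\hat\mu$ is reported where the optimizer stops climbing the plateau and
the upper confidence endpoint is set to the parameter bound with
`upper_at_boundary = TRUE`. This is a property of the model at such
conditions, not a numerical failure: the data genuinely cannot bound $\mu$
from above.

## Confidence intervals

`profile_ci()` profiles one parameter: at each fixed value the likelihood is
re-maximized over all the others (warm-started from the neighboring solution),
and the confidence set is where the profile deviance
$2[\ell(\hat\theta) - \ell_{\text{profile}}(v)]$ stays below the
$\chi^2_1$ quantile (3.841 at 95%). Endpoints are bracketed by geometric
expansion away from the estimate — on the log scale for $\mu$, logit scale
for frequencies — and refined by bisection to absolute tolerance $10^{-4}$ on
the parameter scale (log scale for $\mu$). Non-negativity of the profile
deviance is asserted during the search; an endpoint the deviance never
reaches before the parameter bound is returned at the bound, flagged.

## The synthetic-data generator

`simulate_experiment()` reproduces the assumed sampling process literally:
draw $k \sim$ Poisson($\mu$), reject and count $k = 0$ draws (mirroring the
discarding of clone-free images — rejection sampling is distributionally
identical to simulating the truncated law, and the rejection count feeds the
$e^{-\mu}$ diagnostic), color each clone i.i.d. from $p$, record the color
set. Everything is determined by the seed, in a private RNG scope (pinned
Mersenne-Twister) that never disturbs the caller's stream.

`simulate_paper_grid()` generates the full reference design — induction times
of 30, 60, 120 minutes, early ($\le 5$ days post-induction) and late
($\ge 20$ dpi) stages, tumor and clone-control images, 12 datasets — with
per-dataset seed streams derived from (seed, dataset index). Its defaults are
the package's study conditions, chosen once: GFP-dominant frequencies
$(0.94, 0.02, 0.02, 0.02)$ at 30-minute induction, flattening but remaining
GFP-heavy at 60 minutes $(0.70, 0.10, 0.10, 0.10)$ and 120 minutes
$(0.55, 0.15, 0.15, 0.15)$; mean clone numbers of 8 for late tumors (the
polyclonality estimate the model exists to produce), 6 for early tumors, and
1.5/1.2 for early/late clone-control images, which are individual lineages
rather than clone assemblies; 150 retained images per dataset, a realistic
imaging-campaign size that also matches the package's coverage study.

What the generator deliberately does not emulate: clone sizes and growth (the
observation is the color *set* per image only; growth arithmetic lives in
`theoretical_clone_size()`, $2^d$ cells after $d$ synchronous divisions),
fluorophore misclassification or imaging noise, spatial structure and clone
merging, and between-image heterogeneity in $\mu$. Passing simulation-based
tests therefore validates the estimator *under the model's own assumptions*;
on real images, color-calling errors or overdispersed clone numbers would
bias $\hat\mu$ in ways these tests cannot detect.

## Numerical choices

* Series truncation: residual Poisson tail mass $< 10^{-12}$, hard cap
  $k \le 1000$ (the closed form, not the series, is the production path).
* Simplex validation tolerance $10^{-9}$ (inputs may arrive from transformed
  optimizer space); category probabilities renormalized after clearing
  negative round-off from inclusion–exclusion.
* The multinomial coefficient is included in reported log-likelihoods, so
  they are true log-probabilities; it is constant in $\theta$ and cancels in
  every deviance and interval.
* Count tables are read with fail-fast column validation — the 15 category
  columns are required by exact name and order, because a silently permuted
  column corrupts $\hat p$ irrecoverably.
* Problem sizes of the simulation studies: 200 replicates of 500 images for
  parameter recovery, 400 replicates of 150 images for interval coverage —
  large enough that the Monte-Carlo error on a 95% coverage proportion is
  about $\pm 2$ points.

## Worked example

```{r example}
sim <- simulate_experiment(mu = 6, p = c(0.55, 0.15, 0.15, 0.15),
                           n_images = 150, seed = 1)
sim$counts

fit <- fit_mle(sim$counts, seed = 1)
fit

profile_ci(sim$counts, fit, "mu")
```

And across the full design:

```{r grid, fig.width = 7, fig.height = 4}
datasets <- simulate_paper_grid(seed = 1)
tab <- fit_all(datasets, seed = 1)
tab[, c("dataset_id", "mu_hat", "mu_lo", "mu_hi", "mu_hi_boundary")]
plot_condition_table(tab)
```

## Design choices and limitations

Each dataset is fitted independently (its own $\mu$ and $p$), matching
per-condition estimation; `fit_all(fix_p_from = )` optionally borrows
$\hat p$ from a designated clone-control dataset when fitting the paired
tumors, since controls exist to calibrate the palette, but independent fits
are the default because parameter sharing across conditions is an assumption,
not a given. Only the requested parameter is profiled (any of $\mu$ or the
four frequencies). Not implemented, by intent: Dirichlet-multinomial
overdispersion, negative-binomial clone numbers, hierarchical fits across
conditions, Bayesian inference, and any image processing upstream of the
count table. Under strongly skewed palettes or few images the upper
confidence limit for $\mu$ is frequently unbounded — more images, or a more
even palette (longer induction), is the experimental remedy.
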
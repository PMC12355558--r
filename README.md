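# clonecount

Are tumors founded by one clone or by many? Multicolor lineage tracing
(flybow/brainbow cassettes) marks each independently induced cell lineage —
each **founder clone** — with one of four fluorophores (G, R, Y, B), so an
image of a tumor or clone field displays one of the 15 non-empty color
combinations. The number of colors visible is only a censored readout of the
number of clones: clones share colors, and the palette is skewed (the
cassette defaults to GFP). `clonecount` is for experimentalists and
biostatisticians who have such 15-category image counts and want a principled
estimate of the **mean number of founder clones per image**.

## The model

Per image, the clone number $k$ is Poisson($\mu$); each clone independently
takes color $c$ with frequency $p_c$; images without clones are discarded, so
$k$ is zero-truncated. The observable category frequencies are

$$F(\mu, p) = \frac{1}{1 - P(0,\mu)} \sum_{k>0} P(k,\mu)\, f(p, k),
\qquad P(k,\mu) = \frac{\mu^k e^{-\mu}}{k!},$$

where $f_S(p,k) = \sum_{T \subseteq S} (-1)^{|S|-|T|} (\sum_{c\in T} p_c)^k$
(inclusion–exclusion) is the chance that $k$ clones display exactly the color
set $S$. The counts are multinomial in $F(\theta)$, $\theta = (\mu, p)$;
`clonecount` maximizes that likelihood on a transformed scale (log $\mu$,
additive-log-ratio simplex coordinates) and profiles it for confidence
intervals. An exact product identity (Poisson thinning),
$F_S \propto \prod_{c \in S}(1-e^{-\mu p_c}) \prod_{c \notin S} e^{-\mu p_c}$,
is the fast path and is cross-checked against the series and against
exhaustive enumeration in the test suite. A seeded simulator with exactly the
assumed sampling structure makes every stage testable end to end.

## Worked example

```r
library(clonecount)

sim <- simulate_experiment(mu = 6, p = c(0.55, 0.15, 0.15, 0.15),
                           n_images = 150, seed = 1)
sim$counts
#> <category_counts sim: 150 images (induction NA min, NA, NA)>
#>    G    R    Y    B   GR   GY   GB   RY   RB   YB  GRY  GRB  GYB  RYB GRYB
#>   10    0    0    2   18   12   16    3    0    0   24   25   14    1   25

fit <- fit_mle(sim$counts, seed = 1)
fit
#> <fit_result sim: mu_hat = 5.704, loglik = -25.2086, converged>
#>   p_hat = (G=0.5509, R=0.1781, Y=0.1305, B=0.1406)

profile_ci(sim$counts, fit, "mu")
#> <profile_ci mu: 5.704 [4.93, 6.671] at 95%>
```

150 images generated at a true mean of 6 founder clones per image give back
$\hat\mu = 5.70$ with 95% profile interval $[4.93, 6.67]$: the interval
covers the truth, and the estimated color frequencies (0.55, 0.18, 0.13,
0.14) sit close to the generating palette. `fit_result` also carries
convergence and boundary diagnostics — with few images or a strongly
GFP-dominant palette the upper limit for $\mu$ can be genuinely unbounded,
in which case the endpoint is returned at the parameter bound with
`upper_at_boundary = TRUE` instead of a pretend-finite number.

## The analysis workflow

Numbered drivers under `analysis/` run the package over the full simulated
12-dataset design (3 induction times × early/late stage × tumor/clone
images) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_grid.R 1       # category-count table
Rscript analysis/02_fit_grid.R 1            # per-condition mu + 95% CI table
Rscript analysis/03_parameter_recovery.R 1  # 200-replicate bias study
Rscript analysis/04_ci_coverage.R 1         # 400-replicate coverage study
```

The trailing argument is the seed; every table is byte-reproducible from it.
See `vignettes/founder-clone-inference.Rmd` for the model's assumptions,
numerical choices, and what the simulation studies do and do not establish.

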
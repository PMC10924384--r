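---
title: "Transfer-learning eGene identification: model, tests and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer-learning eGene identification: model, tests and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlegene)
```

## The problem

An *eGene* is a gene whose expression level is influenced by at least one
of its local (cis) genetic variants. The standard multilocus test treats
the effects of the $m$ cis-SNPs as random: for one gene with expression
$e$ in $n$ target-study individuals,

$$ e = X\alpha + G\beta + \varepsilon, \qquad \beta_j \sim N(0, \tau), $$

and declares an eGene when $H_0{:}\,\tau = 0$ is rejected by the
variance-component score test (the SKAT-style test we call **Score**).
This ignores any external information. Many expression studies have a
closely related, often larger, auxiliary study (for example a matched
normal tissue) whose per-SNP effect estimates $\gamma$ are available as
summary statistics. `tlegene` transfers them into the target model by
assuming

$$ \beta_j = \gamma_j \theta + b_j, \qquad b_j \sim N(0, \tau), $$

which turns the model into

$$ e = X\alpha + (G\gamma)\,\theta + Gb + \varepsilon. $$

$G\gamma$ is a *burden* score — the SNP dosages weighted by the auxiliary
effects — and $\theta$ measures how much of the auxiliary signal carries
over (the *indirect* effect); $\tau$ captures *direct* target effects not
explained by the auxiliary study. The eGene null becomes the joint
hypothesis $\theta = 0$ and $\tau = 0$.

## The decorrelated pair of score tests

Score statistics for $\theta$ (fixed effect, $\chi^2_1$ null) and $\tau$
(variance component, mixture-of-$\chi^2$ null) are correlated if both are
derived under the joint null. `tlegene` decorrelates them: the burden
statistic $S_\theta$ is computed under the full null, while the
variance-component statistic $Q_\tau$ is computed under the null of
*only* $\tau = 0$, i.e. with the burden vector $G\gamma$ included in the
fixed-effect design. The two statistics are then asymptotically
independent (`decorrelated_pair()`), which the test suite verifies
empirically: across 5,000 null replicates the correlation of the two
statistics stays within $\pm 0.05$.

Concretely, with $P_0 = I - X(X'X)^{-1}X'$ and null residuals $r$,

* $S_\theta = (s'r)^2 / (\hat\sigma^2\, s'P_0 s)$ with $s = G\gamma$,
  $\chi^2_1$ under the null;
* $Q_\tau = r_1' G G' r_1$ with $r_1$ the residuals of the design
  $[X, G\gamma]$, distributed as $\sum_j \lambda_j \chi^2_1$ with
  $\lambda_j$ equal to $\hat\sigma^2$ times the eigenvalues of
  $G'P_1 G$.

The residual variance uses the unbiased divisor $n - p$; dosages enter
unweighted and uncentered (the intercept makes centering immaterial for
the projected statistics). Eigenvalues below $10^{-10}$ of the largest
are truncated to zero to handle LD-collinear genotype columns, with an
absolute guard for genotype blocks lying entirely in the design span.

When $\gamma$ is identically zero after harmonization (or $G\gamma$ is
collinear with the covariates) the burden test is degenerate: the
$\theta$ p-value is reported missing and every joint test reduces to the
plain Score test; the per-gene scan annotates such genes.

## Mixture-of-chi-square p-values

`mixture_chisq_pvalue()` evaluates $\Pr\{\sum_j \lambda_j \chi^2_1 > q\}$
by numerically inverting the characteristic function (Imhof's integral),
summed at midpoints of a uniform grid in the Davies style: the step is
chosen so the aliasing mass implied by Poisson summation is below the
accuracy target (default $10^{-9}$), and the sum is truncated once an
alternating-series bound on the oscillatory tail falls below it. If the
inversion cannot reach its target the Liu–Tang–Zhang moment-matching
approximation (a non-central $\chi^2$ surrogate matching skewness where
possible) is used, and every returned p-value is clamped to
$[10^{-300}, 1]$ so downstream logarithms and reciprocals stay finite.
The tests compare this machinery against closed forms, a $10^6$-draw
Monte-Carlo null, and a residual-resimulation oracle.

## Combining the two components

Because the components are independent, three classical combinations are
exact under the null:

* **fScore** — Fisher: $-2(\log p_\theta + \log p_\tau) \sim \chi^2_4$.
* **aScore** — adaptively weighted: the smaller component p-value with a
  Šidák correction, $1 - (1 - \min p)^2$.
* **oScore** — optimally weighted: a SKAT-O-style grid search over
  $T_\rho = \rho S_\theta + (1-\rho) Q_\tau$, $\rho \in \{0, 0.1, \dots,
  1\}$. Each $T_\rho$ is itself a chi-square mixture; the p-value of the
  minimum over the grid is computed by one-dimensional integration over
  the $\chi^2_1$ component (Gauss–Legendre, 512 nodes, integrating over
  the half-normal root of the $\chi^2_1$ variable to avoid the density
  singularity at zero). Grid quantiles and the conditional CDF inside the
  integral use the Liu approximation — the same compromise the SKAT
  implementations make — while the per-$\rho$ p-values use the exact
  inversion; the resulting test is calibrated within the 99% binomial
  band at $10^4$ null replicates in the test suite.

The three combined p-values target different alternatives (sparse strong
transfer, either-component, diffuse both), so they are aggregated by the
harmonic mean p-value (**HMP**): with $\mathring p$ the harmonic mean of
the three, the reported omnibus p-value is
$\Pr\{\mathrm{Landau}(\log 3 + 0.874,\, \pi/2) > 1/\mathring p\}$. The
asymptotically exact calibration uses $\log L$ with $L = 3$ the number of
tests; a `location = "log_T"` switch reproduces the variant that plugs in
the statistic itself. HMP is robust to the positive dependence among the
three combinations and errs on the conservative side, which the size
simulations show.

The Landau tail itself (`landau_tail()`) is evaluated from two exact
integral representations: a Gil–Pelaez inversion of the characteristic
function $\exp(-t - i\,(2t/\pi)\, t\log t)$ for the bulk and left tail,
and a rescaled direct tail integral for the right tail that remains
accurate arbitrarily far out (tail $\sim (2/\pi)\sigma/x$). The location
shift between the classic Landau integral form and the location–scale
convention is exactly $\ln(\pi/2)$.

## Harmonization and quality control

Transferring $\gamma$ presupposes that effect alleles agree between the
studies. `harmonize()` applies, in order: drop non-biallelic SNPs and
alleles outside A/C/G/T; drop strand-ambiguous variants (A/T, C/G); drop
variants without an rs identifier; drop duplicated ids (all copies, since
duplicated summary-statistic records cannot be told apart); intersect on
id; drop allele-set mismatches; and negate $\gamma_j$ where effect and
other allele are swapped. The operation is idempotent and reports counts
per rule. Genotype QC (`qc_genotypes()`) retains SNPs with MAF strictly
above 0.05 (configurable), removes monomorphic variants, and mean-imputes
remaining missing dosages per SNP — imputation after filtering leaves
column means unchanged. Coordinates are 1-based inclusive internally; BED
input is converted on read. The cis window defaults to ±1 Mb around the
gene body — the field's convention, configurable per scan.

## What the simulator emulates

`simulate_study()` generates the study conditions used throughout the
package's validation:

* genotypes from a Gaussian-copula AR(1) model (`simulate_genotypes()`):
  each haplotype thresholds a latent $N(0, \Sigma)$ vector with
  $\Sigma_{jk} = \rho^{|j-k|}$ at the MAF quantile; dosages are sums of
  two haplotypes. Defaults: $\rho = 0.5$, MAF $\sim U(0.05, 0.5)$. This
  preserves the block-like LD the tests must handle while avoiding any
  dependence on external reference panels; it does not reproduce real LD
  block boundaries, allele-frequency spectra, or population structure.
* an auxiliary study of 165 individuals whose gene expression is driven
  by $m \sim U\{20..50\}$ cis-SNPs, a configurable fraction of which (30%
  by default) are null; non-null effects are normal and rescaled so the
  SNPs explain the requested fraction of variance (PVE 0.3 by default)
  against unit residual noise. The transferred weights are the *estimated*
  per-SNP marginal effects from that auxiliary sample
  (`estimate_marginal_effects()`), mirroring the use of summary
  statistics rather than true effects.
* a target study of 300 individuals with true effects
  $\beta = \gamma\theta + b$, $b \sim N(0, \tau)$, unit residual noise,
  and in both studies one binary and one standard-normal covariate, each
  with effect 0.50.

All draws are deterministic given the master seed; replicate loops spawn
one substream seed per replicate, recorded in the output. Because the
generator matches the tests' assumptions exactly (normal residuals,
linear covariates), passing size and power checks here demonstrates the
statistics are implemented and calibrated correctly — not that the
method is robust to, e.g., expression heteroskedasticity or unmodelled
confounding in real data.

## Problem sizes and numerical defaults

The packaged evaluations use 5,000 replicates for size (a 99% binomial
band of $0.05 \pm 0.008$) and 1,000 per cell for power; both are package
defaults chosen to give informative Monte-Carlo precision at desk scale,
and both scale up by argument for full-scale runs. Other defaults worth
knowing: inversion accuracy $10^{-9}$; p-value floor $10^{-300}$, with
HMP inputs additionally floored at $10^{-10}$ before reciprocals (with a
warning); oScore grid $\{0, 0.1, \dots, 1\}$ with 512 Gauss–Legendre
nodes; MAF filter strict at 0.05; cis window $10^6$ bp.

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(theta = 0.3, tau = 0.02, seed = 7)
study <- simulate_study(cfg)
gamma_hat <- study$gamma_hat
gamma_hat[is.na(gamma_hat)] <- 0
res <- tlegene_test(study$target$e,
                    cbind(1, study$target$X),
                    study$target$G$dosages,
                    gamma_hat)
res
```

## Known limitations

* The exact forms of the optimally and adaptively weighted combinations
  are implementation choices (grid search and Šidák minimum) that are
  exact under independence; other weightings could be swapped in behind
  the same interfaces.
* The scan treats genes independently; no conditional (step-down)
  analysis pinpoints individual eQTLs within an eGene.
* Harmonization trusts rs identifiers; no liftover or dbSNP validation is
  performed, and indels are dropped.
* Liu moment matching inside the oScore grid is an approximation; its
  effect is confined to the grid quantiles and the conditional CDF and is
  validated empirically, but extremely small oScore p-values inherit the
  approximation.
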
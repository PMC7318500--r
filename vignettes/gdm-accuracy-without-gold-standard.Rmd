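---
title: "Estimating diagnostic accuracy without a gold standard: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diagnostic accuracy without a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmroc)
```

## The problem

Screening markers are usually validated against a reference ("gold
standard") test.  For gestational diabetes mellitus (GDM) the reference is
an oral glucose tolerance test performed at 24–28 weeks of gestation —
weeks *after* the serum markers (uE3, β-hCG, AFP, on the
multiples-of-median scale) are measured in early second trimester.  At
marker time no disease label exists, so sensitivity, specificity and the
ROC curve cannot be estimated by counting.  `lcmroc` treats the disease
status $d_i \in \{0,1\}$ as a latent class and estimates accuracy from the
joint distribution of the marker values alone, in a Bayesian mixture
model.

A green test suite here shows that the machinery recovers the parameters
of data *generated by the model's own assumptions*.  It cannot show that
real marker data satisfy those assumptions (within-class normality,
covariate-linear means, a single latent dichotomy); that caveat is
inherent to every no-gold-standard analysis.

## Single-marker model

For one marker,
$$d_i \sim \mathrm{Bernoulli}(\pi), \qquad
  Y_i \mid d_i \sim
  \mathcal N(\mu_D, \sigma^2_D)^{d_i}\,
  \mathcal N(\mu_{\bar D}, \sigma^2_{\bar D})^{1-d_i}.$$
The mixture is invariant to swapping the two classes; identifiability is
restored by the convention $\mu_D > \mu_{\bar D}$ (on an internal,
possibly sign-flipped scale — see *Orientation* below).  Closed forms
follow for the ROC curve
$(1-\Phi((c-\mu_{\bar D})/\sigma_{\bar D}),\; 1-\Phi((c-\mu_D)/\sigma_D))$
and the AUC $\Phi\!\big((\mu_D-\mu_{\bar D})/\sqrt{\sigma^2_D+\sigma^2_{\bar D}}\big)$.

Estimation is plain Gibbs sampling: Bernoulli full conditionals for the
labels, normal for the class means, gamma for the precisions, Beta for
$\pi$.  Draws violating the ordering are *relabeled* (classes swapped,
$\pi \mapsto 1-\pi$) rather than rejected; relabeling is the standard way
to restrict a label-symmetric posterior to its identified half without
changing it.

**Priors.** Class means $\mathcal N(0, 10^3)$, precisions
$\mathrm{Gamma}(10^{-3}, 10^{-3})$, $\pi \sim \mathrm{Beta}(1,1)$ (the
two-category Dirichlet).  These are the conventional vague choices for
the named families.  One consequence matters operationally: essentially
all of the $\mathrm{Gamma}(10^{-3},10^{-3})$ prior mass lies at
astronomically small precisions, so if a latent class ever becomes empty
its full conditional *is* that prior and the class never recovers (the
state is absorbing, with numerically infinite variance draws).  The
sampler therefore guards near-empty classes (< 2 members) by re-drawing
that class's mean and precision on the data scale
($\mathcal N(\bar y, s^2_y)$ and $\mathrm{Gamma}(1/2, s^2_y/2)$), counting
and reporting the event.  In identified regimes the guard never fires.

**Orientation.** The ordering constraint as printed cannot hold for all
three GDM markers simultaneously: uE3 is *lower* in disease while β-hCG
and AFP are higher.  Each marker therefore carries an orientation flag;
`orientation = "lower"` fits the negated values internally and reflects
the reported means back, leaving ROC/AUC/overlap invariant.

**Overlap diagnostic.** Practical identifiability is summarized by the
overlap coefficient $\Delta = \int \min(f_D, f_{\bar D})$ between the two
fitted normals, computed in closed form by partitioning the real line at
the density crossing points (log-density comparisons avoid tail
underflow).  $\Delta \ge 0.5$ is flagged "poor": mixtures that entangled
are weakly identified and latent class output should not be trusted.
This threshold and interpretation follow the diagnostic-accuracy
literature for LCMs; the exact formula behind the originally reported
measure is not published, and the overlap coefficient is the natural
reading consistent with its printed interpretation.

**Reported accuracy.** Sensitivity and specificity need a cutoff, which
the source analyses do not state.  We report them at the Youden-optimal
cutoff (maximizing Se + Sp − 1) of the posterior-mean parameters, solved
from the density-intersection quadratic with a grid fallback.  All of
Se/Sp/AUC are then evaluated **draw-wise** over the retained MCMC draws,
so credible intervals propagate parameter uncertainty.

## Covariate-adjusted multivariate model

With $K$ markers $Y_i \in \mathbb R^K$ and covariates $x_i$ (maternal age
and BMI):
$$\operatorname{logit} P(d_i = 1) = \alpha_0 + \alpha_1\,\mathrm{age}_i +
  \alpha_2\,\mathrm{BMI}_i,$$
$$Y_i \mid d_i, x_i \sim \mathrm{MVN}\big(\mu(x_i, d_i), \Sigma_{d_i}\big),
  \qquad
  \mu_k(x, d) = \beta^k_0 + \beta^k_1\,\mathrm{age} + \beta^k_2\,\mathrm{BMI}
  + \beta^k_3\,d + \beta^k_4\,d\cdot\mathrm{age} + \beta^k_5\,d\cdot\mathrm{BMI}.$$
$\Sigma_d$ depends on the class only.  Priors: $\alpha \sim
\mathrm{MVN}(0, I\sigma^2_\alpha)$, $\beta^k \sim \mathrm{MVN}(0,
I\sigma^2_k)$, and $\Sigma_d^{-1} \sim \mathrm{Wishart}(\nu, \Gamma)$
with $\nu = K + 2$, $\Gamma = I$ (the Wishart is read as a prior on the
precision matrix, the convention of the BUGS family the original analysis
used).

**Why $\sigma^2_\alpha = 25$, not $10^3$.**  A zero-mean normal with
variance $10^3$ on the *logit* scale is not vague on the probability
scale: it concentrates the induced prior on prevalences within machine
epsilon of 0 or 1.  In this sampler that preference is destructive — it
steers the chain toward emptying a class, and (as above) an empty class
is nearly absorbing.  We observed deterministic collapse of the chain to
"nobody diseased" within a few hundred iterations under $10^3$.  SD 5 on
the log-odds scale still spans prevalences from about 0.007 to 0.993
within one prior SD and leaves the likelihood in charge whenever the data
are informative, so 25 is the default; it is a single argument
(`alpha_prior_var`) if you want the textbook value back.  The regression
prior variance $\sigma^2_k = 10^3$ is kept: it is conjugate and harmless
while classes are populated.

**Sampler.** Metropolis-within-Gibbs:

* labels: exact Bernoulli full conditional combining the logistic prior
  with the two MVN likelihoods (log-scale throughout);
* all $K$ coefficient vectors jointly: the stacked $\mathrm{vec}(B)$ has
  an exact MVN full conditional with precision
  $\Sigma_0^{-1} \otimes S_0 + \Sigma_1^{-1} \otimes S_1 + I/\sigma^2_k$,
  where $S_d$ is the class-$d$ design cross-product — one Cholesky per
  iteration, no within-marker Gibbs sweep;
* $\Sigma_d^{-1}$: Wishart full conditionals ($\nu + n_d$ degrees of
  freedom); iterations in which a class holds fewer subjects than markers
  are counted and reported;
* $\alpha$: Gaussian random-walk Metropolis with a fixed proposal shape
  from the logistic information bound $(X'X/4 + I/\sigma^2_\alpha)^{-1}$
  and a scalar step size Robbins–Monro-adapted toward 30% acceptance
  during burn-in only (so the retained chain uses a fixed kernel).

Covariates are mean-centered internally — the posterior correlation
between intercepts and slopes is otherwise severe — and every stored draw
is mapped back to the original covariate scale, so users never see the
centering.

**Label switching.** The single-marker mean ordering does not generalize
when markers move in opposite directions, so the joint model uses an
*anchor*: one marker whose disease effect at the covariate means must
have a stated sign.  Violating draws are relabeled (classes, $\Sigma$s
swapped; $\alpha \mapsto -\alpha$; $\beta$ disease blocks folded into the
baseline and negated).  The anchor defaults to the marker with the
strongest two-means separation at initialization, with sign $+1$; because
*no* unlabeled statistic can reveal which direction "disease" moves a
marker, the direction is an explicit modelling input, and the default
pipeline anchors on β-hCG (elevated in GDM).  Initialization uses a
deterministic 2-means split of the anchor marker, per-marker ridge least
squares for $B$, residual covariances for $\Sigma_d$.

## Optimal marker combination

Given class covariances and the covariate-specific mean difference
$\Delta(x) = \mu(x,1) - \mu(x,0)$, the linear score $a'Y$ with
$$a = (\Sigma_0 + \Sigma_1)^{-1} \Delta(x)$$
maximizes the AUC among all linear combinations, and
$\mathrm{cAUC} = \Phi\big(\sqrt{a'\Delta(x)}\big)$, with the combined
ROC built from the two normal score distributions
$\mathcal N(a'\mu(x,d),\, a'\Sigma_d a)$.  The weights are obtained by a
Cholesky solve (never an explicit inverse).  Combination accuracy is
evaluated **per posterior draw** — weights, cAUC and cSe/cSp are
recomputed at every retained draw and then summarized — because plug-in
evaluation at posterior means would understate the credible intervals.
The cutoff for cSe/cSp is fixed across draws at the Youden cutoff of the
posterior-mean score distributions.  Subsets (all pairs and the full
triple by default) are ranked by posterior-mean cAUC, ties broken by
higher cSensitivity; a Mahalanobis-nesting argument guarantees that at
any fixed parameter draw a superset never has lower cAUC, so the triple
ranking first is a structural property, not luck.  The reference
covariate value `x_ref` defaults to the cohort means of age and BMI.

Subjects are classified by their retained posterior disease probability
$P(d_i = 1 \mid Y)$ with a strict `> threshold` rule (default 0.5;
a probability exactly at the threshold classifies negative).

## Synthetic cohort generator

The generator *is* the stated world of the study it emulates, not a
tuning knob: $n = 523$; age $\sim \mathcal N(28.76, 5.33^2)$ truncated to
the inclusion window $[20, 40]$ by rejection (which preserves the normal
shape; the truncation shifts the realized mean to about 29.1, within one
standard error of the target); BMI $\sim \mathcal N(24.57, 3.22^2)$,
untruncated (no stated bounds); marker marginal means/SDs
1.06/0.58, 1.17/0.77, 1.11/0.43 MOM.  Where the study reports no value we
fixed, once:

* **Prevalence** ~0.25 at the covariate means (the top of the 9.8–25.5%
  range quoted for GDM; higher prevalence also keeps the diseased class
  large enough to estimate), with mild positive age and BMI effects
  ($\alpha_1 = \alpha_2 = 0.1$ per unit).
* **Disease shifts**: the study never reports per-class marker moments,
  but it *does* report the per-marker overlap diagnostics 0.29, 0.37,
  0.32 — and for two equal-variance normals the overlap
  $2\Phi(-\delta/2)$ inverts to standardized shifts of 2.12, 1.79 and
  1.99 within-class SDs.  The defaults use exactly those shifts (uE3
  negative), so the generator reproduces the one separation statistic the
  study actually printed.  A flat 1.0-SD shift was considered and
  rejected: it implies overlap 0.62, which the source literature itself
  labels as the regime where latent class estimation breaks down — and
  where this sampler demonstrably collapses.
* **Within-class correlation** 0.2 (none reported; configurable,
  including 0), identical $\Sigma_0 = \Sigma_1$ by default.
* Intercepts are back-solved so the *marginal* mixture moments match the
  printed means/SDs at the default prevalence; covariate main effects on
  markers default to 0.

What the generator does *not* emulate: OGTT outcomes, gestational-age
dynamics, the raw-assay-to-MOM transformation, missing data, and any
non-normality of real MOM distributions (real MOM values are positive
and right-skewed; a normal with SD 0.43–0.77 around 1 occasionally
produces negative values).  With ~2-SD class separation the *marginal*
mixture is also detectably non-normal at $n = 523$, so the KS preflight
can warn on perfectly healthy synthetic data — one more reason it is
advisory, not a gate.

## Diagnostics

Posterior summaries are the table columns of the source analyses: mean,
median, SD, Monte-Carlo error, equal-tailed 95% credible interval.  "MC
error" is concretized as the batch-means standard error with
$\lfloor\sqrt N\rfloor$ batches (the quantity is named in the source but
no estimator is given; batch means is the standard choice and reduces to
$s/\sqrt N$ on iid chains).  Geweke's $z$ compares the first 10% and last
50% window means, with window variances from the spectral density at
frequency zero estimated by Bartlett-windowed autocovariances (lag window
$\lfloor\sqrt n\rfloor$).  Autocorrelations come from the standard sample
ACF with lag 0 pinned to 1.  The pipeline flags a run when more than 20%
of monitored parameters have $|z| > 3$.

## Numerical choices, edge cases

* Youden cutoff: density-intersection quadratic; equal variances (within
  relative $10^{-10}$) take the midpoint branch; no real roots fall back
  to a 10001-point grid.
* Overlap: closed-form via crossing points, log-density interval tests.
* Logistic terms use `log1p(exp(·))` with a linear tail above 30.
* $(\Sigma_0+\Sigma_1)a = \Delta$ solved by Cholesky; a singular sum
  raises an error suggesting regularization.
* Empty cohort (`n = 0`) is returned with all declared columns; constant
  marker vectors and non-PD covariances error with the offending name.
* Chains are seeded `seed + chain - 1`; identical config + seed gives
  bit-identical draws, and pipeline CSV output is printed through a fixed
  `%.10g` format so reruns are byte-identical.

## Known limitations

The weak-identifiability regime deserves honesty: at overlap ≈ 0.32
(the single-marker world with a 2-SD shift) and $n = 1000$, the
*likelihood itself* occasionally places its global mode at a visibly
different mixture decomposition (e.g. prevalence 0.8 instead of 0.3) —
an EM check confirms this is not a sampler artifact.  Posterior means can
then sit several posterior SDs from the generating values for unlucky
datasets even though interval coverage remains near nominal.  This is a
property of binormal mixtures, is exactly what the overlap diagnostic is
for, and is materially milder in the joint three-marker model, where the
shared latent class is far better identified.  Single-marker accuracy
estimates at moderate overlap should be read with their credible
intervals, never as point estimates.
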
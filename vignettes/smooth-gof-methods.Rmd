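---
title: "Smooth goodness-of-fit testing for the negative binomial in sequence count data"
author: "smoothNB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smooth goodness-of-fit testing for the negative binomial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smoothNB)
```

## The problem

RNA-Seq and 16S microbiome count tables are routinely analysed with
negative binomial (NB) regression: for one feature and samples
$i = 1,\dots,n$,
$$ Y_i \sim \mathrm{NB}(\mu_i, \phi), \qquad
   \log \mu_i = \beta_0{}_i + \beta_1 + \beta_2 x_i, $$
with $\beta_{0i} = \log(\text{library size}_i)$ an offset with unit
coefficient, $x_i \in \{0,1\}$ the two-group dummy, and $\phi > 0$ the
overdispersion in the parameterisation
$\operatorname{Var} Y = \mu(1 + \phi\mu)$.  Whether the data actually
follow this distribution is rarely tested, although downstream error
control (FDR in differential-abundance scans) rests on it.  This package
provides a dedicated goodness-of-fit (GoF) test for the NB assumption in
exactly this regression setting, machinery to summarise lack of fit over
thousands of features, and a study design that quantifies what lack of
fit does to NB-based tests.

## The smooth test

The NB null is embedded in an exponentially tilted family
$$ f_J(y) \;\propto\; \exp\!\Big(\sum_{k=1}^{J} \theta_k
   h_k(y;\mu,\phi)\Big) f(y;\mu,\phi), $$
and the GoF null hypothesis is $\theta = 0$.  The test is the efficient
score test for $\theta$: with h-functions that are (i) orthonormal under
the fitted NB and (ii) orthogonal to the score functions of the nuisance
parameters $(\beta, \phi)$, the components
$$ V_k = n^{-1/2} \sum_{i=1}^{n} h_k(y_i; \hat\mu_i, \hat\phi) $$
are asymptotically independent standard normal and
$T_J = \sum_k V_k^2$ is asymptotically $\chi^2$ with one degree of
freedom per retained component.  Orthogonalising the h-functions against
the nuisance scores (rather than correcting the information matrix)
makes the Fisher information of $\theta$ proportional to the identity,
which is what gives the clean sum-of-squares decomposition.

Because the means $\hat\mu_i$ are sample-specific (offsets differ), the
h-system is constructed separately at every sample's
$(\hat\mu_i,\hat\phi)$; with constant offsets within a group this
reduces to a per-group construction.  Components are aligned across
samples by their monomial degree.  Polynomial h-functions are used so
that components have a moment interpretation: the degree-3 component
responds to skewness misfit, the degree-4 component to kurtosis misfit.
Since the dispersion score contains $\psi(y + 1/\phi)$ (digamma), which
is not a polynomial, the span that the h-functions must avoid is
$\{1, y, \psi(y+1/\phi)\}$; retained components may therefore carry a
digamma term themselves.  With the default order $J = 4$, the retained
components have monomial degrees 2–5 and the test has 4 degrees of
freedom; degenerate directions (e.g. the dispersion direction in the
Poisson limit) are detected by a relative norm threshold of $10^{-10}$
and dropped, and the degrees of freedom follow the retained count.

### Numerical construction

Inner products under the fitted NB are needed for monomials up to degree
$2(J+2)$ and for the digamma direction.  Polynomial inner products use
exact central moments computed by the variance-function recursion
$m_{k+1} = V(\mu)\,(m_k' + k\, m_{k-1})$ with $V(\mu)=\mu(1+\phi\mu)$,
whose polynomial coefficients are all positive — no cancellation, machine
precision at any parameter value.  Digamma-direction products are
truncated sums run to the $1-10^{-12}$ NB quantile and extended until the
remaining terms are negligible for the highest-degree integrand.

The delicate part is conditioning.  Near the Poisson limit the
dispersion score is numerically collinear with the affine-plus-quadratic
polynomial span (to $\sim 10^{-6}$), and a textbook Gram–Schmidt on the
Gram matrix loses twice that many digits — catastrophically.  The
construction therefore (i) replaces the raw digamma direction by its
affine-reduced form $g_2(y) = \psi(y+a) - \psi(a) - \psi'(a)\,y$
(computed termwise, no floating cancellation), (ii) builds orthonormal
polynomials $P_0,\dots,P_{J+2}$ first, (iii) expresses $g_2$ in that
frame with its non-polynomial remainder $\rho$ as one extra orthonormal
coordinate, and (iv) performs the remaining orthogonalisation as plain
Euclidean Gram–Schmidt in that frame, in extended precision.  When
$\|\rho\|^2$ falls below $10^{-8} \langle g_2, g_2\rangle$ (the noise
floor of the grid sums), $g_2$ is treated as exactly polynomial; this
changes score-orthogonality by at most $\|\rho\|$ — measured below
$10^{-12}$ — and keeps component coefficients small.  The resulting
system satisfies orthonormality and score-orthogonality to about
$10^{-9}$ for $\mu \in [0.3, 150]$ and $\phi \in [0.25, 2]$.  In extreme
corners (very small $\phi$, or $\phi\mu \gtrsim 10^3$) the component
norms can still lose digits through the polynomial Gram conditioning;
inference there rests on the parametric bootstrap, which applies the
identical construction to observed and resampled data and is therefore
insensitive to such representation error.

## P-values: asymptotics fail, the bootstrap works

At $n = 50$ the $\chi^2$ reference is unusable — its p-values fail
uniformity grossly under the null (the test suite demonstrates this on
the reference designs).  The package therefore computes a full parametric
bootstrap: draw $y^*_i \sim \mathrm{NB}(\hat\mu_i, \hat\phi)$, refit all
of $(\beta,\phi)$, rebuild the basis at the refitted parameters,
recompute $T^*$; the p-value is $(1 + \#\{T^* \ge T\})/(B+1)$, which
cannot be exactly zero.  Refits are warm-started at the observed fit,
cold-restarted on failure, and the replicate is redrawn if both fail;
features whose redraw count exceeds 10% of $B$ are flagged and skipped.
The refit of the dispersion in every replicate is the default (a
held-dispersion variant, `refitDispersion = FALSE`, refits only the
regression coefficients); in the packaged studies both modes give
null-uniform p-values for the features they can test.

Large overdispersion degrades the procedure, but in this implementation
the degradation is explicit rather than silent: as $\phi$ grows past 10,
an increasing share of features fails the convergence guards or the
bootstrap redraw cap and is excluded with a reason, while the p-values
of the surviving features remain calibrated.  On the reference grid the
testable share falls from essentially all features at $\phi \le 1$ to
roughly a quarter at $\phi = 30$.  Matrix-wide testing additionally
skips features with $\hat\phi \ge$ `maxPhi` (default 10) — they keep
their dispersion estimates in the output so the dispersion distribution
can still be summarised.

### Model fitting

Maximum likelihood over $(\beta, \log\phi)$ alternates iterated
reweighted least squares for $\beta$ with a safeguarded Illinois
root-search of the dispersion score in $\log\phi$; $\beta$ is initialised
from a Poisson fit and $\phi$ from a method-of-moments estimate on the
Poisson residuals.  Convergence requires a relative log-likelihood change
below $10^{-10}$ and a maximum absolute score below $10^{-6}$, within 200
iterations.  $\phi$ is constrained to $[10^{-8}, 10^8]$.  The lower bound
is the Poisson limit: when counts are under-dispersed relative to
Poisson, the likelihood is maximised on the boundary — this is a regular,
admissible fit (roughly half of all refits under a true $\phi$ near zero
land there) and is reported as converged with a flag, while the upper
bound signals a genuine failure.  The dispersion score is evaluated in a
cancellation-free form (rising-sum digamma differences), which matters
below $\phi \sim 10^{-3}$.

At $n = 50$ the ML dispersion estimate carries an intrinsic downward
median bias of just under 5% at $\phi = 1$ (no degrees-of-freedom
correction is applied for the two estimated regression coefficients),
and far larger bias with strong right-skew at $\phi = 0.01$; scarce
counts amplify both.  `dispersionSamplingStudy()` reproduces this and by
default holds the feature baseline fixed at a moderately abundant level
(mean counts around 70) so the $\phi$-grid comparison is not confounded
by abundance.

## Estimating the fraction of poorly fit features

The GoF p-values across features follow the mixture
$g(p) = \pi_0 g_0(p) + (1-\pi_0) g_A(p)$ with $g_0$ uniform and $g_A$
decreasing.  `grenanderFit()` estimates $g$ by the modified Grenander
estimator — the left derivative of the least concave majorant of the
empirical CDF, the natural monotone-decreasing density estimate.
Assuming $g_A$ vanishes above a cutoff $p_c$, the null proportion is the
tail count over the null tail mass,
$\hat\pi_0 = \min\{1, \#\{p_k > p_c\}/(n(1-p_c))\}$, and $1-\hat\pi_0$
is the lack-of-fit fraction.  The default cutoff is $p_c = 0.75$: a
data-driven cutoff at the point where the Grenander density first drops
to 1 is available (`pcMethod = "crossing"`), but it is biased when the
alternative density has a heavy right tail and unstable under a pure
null, while the fixed conservative cutoff behaves well in both regimes.
The standard error is a nonparametric bootstrap over features (the
error-bar construction is a documented package choice; 200 resamples by
default).  Because the estimator only uses the shape of the p-value
distribution, modest bootstrap resolution upstream suffices — estimates
from $B = 50$ and $B = 1000$ p-values agree closely, which is what makes
matrix-wide auditing affordable.

q-values are Benjamini–Hochberg adjusted p-values scaled by
$\hat\pi_0$; features with $q < 0.1$ are conventionally labelled poorly
fit.

## The zero-inflation screen

`fitZINB()` fits the mixture
$\pi 1\{y=0\} + (1-\pi) f(y;\mu,\phi)$ with the same regression mean and
a covariate-free $\pi$ on the logit scale (direct maximisation warm-
started from the NB fit, EM fallback, and the boundary value $\pi \to 0$
— which recovers the NB exactly — taken whenever the optimiser lands
below it).  Features without a zero observation leave $\pi$
unidentifiable and are flagged rather than fitted.  The likelihood-ratio
statistic is referred to the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ by default (the $\chi^2_1$
convention is available), since $\pi = 0$ sits on the parameter
boundary.

Summarising zero inflation over a matrix needs care: under the boundary
null about half of all LR statistics are exactly zero, so the p-values
are *not* uniform and cannot go into the Grenander machinery directly.
`zinbScreen()` conditions on a positive statistic — there
$p' = P(\chi^2_1 > \mathrm{LR})$ is null-uniform — estimates the null
proportion among those, and scales the alternative fraction by the
positive-statistic proportion.  The reported fraction refers to
ZINB-fittable features only and can overestimate dataset-wide
prevalence when many features have no zeros.

## The mock relabelling study

To measure consequences of lack of fit, samples are re-allocated to two
pseudo-groups at random (Bernoulli(½), redrawn if a group would have
fewer than two samples), so that any rejection is a false positive.  Per
feature, two tests of the random grouping are run: the NB Wald test
(design: intercept, original group, random group; standard error from
the observed information at the MLE; standard normal reference,
two-sided) and the Prentice stratified rank-sum test (midranks within
strata of the original group, permutation variance with midrank tie
correction, van Elteren weights $1/(N_s+1)$; with one stratum it reduces
exactly to the normal-approximation Wilcoxon test).  Repetitions and
tabulation of $\Pr(p < \alpha)$ by test and by poorly/well-fit group are
handled by `runMockStudy()`.

On truly-NB data both tests sit near the nominal level (the Wald test a
few points above it — the usual finite-sample anticonservatism of ML
Wald tests at $n = 50$).  The misfit arm of the packaged study uses rare
multiplicative outliers: misfit that the NB can absorb into its
dispersion estimate (such as uniform structural zeros) inflates the
standard errors along with the variance and does not raise the mock
type-I error, whereas heavy-tailed contamination that no NB can match
does.  On such data the Wald proportion rises sharply on the poorly fit
features while the rank test stays nominal in both groups — the
package's headline contrast, and the basis for the recommendation that
`nbAudit()` prints: when an appreciable fraction of features is poorly
fit by the NB, prefer nonparametric tests.

## The synthetic-data generator

`simulateDataset()` draws from the reference design: $p = 500$ features,
$n = 50$ samples balanced over two groups, log-depths
$\beta_{0i} \sim N(9.21, 1.15^2)$ (natural logs; a typical depth of
$e^{9.21} \approx 10^4$), baselines
$\beta_{1j} \sim U(-13.8, -6.91)$ (relative abundances
$10^{-6}$–$10^{-3}$), log-fold change $\beta_2 = 2$, and a single
overdispersion $\phi$ (grid $\{0.01, 0.1, 1, 10, 20, 30\}$ in the
studies).  Counts are Gamma–Poisson draws with shape $1/\phi$, exactly
the $\mathrm{Var} = \mu(1+\phi\mu)$ parameterisation.  Library sizes of
the returned object are the generating depths, so fitted offsets match
the generating model.  Misfit variants (structural zeros, dispersion
heterogeneity, multiplicative outliers) perturb a configurable fraction
of features and are recorded in the truth table.

What the generator emulates is the marginal count behaviour of
sequencing data under an exactly-true NB null (or controlled departures
from it); what it does not emulate are compositionality, feature-feature
correlation, batch structure, or realistic library-size estimation error.
Tests passing on these data therefore validate the machinery — type-I
error control, estimator calibration, power against gross misfit — not
the claim that any particular real dataset is well fit.

### Study designs and problem sizes

The packaged studies use sizes chosen to give stable Monte-Carlo
estimates at desk scale: the null-uniformity grid runs 150 features per
$\phi$ with $B = 150$ bootstrap replicates in the reproduction script
and $B = 120$ in the test suite; 20 random allocations over 150--200 features
for the mock study; 300 features for the zero-inflation screens; 500
replicate features per $\phi$ for the dispersion study.  Two designs deviate deliberately from the reference
priors, for identifiability rather than convenience: the zero-inflation
recovery draws baselines from $U(-9.21, -4.61)$ (moderate abundance)
and the misfit arm of the mock study from $U(-6.91, -4.61)$ (abundant
features), because structural zeros are information-theoretically
invisible in features whose NB already produces mostly zeros — at the
reference abundances the majority of inflated features cannot be
detected by any method, and a recovery check there would measure
abundance, not the estimator.

## Known limitations

* The bootstrap p-value floor is $1/(B+1)$; FDR-style analyses needing
  very small p-values need a larger $B$ than the lack-of-fit fraction
  does.
* Features with $\hat\phi \ge 10$ are not bootstrap-tested; datasets
  dominated by such features (some human microbiome data) can only be
  partially audited, and the lack-of-fit fraction then refers to the
  testable subset.
* The two-group design with log library-size offsets is the only
  supported mean structure (an internal general-design fitter exists for
  the mock study's three-column design).
* Near-Poisson dispersion ($\phi \lesssim 0.1$) and extreme products
  $\phi\mu \gtrsim 10^3$ degrade the orthonormal system's numerical
  precision as described above; bootstrap inference remains valid there,
  asymptotic component interpretation does not.
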
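---
title: "Detecting irreducible dictionaries of anomalous binary patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting irreducible dictionaries of anomalous binary patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given `M` samples of `N` binary units — spike/no-spike in 2 ms bins of a
premotor window, presence/absence of a mutation, and so on — we want the
*dictionary* of the underlying distribution: the set of unit subsets
("words") whose joint activation is statistically over- or under-represented
relative to an independent-unit null model that matches every unit's marginal
frequency. Two features make this hard at realistic sample sizes
(`M ~ 100...1000`, `N ~ 20`): the number of potential words is `2^N - 1`, and
words overlap, so a single statistical anomaly can be "explained" by many
related subsets. A useful dictionary must be *irreducible*: an anomaly should
be attributed to the one word that explains it best, not to its whole family
of sub- and super-words.

## The model

Write the distribution as a log-linear model with one coefficient per subset,
and attach to every word `mu` a binary indicator `s_mu` saying whether that
coefficient is in the model. Under a strong-regularisation prior (all
coefficients small, inverse regularisation strength `eps << 1`), integrating
the coefficients out around the prior peak and expanding to second order in
`eps` leaves a *pairwise Ising model over the indicators*:

    P(s | data) ∝ exp( eps * sum_mu h_mu s_mu
                       + eps^2 * sum_{mu != nu} J_munu s_mu s_nu )

with closed-form fields and couplings built from the empirical frequency
`sigma_bar_mu = n_mu / M`, the null expectation `<sigma_mu> = prod n_i / M`
and the null variance/covariance of the word indicators:

    h_mu    = (M^2 / 2) [ (sigma_bar_mu - <sigma_mu>)^2 - var(sigma_mu) / M ]
    J_munu  = (M^2 / 4) cov(sigma_mu, sigma_nu)
              [ cov(sigma_mu, sigma_nu)
                - 2 M (sigma_bar_mu - <sigma_mu>)(sigma_bar_nu - <sigma_nu>) ]

The field is positive exactly when a word's deviation from its null
expectation exceeds the null standard error — over- and under-representation
count equally — and negative when the frequency is as expected. The coupling
is nonzero only for overlapping supports and is predominantly *negative* when
two words are expected to be correlated and co-occur about as much as
expected: overlapping candidates then compete for inclusion, which is what
makes the extracted dictionary irreducible. A derivation detail worth
recording: the second term in the coupling bracket carries a factor `2M`
(it is the product of two first-derivative terms of the log-likelihood, each
proportional to `M`); without it the couplings would be almost always
positive and no competition would occur.

Marginal inclusion probabilities are computed by naive mean field on the
magnetizations `m_mu = 2<s_mu> - 1`:

    atanh(m_mu) = (eps/2) [ h_mu + eps sum_nu J_munu
                            + eps^2 sum_nu J_munu m_nu ]

iterated to a fixed point while `eps` grows from 0 (total ignorance,
`m = 0`) in steps of `1/(20 M)` up to `eps_max = min(eps1, eps2)`:
`eps1 = 1/M` is where the prior width reaches the likelihood width, and
`eps2` is the last grid point at which the mean coupling correction still
stays below the mean field term (`mean|h| >= mean|eps * h_eff|`). We keep the
printed form of the self-consistency equation, with `eps^2` on the
magnetization-feedback term; a textbook naive-mean-field derivation of the
indicator Hamiltonian gives `eps` there instead, but the two differ at higher
order in `eps` than anything retained by the expansion, and both stay within
the solver's acceptance band against exact enumeration (below). TAP
corrections are likewise higher-order here and are not implemented.

## The pipeline and its tunable parameters

`isingdict()` runs, in order:

1. *(optional, `flip = FALSE`)* complement any column active in more than
   half the samples (`sigma -> 1 - sigma`). The absent-word analysis below
   requires mean activation below 1/2; columns at exactly 1/2 are left
   alone (the boundary choice is ours — the rule is stated as strict).
   Reported supports are unchanged; the flip mask is recorded.
2. Candidate enumeration over all supports of order `k_max` or less
   (`k_max = 5`): every support that occurs at least once, plus absent
   supports whose null-expected count `M * <sigma_mu>` is at least
   `absent_threshold = 0.02` — such words can be significantly
   *under*-represented. Absent words below the threshold have fields of
   order `M q^k` with `q^k M << 1` and cannot be detected; at activation
   `q ~ 0.2` this makes orders beyond 4-5 pointless, hence the `k_max`
   default. Constant columns are excluded: their null variance is zero and
   their words carry no signal.
3. Top-`n_max` selection (`n_max = 500`) by absolute field, ties broken by
   lower order then lexicographic support so reruns are identical.
4. Couplings among the retained candidates and the mean-field sweep.
   Fixed-point iteration warm-starts at each `eps` from the previous one,
   with convergence at max-norm `1e-10`, a 1000-sweep cap (non-convergence
   is warned about, never silent) and a 0.5 damping factor that engages
   only if the residual grows (the iteration scheme is our choice; at
   `eps <= 1/M` the map is strongly contractive in practice).
5. Threshold calibration: each of `shuffles` (default 100) column-wise
   permutations of the data — marginal counts are preserved exactly,
   dependence is destroyed — is run through steps 2-4, and `n_false(m)` is
   the mean number of shuffle words with magnetization above `m`. The
   threshold grid is the set of observed shuffle magnetizations (exact
   inversion, no lattice), and the dictionary admits words with
   `m_mu > m*`, where `m*` is the smallest threshold with
   `n_false <= n_false_target` (default 0.5: half a false word per
   dataset on average). Calibration is per dataset.

Words containing a designated output unit (`behavior_col`) are flagged as
*codewords*. The diagonal coupling `J_mumu` is excluded from the indicator
sums: an indicator squared is itself, so the diagonal would only shift fields
at second order, and the expansion does not distinguish that shift from the
terms already kept.

## The synthetic benchmark

`pattern_model()` draws the generative models used to validate the method:
`N = 20` units with biases `theta_i ~ N(-0.7, 0.1^2)` — under the `{0,1}`
convention used here the interaction-free marginal is
`p_i = 1/(1 + exp(-2 theta_i)) ~ 0.2`, matching sparse spiking data (the
bias enters the log-probability as `2 theta_i` per active unit precisely so
that this printed marginal relation holds) — and `K = round(alpha N / 3)`
planted interactions split as evenly as possible across orders 2, 3 and 4
(the density `alpha`, interactions per unit at mean order 3, spans tree-like
to lattice-like networks at 2-4). Strengths come from an equal-weight
mixture of two Gaussians at `+/-0.5` (sd 0.1) — weights are not dictated by
the construction, so we take them equal — or from one zero-mean Gaussian
(sd 0.5). Supports are distinct but may nest (a planted quadruple may
contain a planted pair); nothing in the construction forbids it.
Sampling is by exact enumeration of all `2^N` states for `N <= 22` (no
mixing-time concerns at this scale); a single-site Gibbs sampler with a
5000-sweep burn-in and thinning 10 covers larger systems.

Scoring is strict: a detected word is a true positive only if its support
*equals* a planted support; sub- and super-words count against precision.
Precision is the fraction of dictionary words that are planted; recall the
fraction of planted interactions recovered.

What the generator does *not* emulate about real recordings: temporal
non-stationarity, refractory structure between neighbouring bins, and
marginals near 1/2 (real firing rates can cross 50% in some bins, which is
what the flip rule is for). Passing benchmarks therefore demonstrate
correctness of the inference machinery under the stated generative family,
not robustness to those effects.

## Numerical choices and problem sizes

* Counting is exact integer arithmetic (bitmask row encodings in compiled
  code); null moments are floating point. Null covariances use
  `exp(a+b) * expm1(-c)` so that disjoint supports give exactly zero.
* The calibration and benchmark runs shipped with the package use 40
  shuffles per dataset and 25 replicate models per interaction density
  (50 in total) at `M = 1600`; the false-discovery target resolution at 40
  shuffles is 0.025 words. These are the package's benchmark problem
  sizes; the method itself is indifferent to them.
* The mean-field solver is validated against exact enumeration of the
  indicator distribution (feasible to 20 candidates; the acceptance suite
  uses 100 random systems of up to 12) with an acceptance band of 0.05 in
  absolute magnetization at `eps <= eps_max`. The closed-form fields are
  validated against Richardson-extrapolated numerical derivatives of the
  exact log-likelihood at the independent-model saddle, at relative
  tolerance `1e-6`.
* Degenerate inputs: non-binary entries are rejected with the offending
  row/column (never coerced); an all-constant dataset yields an empty
  candidate set and an empty dictionary (a legal outcome); an unreachable
  false-discovery target warns and falls back to the top of the threshold
  grid; if the perturbative bound fails already at the first `eps` step,
  that step is used and a warning is raised.

## The neural front end

Spike-time trials are binarised on a half-open 2 ms grid over the 40 ms
window preceding the behavioural measurement (20 bins; a spike exactly on a
boundary belongs to the later bin — the half-open convention keeps the bins
a partition, and boundary spikes have measure zero in recorded data). The
scalar behaviour (pitch, amplitude, spectral entropy, ...) is binarised by
median split (ties at the median go to 0; a polarity flag swaps sides),
by 20-percentile window, or by terciles; percentile ranks use average ranks
for cross-platform reproducibility. The behaviour bit is column 1 of the
assembled dataset (index 0 in serialised output), giving `N = 21` units for
a 20-bin window. Analysing the same data with both polarities provides a
consistency check: a spike pattern must not be anomalous in the same
direction for both labellings, and the count of such contradictions
estimates the false-positive load.

## Predictive validation

To check that codewords are informative and not merely statistically
anomalous, `compare_predictors()` fits two ridge-penalised logistic
regressions of the behaviour bit — one on the 20 raw time-bin columns, one
on the codeword activation features (active iff all bins of the word are
active) — and compares held-out accuracy and mean cross-entropy under
stratified twofold cross-validation. The penalty default is
`lambda = 0.1` with the intercept unpenalised (the penalty exists to keep
separated fits finite, not to select features; the sum in the penalised
objective is read as excluding the intercept, which is the standard
convention). The fit is a Newton iteration on the exact penalised
likelihood, so the first-order conditions hold to near machine precision
and restarts agree. The comparison requires at least 4 codewords, else it
is skipped with a reason.

## Known limitations

* The null model is the product of marginals; anomalies relative to richer
  nulls (e.g. preserving pairwise correlations) are out of scope.
* Only symmetric co-occurrence structure is detected; no causality, no
  temporal directionality, and stationarity across samples is assumed.
* The large-field pruning fraction — among candidates whose field magnitude
  exceeds the weakest dictionary word's, the share removed by couplings —
  is small in the synthetic benchmark regime (`M = 1600`, activation
  `~0.2`): there the coupling corrections `eps * sum(J)` are a few percent
  of the fields, so few large-field words can be displaced. It grows
  sharply when many strongly overlapping words compete (as in dense
  neuro-behavioural dictionaries, where it can exceed one half). It is
  reported as computed by `scripts/acceptance.R`.
* Enumeration is exhaustive up to `k_max`; occurring words of higher order
  are not considered, and the compiled enumerator supports up to 52
  non-constant columns.

## A worked call

```{r, eval = FALSE}
library(isingdict)
model <- pattern_model(n_units = 20, alpha = 2)   # draw a generative model
data <- simulate(model, M = 1600, seed = 1)       # sample a dataset
fit <- isingdict(data, shuffles = 40, seed = 2)   # calibrate + extract
summary(fit)
score_dictionary(fit, model)                      # precision / recall
```
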
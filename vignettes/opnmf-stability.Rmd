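---
title: "Factorizing psychometric scores with OPNMF and split-half stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Factorizing psychometric scores with OPNMF and split-half stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opnmfcv)
```

## The problem

Executive-function batteries such as the D-KEFS produce a handful of
non-negative, age-corrected scaled scores per subject (17 total achievement
scores in the canonical battery). Which latent dimensions organize those
scores is contested: exploratory factor analysis (EFA) applied to such data
has produced many mutually incompatible models, partly because the number of
factors retained is sensitive to the retention rule and generalizes poorly
across samples. `opnmfcv` implements an alternative: factorize the score
matrix with orthonormal projective non-negative matrix factorization
(OPNMF) and choose the number of factors by split-half cross-validation,
preferring the solution that is *stable* (independent halves assign items to
the same factors) and *generalizable* (a basis fitted on one half
reconstructs the other half almost as well as its own). PCA and EFA with
promax rotation, scree diagnostics, Horn's parallel analysis and the
Tucker-Lewis index (TLI) are provided as the comparison arm.

## The OPNMF model

Let $X$ be the $p \times n$ items-by-subjects matrix of non-negative scores.
OPNMF seeks an element-wise non-negative basis $W \in \mathbb{R}^{p\times k}$
minimizing

$$ \lVert X - W W^\top X \rVert_F^2 , $$

i.e. it approximates the data by its projection onto the cone spanned by
$W$. Because $W$ is simultaneously the projection and the reconstruction
map, minimizing this objective drives $W$ toward non-negative, nearly
orthonormal columns — and non-negative orthogonality forces near-disjoint
support, so each item ends up dominated by a single factor. The factor
loading matrix is $H = W^\top X$, and each item is assigned to the factor
holding its largest basis coefficient (ties toward the lower factor index;
an all-zero row goes to factor 1 with a warning).

Fitting uses the multiplicative update

$$ W \leftarrow W \circ \frac{A W}{W (W^\top A W)}, \qquad A = X X^\top, $$

with $A$ precomputed once ($p \times p$ is tiny at $p = 17$, so iteration
cost is independent of the number of subjects). Two numerical safeguards
matter:

* a guard of $10^{-16}$ is added to the denominator so converged zero
  entries never divide by zero;
* after every update $W$ is rescaled to unit spectral norm. The raw rule is
  scale-sensitive and oscillates without this; with it the recorded
  objective trace is non-increasing in practice, which the tests assert at
  a relative slack of $10^{-9}$.

Column normalization to unit Euclidean norm, deterministic column ordering
(descending loading mass, ties by the row index of the column maximum) and
item assignment happen once at finalization; the scale is absorbed into
$H$.

### Initialization and convergence

The default start is NNDSVD-a: per singular triplet keep the sign-consistent
half pair with more mass, then replace zeros by the data mean. It is
deterministic, which makes the headline pipeline fully reproducible without
seed bookkeeping; `init = "random"` (uniform entries scaled to the data
magnitude) is available for restart experiments. Default stopping is a
relative objective change below $10^{-5}$ or 50,000 iterations. These values
are conventional for this family of algorithms; the method's originating
implementations do not document theirs. One property worth knowing:
multiplicative updates have a slow tail, so driving the reconstruction error
of noiseless, exactly representable data below $10^{-6}$ takes on the order
of $2 \times 10^6$ iterations (a few seconds at $p = 17$). The test suite
uses that deep-convergence profile (`tol = 0, max_iter = 2e6`) only where
exactness itself is the property under test.

## Split-half stability selection

For each candidate rank $k$ (default 2–9) and each of `n_splits` independent
half-splits of the subjects (the production default is 10,000; 50–200 gives
readable curves in minutes), OPNMF is fitted on each half and four criterion
families are recorded:

* **Adjusted Rand index (ARI)** between the two halves' item partitions
  (chance-corrected; 1 = identical up to relabeling);
* **Variation of information (VI)**, the entropy-based partition distance
  (0 = identical; bounded by $\ln p$);
* **Concordance**: basis columns are matched one-to-one by maximizing
  summed Pearson correlation (an exact linear-assignment solve), then Lin's
  concordance correlation coefficient is averaged over matched pairs. The
  source literature names a "concordance index" without restating its
  formula; matched mean CCC is our documented operationalization because it
  scores agreement of the *whole entries*, not just the induced partition.
  A Pearson variant sits behind `method = "pearson"`.
* **Out-of-sample error increase**: the mean of the two transfer errors
  (reconstructing each half through the other half's basis) minus the mean
  within-half error. The transfer direction is symmetrized because neither
  direction is privileged.

`select_rank()` ranks the candidate $k$ on each criterion (maximize ARI and
concordance, minimize VI and error increase), averages the four ranks, and
returns the best average; exact ties go to the smaller $k$ (parsimony).
Splits are expressed in subject ids, so results are invariant to column
order; with `stratify_by`, halves balance each group to within one subject.
Aggregates report mean, SD and the 5th/95th percentile band per rank.

## PCA and EFA comparison arm

The baselines work on the item correlation matrix. PCA loadings are
eigenvectors scaled by root eigenvalues with a positive-largest-entry sign
convention. EFA defaults to minimum-residual (minres/ULS) extraction —
uniquenesses chosen to minimize the sum of squared discarded eigenvalues of
$R - \Psi$, optimized by L-BFGS-B with analytic gradients from
eigenvalue perturbation theory and squared-multiple-correlation starts —
because that is the default of the common desktop tools this package
parallels; `method = "ml"` delegates to `stats::factanal()`. Model fit uses
the ML discrepancy at the solution with Bartlett's correction factor
$(n - 1 - (2p+5)/6 - 2k/3)$, the null model from $-\log\lvert R\rvert$, and
the TLI from the two $\chi^2/df$ ratios (not clipped to $[0,1]$).

Promax rotation is the textbook two-stage construction: Kaiser-normalized
varimax (SVD iteration), an element-wise power-$\kappa$ target with signs
preserved ($\kappa = 4$ by default), least-squares target fit, and column
rescaling so the factor correlation matrix $\Phi$ has unit diagonal. With
Kaiser row-normalization the pattern matrix is not an exact right-multiple
of the unrotated loadings (the same is true of the reference implementation
in `stats`); the exact identity `loadings == L %*% rotmat` holds for the
unnormalized varimax core and is tested there.

Rank retention uses Horn's parallel analysis: eigenvalues of `n_sim`
standard-normal datasets of matching shape, per-position 95th-percentile
thresholds (the mean is available by flag), retaining leading observed
eigenvalues that strictly exceed their threshold and stopping at the first
failure. For PCA the raw correlation spectrum is used. For EFA retention the
pipeline uses the *reduced* correlation spectrum (squared multiple
correlations on the diagonal, `basis = "efa"`): the two spectra genuinely
answer different questions (components vs common factors), and only the
reduced-spectrum variant reproduces the empirically observed divergence
where EFA retains finer structure than PCA on hierarchically organized
batteries. The scree elbow (largest second difference of the spectrum) is
reported as advisory only — scree reading is a judgment call, and the
automated value never feeds rank selection.

## The synthetic generator

Because the motivating dataset is access-controlled, the package ships a
generator that emulates its statistical regime rather than its marginals:

* `generate_basis(p, k, overlap)`: items allocated evenly to factors
  (remainder to the lowest-index factors, so allocation is deterministic),
  one primary loading per item drawn from $U(0.8, 1.2)$, optional secondary
  loadings of relative magnitude `overlap` on a random half of the items,
  columns normalized to unit norm.
* `generate_scores()`: subject factor scores are half-normal
  ($\lvert N(0,1)\rvert$) by default, log-normal(0, 0.5) under
  `skew = TRUE` to mimic the skewed marginals executive-function scores can
  show. Noise is additive Gaussian clipped at zero — the simplest contract
  that preserves non-negativity; clipping (rather than truncating and
  renormalizing) is recorded in the ground-truth metadata. Defaults are
  $p = 17$, $n = 334$, `noise_sd = 0.25`, matching the scale of the
  motivating study; at $p = 17$ items carry the canonical D-KEFS variable
  names.
* `generate_hierarchical()`: `k_fine` item blocks whose subject scores are
  correlated at `within_corr` inside each of `k_coarse` parent domains and
  at `within_corr / 4` across parents. Fine scores are shifted Gaussians
  (mean 3, clipped at 0) rather than half-normals: taking absolute values
  would shrink a target correlation of 0.7 to roughly 0.45, while the shift
  preserves it on the non-negative scale with negligible clipping.
* `generate_subgroups()`: multiple groups drawn from one basis with
  optional per-group loading perturbations, for gender/age-style subsample
  analyses. `generate_null()`: i.i.d. shifted Gaussians with no structure,
  for calibrating rank diagnostics.

What the generator does **not** emulate: the integer-valued scaled-score
marginals of real batteries, age-correction artifacts, item-level floor and
ceiling effects, and missingness mechanisms. Green tests therefore show
that the machinery recovers planted structure under realistic noise, not
that any particular empirical battery has two factors.

## Design choices and scaled-down defaults

Open choices were resolved as follows, and are deliberate:

* Matrix orientation is items-by-subjects so the basis is items-by-factors
  and "largest coefficient within the basis matrix" is a row argmax;
  data-frame loaders transpose the conventional subjects-as-rows table.
* No centering or z-scoring: centering would break non-negativity, and the
  intended input (age-corrected scaled scores) is already on a common scale.
* The final reported OPNMF solution refits on the entire (sub)sample at the
  selected rank, since one loading structure per sample is what gets
  interpreted.
* Age-style subgrouping in examples uses a threshold of 50 ("50 or under"
  vs "over 50").
* Test and vignette problem sizes: stability curves use 10–50 splits and
  rank-recovery experiments 20 replicates of 50 splits; these reproduce the
  10,000-split curves' ordering faithfully because the per-rank means
  stabilize quickly at $p = 17$.

## Worked example

```{r example, eval = FALSE}
x <- generate_hierarchical(p = 17, k_fine = 5, k_coarse = 2,
                           within_corr = 0.7, n = 334, seed = 1)
st <- run_stability(x, ranks = 2:9, n_splits = 50, seed = 2)
select_rank(st)$k_star          # 2: the coarse division wins
autoplot(st)                     # the four stability curves

parallel_analysis(x, basis = "pca", seed = 3)$k_parallel  # 2
parallel_analysis(x, basis = "efa", seed = 3)$k_parallel  # 5

report <- run_full_analysis(x, ranks = 2:9, n_splits = 50, seed = 4)
report
```

On hierarchical data the three routes disagree in a structured way: OPNMF
and PCA parallel analysis settle on the two coarse domains, while
EFA-basis parallel analysis retains the five fine blocks. That divergence
is not a bug — the methods weight shared variance differently — and
reproducing it is one of the package's acceptance properties.

## Known limitations

* The multiplicative update converges linearly; near-exact fits need the
  deep-convergence profile. No second-order acceleration is provided.
* Minres EFA assumes a well-conditioned correlation matrix; Heywood cases
  are flagged, not repaired.
* `concordance_index()` with zero-variance columns falls back to an
  equality check with a warning.
* Stability selection is only implemented for OPNMF; the baselines select
  ranks via scree/parallel analysis, mirroring common practice.
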
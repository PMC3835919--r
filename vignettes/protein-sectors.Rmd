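---
title: "Detecting coevolving protein sectors with bifanr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coevolving protein sectors with bifanr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifanr)
```

## The problem

Amino-acid positions in a protein family do not evolve independently.
Groups of positions whose substitutions are correlated across the family —
*protein sectors* — tend to be spatially contiguous in the tertiary
structure and to carry a coherent functional role (substrate specificity,
core stability, catalysis), while different sectors are close to
statistically and evolutionarily independent of one another. `bifanr`
detects such sectors from a multiple sequence alignment (MSA) alone, and
ships the statistical machinery to scrutinise what it found.

The method is alignment-statistical: it sees only the residue columns,
not a phylogeny or a structure. Its two distinctive ingredients are a
noise-reduction step that removes positions weakly coupled to everything
(these otherwise dilute the factor structure), and a *bi*-factor analysis:
eigenvectors of the coupling matrix are screened against a column-shuffle
null, varimax-rotated, and read out **bidirectionally** — both strongly
positive and strongly negative loadings can define a sector.

## The model, step by step

### Coupling matrix

Residues are encoded 1–20 (alphabetical one-letter order; gap and
ambiguity codes are 0). With $f_i^a$ the frequency of amino acid $a$ at
column $i$ (denominator: all $S$ sequences, so gaps dilute), and
$f_{ij}^{ab}$ the joint frequency, the raw covariance is

$$C_{ij}^{ab} = f_{ij}^{ab} - f_i^a f_j^b .$$

A conservation weight
$\phi_i^a = \ln\!\big[f_i^a (1-q^a) \,/\, (1-f_i^a) q^a\big]$
(the log-odds of the observed frequency against the background $q^a$,
pooled from the alignment) promotes conserved, surprising residues, in
the tradition of statistical coupling analysis. The weighted tensor is
collapsed over the amino-acid dimensions by the Frobenius norm,

$$W_{ij} = \Big[ \textstyle\sum_{ab}\big(\phi_i^a \phi_j^b C_{ij}^{ab}\big)^2 \Big]^{1/2},$$

giving a symmetric, nonnegative position-coupling matrix with zero
diagonal (self-coupling carries no coevolution signal). Frequencies are
clamped to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 1/(2S)$
before the logarithm so fully conserved or absent residues get large but
finite weights. Both the weight and the reduction are isolated behind
single functions (`conservation_weight()`, an internal reducer) so
alternative conventions can be swapped without touching the pipeline.

`weighted_correlation()` evaluates $W$ without materialising the
$L^2 \times 400$ tensor: writing $w = \phi^2$, $W^2$ expands into three
sums over amino acids that reduce to sparse one-hot crossproducts. The
tensor route (`covariance_tensor()` + `weight_and_reduce()`) is retained
for inspection and for the `"nongap"` denominator convention; the two
agree to $10^{-10}$ relative error, and are tested against a naive
triple-loop oracle.

### Noise reduction

For each site, $R_{\max}(i)$ is the mean of its top
$\lceil 0.05 (L-1) \rceil$ couplings; *plus* is the mean of $R_{\max}$
over sites. Sites with $R_{\max}(i) \le 0.8 \cdot plus$ are classified as
noise and removed before factor analysis (ties at the boundary are
removed — "no larger than" is read strictly). Both the 5% neighbour
fraction and the 0.8 factor are exposed parameters.

### Factor retention against a shuffle null

Each column of the alignment is permuted independently across sequences —
destroying inter-column correlation while preserving every single-site
frequency, hence the weights and background — and the full
coupling-matrix pipeline is recomputed; 100 shuffles yield the null
eigenvalue multiset $E$. For the observed eigenvalues
$\lambda_1 \ge \dots \ge \lambda_n$ of the reduced matrix, $N(i)$ counts
null eigenvalues strictly greater than $\lambda_i$, and the retained
factor count is the largest $t$ with $N(t) < 100$.

One design point deserves emphasis. The null is computed from the **whole
alignment**, not from the noise-reduced subset. Any nonnegative coupling
matrix carries a leading "Perron" eigenvalue set by its mean coupling
level, in both the observed and the shuffled data. Had the null been
restricted to the kept sites, the observed $\lambda_1$ would be
exchangeable with the null leading eigenvalues (the kept sub-alignment
shuffled is distributionally the kept sub-alignment, when no true
coupling exists), and $N(1) < 100$ — one spurious factor — would occur
with probability $\approx 100/101$ on pure-noise data. Drawing the null
from all $L$ columns makes the null Perron mode dominate (Cauchy
interlacing: the kept principal submatrix's $\lambda_1$ cannot exceed the
full matrix's), so uncoupled data is usually, though not always, rejected
— see *Limitations*.

### Varimax rotation and bidirectional selection

The $t$ retained eigenvectors are rotated to maximise the raw varimax
criterion $\sum_k [\, \overline{b^4_{\cdot k}} - (\overline{b^2_{\cdot
k}})^2 ]$ by classic pairwise planar rotations (Kaiser row-normalisation
is available behind a flag; raw varimax is the default since the source
convention is not fixed). Rotation is orthogonal, so per-site
communalities are preserved; sweeps stop when the criterion gain falls
below `tol`. Eigenvector signs are fixed beforehand
(largest-magnitude entry positive) so results are reproducible.

For every factor and for each sign, coefficients $p(i)$ are ranked, $w$
is the mean of the top 50% (ceiling for odd counts), and $r(i) =
p(i)/w$. A site joins the candidate sector when $r(i) \ge r_0$ and
$p(i) > p_0$, or outright when $p(i) \ge p_1$. Defaults: $r_0 = 0.8$,
$p_0 = 0.1$, $p_1 = 0.4$. These three constants are not fixed by the
method's source description; the defaults were chosen as round values
that behave sensibly on the synthetic study conditions, and are exposed
in every user-facing entry point. Candidate sectors with fewer than two
sites are discarded — a single site cannot coevolve with itself.

Overlapping candidates (a natural by-product of bidirectional selection)
are merged greedily: keep the overlap, then repeatedly absorb the
symmetric-difference site with the largest summed coupling to the current
core (ties: lowest column index) until the core reaches the size of the
smaller parent. Merging repeats until sectors are pairwise disjoint; it
is idempotent, and the merged size always equals the smaller parent's.

## Evaluation suite

* **Internal correlation** (`internal_correlation()`): mean pairwise
  coupling inside a sector against 1000 equal-size random site sets drawn
  from the analysed (kept) sites, with an empirical p-value.
* **Statistical independence** (`mdi_entropy()`,
  `independence_test()`): the MDI entropy of a site group is the
  Kullback–Leibler divergence between the group's empirical joint
  distribution and the closest maximum-entropy distribution with the same
  single-site marginals. For two independent sectors the MDI of the union
  equals the sum of the parts; the reported baseline re-assigns the
  union's sites into random groups of the original sizes 100 times
  (random splits of coupled sites leave between-group coupling
  uncounted, so the baseline falls below the joint MDI).
* **Evolutionary rates** (`read_rate4site()`, `rate_summary()`): Rate4Site
  output is parsed, never re-implemented; sectors are summarised by mean
  normalised rate and the fraction of sites evolving slower than average.
* **Evolutionary independence** (`evolutionary_independence()`): PCA of
  the sequence-by-sequence similarity matrix over a sector's columns
  (identity fraction; any gap comparison is a mismatch), splitting
  sequences by the sign of the first principal component.
* **Sensitivity / PPV** (`sensitivity_ppv()`): each reference sector is
  matched to the single predicted sector containing most of its sites.

### Why GIS has a closed form here

Generalized iterative scaling fits the max-ent model, and with *only*
single-site marginal constraints its fixed point is analytic: the product
of the marginals. `mdi_entropy()` therefore runs GIS (with its
convergence diagnostics: fitted marginals within `tol` of empirical) when
the product state space is enumerable (`state_cap`, default $2\times
10^5$), and evaluates the fixed point in closed form —
$\mathrm{MDI} = \sum_j H(X_j) - H(X_{\text{group}})$ with plug-in
entropies — beyond it. The closed form is exact, not an approximation;
an equivalence test keeps the two routes honest against each other.

The *estimator*, however, is plug-in: with $S$ sequences and a large
joint pattern space, empirical entropies are biased, and the additivity
gap of two independent sectors measures exactly the empirical mutual
information between their pattern vectors — pure sampling bias, growing
with the fraction of patterns observed once. Independence conclusions
should therefore only be drawn where the joint patterns are reasonably
well sampled. This is why the package's additivity checks run on deeply
sampled conditions (6+6 sites, $\rho = 0.98$, 2000 sequences, measured
relative gap 2–3%) rather than on the default detection conditions
(12-site sectors, 300 sequences), where most joint patterns are
singletons and the plug-in gap is estimator bias, not evidence of
dependence.

## The synthetic generator

`synthetic_spec()` / `generate_alignment()` plant known structure: each
sequence draws one independent latent state per sector (binary by
default), each sector column shows its state's consensus residue with
probability $\rho$ and a uniform residue otherwise; noise columns are
independently drawn with a set conservation level; gaps are injected per
cell. The reference study conditions are 300 sequences × 80 columns, two
scattered 12-site sectors at $\rho = 0.9$, noise conservation 0.3 and gap
rate 0.05 — a moderately diverged family with realistic gappiness. A
latent-trait model was chosen over phylogenetic simulation deliberately:
the detector is alignment-statistical, and planting exact independence
between sectors is the property the evaluation suite needs to probe.

What the generator does **not** emulate: phylogenetic autocorrelation
(sequences are exchangeable draws, real families are not), alignment
errors, column-specific amino-acid propensities, or gap stretches.
Passing tests on these conditions show the algorithm recovers planted
exchangeable structure; they do not certify behaviour under strong
phylogenetic confounding, which is the classic failure mode of
covariance-based coevolution detection.

## Numerical choices

* Frequency clamp $\varepsilon = 1/(2S)$; background $q$ clamped away
  from 0 so absent amino acids contribute exactly nothing.
* `eigen(symmetric = TRUE)` on the symmetrised matrix; eigenvector sign
  convention applied before rotation.
* Varimax `tol` $10^{-6}$ on the criterion gain, `max_iter` 1000 sweeps;
  $t = 1$ returns the identity rotation.
* GIS `tol` $10^{-6}$ on the max marginal gap, `max_iter` $10^4$;
  non-convergence warns and flags the result rather than erroring.
* Ties: noise-filter boundary ties are removed; merge-step coupling ties
  go to the lowest column index; the 50% cut uses the ceiling.
* Degenerate inputs: all-gap columns warn; a constant similarity matrix
  or a tied first principal component returns one group with a warning;
  `t = 0` yields an empty sector set with a message, not an error.

## Reproducibility and problem sizes

Every stochastic step (null shuffles, random baselines, the generator)
is seeded explicitly; identical seeds give bit-identical sector tables.
The bundled checks run on 300×80 alignments with 100-shuffle nulls
(seconds per fit on one core) and 2000-sequence alignments for the
independence checks; these sizes were chosen as the smallest at which
the planted structure is comfortably identifiable and the entropy
estimators well behaved.

## Limitations

* **Pure-noise false positives.** On uncoupled data the decision
  "$N(1) < 100$" compares the reduced matrix's Perron eigenvalue with the
  *minimum* of 100 null Perron draws — an extreme-value comparison with a
  margin of a few percent. Measured over 20 pure-noise replicates of the
  study conditions, the rule returned $t = 0$ in 13; the remainder
  yielded one spurious factor whose loadings are nearly uniform (the
  Perron vector), producing one large undifferentiated "sector". Treat a
  single sector with flat loadings sceptically. When genuine coupling is
  present the factor eigenvalues clear the null by a wide margin
  (observed $\lambda_{1,2} \approx 29, 25$ vs null top $\approx 8$ on the
  study conditions).
* **Threshold provenance.** $r_0, p_0, p_1$ defaults are this package's
  choices; sector boundaries (not their existence) can be sensitive to
  them.
* **Plug-in entropies.** MDI values on deep sectors with shallow
  alignments are biased upward; see above.
* **No phylogenetic correction.** Shared ancestry can masquerade as
  coevolution; the shuffle null destroys it in the null but not in the
  observed data.

## A worked run

```{r run, eval = FALSE}
sim <- generate_alignment(synthetic_spec(seed = 11))
fit <- bifanr(sim$alignment, seed = 42)
print(fit)
sector_sites(fit$sectors)
report <- evaluate_fit(fit, seed = 1)
```
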
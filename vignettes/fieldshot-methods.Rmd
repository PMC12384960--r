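---
title: "Neural-field few-shot classification: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-field few-shot classification: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldshot)
```

## The model

`fieldshot` classifies queries in the N-way K-shot setting with two
discrete neural fields, an architecture patterned on the memory stages
of the ventral visual pathway.  Sample neurons of the *elementary field*
sit at the embedded support positions $z_i \in \mathbb{R}^d$; class
neurons of the *high-level field* sit at the class means
$\tilde z_j = \tfrac{1}{l_j}\sum_{i \in j} z_i$.  The full dynamics are
relaxation equations

$$\tau_u \dot u_i = \eta\Big(\sum_k \omega_u(\|z_i - z_k\|)\,\phi(u_k)\Big) + e_{u,i} - u_i,$$
$$\tau_v \dot v_j = \eta\Big(\sum_k \omega_v(\|\tilde z_j - \tilde z_k\|)\,\phi(v_k)\Big) + \phi\Big(\sum_i w_{j,i}\,\phi(u_i)\Big) + e_{v,j} - v_j,$$

with rate nonlinearity $\phi(u) = 1 - e^{-u}$ for $u > 0$ (else 0), odd
threshold $\eta(u) = \operatorname{sign}(u)(1 - e^{-|u|})$, binary
external inputs $e$, and the Mexican-hat interaction kernel

$$\omega(r) = \tfrac{3}{2} e^{-r^2/2\sigma_1^2} - \tfrac{1}{2} e^{-r^2/2\sigma_2^2},
  \qquad \sigma_2 = 3\sigma_1 .$$

The kernel family is deliberately rigid.  Fixing the amplitude pair at
$A = 3/2$, $B = 1/2$ gives $A - B = 1$ (unit peak: $\omega(0) = 1$
exactly) and $A/B = 3$; together with $\sigma_2 = 3\sigma_1$ the profile
has a unique positive root at

$$r^* = \tfrac{3}{2}\sqrt{\ln 3}\,\sigma_1 \approx 1.5722\,\sigma_1,$$

which the tests confirm against an independent numeric root-finder.
(A Gaussian-normalisation amplitude convention, $A \propto 1/\sigma$,
would break the unit-peak identity and the closed-form root; the
constant-amplitude convention is the one every downstream relation in
the package uses.)  Only $\sigma_1$ is free, and it is the quantity the
classifier adapts.

**Training** consists of a single Hebbian assignment: support sample $i$
with label $j$ sets $w_{j,i} = 1$ and nothing else
(`hebbian_connections()`).  Every column of $W$ sums to 1 and row $j$
sums to the class size — an invariant checked after every fit.

**Prediction** replaces the dynamics by a static one-pass composition
(`static_elementary_response()`, `static_highlevel_response()`): for a
query $q$ with unit input,

$$u_i = \eta\big(\omega_u(\|z_i - q\|)\,\phi(1)\big), \qquad
  v_j = \phi\Big(\sum_i w_{j,i}\,\phi(u_i)\Big).$$

Because $\phi$ vanishes on non-positive input and $\eta$ preserves sign,
$v_j > 0$ exactly when some support of class $j$ lies strictly inside
the kernel's zero-crossing radius $r^*(\sigma_1)$ of the query.  That
*detection-radius rule* is the package's core oracle: the property
tests compare the static activation set against a brute-force distance
scan on a thousand random instances.

The class-to-class lateral term of the high-level field is dropped in
this static pass (`lateral_enabled = FALSE` by default): the few-shot
regime assumes classes far apart relative to the kernel scale, where
that term is negligible.  When enabled, the lateral contribution
$\eta(\sum_k \omega_v \phi(v_k))$ is solved by damped fixed-point
iteration started from the feedforward solution, consistent with the
steady state of the dynamic equation; non-convergence within the cap is
an error that carries the last iterate.

## Scale initialisation and adaptation

The scale is tied to the support geometry through the radius relation
$\sigma_1 = 2z / (3\sqrt{\ln 3})$, the exact inverse of $r^*$
(`sigma_from_z()`), with the detection distance $z$ chosen per shot
regime (`initial_z()`):

- **1-shot**: half the *minimum* inter-class support distance.  Taking
  the minimum over all inter-class pairs is the conservative choice —
  the initial radius can never span two classes' nearest frontier.
- **multi-shot**: the maximum intra-class pairwise distance, so the
  initial radius covers the spread of a class.

Duplicate support points collapse $z$ to zero; this is rejected with a
dedicated error condition rather than silently producing a degenerate
radius.  The 3-sigma rule sets the initial search bracket
$[\sigma_1/3,\, 3\sigma_1]$.

At prediction time the count of activated class neurons drives a
bracketed search on $\sigma_1$ (`scale_adapt_predict()`): zero
activations mean the radius is too small (enlarge), several mean it is
too large (shrink), exactly one terminates.  The update is designed
around an observation-certification rule:

- `num = 0` at $\sigma$ certifies $\sigma$ as a true lower bound:
  $\sigma_{lo} \leftarrow \sigma$; while no upper bound has been
  certified, the bracket may still grow,
  $\sigma_{hi} \leftarrow \max(\sigma_{hi}, \sigma/\lambda)$; then
  $\sigma \leftarrow \sigma_{lo} + \lambda(\sigma_{hi} - \sigma_{lo})$.
- `num > 1` certifies an upper bound, with the mirror-image shrink step
  ($\sigma_{lo} \leftarrow \min(\sigma_{lo}, \lambda\sigma)$ while the
  lower bound is uncertified,
  $\sigma \leftarrow \sigma_{hi} - \lambda(\sigma_{hi} - \sigma_{lo})$).

Restricting the escape factors $1/\lambda$ and $\lambda$ to the phase
before the opposite bound is certified matters: applied
unconditionally, they re-inflate the bracket past bounds already
established by observation, and the search can oscillate indefinitely
around a narrow target window (class-minimum distances that almost
tie).  With certification, the bracket grows geometrically while the
target lies outside it and contracts by a factor $1 - \lambda$ per step
once straddled, so whenever the class-minimum distances $d_{(1)} <
d_{(2)}$ are distinct the search reaches the non-empty window $\sigma
\in (d_{(1)}/c,\ d_{(2)}/c)$, $c = \tfrac32\sqrt{\ln 3}$, in a number of
steps logarithmic in the window's relative width.  Empirically, 10,000
random instances all terminate within 18 iterations at $\lambda = 0.5$;
the cap is 100.

Defaults: $\lambda = 0.5$ (the midpoint rule; any value in $(0,1)$
works, smaller values take larger steps), `max_iter = 100`, activation
threshold `eps = 0` (strict positivity — the natural threshold given
$\phi$'s hard zero).

Two deliberate policies: queries are adapted **independently**, with
$\sigma$ reset to the fitted value before each query, so predictions
never depend on query order; and when the cap is exhausted (exact ties
make a single activation unattainable) the **fallback** predicts the
class of smallest minimum distance, remaining ties to the smallest
class index in sorted-label order.  Since the activated set at any
$\sigma$ is $\{j : d_j < r^*(\sigma)\}$ and $r^*$ is strictly
increasing, a successful search always returns the nearest class —
post-adaptation predictions provably coincide with the 1-NN class rule,
and the fallback extends that rule to ties.  This equivalence is
asserted on a thousand random instances and, per-query, across entire
600-episode evaluations.

## Embedding front end

Features enter through a plugin boundary (`register_extractor()`): any
deterministic map from input rows to fixed-length numeric vectors. The
built-in `identity` extractor passes numeric columns through and is the
test-path extractor; a real vision backbone is expected to be wrapped by
the user and is intentionally outside this package.

Dimensionality reduction is Laplacian Eigenmaps
(`laplacian_eigenmap()`): a k-nearest-neighbour graph under the
configured metric, **binary** 0/1 affinities (the variant with the
fewest free parameters — no heat-kernel bandwidth to tune), union
symmetrisation, and the bottom non-trivial generalized eigenvectors of
the graph Laplacian, computed via the symmetric normalized Laplacian
with base R's deterministic dense eigensolver.  Two reproducibility
rules: the trivial constant eigenvector is dropped by eigenvalue order,
and each returned column is sign-fixed so its largest-magnitude entry is
positive, making embeddings invariant to input row order up to that
rule (asserted in tests).  A disconnected graph is an error advising a
larger neighbourhood — per-component spectral coordinates are arbitrary
relative to one another, so silently proceeding would be wrong.

Episode embedding is **transductive** (`embed_episode()`): support and
query features are pooled, embedded jointly, and split by role.  With
the reference neighbourhood size of 99 and only $N \cdot K \le 25$
support points, a support-only graph cannot exist, so queries (or a
larger pool) must join the fit; a Nyström out-of-sample extension is
deliberately not provided.  The neighbour count is capped at one less
than the pooled size.

The neighbourhood size interacts with episode geometry in a way worth
stating plainly.  In an episode of $N$ compact, well-separated classes
with $K + Q$ points each, $k < K + Q$ leaves the graph disconnected,
while $k$ near the episode size makes it complete — and a complete
graph with binary affinities carries *no* geometry (its non-trivial
Laplacian eigenspace is fully degenerate).  `evaluate_episodes()`
therefore defaults to $k = K + Q + 1$, the smallest neighbourhood
guaranteed to bridge compact classes, and accepts any explicit value.
The same metric drives the embedding graph and every distance in the
classifier — the evaluation pipeline passes one metric to both, and a
test asserts the consistency.

Supported metrics: Euclidean, cosine ($1 - \cos\theta$; rejects zero
vectors), correlation ($1 - r$; rejects constant vectors), Minkowski
with configurable $p \ge 1$.  The lateral kernel is evaluated on the
metric distance, which for non-Euclidean metrics means "radius" is read
in the metric's units; the detection-radius rule holds for any of them
because the kernel profile is strictly decreasing through its root.

## Dynamic integration

`integrate_fields()` integrates the coupled equations by forward Euler
from zero initial activations: step $dt = 0.1\,\min(\tau_u, \tau_v)$
(well inside the stability limit of these relaxation dynamics), horizon
$10^4 \max(\tau)$, convergence when the largest time-derivative falls
below $10^{-8}$, and a divergence guard at $|u| > 10^3$.  Both evolution
rates default to 1.  The static path is validated against it: on
instances with well-separated classes — a probe near one class, classes
at least 8 apart, detection radius between 1.5 and 2.5, the regime in
which dropping the high-level lateral term is justified — the
steady-state activation ranking (activated classes ordered by
activation, non-activated grouped) matches the static approximation's
on 50 of 50 instances.  The comparison family is 1-shot by design:
with several supports per class the dynamic field's sample-to-sample
lateral couplings have no static counterpart, and rank agreement
between sums of differently-saturated activations is not a theorem.

## Synthetic data: what it does and does not show

`generate_clusters()` produces the test bed: class means at the
vertices of a regular simplex scaled to pairwise distance `separation`
(exact, analyzable geometry; random placement with rejection is the
fallback when the dimension cannot hold a simplex), isotropic Gaussian
within-class noise `spread`, optional projection to the unit sphere for
cosine work.  The shipped evaluations use 12 classes, 40 points per
class, dimension 11, `separation = 10`, `spread = 0.5` — clusters
separated by twenty standard deviations, emulating the embedding-space
geometry that a strong frozen extractor produces for visually distinct
classes.

What the bank does *not* emulate: anisotropic or heavy-tailed feature
noise, class overlap, fine-grained class hierarchies, or the
correlation structure of real backbone features.  Passing the
600-episode evaluations at $\ge 0.99$ accuracy therefore certifies the
pipeline's *mechanics* — embedding, fitting, adaptation, and their
agreement with the nearest-class oracle — not performance on real
images, which depends almost entirely on the quality of the plugged-in
extractor.

Validation problem sizes, chosen to exercise the properties densely
while keeping the suite quick: 1,000 instances for the radius-rule and
1-NN equivalences, 10,000 for adaptation termination, 600 episodes per
shot regime (the standard episodic averaging count), 50 dynamic
integrations, 1,000 Hebbian fits.

## Known limitations

- No out-of-sample embedding: queries must be embedded jointly with the
  support; a new query means a new episode fit.
- Transductive embedding means query-set composition influences support
  coordinates (though never across episodes, and predictions within an
  episode remain query-order independent).
- Activations are not calibrated confidences; the classifier returns a
  label and diagnostics, not probabilities.
- Binary graph affinities discard within-neighbourhood distance
  information; with neighbourhoods at or above the cluster size the
  embedding keeps between-cluster structure but flattens within-cluster
  geometry.
- The scale search assumes distinct class-minimum distances for
  guaranteed single-activation termination; exact ties are handled by
  the deterministic fallback, not by the search itself.
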
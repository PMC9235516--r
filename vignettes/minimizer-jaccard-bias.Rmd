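---
title: "The minimizer Jaccard estimator and its bias: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The minimizer Jaccard estimator and its bias: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sketchbias)
```

## The model

Two duplicate-free sequences $A$ and $B$ of $L$ $k$-mers each are compared
through their $k$-mer spectra.  The true Jaccard similarity
$J = I/U$ counts shared ($I$) and total distinct ($U = 2L - I$) $k$-mers.
A hash function $h$ assigns every $k$-mer an independent uniform value in
$[0,1)$; the minimizer sketch $MS(A;w)$ keeps the $k$-mers that attain the
minimum hash value in at least one window of $w$ consecutive positions.  The
minimizer Jaccard estimator is the Jaccard similarity of the two sketches
under one shared hash,

$$\hat J = \frac{|MS(A;w)\cap MS(B;w)|}{|MS(A;w)\cup MS(B;w)|} = \frac{\hat I}{\hat U}.$$

Unlike the classical minhash estimator, $\hat J$ is biased: $E[\hat J]\ne J$,
and the gap persists as $L \to \infty$ (inconsistency).  The reason is
structural.  $J$ depends only on the *number* of shared $k$-mers, while the
probability that a shared $k$-mer survives into both sketches depends on its
*surroundings* — whether its window neighbours are themselves shared.  The
package's exact enumeration oracle shows this on a three-position instance
with one shared $k$-mer and $w = 2$: with unshared flanks the joint selection
probability is $64/120$, but if the right flank is also shared it rises to
$14/24$, because the neighbour's hash value is common to both sequences.
Equal $(I, U)$, different layout, different expectation — hence bias.

```{r tau}
A <- kmer_seq(c("AA", "CC", "GG")); B <- kmer_seq(c("TT", "CC", "AT"))
joint_minimizer_probability(A, B, w = 2, p = 1, q = 1)[c("num", "den")]
```

## The charging decomposition and the configuration sum C

Each minimizer is attributed to exactly one window through *charging*:
position $p$ charges index $i$ when $i \in [\max(-1, p-w),\, \min(p-1, L-w-1)]$,
$a_p$ is the minimum over the window $[i+1, i+w]$, and either $i$ is the
leftmost legal index or $a_i < a_p$ (`charges()`).  The events for different
$i$ are mutually exclusive, and their union is the event that $p$ is a
minimizer — this is asserted property-style in the test suite.  The upper
limit of the window range in the charging condition admits more than one
typographic reading; the implementation fixes the window at $[i+1, i+w]$ with
$i \le L-w-1$, the reading under which the uniqueness/equivalence property
holds on brute-force enumeration, which is how the choice was validated.

A charging event, conditioned on the anchor value $a_p = x$, constrains each
remaining window position to hash above $x$, plus (for interior $i$) position
$i$ to hash below $x$.  For a matched pair $(p, q)$ the joint event over both
sequences multiplies independent constraints — *except* that a constrained
position of $A$ matched to a constrained position of $B$ is the same hash
variable.  Merged consistently it is counted once; with conflicting signs the
term vanishes.  With $\alpha$ distinct below-constraints and $\beta$ distinct
above-constraints the conditional probability is $x^\alpha(1-x)^\beta$, and
integrating out $x$ gives the exact Beta integral
$\alpha!\,\beta!/(\alpha+\beta+1)!$ (`joint_integral()`; closed form, no
quadrature).  Summing over matched pairs and legal index pairs yields
$C(A,B;w)$ (`expected_intersection()`), which brackets the exact expectation:
$C \le E[\hat I] \le C + 2$.

Two implementation choices matter here:

* **Boundary windows are included** (indices $-1$ and the truncated ranges
  near the ends), so $C$ is valid for non-padded inputs; padding is a
  property of instances, not a precondition of the computation.
* **Neighbourhood-signature caching.**  A pair's contribution depends only on
  the matching layout within $w$ positions of $(p, q)$ and the distances to
  the sequence ends, all clamped at $w$.  Contributions are cached by this
  signature, which collapses the cost from
  $O(I\,w^3)$ to roughly $O(I\,w)$ plus one full evaluation per distinct
  local layout — a handful for the structured generators, and essentially one
  for unrelated pairs.  An unrelated pair with $L \approx 62{,}000$ and
  $w = 20$ computes in well under a second.

## The bias estimate and its error bound

The expected sketch union is approximated by $4L/(w+1) - C$ (each sketch has
expected density $2/(w+1)$), giving

$$B(A,B;w) = \frac{C}{4L/(w+1) - C} - J,$$

implemented by `bias_estimate()`, with guards: a warning outside the regime
$L \ge 7(w+1)$, and an error if $C$ ever reached its ceiling $4L/(w+1)$
(it cannot exceed $2L/(w+1)$ for valid input).  The additive error of $B$ as
an estimate of $E[\hat J] - J$ is bounded by
$\varepsilon = c\,w^2/L^{1/3}$ (`epsilon_bound()`).  The leading constant is
exposed as a parameter with default 15 because published statements of the
bound differ in the constant; nothing in the package depends on it.  The
bound is loose — at $w = 20$ it exceeds 1 for any practical $L$ — while the
measured error on the unrelated-pair grid stays below $0.007$; the test
suite fits the empirical decay and finds an exponent clearly steeper than
the $-1/3$ the bound guarantees.

## Closed forms for structured layouts

**Sparsely matched pairs** (every shared $k$-mer isolated by more than $w$
positions on both sides, and no shared content in the boundary windows): each
matched pair contributes the same interior constant, which the Beta-integral
machinery evaluates to $(5w-2)/(4w^2-1)$ — at $w=2$ this is the $64/120$ of
the worked instance.  It follows that
$B \le -J\,(3w^2-3w)/(8w^2-2)$ (`sparse_bias_bound()`), tight as $J \to 0$.
`sparse_ratio_bound()` evaluates the conventionally quoted headline ratio
$(5w^2-3w-2)/(8w^2-2)$ — 40% at $w=2$, 61% at $w=20$, limit $5/8$.  A reader
deriving the ratio from the bias bound will instead obtain
$(5w^2+3w-2)/(8w^2-2)$; the two coincide in the large-$w$ limit, and the
documentation of both functions records the distinction so users are not
surprised.  The bias bound (not the headline ratio) is what the property
tests enforce on generated sparse pairs.

**Deterministic-gap layout**: sequences identical except for substitutions
every $g$ nucleotides ($\ell+1$ of them, $g > w + 2k$, $L = \ell g + k$).
Each substitution destroys exactly $k$ matches, leaving $\ell$ identical
isolated runs of shared $k$-mers, and

$$B = \frac{2\ell L\, h(w)}{(U - \ell h(w))\,U}, \qquad
  h(w) = \frac{(w+1)\bigl(1 - 2(H_{2w}-H_w)\bigr)}{2},$$

with $U = \ell(g+k) + 2k$ and $H_n$ the harmonic numbers
(`gap_layout_bias()`).  The trailing factor of $h(w)$ admits two typographic
readings ("squared" versus "halved"); the halved reading is implemented
because (a) it makes $h(w) < 0$ for $w \ge 2$ and hence $B < 0$, as the sign
theory requires for padded pairs, and (b) it agrees with both the
configuration computation on constructed instances (to machine precision —
$h$ is exactly the per-run deficiency the configuration sum produces) and
the Monte-Carlo estimate (within sampling error), while the squared reading
has the wrong sign and magnitude.  At $k=15$, $w=10$ the layout with
$g=43$ loses about 9.5% of $J$ and the one with $g=100$ about 3.7%.

## Oracles

*Exact enumeration* (`exact_expectations()`,
`joint_minimizer_probability()`): only the relative order of hash values
matters, so expectations are averages over all $n!$ rank assignments to the
$n$ distinct $k$-mers.  Sums are integer-exact (the $\hat J$ accumulator
uses the fixed denominator $2520 = \mathrm{lcm}(1..10)$, divisible by every
possible $\hat U$), so results are exact rationals and acceptance checks are
float-flake-free.  The limit is $n \le 10$; beyond it the function refuses
and points to Monte Carlo.

*Monte Carlo* (`monte_carlo()`): hash replicates with seeds derived from a
master seed by counter-mode 64-bit mixing, recorded in the output, so every
estimate is bit-reproducible from one integer.  The replicate table carries
$\hat I$, $\hat U$, $\hat J$ per seed; summaries include the 2.5/97.5
percentiles used by the sweep plots.

## Generators: what they emulate, and what they do not

The generators' defaults *are* the study conditions; they are not tuning
knobs.

* `random_duplicate_free()` draws a nucleotide string with all-distinct
  $k$-mers by randomized extension with backtracking on the order-$(k-1)$
  de Bruijn graph.  For dense draws (more than 40% of all $4^k$ $k$-mers,
  $k \le 12$) it switches to a random Eulerian circuit (Hierholzer) of the
  full de Bruijn graph and takes a window — every window of an Eulerian
  circuit is duplicate-free, so draws at 95% density are as cheap as sparse
  ones.  Sampling is uniform-ish, not exactly uniform over all
  duplicate-free strings; nothing downstream depends on exact uniformity.
* `unrelated_pair()` sizes $L = \lfloor 2j\,4^k/(j+1)\rfloor$ so the
  expected Jaccard of two uniform spectra equals the target $j$ — obtained
  by inverting $E[J] \approx (L/M)/(2-L/M)$ for $M = 4^k$.  Realized $J$
  concentrates within about $10^{-3}$ of $j$.
* `related_pair()` applies independent per-position substitutions at rate
  $r_1$, choosing replacements uniformly among the nucleotides that do not
  create a duplicate $k$-mer.  When all three alternatives would, the
  position is left unmutated and counted (`n_skipped`); mutations are
  applied left-to-right against the partially mutated string so the
  duplicate-free invariant always refers to the final sequence.  This rule
  is the package's own resolution of an under-specified corner; skips are
  essentially nonexistent for $k \ge 12$.  At $r_1 = 0.01$, $k = 16$,
  $L = 10^4$ the realized $J$ lands near $0.74$
  (per-$k$-mer survival $(1-r_1)^k$).
* `deterministic_gap_pair()` realizes the closed-form layout and rejects
  draws with accidental duplicate $k$-mers or accidental extra matches, so
  the constructed matching is exactly the intended one.
* `sparsely_matched_pair()` builds *abstract* ordered $k$-mer lists (no
  contiguous source string): distinct $k$-mers are sampled from the $4^k$
  universe and shared ones are placed with pairwise gaps above $w$, away
  from the boundary windows.  The theory depends only on the matching, and
  abstract lists make the placement exact; objects without a source string
  simply cannot be exported as FASTA.

What the generators do **not** emulate: reverse-complement (strand)
identification, indels, sequencing error, compositional bias, repeat
structure of real genomes.  Tests passing on these models therefore
demonstrate correctness of the estimator and bias machinery under the
idealized hash model, not fidelity of any biological simulation; on real
padded-ish sequences the bias term remains accurate in published practice,
but boundary effects can flip the bias sign for heavily non-padded pairs.

## Numerical choices

* Hashing is a seeded 64-bit mix of the $k$-mer content (FNV-1a into a
  SplitMix-style finalizer), scaled to $[0,1)$ with 53-bit resolution.  The
  idealized model assumes a collision-free real-valued hash; practical
  results are known to be robust to the choice of mixer.
* Argmin ties (possible only via hash collisions) break toward the smaller
  position, consistently in sketching and charging.
* The exact oracle and the Beta integrals avoid floating-point accumulation
  error by construction (integer counts, factorial ratios).
* Monte-Carlo seed lists come from `derive_hash_seeds()` so that sweeps can
  share one seed list across grid points and mutation replicates, which
  removes hash noise from cross-point comparisons.
* Degenerate inputs: sequences shorter than $w$ are rejected; duplicate
  $k$-mers warn (sketching) or error (matching-based machinery, where the
  matching property would fail); $\hat J$'s divergence conversion returns
  the sentinel 1 at $\hat J = 0$.

## Problem sizes used by the test suite

The acceptance-style tests run the full study conditions where they are
cheap (unrelated grid at $k \in \{7, 8\}$ with 50 hash replicates; gap
layouts at $L \approx 10^4$ with 200 replicates) and scale down only the
purely diagnostic checks: the error-decay fit uses
$L \in \{300, 1000, 3000, 10^4\}$ with 6 mutation replicates and 50 hash
replicates, enough to pin the decay exponent to the broad band the check
asserts.  Exact-oracle property tests use $n \le 8$ distinct $k$-mers
(40,320 orderings), 100 random instances per sandwich bound.

## Known limitations

* $E[\hat U]$ is approximated by $4L/(w+1) - C$; for very short sequences
  the boundary deficit of the sketch density (order $\log w$ per end) makes
  the estimator's Monte-Carlo mean drift slightly above $J + B$, visible in
  the gap-layout checks as a relative bias a few tenths of a percentage
  point below the closed form.
* The $\varepsilon$ bound is not tight in $L$ or $w$; treat it as a
  worst-case certificate, not an expected error.
* No strand awareness: sequences are compared as written.  Canonical
  $k$-mers would change the matching structure and are out of scope.
* The stochastic mutation model has no closed-form bias here (only the
  deterministic-gap surrogate); its bias is measured empirically by the
  sweep machinery.
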
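---
title: "Probabilistic composition–abundance binning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic composition–abundance binning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: the statistical
models, what each tunable parameter means, what the synthetic benchmark does
and does not establish, and the design decisions taken where the method
description left choices open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Composition: calibrated tetranucleotide distances

**Signature.** Every contig is summarized by its tetranucleotide frequency
(TNF) vector. Assembled contigs have arbitrary strand, so the 256 4-mers are
collapsed onto 136 canonical classes (each 4-mer pooled with its reverse
complement; 16 tetramers are self-complementary). Windows containing `N` are
skipped rather than fractionally distributed — simpler, and unbiased for the
low-ambiguity assemblies binning targets. Counts are normalized to
frequencies; a sequence with no valid window gets `valid_kmers = 0` and is
rejected by the distance functions rather than silently treated as distance
zero.

**Calibration.** The Euclidean TNF distance $D$ is converted into the
posterior probability that two contigs come from *different* genomes:
training genomes are shredded into fragments, intra-/inter-genome fragment
pairs are sampled, the class-conditional densities $P(D\mid T)$ and
$P(D\mid R)$ are estimated by equal-width histograms (default 100 bins) on a
shared grid, and Bayes' rule is applied with prior odds
$P(T)/P(R) = 10$ — inter-genome pairs vastly outnumber intra pairs in a real
community, and the informative prior compensates for that asymmetry. The
posterior curve is then summarized by a two-parameter logistic
$\mathrm{TDP}(D) = 1/(1+e^{-(b + cD)})$, fitted by weighted maximum
likelihood (per-bin pair counts as weights; damped Newton, cap 100,
tolerance $10^{-10}$; the fit must return $c > 0$ or it errors).

**Size awareness.** TNF estimates tighten with fragment length, so $b$ and
$c$ are fitted per fragment-size pair over a size grid and interpolated
bilinearly in $\log(\text{size})$. The grid spans 2.5–40 kb by default
(training fragments at exactly each grid size); contig lengths outside the
model's range are clamped to $[2.5\,\text{kb}, 500\,\text{kb}]$ and then to
the grid. The 2.5 kb floor is deliberate: parameter estimates are unstable
for very short fragments, and the binner admits only contigs ≥ 2.5 kb
anyway, so one floor keeps model and binner consistent. The score is made
*exactly* symmetric in the two lengths by ordering the pair before
interpolation.

Interpolation scheme, histogram settings and the fitting algorithm are
package choices (the method description fixes only the logistic form and
the prior); any converging fitter satisfying the recovery tests would do.
One numerical caveat is documented in the tests: on strongly separated
training corpora the empirical posterior approaches a step function, the
slope is then weakly identified from above (quasi-separation), and the
fitter stops when its damped step collapses — yielding a steep, finite
logistic. That is the honest calibration of such a corpus, not a defect to
smooth away.

For off-diagonal size cells the trainer samples one fragment at each of the
two sizes (the cell models exactly that size pair); the exported
`sample_pairs()` keeps the simpler single-list contract used by the
diagonal cells and by tests.

**Default model.** The package trains its default model on 8 synthetic
Markov-chain genomes of 1 Mb (seed 7, 10,000 pairs per size cell — scaled
from the original large-corpus calibration to desk runtime; both corpus and
pair count are configurable, and user FASTA genomes can be supplied
instead). Models serialize to a versioned JSON file.

## 2. Abundance: non-shared area of depth distributions

Per sample, a contig's depth is modelled as normal with the observed mean
$\mu$ and variance $\sigma^2$. Real depth variance is super-Poisson, which
is why the variance is carried explicitly. The per-sample distance of two
contigs is the total-variation distance
$\tfrac12\int|\phi_{\mu_1,\sigma_1^2}-\phi_{\mu_2,\sigma_2^2}|$, evaluated
in closed form: for equal variances $2\Phi(|\mu_1-\mu_2|/2\sigma)-1$ via the
midpoint; otherwise the four-term CDF expression at the two density
crossing points, the roots of $\phi_1(x)=\phi_2(x)$:

$$k_{1,2} = \frac{(\mu_1\sigma_2^2-\mu_2\sigma_1^2) \pm
\sqrt{\sigma_1^2\sigma_2^2\big((\mu_1-\mu_2)^2 +
2(\sigma_2^2-\sigma_1^2)\ln(\sigma_2/\sigma_1)\big)}}
{\sigma_2^2-\sigma_1^2}, \qquad \sigma_2^2 > \sigma_1^2 .$$

These roots were re-derived from the crossing quadratic; the derivation is
verified against numerical integration split at the crossings (plain
adaptive quadrature is unreliable at the integrand's kinks, so the oracle
in the tests locates sign changes first). Numerical guards: variances are
floored at $10^{-4}$ (a zero variance breaks the crossing formula), the
branch switches to the equal-variance form when the variances agree to
$10^{-12}$ relative, and the result is clamped to $[0,1]$.

Per-sample distances combine by geometric mean over *informative* samples —
those where at least one contig's mean depth exceeds `min_cv` (default 1
read/base; "reasonable minimum abundance" is otherwise unquantified).
Uninformative samples are excluded from both product and root rather than
zeroing the product; if no sample is informative the pair's ADP is
undefined and the composite falls back to composition alone.

## 3. The composite distance

With $w = \min(\log(n+1)/\log(m+1), \alpha)$, $n$ the pair's informative
sample count (a package reading: the filtering intent makes the per-pair
informative count the natural $n$; a switch to total sample count is one
argument away), $m = 100$, $\alpha = 0.9$:

* TDP > 0.05 → composite = max(TDP, ADP);
* otherwise → composite = ADP·w + TDP·(1−w);
* ADP undefined → composite = TDP.

The rule is discontinuous at the switch by construction; the implementation
reproduces the jump (a test *reports* its magnitude rather than failing).
The $O(n^2)$ matrix is built by a compiled kernel that computes each
unordered pair once — exact symmetry by construction — and is verified
pair-by-pair against the R-level `tdp()`/`adp_combined()`/
`composite_distance()` route on random pairs (dual-route check, tolerance
$10^{-10}$).

## 4. Clustering

Iterative medoid sweep: seed on the unbinned contig with the greatest
summed mean depth (longest contig in composition-only mode); recruit all
candidates within $1-p_1$ of the medoid; re-elect the medoid as the member
minimizing summed distance to the members; iterate until stable (cap 50);
after convergence drop members beyond $1-p_2$; repeat the sweep until no
contig remains; dissolve bins ≤ 200 kb; optionally (≥ 10 samples) recruit
leftovers whose depth profile correlates ≥ 0.9 with a unique best bin.

$p_1$ and $p_2$ are named but undefined in the method description; the
package defines them as probability cutoffs mapped to distance cutoffs
$1-p_1$ (recruitment) and $1-p_2$ (refinement), defaults 0.90/0.95,
both exposed. Recruitment is against the current medoid (the description's
"within a cutoff distance to the seed" is ambiguous once the medoid moves).
Dissolved members are not re-seeded within a sweep (prevents cycling); they
remain available to correlation recruitment. Every tie-break — seeding,
medoid election, recruitment — is a total order on (criterion, length, id),
which makes runs byte-identical; the determinism test reruns the full
reference community twice and compares membership files bytewise. One
subtlety: the written medoid-update rule (summed distance to members) can
tie where a trace over all candidates would not; the package follows the
member-only rule and resolves ties toward the longer contig.

## 5. The synthetic world, and what green tests establish

The generator emulates: genomes with distinct compositional bias (order-2
Markov chains, Dirichlet transition rows with concentration
1/sharpness, sharpness 5), contigs with exponential sizes (mean 8 kb,
minimum 2.5 kb), and multi-sample depth tables where each genome's
per-sample abundance is log-uniform on 2–100 reads/base and each contig
reports mean $\sim \mathcal N(a, a\,k\,1000/L)$ truncated at 0 with
variance $k\cdot$mean, $k = 5$ (super-Poisson). Log-uniform abundance
maximizes the between-sample variation the abundance signal feeds on; the
$1/L$ scaling makes longer contigs report tighter depth estimates. These
defaults were fixed before any acceptance measurement and not revisited.

The reference benchmark (10 genomes × 3 Mb, 5 samples, seed 42) is
deliberately easier than real data: genomes are compositionally farther
apart than related species, there are no chimeric contigs, no shared
plasmids or conserved regions, no GC bias, and depth noise is exactly the
assumed normal model. A green recovery test therefore establishes that the
pipeline's statistics and clustering are implemented correctly and fit
together — not that the method attains any particular accuracy on real
assemblies. Conversely the per-module tests (closed forms against
integration, logistic recovery, posterior arithmetic, brute-force medoid
oracle) do not depend on the generator at all.

## 6. Degenerate inputs and numeric edges

* Contigs shorter than 4 bases or all-N: zero TNF vector, `valid_kmers = 0`,
  rejected by `tnf_distance()`.
* Genomes shorter than `min_size` are skipped (with a warning count) by the
  shredder; remainders ≥ `min_size` are emitted as final shorter fragments,
  remainders below it discarded.
* Zero reported depth variance → variance floor $10^{-4}$; identical
  (μ, σ²) pairs → ADP exactly 0.
* A per-sample ADP of exactly 0 drives the geometric mean to 0 (the
  compiled kernel floors the log argument at $10^{-300}$, i.e. ~0 within
  $10^{-300}$ of the R path).
* Empty candidate pools, singleton bins, communities whose every bin falls
  under 200 kb: all return empty/free results rather than erroring.

## 7. Known limitations

* TDP calibration quality is bounded by the training corpus; the shipped
  default is synthetic and steep (see §1). For real assemblies, train on a
  representative reference set via `build_tdp_model()`.
* The full distance matrix is dense ($8n^2$ bytes); ~20k contigs ≈ 3.2 GB.
  The kernel computes pairs lazily enough to extend to block-sparse
  storage, but that engineering is out of scope here.
* Post-binning reassembly and marker-gene (single-copy-gene) quality
  estimation are out of scope; evaluation requires a ground-truth table.
* The depth simulator draws contig depths independently given the genome
  abundance; real per-sample depth correlations along a genome (GC, origin
  of replication) are not emulated.
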
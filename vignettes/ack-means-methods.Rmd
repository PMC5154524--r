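---
title: "Adaptively constrained K-means for cryo-EM 2D classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptively constrained K-means for cryo-EM 2D classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-particle cryo-electron microscopy records many noisy 2D projection
images of a macromolecule in unknown orientations. Before any 3D work, the
images are grouped by unsupervised 2D classification so that each class
collects projections of similar orientation; class averages then raise the
signal-to-noise ratio enough to judge data quality and seed *ab initio*
reconstruction. The classical tool for this grouping is K-means, but on
cryo-EM data plain K-means has a well-known pathology: classes with many
members (hence high-SNR averages) attract still more images, other classes
are starved or emptied, and the final partition mixes badly unbalanced sizes
with misassigned orientations.

`ackmeans` implements an adaptively constrained K-means (ACK-means) that
counters this attraction with a size-dependent penalty, together with the
three baselines it is naturally compared against: the traditional K-means
loop, a SPIDER-style variant that multiplies distances by the class-size
factor `s/(s∓1)`, and equally-sized-group K-means (EQK-means) that forces
all class sizes equal at every iteration.

## The constrained objective

Write the image set as rows `x_1 … x_n`, class representatives (centroids)
`μ_1 … μ_k`, assignment vector `p`, and per-class size vector `s`. The
clustering objective is

    J = Σ_j Σ_{p_i = j} dissim(x_i, μ_j) + λ Σ_j s_j²

Because `Σ_j s_j = n` is fixed, the quadratic size term is minimized exactly
when all sizes are equal (Cauchy–Schwarz), so λ trades classification
fidelity against balance: λ = 0 is ordinary K-means; λ → ∞ forces equal
sizes like EQK-means; intermediate λ lets denser orientation regions keep
larger classes while starving none.

Minimizing J over the label of a single image `i`, holding every other
label fixed, reduces to

    p_i = argmin_j { dissim(x_i, μ_j) + 2λ s'_j }

where `s'` counts the current class sizes with image `i` removed. One
iteration of ACK-means visits all images sequentially and applies this
update with sizes maintained online, so later images see earlier
reassignments; a centroid mean-update follows. `ack_assign_sweep()` is
exactly this sweep, and the suite verifies against exhaustive enumeration
that every single decision equals the argmin of the full objective, and
that J never increases within a sweep at fixed centroids and fixed λ.

### The scale-free weight

A fixed λ would need retuning for every dataset because pixel-intensity
scales vary. Each iteration therefore estimates a *characteristic
dissimilarity* `d_c`: for each of 10 randomly sampled images, the spread
(max − min) of its `k` centroid dissimilarities, averaged. The constraint
weight is then set through a single dimensionless balance parameter β:

    2λ = β · d_c / ⌊n/k⌋

`⌊n/k⌋` is the class size of a perfectly balanced partition, so β directly
weighs "one balanced-class-worth of membership change" against one
characteristic dissimilarity. β = 0.5 is a good general-purpose value and
the package default; β = 0 reproduces the traditional baseline bit-for-bit
(the suite asserts identity of every iteration's labels and diagnostics).
Because both `d_c` and squared-Euclidean dissimilarities scale as the
square of a global intensity factor, every assignment of every iteration is
invariant to rescaling the data, which the suite also asserts.

### Termination

All four algorithm shells share one termination rule: stop when the
fraction of images changing class in an iteration, σ, drops to σ₀
(default 0.01), or after `max_iter` (default 100) iterations. A strict
fixed point is not a reliable criterion here because λ is resampled through
`d_c` each iteration, so tiny membership oscillations can persist
indefinitely; the σ₀ rule is applied to the baselines as well so that
iteration counts and convergence traces are comparable.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `beta` | 0.5 | dimensionless | weight of the size constraint; 0 disables |
| `sigma0` | 0.01 | fraction | termination threshold on membership change |
| `max_iter` | 100 | iterations | safety cap |
| `sample_size` | 10 | images | per-iteration `d_c` sample |
| `assignment_order` | dataset order | — | sweep visiting order |
| dissimilarity | squared Euclidean | intensity² | pluggable; see below |

## Design choices on genuinely open points

**Squared vs plain Euclidean distance.** The dissimilarity is squared
Euclidean on flattened pixels by default. With squared distances the
centroid mean-update is the exact minimizer of the within-class term, which
makes the per-sweep descent property provable and testable; the unsquared
variant remains selectable (`dissim_spec("euclid")`), and any pairwise
function can be plugged in.

**Sweep order.** The per-image update depends on the online size vector, so
visit order matters in principle. The default is dataset order, which makes
runs exactly reproducible; a seeded per-sweep shuffle is available
(`assignment_order = "shuffled"`). In practice the converged balance
metrics are indistinguishable.

**`d_c` sampling.** A fresh seeded sample of 10 images per iteration, with
dissimilarities computed against the centroids current at sweep start. The
alternative — reusing dissimilarities computed during the previous sweep —
would save a negligible amount of work here and ties the estimate to stale
centroids.

**Empty classes.** Random-image initialization starts every class with a
member, but a sweep can empty a class. Emptied classes keep their previous
centroid and remain candidates; under the constraint an empty class has
`2λ s'_j = 0` and is therefore maximally attractive, so it typically refills
within the next sweep. The same policy applies to the baselines (for the
traditional baseline a conventional reseed-with-random-image option exists,
off by default). In the SPIDER variant an emptied class gets factor
`s/(s+1) = 0` and likewise refills immediately; its singleton own-class
factor `1/0` is treated as +∞, so a singleton always leaves for any finite
alternative unless it is the only class.

**Tie-breaking.** Every argmin breaks ties toward the lowest class index —
deterministic and directly testable.

**EQK capacities.** When `k` does not divide `n`, the first `n mod k`
classes receive the extra slot. The assignment is the greedy pass over all
`n·k` image–centroid pairs sorted ascending; ties in the sort resolve by
lower class index, then lower image index (stable order).

**Seed discipline.** All randomness flows from one integer seed per run:
initialization uses the seed itself; the iteration-`t` `d_c` sample uses
`seed + 7000 + t`; the optional shuffle `seed + 9000 + t`; reseeding
`seed + 8000 + t`. The pipeline derives stage seeds (`seed + 100`
simulation, `seed + 200` clustering) and records them in
`provenance.json`. Caller RNG state is always saved and restored.

## The aligned dissimilarity

Multi-reference alignment defines the distance between an image and a
reference as the best match over in-plane rotations and translations.
`aligned_dissim()` implements a simplified version: the minimum squared
Euclidean distance over a discrete grid (default 10° rotation steps, ±2 px
shifts), using bilinear interpolation with zero fill about the pixel at
`(D%/%2, D%/%2)`. Minimizing squared distance rather than maximizing
correlation keeps one objective throughout; for mean-centered, fixed-norm
images the two orderings coincide. The implementation *is* the exhaustive
grid search — there is no approximation to drift from — and the suite
cross-checks it against an independently coded triple loop. Because the
identity transform is on the grid, the aligned dissimilarity never exceeds
the unaligned one. Grid increments are package choices; the upstream
packages this emulates do not publish theirs.

## The benchmark simulator

`simulate_dataset()` emulates the standard simulated benchmark for 2D
classification:

1. **Density**: an asymmetric phantom (`make_phantom()`) of 8 anisotropic
   Gaussian blobs in a 0.4·D sphere — a synthetic stand-in for a ribosome-
   like density; any MRC volume can be substituted.
2. **Orientations**: `n_centers` directions placed near-uniformly on the
   upper hemisphere by a golden-angle spiral (asymmetric particles make
   antipodal views distinct; sampling half a sphere mimics preferred
   orientation statistics), each spawning `per_center` orientations with a
   tangent-plane Gaussian spread of `angular_sigma` (default 5°; the
   benchmark's cluster width is a package choice) and uniform in-plane
   angle.
3. **Projection**: trilinear-interpolated rotation of the sampling grid
   (ZYZ intrinsic Euler convention; the projection axis is the rotated
   z-axis) summed along z.
4. **CTF**: standard weak-phase CTF with relativistic electron wavelength;
   defaults 300 kV, Cs 2 mm, amplitude contrast 0.07, pixel size 2 Å,
   per-image defocus uniform on 1–3 µm. All package choices, reported in
   the output metadata.
5. **Noise**: additive i.i.d. Gaussian at a target SNR defined as signal
   pixel variance over noise variance (the dominant cryo-EM convention);
   the calibration is verified to 5% in the suite.
6. **Phase flipping**: multiplication of the spectrum by the CTF's sign
   (with sign(0) := +1, making the flip an exact involution), the usual
   first-order CTF correction applied to classification input.

Paper-scale is 100 centers × 100 projections (n = 10,000); the package's
desk-scale default is 20 × 50 (n = 1,000) at D = 32 px, which keeps a full
simulate–cluster–evaluate comparison of three algorithms over ten seeds
within a few minutes on one core. These sizes are the package's standard
benchmark configuration, stated here so results are interpretable.

**What the simulator does not model**: structural noise and ice, beam-
induced motion, amplitude decay/envelope functions, per-micrograph CTF
estimation error, particle-picking offsets, or conformational
heterogeneity. Passing benchmarks here therefore demonstrate correctness of
the clustering machinery on idealized data, not end-to-end performance on
micrographs.

## Evaluation instruments

With ground-truth orientations in hand, quality is read from two curves:
the normalized histogram of within-class pairwise angular distances
(arccos of projection-direction dot products, pooled over classes; sharper
low-angle peaks are better) and the ascending class-size curve (a
horizontal line is perfect balance). The in-plane angle ψ is deliberately
ignored in the angular distance: grouping by projection direction is the
classification task; in-plane rotation belongs to alignment. Antipodal
directions count as 180° since the benchmark samples one hemisphere.
Default bin width is 2°. For tests, `adjusted_rand_index()` provides exact
partition-recovery scoring (cross-checked against an independent
implementation).

On the desk-scale benchmark at SNR 1/10 the package reproduces the expected
qualitative picture: ACK-means (β = 0.5) converges in a handful of
iterations to class-size standard deviations an order of magnitude below
the traditional K-means while its pooled mean angular distance is slightly
*better*; EQK-means achieves perfect balance by construction with
comparable angular quality on this pre-aligned, isotropic-noise data. The
acceptance script recomputes these numbers from scratch.

## Numerical notes

- Cross-distances use the `‖x‖² + ‖μ‖² − 2xμ` expansion with clamping of
  tiny negatives; the sweep itself and all oracle comparisons use the same
  matrix, so exactness checks are well-posed.
- `σ` histories, `d_c`, `2λ` and J are recorded every iteration for all
  algorithms. J is logged at the sweep's centroids and λ; it is *not*
  asserted monotone across iterations, because λ changes with `d_c` each
  iteration — monotonicity holds (and is tested) only within a sweep.
- Degenerate inputs: `k > n` and `k < 1` error; zero-variance images error
  in the noise stage (SNR undefined); non-finite dissimilarities error
  naming the offending image–centroid pair.

## Known limitations

**Initialization sensitivity.** Like every K-means-family method started
from `k` random images, ACK-means can start with two seeds in one true
cluster. The size constraint substantially raises the chance of escaping
such starts (recovery of three well-separated image clusters rises from
roughly 60–70% of seeds for the traditional baseline to roughly 75–95%
for ACK-means, depending on dimension and geometry), but at β = 0.5 escape
is not guaranteed: a merged double cluster with two half-classes elsewhere
can be a genuine local minimum of the constrained objective, stable under
every single-image move — analytically, in near-equilateral geometry the
size-penalty margin `2λ·Δs ≈ 0.74·d_c` falls just short of the
dissimilarity gap `0.75·S²`. The package reports recovery rates honestly
rather than restarting; multiple seeds plus the diagnostics (`size_sd`,
`mean_angular`) are the practical remedy.

**No within-class alignment during clustering.** The `aligned` dissimilarity
searches a discrete transform grid per image–centroid pair and is O(grid)
slower; the intended large-scale use is pre-aligned input (reference-free
alignment upstream) with squared-Euclidean distance, as in the benchmark.

**EQK complexity.** The greedy equal-size pass sorts all `n·k` pairs per
iteration; at desk scale this is negligible, at very large `n·k` it
dominates.
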
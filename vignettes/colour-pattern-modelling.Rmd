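---
title: "Colour Pattern Modelling and dominance analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour Pattern Modelling and dominance analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmr)
```

## The problem

Butterfly wing patterns in mimetic species such as *Heliconius numata* vary
in complex combinations of patch size, colour and position, and in
polymorphic species these forms are controlled by alleles of a single
supergene.  Quantifying genetic dominance for such a trait requires
comparing whole-wing phenotypes of heterozygotes with those of both
homozygotes, without pre-deciding which pattern elements matter.  Colour
Pattern Modelling (CPM) does this in three steps:

1. **Colour categorization.** Each standardized wing photograph is reduced
   to a categorical raster over a small set of colour classes (here black,
   orange, yellow, plus background), treating colours as classes
   independent of minor colorimetric variation.
2. **Pattern-based alignment.** All categorized wings are registered into
   one model frame with similarity transforms (translation, rotation,
   isotropic scale) chosen to maximize pattern match against an average
   "wing model" that is itself rebuilt from the registered wings, and the
   loop repeated until the model stabilizes.  The converged model defines
   pixel-wise positional homology across specimens.
3. **Pixel-wise analysis.** Every homologous pixel becomes a trait:
   genotype modal patterns, a surface-based heterozygote trait `T`,
   dominance coefficients `h`, dominance heat maps, colour-hierarchy maps
   and conformity statistics are all computed on the aligned stack.

Because the original specimen photographs are not available, the package
ships a first-class synthetic generator whose outputs carry full ground
truth (allele patterns, dominance mechanism, applied transforms), so every
stage can be validated against known answers.

## The synthetic generator

An allele is a base colour filling a fixed parametric forewing silhouette
plus an ordered list of patches (ellipses and polygons in normalized wing
coordinates); later patches overwrite earlier ones.  A heterozygote's
noise-free phenotype is resolved pixel-by-pixel from the two allele
patterns by one of three mechanisms:

* `colour_hierarchy` — the colour higher in a strict hierarchy (default
  black > orange > yellow) is expressed wherever the alleles disagree;
* `full_dominance` — one allele's whole pattern is expressed regardless of
  colour;
* `mosaic` — each patch is won by a designated allele, so the area-weighted
  fraction of disagreement pixels won by one allele programs any dominance
  level between 0.5 and 1 (`make_mosaic_pair()` provides a 20-stripe pair
  with ~0.05 granularity; the realized fraction is recorded in the truth
  bundle by brute-force pixel counting).

Specimen images are rendered *analytically*: the native pixel centres are
mapped through the inverse nuisance transform and a smooth random
displacement field (boundary jitter), and the continuous wing geometry is
evaluated at those points.  No intermediate raster is sampled, so a
zero-noise, identity-transform render categorizes back to the canonical
truth pixel-for-pixel — the oracle used throughout the tests.

Nuisance parameters default to: boundary jitter SD 1.5 px (a smooth 8x8
knot displacement field — emulating individual variation in patch size and
shape), per-channel Gaussian RGB noise SD 8 (0-255 scale), translation up
to 10 px, rotation up to 8 degrees, scale 0.95-1.05, and 0.2% salt-pixel
noise.  No within-genotype variance magnitudes are published for the real
material; these values were chosen once as plausible for standardized
museum-style imaging (boundaries vary by a few scale rows; photographic
positioning errors of a few percent) and are deliberately not tuned.  The
canonical frame is 256x256 px.  Real wings additionally show venation,
scale texture, iridescence and damage, none of which are emulated, so
passing tests demonstrate correctness of the machinery, not robustness to
every artefact of real photographs.

## Categorization

The wing is separated from the (reserved) background colour by
thresholding RGB distance and keeping the largest connected component.
Optional simplification mirrors size-reduction and region-merging: block
averaging, single-linkage merging of adjacent pixels closer than
`merge_threshold` (default 60 RGB units), and absorption of regions under
`min_region_px` into the nearest-colour neighbour.  Classification itself
is nearest-centroid in RGB with fixed class centroids; pixels farther than
the threshold from every centroid, or exactly tied, are flagged
*unresolved* and assigned deterministically (ties break to the class
declared earlier).  The unresolved count replaces the interactive manual
checking a human operator would do; an unsupervised mode
(`categorize_unsupervised()`, k-means with k chosen by silhouette) mirrors
categorization without a fixed number of colours.

## Alignment

The initial alignment uses mask moments only: centroid, area and
principal-axis orientation, scaled to the common geometric-mean area.  The
wing model stores, per model pixel, the frequency of each class (including
background) over all contributing wings; frequencies sum to 1 wherever
support is positive.  The registration score of a transform is the mean
model frequency of the class observed at each supported model pixel — a
categorical template-matching score that is 1 exactly when the pattern
reproduces a deterministic model.  The optimizer is deterministic:
a coarse grid around the moment initialization, then pattern search with
shrinking steps (floors 0.04 px, 0.04 degrees, 0.1% scale), candidates
ordered by parameter magnitude so ties keep the smallest transform.  The
recursive loop enforces a non-decreasing mean score: an iteration that
lowers it is rolled back and iteration stops; otherwise it stops when the
mean absolute change in model frequencies drops below `tol` or after
`n_iter` iterations.

**Model frame resolution.** Aligned rasters are produced by area-majority
resampling (`vote^2` subpixel samples per output pixel, default 5x5 during
alignment).  Categorical rasters cannot carry subpixel boundary
information, so every resampling re-quantizes boundaries by up to half a
source pixel.  The model frame is therefore set to *half* the native
resolution by default (`model_factor = 0.5`): each model pixel then
aggregates several native pixels and boundary positions are recovered at
sub-model-pixel precision.  Residual disagreement between aligned copies
of the same pattern scales roughly like (model/native)^1.5; at an imaging
ratio of 3 (384 px photographs, 128 px model frame — still far below the
ratio of real photographs to any feasible model frame) the maximum
pairwise disagreement on same-pattern sets is under 1% of the wing area,
the figure the alignment tests check.  Forewings and hindwings, and
dorsal and ventral sides, are always aligned in separate runs.

## Phenotype space

Every non-background pixel common to *all* aligned wings is a trait, with
the colour class one-hot encoded, so squared Euclidean distance between
specimens counts disagreeing pixels (x2).  PCA is centred and unscaled;
only components explaining more than `min_var_fraction` (default 1%) of
the variance are retained.  Genotype distance is the Euclidean distance
between genotype centroids in retained-component space.  Modal patterns
take the per-pixel mode over a genotype's specimens, excluding background
wherever any specimen shows colour; ties break by class declaration order
and are flagged.  Genotype separation is checked by leave-one-out linear
discriminant classification (`MASS::lda`, with a ridge-regularized
fallback for singular scatter) and by a permutation test on the
between/within distance ratio — the permutation analogue of a MANOVA,
chosen because parametric F statistics are meaningless at the small
synthetic sample sizes used here.

## Dominance quantification

For an allele pair (a, b) the per-individual trait toward `a` is

> T = #(pixels matching modal_a and differing from modal_b) / wing surface

computed over pixels where the individual and both modals are
non-background; pixels where the modals agree are uninformative and are
excluded from the numerator by construction.  The dominance of `a`
relative to `b` is the linear position of the heterozygote group mean
between the homozygote group means,

> h_raw = (T̄_ab − T̄_bb) / (T̄_aa − T̄_bb),

clipped to [0, 1] (clipping is flagged), and normalized to the dominant
direction, h = max(h_raw, 1 − h_raw) ∈ [0.5, 1]; h = 1 is strict
dominance, h ≈ 0.5 co-dominance.  T is computed per individual and then
averaged so that per-individual QC (e.g. the fraction of the wing
matching neither modal) and resampling are possible.

Dominance heat maps give, per pixel, the proportions of heterozygotes
matching the dominant modal only, the recessive only, both (where the
modals agree) or neither; the four proportions sum to 1 at every pixel
and render to red/blue/grey/white.  Colour-hierarchy statistics pool
*pixel-observations* — one heterozygous individual at one informative
pixel — with equal weight across allele pairs: `hierarchy_conformity()`
is the fraction of observations expressing the hierarchy-dominant of the
two modal colours; `full_dominance_conformity()` the fraction matching
one modal wholesale (both directions computed, larger reported);
`colour_expression_probability()` and `colour_hierarchy_map()` restrict
to a colour pair and report what heterozygotes express where homozygotes
differ in exactly those colours.

Group comparisons (sympatric vs parapatric h; conformity between allele
classes) use a two-sided permutation test on the mean difference.  When
`choose(n, n1)` is at most 20000 the null distribution is enumerated
exactly; otherwise `n_perm` random permutations give
p = (1 + #extreme)/(1 + n_perm), deterministic under the supplied seed.
The h–distance relation uses Pearson correlation with a permutation p by
shuffling the pairing.  No multiple-testing correction is applied across
allele pairs; pair analyses are reported as independent.

## Numerical choices and degenerate inputs

* Raster indexing is row-major, 0-based, origin top-left; transforms act
  about the image centre ((dim−1)/2).  All class rasters use
  nearest-neighbour or area-majority lookups — class labels are never
  blended.
* All ties (class assignment, modal vote, resampling vote, registration
  candidates) break deterministically by declaration order / parameter
  magnitude, so every pipeline output is bit-reproducible for a fixed
  config and master seed.  Per-specimen RNG streams are derived from
  (master seed, specimen id), making datasets order-independent.
* Degenerate inputs fail loudly: empty foreground, empty wing mask, empty
  common-pixel set, equal homozygote trait means ("uninformative pair"),
  missing pattern sidecar, empty registration grid.  Degenerate masks are
  excluded from alignment and logged; pairs whose modals nowhere differ
  are skipped with a warning.

## Test problem sizes

The acceptance-level tests run: 20 zero-noise specimens (categorization
oracle), 50 registrations at 256 px against a twin model (transform
recovery within 0.5 px / 0.5 degrees / 1% scale), 8-wing alignment at
384/128 px (disagreement < 1%), five 40-specimen crosses at 256 px for
programmed mosaic dominance p in {0.5, 0.6, 0.75, 0.9, 1}, two 24- and
12-specimen crosses for mechanism discrimination, 1000-replicate
permutation-null calibration, and a 20-specimen four-genotype run for the
3-component leave-one-out check.  These sizes keep the full suite within
a few minutes on one core while leaving each property's sampling error
well below its test tolerance.

## Known limitations

* Similarity transforms only; shape change beyond translation/rotation/
  scale (allometry, wing damage, non-rigid deformation) ends up as
  pattern noise rather than being absorbed by the registration.
* The registration score landscape is piecewise constant, so the
  optimizer recovers transforms to roughly the boundary-quantization
  limit, not to arbitrary precision; equivariance under common input
  transforms holds to well under 1% of pixels but not bit-exactly.
* The colour set is fixed at three wing colours; extending it means
  extending the class table and centroids, which all structures take as
  parameters.
* One wing surface per run: combining the four photographed surfaces of a
  specimen into one h estimate is left to the caller (the default
  recommendation is averaging per-surface h values).
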
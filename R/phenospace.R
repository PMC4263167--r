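#' Build the pixel-as-trait matrix
#'
#' Every non-background pixel common to all aligned wings is a trait;
#' colour classes are one-hot encoded (one indicator column per colour
#' class per pixel), so Euclidean row distance counts disagreeing pixels
#' (times sqrt(2)).
#'
#' @param aligned named list of [colour_pattern]s in model space, same
#'   resolution.
#' @return a `trait_matrix`: list with `x` (specimens x traits matrix),
#'   `pixel_index` (linear indices of retained pixels in the model frame),
#'   `dim_model`, `classes`, and `retained_fraction` (retained pixels /
#'   union of wing pixels).
#' @export
build_trait_matrix <- function(aligned) {
  aligned <- aligned[!vapply(aligned, is.null, NA)]
  if (length(aligned) < 1) stop("no aligned patterns")
  dims <- dim(aligned[[1]]$grid)
  grids <- vapply(aligned, function(p) {
    stopifnot(identical(dim(p$grid), dims), p$space == "model")
    as.vector(p$grid)
  }, integer(prod(dims)))
  common <- rowSums(grids > 0L) == ncol(grids)
  anywing <- rowSums(grids > 0L) > 0
  if (!any(common)) stop("empty common-pixel set: alignment failure")
  K <- length(aligned[[1]]$classes) - 1L   # colour classes
  sub <- grids[common, , drop = FALSE]     # pixels x specimens
  n <- ncol(sub); P <- nrow(sub)
  x <- matrix(0, n, P * K)
  for (cl in seq_len(K)) {
    x[, seq.int(cl, by = K, length.out = P)] <- t(sub == cl)
  }
  rownames(x) <- names(aligned)
  structure(list(x = x, pixel_index = which(common), dim_model = dims,
                 classes = aligned[[1]]$classes,
                 retained_fraction = sum(common) / sum(anywing)),
            class = "trait_matrix")
}

#' Component retention rule
#'
#' Retains exactly the components whose variance fraction exceeds the
#' threshold.
#'
#' @param var_frac numeric vector of variance fractions.
#' @param min_var_fraction threshold (default 1%).
#' @return integer vector of retained component indices.
#' @export
retain_components <- function(var_frac, min_var_fraction = 0.01) {
  which(var_frac > min_var_fraction)
}

#' PCA summary of the trait matrix
#'
#' Centred (unscaled) PCA of the pixel-trait matrix; only components
#' explaining more than `min_var_fraction` of the variance are retained.
#'
#' @param tm a `trait_matrix` (or bare numeric matrix).
#' @param min_var_fraction retention threshold on the variance fraction.
#' @return list with `scores` (specimens x retained components),
#'   `rotation`, `var_frac` (all components), `retained` (indices).
#' @export
pca_summary <- function(tm, min_var_fraction = 0.01) {
  x <- if (inherits(tm, "trait_matrix")) tm$x else tm
  if (nrow(x) < 3) stop("need >= 3 specimens for PCA")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  if (sum(v) <= 0) stop("no variance in trait matrix")
  var_frac <- v / sum(v)
  keep <- retain_components(var_frac, min_var_fraction)
  if (!length(keep)) stop("no component exceeds the variance threshold")
  list(scores = pc$x[, keep, drop = FALSE],
       rotation = pc$rotation[, keep, drop = FALSE],
       var_frac = var_frac, retained = keep)
}

#' Phenotypic distance between two genotypes
#'
#' Euclidean distance between the centroid positions of the two genotype
#' groups in retained-component space.
#'
#' @param scores specimens x components score matrix.
#' @param labels genotype label per specimen.
#' @param gA,gB genotype labels to compare (each needs >= 2 specimens).
#' @return non-negative scalar distance.
#' @export
genotype_distance <- function(scores, labels, gA, gB) {
  for (g in c(gA, gB)) {
    if (!g %in% labels) stop("unknown genotype label: ", g)
    if (sum(labels == g) < 2) stop("genotype needs >= 2 specimens: ", g)
  }
  ca <- colMeans(scores[labels == gA, , drop = FALSE])
  cb <- colMeans(scores[labels == gB, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' Modal pattern of a genotype
#'
#' Per-pixel mode over all specimens of the genotype.  Background is
#' excluded from the vote wherever at least one specimen shows colour;
#' ties break to the class declared earlier and are flagged.
#'
#' @param aligned list of [colour_pattern]s in model space (the specimens
#'   of one genotype).
#' @param genotype genotype label stored on the result.
#' @return a `modal_pattern`: [colour_pattern] with attributes `"n"`,
#'   `"genotype"`, `"support"` (specimens voting per pixel) and
#'   `"tie"` (logical matrix of tie pixels).
#' @export
modal_pattern <- function(aligned, genotype = NA_character_) {
  aligned <- aligned[!vapply(aligned, is.null, NA)]
  if (length(aligned) < 2) stop("modal pattern needs >= 2 specimens")
  dims <- dim(aligned[[1]]$grid)
  K <- length(aligned[[1]]$classes)
  counts <- array(0L, c(dims[1], dims[2], K))
  for (p in aligned) {
    stopifnot(identical(dim(p$grid), dims))
    for (cl in seq_len(K) - 1L)
      counts[, , cl + 1L] <- counts[, , cl + 1L] + (p$grid == cl)
  }
  colour_counts <- counts[, , -1, drop = FALSE]
  any_colour <- apply(colour_counts, c(1, 2), sum) > 0
  # background wins only where no specimen shows colour
  flat <- matrix(colour_counts, dims[1] * dims[2], K - 1)
  best <- max.col(flat, ties.method = "first")    # earliest class wins ties
  best_count <- flat[cbind(seq_len(nrow(flat)), best)]
  tie <- rowSums(flat == best_count) > 1 & best_count > 0
  g <- matrix(0L, dims[1], dims[2])
  g[any_colour] <- best[any_colour]
  out <- colour_pattern(g, aligned[[1]]$classes, "model")
  attr(out, "n") <- length(aligned)
  attr(out, "genotype") <- genotype
  attr(out, "support") <- matrix(best_count, dims[1], dims[2]) * any_colour
  attr(out, "tie") <- matrix(tie, dims[1], dims[2]) & any_colour
  class(out) <- c("modal_pattern", class(out))
  out
}

#' Leave-one-out genotype classification accuracy
#'
#' Leave-one-out cross-validated accuracy of a linear discriminant
#' classifier on the first `k` retained components.  A singular
#' within-class scatter falls back to a ridge-regularized discriminant
#' (noted in attribute `"regularized"`).
#'
#' @param scores specimens x components matrix.
#' @param labels class label per specimen (each class >= 2 members).
#' @param k number of leading components to use.
#' @return accuracy fraction in \[0, 1\].
#' @export
crossvalidate_genotypes <- function(scores, labels, k = 3) {
  stopifnot(k >= 1, k <= ncol(scores))
  labels <- as.character(labels)
  if (any(table(labels) < 2)) stop("every class needs >= 2 members")
  x <- scores[, seq_len(k), drop = FALSE]
  n <- nrow(x)
  regularized <- FALSE
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(MASS::lda(x[-i, , drop = FALSE], grouping = labels[-i]),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      pred[i] <- as.character(stats::predict(fit, x[i, , drop = FALSE])$class)
    } else {
      regularized <- TRUE
      pred[i] <- ridge_lda_predict(x[-i, , drop = FALSE], labels[-i],
                                   x[i, , drop = FALSE])
    }
  }
  out <- mean(pred == labels)
  attr(out, "regularized") <- regularized
  out
}

# ridge-regularized linear discriminant: pooled covariance + lambda*I,
# classify by Mahalanobis distance to class means
ridge_lda_predict <- function(x, labels, newx, lambda = 1e-6) {
  cls <- unique(labels)
  p <- ncol(x)
  pooled <- matrix(0, p, p)
  for (cl in cls) {
    xc <- x[labels == cl, , drop = FALSE]
    if (nrow(xc) > 1) pooled <- pooled + crossprod(scale(xc, scale = FALSE))
  }
  pooled <- pooled / max(1, nrow(x) - length(cls))
  pooled <- pooled + diag(lambda * max(1, mean(diag(pooled))), p)
  inv <- solve(pooled)
  d <- vapply(cls, function(cl) {
    mu <- colMeans(x[labels == cl, , drop = FALSE])
    v <- as.numeric(newx) - mu
    as.numeric(t(v) %*% inv %*% v)
  }, 0)
  cls[which.min(d)]
}

#' Permutation check of genotype separation
#'
#' Permutation analogue of a MANOVA on genotype groups: the observed
#' ratio of between-group to within-group mean squared distance in score
#' space is compared with its distribution under label permutation.
#'
#' @param scores specimens x components matrix.
#' @param labels genotype label per specimen.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return list with `statistic` (between/within ratio) and `p`.
#' @export
genotype_separation_test <- function(scores, labels, n_perm = 999, seed = 1) {
  stat <- function(lab) {
    grand <- colMeans(scores)
    between <- 0; within <- 0
    for (g in unique(lab)) {
      xg <- scores[lab == g, , drop = FALSE]
      mu <- colMeans(xg)
      between <- between + nrow(xg) * sum((mu - grand)^2)
      within <- within + sum(sweep(xg, 2, mu)^2)
    }
    if (within == 0) Inf else between / within
  }
  obs <- stat(labels)
  with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm))
      if (stat(sample(labels)) >= obs - 1e-12) cnt <- cnt + 1L
    list(statistic = obs, p = (1 + cnt) / (1 + n_perm))
  })
}
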
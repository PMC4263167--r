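#' Permutation test for a two-group mean difference
#'
#' Two-sided test of `mean(group1) - mean(group2)` against the
#' distribution obtained by permuting group labels.  When the number of
#' distinct label assignments is small enough the test enumerates all of
#' them exactly (p = fraction of assignments, including the observed one,
#' with an absolute difference at least as large); otherwise it samples
#' `n_perm` random permutations and reports
#' `p = (1 + #extreme) / (1 + n_perm)`, deterministic given `seed`.
#'
#' @param values numeric vector.
#' @param labels two-level group label per value.
#' @param n_perm number of random permutations (Monte Carlo mode).
#' @param seed RNG seed (Monte Carlo mode).
#' @param exact `"auto"` (enumerate when feasible), `"always"`, `"never"`.
#' @param max_exact enumeration limit on `choose(n, n1)`.
#' @return list with `observed`, `p`, `method` (`"exact"` or
#'   `"montecarlo"`) and `n_used` (assignments or permutations).
#' @export
permutation_test_mean_difference <- function(values, labels, n_perm = 999,
                                             seed = 1,
                                             exact = c("auto", "always", "never"),
                                             max_exact = 20000) {
  exact <- match.arg(exact)
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2) stop("labels must have exactly two levels")
  if (n_perm < 99) stop("n_perm must be >= 99")
  g1 <- values[labels == lv[1]]; g2 <- values[labels == lv[2]]
  if (!length(g1) || !length(g2)) stop("both groups must be non-empty")
  obs <- mean(g1) - mean(g2)
  n <- length(values); n1 <- length(g1)
  total <- choose(n, n1)
  eps <- 1e-12
  if (exact == "always" || (exact == "auto" && total <= max_exact)) {
    sets <- combn(n, n1)
    diffs <- apply(sets, 2, function(ix)
      mean(values[ix]) - mean(values[-ix]))
    p <- mean(abs(diffs) >= abs(obs) - eps)
    return(list(observed = obs, p = p, method = "exact", n_used = ncol(sets)))
  }
  with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      ix <- sample.int(n, n1)
      if (abs(mean(values[ix]) - mean(values[-ix])) >= abs(obs) - eps)
        cnt <- cnt + 1L
    }
    list(observed = obs, p = (1 + cnt) / (1 + n_perm),
         method = "montecarlo", n_used = n_perm)
  })
}

#' Correlation between dominance and phenotypic distance
#'
#' Pearson correlation of per-pair dominance coefficients with the
#' phenotypic distance between the corresponding homozygotes, with a
#' two-sided permutation p-value obtained by shuffling the pairing.
#'
#' @param h numeric vector of dominance coefficients, one per allele pair.
#' @param distance matching vector of homozygote phenotypic distances.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `r`, `r_squared`, `p`, `n_pairs`.
#' @export
correlate_h_distance <- function(h, distance, n_perm = 999, seed = 1) {
  stopifnot(length(h) == length(distance))
  if (length(h) < 3) stop("need >= 3 allele pairs")
  if (sd(h) == 0 || sd(distance) == 0)
    stop("zero variance in h or distance")
  r <- cor(h, distance)
  with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm))
      if (abs(cor(sample(h), distance)) >= abs(r) - 1e-12) cnt <- cnt + 1L
    list(r = r, r_squared = r^2, p = (1 + cnt) / (1 + n_perm),
         n_pairs = length(h))
  })
}
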
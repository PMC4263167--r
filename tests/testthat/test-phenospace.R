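aligned_fixture <- function() {
  fixture("aligned_mixed", function() {
    al <- demo_alleles(ancestral = TRUE)
    out <- list(); labels <- character()
    for (g in list(c("arc", "arc"), c("bic", "bic"), c("tar", "tar"),
                   c("sil", "sil"))) {
      for (i in 1:4) {
        ind <- render_individual(g, al, NULL, noise_model(), seed = i,
                                 resolution = test_res)
        id <- sprintf("%s_%d", g[1], i)
        out[[id]] <- ind$truth   # model-space truths double as aligned data
        labels[id] <- paste(g, collapse = "/")
      }
    }
    # per-specimen jitter so rows are not literally identical
    out <- lapply(seq_along(out), function(k) {
      p <- out[[k]]
      set.seed(k)
      idx <- sample(which(p$grid > 0), 30)
      p$grid[idx] <- sample(1:3, 30, TRUE)
      p
    })
    names(out) <- names(labels)
    list(aligned = out, labels = labels)
  })
}

test_that("trait matrix obeys the common-pixel rule and one-hot encoding", {
  p <- fx_truth("arc", res = 32)
  tm <- build_trait_matrix(list(a = p, b = p, c = p))
  expect_equal(nrow(tm$x), 3)
  expect_true(all(tm$x[1, ] == tm$x[2, ]))
  # indicator encoding sums to 1 per pixel per specimen
  expect_true(all(rowSums(tm$x) == length(tm$pixel_index)))

  # a hole in one wing drops that pixel column for all specimens
  q <- p
  hole <- which(q$grid > 0)[1:10]
  q$grid[hole] <- 0L
  tm2 <- build_trait_matrix(list(a = p, b = q))
  expect_equal(length(tm2$pixel_index), sum(p$grid > 0) - 10)
  expect_false(any(hole %in% tm2$pixel_index))
})

test_that("between-genotype distances dominate within-genotype distances", {
  fx <- aligned_fixture()
  tm <- build_trait_matrix(fx$aligned)
  d <- as.matrix(dist(tm$x))
  same <- outer(fx$labels, fx$labels, "==")
  diag(same) <- NA
  expect_gt(mean(d[!same], na.rm = TRUE), 5 * mean(d[same], na.rm = TRUE))
})

test_that("component retention follows the variance-fraction threshold exactly", {
  vf <- c(0.50, 0.30, 0.10, 0.05, 0.03, 0.015, 0.005)
  expect_equal(retain_components(vf, 0.01), 1:6)
  expect_equal(retain_components(c(0.6, 0.4), 0.5), 1L)
})

test_that("PCA scores preserve pairwise distances when all components kept", {
  fx <- aligned_fixture()
  tm <- build_trait_matrix(fx$aligned)
  pc <- prcomp(tm$x, center = TRUE)
  expect_equal(as.matrix(dist(pc$x)), as.matrix(dist(tm$x)),
               tolerance = 1e-8)
  # duplicated specimens score identically
  tm2 <- rbind(tm$x[1, , drop = FALSE], tm$x)
  pc2 <- pca_summary(tm2, min_var_fraction = 0.01)
  expect_equal(unname(pc2$scores[1, ]), unname(pc2$scores[2, ]),
               tolerance = 1e-8)
})

test_that("a constant trait matrix is rejected", {
  x <- matrix(1, 5, 10)
  expect_error(pca_summary(x), "no variance")
})

test_that("genotype distance is a centroid Euclidean distance", {
  scores <- rbind(c(0, 0), c(2, 0), c(5, 4), c(7, 4))
  labels <- c("g1", "g1", "g2", "g2")
  expect_equal(genotype_distance(scores, labels, "g1", "g1"), 0)
  # centroids (1,0) and (6,4): distance sqrt(41)
  expect_equal(genotype_distance(scores, labels, "g1", "g2"), sqrt(41))
  expect_error(genotype_distance(scores, labels, "g1", "zz"), "unknown genotype")
})

test_that("modal pattern takes the per-pixel mode with declared-order ties", {
  make <- function(code) cp(matrix(code, 2, 2))
  pats <- lapply(c(1, 1, 2, 1, 3), make)   # black,black,orange,black,yellow
  m <- modal_pattern(pats)
  expect_true(all(m$grid == 1L))           # black wins
  # order invariance
  m2 <- modal_pattern(rev(pats))
  expect_identical(m$grid, m2$grid)
  # tie between orange and yellow -> orange (earlier), flagged
  pats3 <- lapply(c(2, 3), make)
  m3 <- modal_pattern(pats3)
  expect_true(all(m3$grid == 2L))
  expect_true(all(attr(m3, "tie")))
  # background excluded from the vote when any specimen shows colour
  pats4 <- lapply(c(0, 0, 3), make)
  m4 <- modal_pattern(pats4)
  expect_true(all(m4$grid == 3L))
  expect_error(modal_pattern(pats[1]), ">= 2")
})

test_that("zero-noise homozygote modal equals the allele raster", {
  p <- fx_truth("bic", res = 64)
  m <- modal_pattern(list(p, p, p))
  expect_identical(m$grid, p$grid)
})

test_that("LOO classification separates genotypes and collapses under permutation", {
  fx <- aligned_fixture()
  tm <- build_trait_matrix(fx$aligned)
  pc <- pca_summary(tm)
  acc <- crossvalidate_genotypes(pc$scores, fx$labels, k = 3)
  expect_equal(as.numeric(acc), 1.0)
  # permuted labels: near-chance accuracy (3 classes)
  set.seed(7)
  accs <- replicate(20, {
    as.numeric(crossvalidate_genotypes(pc$scores, sample(fx$labels), k = 3))
  })
  expect_lt(mean(accs), 1 / 4 + 0.25)
  # two identical groups are indistinguishable
  scores <- matrix(rep(rnorm(6), 2), 12, 1)
  labs <- rep(c("x", "y"), each = 6)
  acc2 <- crossvalidate_genotypes(scores, labs, k = 1)
  expect_lt(as.numeric(acc2), 0.75)
})

test_that("genotype separation permutation test flags real structure only", {
  fx <- aligned_fixture()
  tm <- build_trait_matrix(fx$aligned)
  pc <- pca_summary(tm)
  real <- genotype_separation_test(pc$scores, fx$labels, n_perm = 199, seed = 2)
  expect_lt(real$p, 0.05)
  set.seed(3)
  null <- genotype_separation_test(pc$scores, sample(fx$labels),
                                   n_perm = 199, seed = 2)
  expect_gt(null$p, 0.05)
})
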
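shift_pattern <- function(p, dx, dy) {
  tf_apply(p, similarity_transform(tx = dx, ty = dy), space = p$space)
}

test_that("outline alignment recovers relative translation and scale", {
  p <- fx_truth("arc", res = test_res)
  p_nat <- colour_pattern(p$grid, p$classes, "native")
  q <- shift_pattern(p_nat, 10, -4)
  tfs <- initial_outline_alignment(list(p_nat, q))
  rel <- tf_compose(tf_invert(tfs[[1]]), tfs[[2]])   # q frame -> p frame
  expect_lt(abs(rel$tx - (-10)), 0.5)
  expect_lt(abs(rel$ty - 4), 0.5)
  expect_lt(abs(rel$theta), 0.5)
  expect_lt(abs(rel$s - 1), 0.01)

  # embed a 128-px wing in a 256-px frame so a x1.2 blow-up is not clipped
  emb <- matrix(0L, 256, 256)
  emb[65:192, 65:192] <- fx_truth("arc", res = 128)$grid
  p256n <- colour_pattern(emb, space = "native")
  qs <- tf_apply(p256n, similarity_transform(s = 1.2), space = "native")
  tfs2 <- initial_outline_alignment(list(p256n, qs))
  rel2 <- tf_compose(tf_invert(tfs2[[1]]), tfs2[[2]])
  expect_lt(abs(rel2$s - 1 / 1.2), 0.01)

  # identical masks get identical transforms
  tfs3 <- initial_outline_alignment(list(p_nat, p_nat))
  expect_equal(tfs3[[1]], tfs3[[2]])
})

test_that("degenerate masks are excluded from outline alignment", {
  p <- fx_truth("arc", res = 64)
  p_nat <- colour_pattern(p$grid, p$classes, "native")
  m <- matrix(0L, 64, 64); m[30, 30] <- 1L
  tiny <- colour_pattern(m, space = "native")
  tfs <- initial_outline_alignment(list(p_nat, p_nat, tiny))
  expect_equal(attr(tfs, "excluded"), 3L)
  expect_null(tfs[[3]])
})

test_that("similarity score hits its closed-form anchors", {
  p <- fx_truth("bic", res = 64)
  p_nat <- colour_pattern(p$grid, p$classes, "native")
  id <- similarity_transform()
  m1 <- build_wing_model(list(p_nat), list(id), dim(p$grid))
  expect_equal(similarity_score(p_nat, m1, id), 1.0)
  # model from two identical wings still has 0/1 frequencies
  m2 <- build_wing_model(list(p_nat, p_nat), list(id, id), dim(p$grid))
  expect_equal(similarity_score(p_nat, m2, id), 1.0)
  # uniformly background pattern against a zero-background model pixel set
  bg <- colour_pattern(matrix(0L, 64, 64), space = "native")
  m3 <- m1
  m3$support <- (m1$freq[, , 1] == 0) * 1L   # only pixels with no bg freq
  expect_equal(similarity_score(bg, m3, id), 0.0)
})

test_that("model frequencies sum to one wherever supported", {
  pats <- fx_homo_patterns(4)
  tfs <- initial_outline_alignment(pats)
  m <- build_wing_model(pats, tfs, dim(pats[[1]]$grid))
  tot <- apply(m$freq, c(1, 2), sum)
  expect_true(all(abs(tot[m$support > 0] - 1) < 1e-9))
  expect_true(all(tot[m$support == 0] == 0))
})

test_that("registration recovers known transforms and keeps identity on self-match", {
  al <- demo_alleles()
  truth <- fx_truth("arc", res = test_res)
  twin <- colour_pattern(truth$grid, truth$classes, "native")
  model <- build_wing_model(list(twin), list(similarity_transform()),
                            dim(truth$grid))
  ind <- render_individual(c("arc", "arc"), al, NULL,
                           noise_transform_only(10, 10, c(0.95, 1.05)),
                           seed = 9, resolution = test_res)
  pat <- categorize(ind$rgb, extract_outline(ind$rgb))
  est <- register_to_model(pat, model)
  expect_lt(abs(est$tx - ind$to_model$tx), 0.5)
  expect_lt(abs(est$ty - ind$to_model$ty), 0.5)
  expect_lt(abs(est$theta - ind$to_model$theta), 0.5)
  expect_lt(abs(est$s / ind$to_model$s - 1), 0.01)

  # consensus pattern: identity maximal, returned unchanged
  est2 <- register_to_model(twin, model, init = similarity_transform())
  expect_equal(attr(est2, "score"), 1.0)
  expect_equal(est2$tx, 0); expect_equal(est2$theta, 0); expect_equal(est2$s, 1)

  # pure noise: low score, no crash
  set.seed(1)
  noise <- colour_pattern(matrix(sample(0:3, 64^2, TRUE), 64, 64),
                          space = "native")
  m64 <- build_wing_model(list(colour_pattern(fx_truth("arc", res = 64)$grid,
                                              space = "native")),
                          list(similarity_transform()), c(64, 64))
  est3 <- register_to_model(noise, m64)
  expect_s3_class(est3, "similarity_transform")
  expect_lt(attr(est3, "score"), 0.8)
})

test_that("empty search grid and bad iteration counts are rejected", {
  expect_error(search_spec(grid_tx = numeric()), "empty search grid")
  expect_error(align_recursive(fx_homo_patterns(2), n_iter = 0), "n_iter")
})

test_that("recursive alignment converges with a non-decreasing mean score", {
  pats <- fx_homo_patterns(6)
  res <- align_recursive(pats, n_iter = 5, tol = 1e-4)
  sc <- res$trace$mean_score
  expect_true(all(diff(sc) > -1e-9))
  # pairwise disagreement small relative to wing area
  g <- sapply(res$aligned, function(p) as.vector(p$grid))
  area <- mean(sapply(res$aligned, function(p) sum(p$grid > 0)))
  dis <- combn(ncol(g), 2, function(ix) sum(g[, ix[1]] != g[, ix[2]]))
  expect_lt(max(dis) / area, 0.03)
})

test_that("an already-aligned set converges immediately and keeps its model", {
  p <- fx_truth("tar", res = 64)
  pats <- list(colour_pattern(p$grid, p$classes, "native"),
               colour_pattern(p$grid, p$classes, "native"))
  res <- align_recursive(pats, n_iter = 3, tol = 1e-2, model_factor = 1)
  expect_lte(max(res$trace$iteration), 2)
  expect_identical(res$aligned[[1]]$grid, res$aligned[[2]]$grid)
  # model frequencies are the 0/1 average of identical wings
  expect_true(all(res$model$freq %in% c(0, 1)))
})

test_that("alignment is equivariant under a common integer translation", {
  pats <- fx_homo_patterns(4)
  shifted <- lapply(pats, shift_pattern, dx = 3, dy = -2)
  r1 <- align_recursive(pats, n_iter = 2, tol = 1e-4)
  r2 <- align_recursive(shifted, n_iter = 2, tol = 1e-4)
  # equivariant up to search-path tie sensitivity at boundary pixels
  same <- mapply(function(a, b) mean(a$grid == b$grid), r1$aligned, r2$aligned)
  expect_true(all(same > 0.99))
})
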
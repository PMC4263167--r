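# hand-built 10x10 modal patterns: modals differ on 40 of 100 pixels
modals_40 <- function() {
  ga <- matrix(1L, 10, 10)                 # all black
  gb <- ga; gb[, 1:4] <- 2L                # orange on 40% of the surface
  list(a = cp(ga), b = cp(gb))
}

test_that("trait T counts matching pixels normalized by wing surface", {
  m <- modals_40()
  # individual identical to modal_a
  t1 <- trait_T(m$a, m$a, m$b)
  expect_equal(t1$T_a, 0.40)
  expect_equal(t1$T_b, 0)
  expect_equal(t1$neither, 0)
  # individual identical to modal_b
  t2 <- trait_T(m$b, m$a, m$b)
  expect_equal(t2$T_a, 0)
  expect_equal(t2$T_b, 0.40)
  # half the informative pixels from each modal
  gi <- m$a$grid; gi[, 1:2] <- 2L
  t3 <- trait_T(cp(gi), m$a, m$b)
  expect_equal(t3$T_a, 0.20)
  expect_equal(t3$T_b, 0.20)
  expect_equal(t3$informative_fraction, 0.40)
  expect_error(trait_T(cp(matrix(0L, 10, 10)), m$a, m$b), "empty wing surface")
})

test_that("dominance coefficient matches its closed-form anchors exactly", {
  r1 <- dominance_coefficient(0.8, 0.8, 0.2, pair = c("a", "b"))
  expect_identical(r1$h_raw, 1)
  expect_identical(r1$h, 1)
  expect_identical(r1$dominant_allele, "a")
  r2 <- dominance_coefficient(0.8, 0.5, 0.2)
  expect_equal(r2$h_raw, 0.5, tolerance = 1e-14)
  expect_equal(r2$h, 0.5, tolerance = 1e-14)
  r3 <- dominance_coefficient(0.8, 0.35, 0.2, pair = c("a", "b"))
  expect_equal(r3$h_raw, 0.25, tolerance = 1e-14)
  expect_equal(r3$h, 0.75, tolerance = 1e-14)
  expect_identical(r3$dominant_allele, "b")
  expect_error(dominance_coefficient(0.5, 0.3, 0.5), "uninformative")
})

test_that("normalized h stays in [0.5, 1] over random trait triples", {
  set.seed(123)
  for (i in 1:1000) {
    Tm <- runif(3)
    if (Tm[1] == Tm[3]) next
    r <- dominance_coefficient(Tm[1], Tm[2], Tm[3])
    expect_gte(r$h, 0.5)
    expect_lte(r$h, 1)
    expect_equal(r$h, max(r$h_raw, 1 - r$h_raw))
  }
})

test_that("heat map proportions are exact counts and sum to one", {
  m <- modals_40()
  # 10 hets: 7 match dominant(a) only, 2 match both is impossible where
  # modals differ, so build per-pixel expectations on an informative pixel
  hets <- c(lapply(1:7, function(i) m$a),          # match dominant only
            lapply(1:2, function(i) m$b),          # match recessive only
            list(cp(matrix(3L, 10, 10))))          # matches neither
  hm <- dominance_heatmap(hets, m$a, m$b)
  inf <- m$a$grid != m$b$grid
  expect_true(all(hm$prop[, , 1][inf] == 0.7))
  expect_true(all(hm$prop[, , 2][inf] == 0.2))
  expect_true(all(hm$prop[, , 3][inf] == 0))
  expect_true(all(hm$prop[, , 4][inf] == 0.1))
  # where modals agree, matching both counts as "both"
  agree <- !inf
  expect_true(all(hm$prop[, , 3][agree] == 0.9))
  # conservation everywhere
  expect_true(all(abs(apply(hm$prop, c(1, 2), sum) - 1) < 1e-9))
  # rendering has the right shape and range
  rgb <- heatmap_to_rgb(hm)
  expect_true(all(rgb >= 0 & rgb <= 1))
})

test_that("hets identical to the dominant modal give an all-dominant/both map", {
  m <- modals_40()
  hm <- dominance_heatmap(list(m$a, m$a), m$a, m$b)
  expect_true(all(hm$prop[, , 1] + hm$prop[, , 3] == 1))
})

test_that("hierarchy conformity is exact on hierarchy-resolved pixels", {
  m <- modals_40()   # black vs orange
  het_hier <- m$a    # black everywhere = hierarchy-dominant colour
  g <- list(hets = list(het_hier), modal_a = m$a, modal_b = m$b)
  expect_equal(as.numeric(hierarchy_conformity(g)), 1.0)
  # het expressing the recessive colour everywhere conforms nowhere
  g2 <- list(hets = list(m$b), modal_a = m$a, modal_b = m$b)
  expect_equal(as.numeric(hierarchy_conformity(g2)), 0.0)
})

test_that("hierarchy conformity estimates a programmed per-pixel probability", {
  m <- modals_40()
  inf <- which(m$a$grid != m$b$grid)
  set.seed(11)
  hets <- lapply(1:300, function(i) {
    g <- m$a$grid
    flip <- inf[runif(length(inf)) > 0.79]
    g[flip] <- 2L
    cp(g)
  })
  gr <- list(hets = hets, modal_a = m$a, modal_b = m$b)
  est <- hierarchy_conformity(gr)
  expect_gte(attr(est, "n"), 1e4)
  expect_lt(abs(as.numeric(est) - 0.79), 0.02)
})

test_that("full-dominance conformity reports the better direction", {
  m <- modals_40()
  g <- list(hets = list(m$b, m$b), modal_a = m$a, modal_b = m$b)
  fd <- full_dominance_conformity(g, "a", "b")
  expect_equal(as.numeric(fd), 1.0)
  expect_equal(attr(fd, "direction"), "b")
  expect_equal(attr(fd, "toward_a"), 0)
})

test_that("colour expression probabilities recover a programmed mixing rate", {
  m <- modals_40()   # black (a) vs orange (b)
  inf <- which(m$a$grid != m$b$grid)
  set.seed(5)
  q <- 0.3
  hets <- lapply(1:200, function(i) {
    g <- m$a$grid
    flip <- inf[runif(length(inf)) < q]
    g[flip] <- 3L   # yellow where homozygotes show black vs orange
    cp(g)
  })
  gr <- list(hets = hets, modal_a = m$a, modal_b = m$b)
  pr <- colour_expression_probability(gr, c("black", "orange"))
  expect_lt(abs(pr[["other"]] - q), 0.02)
  expect_lt(abs(pr[["black"]] - (1 - q)), 0.02)
  expect_equal(sum(pr), 1)
  expect_warning(colour_expression_probability(gr, c("black", "yellow")),
                 "no pixel-observations")
})

test_that("colour hierarchy maps aggregate per-pixel proportions with remainder", {
  m <- modals_40()
  gr <- list(hets = list(m$a, m$b), modal_a = m$a, modal_b = m$b)
  chm <- colour_hierarchy_map(gr, c("black", "orange"))
  inf <- m$a$grid != m$b$grid
  expect_identical(chm$included, inf)
  expect_true(all(chm$prop[, , 1][inf] == 0.5))
  expect_true(all(chm$prop[, , 2][inf] == 0.5))
  tot <- apply(chm$prop, c(1, 2), sum)
  expect_true(all(abs(tot[inf] - 1) < 1e-9))
  rgb <- hierarchy_map_to_rgb(chm)
  expect_true(all(rgb >= 0 & rgb <= 1))
  expect_warning(colour_hierarchy_map(gr, c("orange", "yellow")),
                 "no contributing pixels")
})

test_that("mechanism discrimination: hierarchy beats full dominance and vice versa", {
  al <- demo_alleles(ancestral = TRUE)
  res <- 96
  # hierarchy-generated heterozygotes
  hier <- dominance_mechanism("colour_hierarchy")
  mk_group <- function(g1, g2, mech) {
    list(hets = list(resolve_genotype(al[[g1]], al[[g2]], mech, res)),
         modal_a = render_allele(al[[g1]], res),
         modal_b = render_allele(al[[g2]], res))
  }
  gh <- list(mk_group("arc", "bic", hier), mk_group("bic", "tar", hier))
  hc <- as.numeric(hierarchy_conformity(gh))
  fc <- as.numeric(full_dominance_conformity(gh))
  expect_equal(hc, 1.0)
  expect_gt(hc, fc)
  # full dominance of the melanic ancestral allele: anti-hierarchy where
  # sil shows yellow over a derived black region and black over yellow
  fd <- dominance_mechanism("full_dominance", dominant_allele = "sil")
  gf <- list(mk_group("sil", "bic", fd), mk_group("sil", "arc", fd))
  hc2 <- as.numeric(hierarchy_conformity(gf))
  fc2 <- as.numeric(full_dominance_conformity(gf))
  expect_equal(fc2, 1.0)
  expect_gt(fc2, hc2)
})
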
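test_that("homozygote render at zero noise and identity transform is exact", {
  al <- demo_alleles()
  ind <- render_individual(c("arc", "arc"), al, NULL, noise_model_zero(),
                           seed = 1, resolution = test_res)
  expect_identical(ind$truth$grid, render_allele(al$arc, test_res)$grid)
  expect_equal(ind$to_model, similarity_transform())
  # RGB maps back to the truth exactly
  pat <- categorize(ind$rgb, extract_outline(ind$rgb))
  expect_identical(pat$grid, ind$truth$grid)
})

test_that("colour hierarchy resolves disagreeing pixels to the dominant colour", {
  al <- demo_alleles()
  het <- resolve_genotype(al$arc, al$bic,
                          dominance_mechanism("colour_hierarchy"), test_res)
  ga <- render_allele(al$arc, test_res)$grid
  gb <- render_allele(al$bic, test_res)$grid
  cls <- cpm_classes()
  # wherever one allele says orange and the other yellow, output is orange
  oy <- (ga == match("orange", cls) - 1 & gb == match("yellow", cls) - 1) |
        (ga == match("yellow", cls) - 1 & gb == match("orange", cls) - 1)
  expect_true(any(oy))
  expect_true(all(het$grid[oy] == match("orange", cls) - 1))
  # black always wins
  bk <- match("black", cls) - 1
  anyblack <- (ga == bk | gb == bk) & ga != gb & ga > 0 & gb > 0
  expect_true(all(het$grid[anyblack] == bk))
})

test_that("full dominance reproduces the dominant homozygote exactly", {
  al <- demo_alleles()
  het <- resolve_genotype(al$arc, al$bic,
                          dominance_mechanism("full_dominance",
                                              dominant_allele = "arc"),
                          test_res)
  expect_identical(het$grid, render_allele(al$arc, test_res)$grid)
  het2 <- resolve_genotype(al$arc, al$bic,
                           dominance_mechanism("full_dominance",
                                               dominant_allele = "bic"),
                           test_res)
  expect_identical(het2$grid, render_allele(al$bic, test_res)$grid)
})

test_that("unknown allele and incomplete mosaic map raise errors", {
  al <- demo_alleles()
  expect_error(render_individual(c("arc", "nope"), al, NULL,
                                 noise_model_zero(), 1, test_res),
               "unknown allele")
  pair <- make_mosaic_pair(4)
  bad <- dominance_mechanism("mosaic",
                             patch_dominance_map = list("1" = "a", "2" = "b"))
  expect_error(resolve_genotype(pair$a, pair$b, bad, test_res),
               "missing patch index")
  expect_error(resolve_genotype(pair$a, pair$b,
                                dominance_mechanism("full_dominance",
                                                    dominant_allele = "zz"),
                                test_res),
               "unknown dominant allele")
})

test_that("mosaic programmed dominance matches brute-force pixel counting", {
  pair <- make_mosaic_pair(20)
  for (target in c(0.5, 0.7, 0.9)) {
    map <- mosaic_map_for_target(pair$a, pair$b, target, test_res)
    het <- resolve_genotype(pair$a, pair$b,
                            dominance_mechanism("mosaic",
                                                patch_dominance_map = map),
                            test_res)
    ga <- render_allele(pair$a, test_res)$grid
    gb <- render_allele(pair$b, test_res)$grid
    dis <- ga != gb
    brute <- sum(het$grid[dis] == ga[dis]) / sum(dis)
    expect_equal(attr(het, "frac_first"), brute)
    expect_equal(attr(map, "realized"), brute, tolerance = 1e-12)
    expect_lt(abs(brute - target), 0.03)
  }
})

test_that("simulated dataset has the right genotype combinatorics and is reproducible", {
  al <- demo_alleles()
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  unlink(c(d1, d2), recursive = TRUE)
  s1 <- simulate_cross_dataset(d1, al, n_per_genotype = 2,
                               noise = noise_model_zero(), seed = 5,
                               resolution = 64,
                               pair_class = c("arc/bic" = "sympatric"))
  # 3 alleles -> 3 homozygous + 3 heterozygous genotypes
  expect_equal(length(unique(paste(s1$table$allele_1, s1$table$allele_2))), 6)
  expect_equal(nrow(s1$table), 12)
  expect_equal(unique(s1$table$pair_class[s1$table$allele_1 == "arc" &
                                          s1$table$allele_2 == "bic"]),
               "sympatric")
  s2 <- simulate_cross_dataset(d2, al, n_per_genotype = 2,
                               noise = noise_model_zero(), seed = 5,
                               resolution = 64,
                               pair_class = c("arc/bic" = "sympatric"))
  expect_identical(readLines(file.path(d1, "specimens.tsv")),
                   readLines(file.path(d2, "specimens.tsv")))
  f <- s1$table$image_path[1]
  expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                   readBin(file.path(d2, f), "raw", 1e6))
})

test_that("zero-noise renders categorize back to the exact truth for heterozygotes too", {
  al <- demo_alleles()
  for (g in list(c("arc", "bic"), c("bic", "tar"))) {
    ind <- render_individual(g, al, dominance_mechanism(), noise_model_zero(),
                             seed = 3, resolution = test_res)
    pat <- categorize(ind$rgb, extract_outline(ind$rgb))
    expect_identical(pat$grid, ind$truth$grid)
  }
})

test_that("noise model validates its parameters", {
  expect_error(noise_model(boundary_jitter_sd = -1), "")
  expect_error(noise_model(transform_ranges =
    list(translation = 5, rotation = 5, scale = c(1.01, 1.2))),
    "contain 1")
})
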
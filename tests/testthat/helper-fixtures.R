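# Shared synthetic fixtures, built once per test session.  Unit tests run
# at a reduced canonical resolution (96-128 px) to keep the suite fast;
# resolution-sensitive properties are exercised at full scale in
# test-acceptance.R.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- build()
  fixture_env[[name]]
}

test_res <- 128

# transform-only nuisance (no jitter / colour noise)
noise_transform_only <- function(t = 8, r = 8, s = c(0.95, 1.05)) {
  noise_model(0, 0, list(translation = t, rotation = r, scale = s), 0)
}

# categorized homozygote set under transform-only noise
fx_homo_patterns <- function(n = 6, allele = "arc", res = test_res) {
  key <- paste("homo", n, allele, res)
  fixture(key, function() {
    al <- demo_alleles()
    lapply(seq_len(n), function(i) {
      ind <- render_individual(c(allele, allele), al, NULL,
                               noise_transform_only(), seed = i,
                               resolution = res)
      categorize(ind$rgb, extract_outline(ind$rgb))
    })
  })
}

# perfectly aligned zero-noise pattern for a genotype
fx_truth <- function(g1, g2 = g1, mech = dominance_mechanism(),
                     res = test_res) {
  al <- demo_alleles(ancestral = TRUE)
  resolve_genotype(al[[g1]], al[[g2]], mech, res)
}

# hand-built tiny colour_pattern from a code matrix
cp <- function(m, space = "model") {
  colour_pattern(matrix(as.integer(m), nrow(m), ncol(m)), space = space)
}
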
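test_that("expected contact vectors are proper probability distributions", {
  set.seed(20)
  for (i in 1:10) {
    m <- small_model(decay_alpha = runif(1, 0.5, 2))
    a <- allele_config("x", runif(1, 0.05, 1))
    p <- expected_contact_vector(m, a)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    # the viewpoint fragment itself carries no probability
    vp <- model_viewpoint(m)
    expect_equal(p[vp$fragment_index], 0)
  }
})

test_that("permeability scales cross-barrier contact as specified", {
  m <- small_model(enhancer_affinity_delta = 1.3)
  p1 <- expected_contact_vector(m, allele_config("open", 1))
  pb <- expected_contact_vector(m, allele_config("closed", 0.25))
  map <- model_fragment_map(m)
  mid <- (map$fragments$start + map$fragments$end) / 2
  cross <- mid > m$barrier_pos
  enh <- cross & mid >= m$enhancer_region$start & mid < m$enhancer_region$end
  # with beta = 1 the enhancer gets no bonus: vector is pure distance decay
  vp <- model_viewpoint(m)
  d <- abs(mid - (vp$position$start + vp$position$end) / 2)
  decay <- d^(-m$decay_alpha); decay[vp$fragment_index] <- 0
  expect_equal(p1, decay / sum(decay), tolerance = 1e-12)
  # un-normalized ratios: beta for neutral cross fragments, beta^delta in
  # the enhancer, 1 on the viewpoint side
  ratio <- pb / p1  # both normalized; constant factor within each class
  same <- !cross & seq_along(mid) != vp$fragment_index
  k <- ratio[same][1]  # common renormalization factor
  expect_equal(ratio[same], rep(k, sum(same)), tolerance = 1e-12)
  expect_equal(ratio[cross & !enh], rep(k * 0.25, sum(cross & !enh)),
               tolerance = 1e-12)
  expect_equal(ratio[enh], rep(k * 0.25^1.3, sum(enh)), tolerance = 1e-12)
})

test_that("beta near zero silences cross-barrier contact", {
  m <- small_model()
  p <- expected_contact_vector(m, allele_config("shut", 1e-9))
  map <- model_fragment_map(m)
  mid <- (map$fragments$start + map$fragments$end) / 2
  expect_lt(sum(p[mid > m$barrier_pos]), 1e-8)
})

test_that("simulated counts are multinomial, seeded, and depth-exact", {
  m <- small_model()
  a <- allele_config("x", 0.5)
  fc <- simulate_counts(m, a, 12345, seed = 9)
  expect_equal(sum(fc$counts), 12345)
  expect_identical(simulate_counts(m, a, 12345, seed = 9)$counts, fc$counts)
  expect_false(identical(simulate_counts(m, a, 12345, seed = 10)$counts,
                         fc$counts))
  expect_error(simulate_counts(m, a, 0, seed = 1), "depth")

  # empirical frequencies near p within binomial error at high depth
  N <- 1e6
  p <- expected_contact_vector(m, a)
  big <- simulate_counts(m, a, N, seed = 11)
  dev <- abs(big$counts / N - p)
  bound <- 3 * sqrt(p * (1 - p) / N)
  expect_gte(mean(dev <= bound | p == 0), 0.99)
})

test_that("expression follows the power law with seeded lognormal noise", {
  m <- small_model(noise_sigma = 0)
  expect_equal(simulate_expression(0.2, m, 1),
               m$expression_scale * 0.2^m$expression_exponent)
  m4 <- small_model(noise_sigma = 0, expression_exponent = 4)
  expect_equal(simulate_expression(0.2, m4, 1) / simulate_expression(0.1, m4, 1),
               16, tolerance = 1e-12)
  mn <- small_model(noise_sigma = 0.3)
  expect_identical(simulate_expression(0.2, mn, 5),
                   simulate_expression(0.2, mn, 5))
  expect_error(simulate_expression(0, mn, 1), "> 0")
})

test_that("the default allelic panel obeys the permeability ordering", {
  panel <- default_allele_panel()
  b <- vapply(panel, `[[`, 0, "beta")
  expect_length(panel, 9L)
  expect_equal(unname(b["Hap"]), 1)
  expect_equal(unname(b["del(L1-R3)"]), 1)
  expect_true(b["Hap"] > b["del(L1-R2)"])
  expect_true(b["del(L1-R2)"] > b["del(L2-R2)"])
  expect_true(all(b["del(L2-R2)"] > b[c("delL", "delR", "invR")]))
  expect_true(all(b[c("delL", "delR", "invR")] > b["STITCH"]))
  expect_equal(unname(b["STITCH"]), unname(b["inv(L1-R3)"]))
})

test_that("panels are complete, reproducible, and beta-monotone", {
  m <- small_model()
  panel <- make_allele_panel(m, depth = 2e5, seed = 3)
  expect_length(panel$counts, 9L)
  expect_equal(nrow(panel$expression), 9L)
  expect_true(all(c("seed", "depth", "beta.STITCH") %in%
                  names(panel$truth)))
  panel2 <- make_allele_panel(m, depth = 2e5, seed = 3)
  expect_identical(lapply(panel$counts, `[[`, "counts"),
                   lapply(panel2$counts, `[[`, "counts"))
  expect_identical(panel$expression, panel2$expression)

  # enhancer contact frequency strictly increases with beta (expected and,
  # at this depth, measured)
  ord <- order(panel$expression$beta)
  expect_true(all(diff(panel$expression$f_enhancer[ord]) >= 0))
  meas <- vapply(panel$counts, function(fc)
    contact_frequency(fc, m$enhancer_region)$ratio, numeric(1))[ord]
  expect_true(all(diff(meas[!duplicated(panel$expression$beta[ord])]) > 0))

  expect_error(make_allele_panel(m, alleles = list(
    allele_config("a", 0.5), allele_config("a", 0.7))), "duplicate")
  expect_error(allele_config("bad", 0), "beta")
  expect_error(allele_config("bad", 1.2), "beta")
})

test_that("enhancer contact escalates preferentially over neutral regions", {
  m <- small_model(enhancer_affinity_delta = 1.2)
  neutral <- genomic_interval(m$chrom, m$enhancer_region$end,
                              m$locus_length)
  betas <- c(0.1, 0.3, 0.6, 1.0)
  f_enh <- vapply(betas, function(b)
    expected_contact_frequency(m, allele_config("a", b), m$enhancer_region),
    numeric(1))
  f_neu <- vapply(betas, function(b)
    expected_contact_frequency(m, allele_config("a", b), neutral),
    numeric(1))
  for (i in 1:3) {
    # releasing insulation (beta up) escalates enhancer contact more
    expect_gt(f_enh[i + 1] / f_enh[i], f_neu[i + 1] / f_neu[i])
  }
  # within one allele the normalization cancels: f_enh / f_neu is
  # proportional to beta^(delta - 1) exactly
  expect_equal(log((f_enh[4] / f_neu[4]) / (f_enh[1] / f_neu[1])) /
                 log(betas[4] / betas[1]),
               1.2 - 1, tolerance = 1e-9)
})

test_that("panel files are written in consumable formats", {
  m <- small_model()
  dir <- withr::local_tempdir()
  panel <- make_allele_panel(m, depth = 5e4, seed = 6, out_dir = dir)
  expect_true(file.exists(file.path(dir, "fragments.bed")))
  expect_true(file.exists(file.path(dir, "expression.tsv")))
  expect_true(file.exists(file.path(dir, "truth.txt")))
  cfiles <- list.files(dir, pattern = "^counts_.*\\.tsv$")
  expect_length(cfiles, 9L)
  # counts round-trip through the profile reader against the panel's map
  map <- panel$counts[[1]]$map
  vp <- panel$counts[[1]]$viewpoint
  back <- read_counts_tsv(file.path(dir, "counts_Hap.tsv"), map, vp)
  expect_equal(back$counts, panel$counts[["Hap"]]$counts)
  truth <- readLines(file.path(dir, "truth.txt"))
  expect_true(any(grepl("^expression_exponent=", truth)))
})
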
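test_that("density-mode marker maps hit the target spacing", {
  g <- nco_genome(c(chr1 = 1e7))
  mk <- synth_markers(g, spacing = 1465, seed = 1)
  gaps <- diff(mk$P1$chr1)
  expect_lt(abs(mean(gaps) - 1465) / 1465, 0.1)
  # deterministic given the seed
  mk2 <- synth_markers(g, spacing = 1465, seed = 1)
  expect_identical(mk$P1$chr1, mk2$P1$chr1)
})

test_that("allele-frequency mode keeps sites with probability 2f(1-f)", {
  g <- nco_genome(c(chr1 = 400000))
  sites <- list(chr1 = seq(10, 399990, by = 10))
  n <- length(sites$chr1)
  mk_half <- synth_markers(g, sites = sites,
                           freqs = list(chr1 = rep(0.5, n)), seed = 2)
  kept <- length(mk_half$P1$chr1) / n
  expect_lt(abs(kept - 0.5), 3 * sqrt(0.25 / n))
  # monomorphic sites are never informative
  expect_error(synth_markers(g, sites = sites,
                             freqs = list(chr1 = rep(0, n)), seed = 3),
               "no markers")
})

test_that("simulated events convert overlapped markers at the penetrance", {
  set.seed(81)
  g <- nco_genome(c(chr1 = 2e6))
  mk <- synth_markers(g, spacing = 100, seed = 82)
  p <- 0.6
  sim <- nco_simulate(g, mk, nco_mixture(500, 2, alpha = 1), p,
                      n_events = 3000, seed = 83)
  pos <- mk$P1$chr1
  n_in <- 0; n_conv <- 0
  conv_by_tract <- stats::setNames(
    sim$dataset$tracts$positions, sim$dataset$tracts$tract_id)
  for (i in seq_len(nrow(sim$truth))) {
    ev <- sim$truth[i, ]
    inside <- pos[pos >= ev$start & pos <= ev$start + ev$length - 1]
    n_in <- n_in + length(inside)
    if (!is.na(ev$tract_id))
      n_conv <- n_conv + length(conv_by_tract[[ev$tract_id]])
  }
  expect_gt(n_in, 1000)
  expect_lt(abs(n_conv / n_in - p), 3 * sqrt(p * (1 - p) / n_in))
  # every tract lies inside its event interval and on informative markers
  for (i in which(!is.na(sim$truth$tract_id))) {
    ev <- sim$truth[i, ]
    s <- conv_by_tract[[ev$tract_id]]
    expect_true(all(s >= ev$start & s <= ev$start + ev$length - 1))
    expect_true(all(s %in% pos))
  }
})

test_that("empirical detection matches the kernel prediction", {
  set.seed(91)
  g <- nco_genome(c(chr1 = 1e6))
  mk <- synth_markers(g, spacing = 400, seed = 92)
  mix <- nco_mixture(300, 2, alpha = 1)
  p <- 0.5
  sim <- nco_simulate(g, mk, mix, p, n_events = 8000, seed = 93)
  X <- truncation_point(mix) + 50
  D <- detection_function(mk, g, p, X)
  pred <- detection_mass(mix$components[[1]], D)
  obs <- nrow(sim$dataset$tracts) / sim$n_events
  expect_lt(abs(obs - pred), 3 * sqrt(pred * (1 - pred) / sim$n_events))
})

test_that("stopping rules are honoured exactly", {
  g <- nco_genome(c(chr1 = 100000))
  mk <- synth_markers(g, spacing = 10, seed = 3)
  mix <- nco_mixture(50, 1, alpha = 1)
  s1 <- nco_simulate(g, mk, mix, 1, n_tracts = 37, seed = 4)
  expect_equal(nrow(s1$dataset$tracts), 37)
  expect_equal(sum(!is.na(s1$truth$tract_id)), 37)
  s2 <- nco_simulate(g, mk, mix, 1, n_events = 55, seed = 5)
  expect_equal(s2$n_events, 55)
  expect_equal(nrow(s2$truth), 55)
  expect_error(nco_simulate(g, mk, mix, 1), "exactly one")
  # an undetectable mixture trips the event cap instead of spinning forever
  mk0 <- nco_markers(list(P1 = list(chr1 = 99999)), genome = g)
  expect_error(
    nco_simulate(g, mk0, nco_mixture(2, 1, alpha = 1), 1e-9,
                 n_tracts = 10, max_events = 2000, seed = 6),
    "event cap")
})

test_that("determinism: same seed, same dataset and ground truth", {
  g <- nco_genome(c(chr1 = 500000))
  mk <- synth_markers(g, spacing = 200, seed = 7)
  mix <- nco_mixture(c(100, 800), c(2, 2), alpha = c(0.7, 0.3))
  a <- nco_simulate(g, mk, mix, 0.75, n_tracts = 60, seed = 8)
  b <- nco_simulate(g, mk, mix, 0.75, n_tracts = 60, seed = 8)
  expect_identical(a$truth, b$truth)
  expect_identical(a$dataset$tracts$positions, b$dataset$tracts$positions)
  expect_identical(a$n_events_component, b$n_events_component)
})

test_that("penetrance closure: the estimator recovers the simulated value", {
  set.seed(95)
  g <- nco_genome(c(chr1 = 2e6))
  mk <- synth_markers(g, spacing = 60, seed = 96)
  p <- 0.7
  sim <- nco_simulate(g, mk, nco_mixture(600, 3, alpha = 1), p,
                      n_tracts = 500, seed = 97)
  est <- estimate_penetrance(sim$dataset$tracts, mk)
  expect_lt(abs(est$p - p), 3 * sqrt(p * (1 - p) / est$n_interior))
})

test_that("experiment grids enumerate the documented combinations", {
  g1 <- e1_grid()
  expect_equal(nrow(g1), 63)
  expect_setequal(unique(g1$mean), c(100, 300, 1000))
  expect_length(unique(g1$k), 7)
  expect_setequal(unique(g1$penetrance), c(0.5, 0.75, 1))
  expect_true(all(g1$n_tracts == 1000))
  # every row builds a valid component under variance = mean^2 * k
  for (i in seq_len(nrow(g1)))
    expect_s3_class(nb_component(g1$mean[i], k = g1$k[i]), "nb_component")
  g2 <- e2_grid()
  expect_equal(nrow(g2), 147)
  expect_true(all(g2$mean1 == 100) && all(g2$mean2 == 1000))
  expect_equal(nrow(unique(g2[, c("k1", "k2")])), 49)
  expect_true(all(g2$n_tracts_per_component == 1000))
})

test_that("two-component quota simulation balances detected tracts", {
  g <- nco_genome(c(chr1 = 1e6))
  mk <- synth_markers(g, spacing = 50, seed = 11)
  sim <- nco_simulate_mixture2(g, mk, nb_component(100, k = 0.5),
                               nb_component(1000, k = 0.5), 1,
                               n_per_component = 50, seed = 12)
  expect_equal(nrow(sim$dataset$tracts), 100)
  tr_comp <- sim$truth$component[!is.na(sim$truth$tract_id)]
  expect_equal(as.numeric(table(tr_comp)), c(50, 50))
  # underlying alpha recorded from realized event counts stays on simplex
  expect_equal(sum(sim$mixture$alpha), 1)
})

test_that("simulated datasets survive the TSV round trip", {
  g <- nco_genome(c(chr1 = 200000))
  mk <- synth_markers(g, spacing = 100, seed = 13)
  sim <- nco_simulate(g, mk, nco_mixture(200, 2, alpha = 1), 0.8,
                      n_tracts = 25, seed = 14)
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  g2 <- read_genome(file.path(dir, "genome.tsv"))
  mk2 <- read_markers(file.path(dir, "markers.tsv"), g2)
  tr2 <- read_tracts(file.path(dir, "tracts.tsv"), mk2)
  expect_equal(unclass(g2), unclass(sim$dataset$genome))
  expect_equal(mk2$P1$chr1, mk$P1$chr1)
  expect_equal(tr2$positions, sim$dataset$tracts$positions)
})
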
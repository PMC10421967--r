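# one-marker genome: the only producible tract is {50}, so its tract
# function equals the detection function and its probability is 1
single_marker_kernel <- function(p = 0.5, X = 30) {
  d <- tiny_dataset(100, 50, list(50))
  nco_kernel(d$tracts, d$markers, d$genome, p = p, X_max = X)
}

test_that("tract probability is a ratio of pmf-weighted kernel sums", {
  k <- single_marker_kernel()
  for (cmp in list(nb_component(2, 1), nb_component(8, 3)))
    expect_equal(tract_prob(as.numeric(k$Tmat[1, ]), k$D, cmp), 1)
  # near-degenerate length distribution concentrates at its mean
  d <- tiny_dataset(200, c(40, 90, 140), list(90))
  k2 <- nco_kernel(d$tracts, d$markers, d$genome, p = 0.5, X_max = 60)
  x0 <- 20
  spike <- nb_component(x0, size = 1e7)
  expect_equal(tract_prob(as.numeric(k2$Tmat[1, ]), k2$D, spike),
               k2$Tmat[1, x0] / k2$D[x0], tolerance = 1e-3)
})

test_that("tract probabilities over the full outcome space sum to 1", {
  set.seed(23)
  G <- 80; pos <- c(15, 30, 42, 61); p <- 0.5; X <- 15
  g <- nco_genome(c(chr1 = G))
  mk <- nco_markers(list(P1 = list(chr1 = pos)), genome = g)
  D <- detection_function(mk, g, p, X)
  cmp <- nb_component(6, 2)
  tot <- sum(vapply(enumerate_tracts(pos, X), function(s)
    tract_prob(tract_function(s, pos, g, "chr1", p, X), D, cmp), 0))
  expect_equal(tot, 1, tolerance = 1e-9)
})

test_that("log-likelihood composes per-tract probabilities", {
  k <- single_marker_kernel()
  mix <- nco_mixture(5, 1, alpha_hat = 1)
  expect_equal(nco_loglik(k, mix), 0)   # log 1
  # duplicated tract doubles the log-likelihood
  d1 <- tiny_dataset(200, c(40, 90, 140), list(90))
  d2 <- tiny_dataset(200, c(40, 90, 140), list(90, 90))
  k1 <- nco_kernel(d1$tracts, d1$markers, d1$genome, 0.5, X_max = 60)
  k2 <- nco_kernel(d2$tracts, d2$markers, d2$genome, 0.5, X_max = 60)
  mix2 <- nco_mixture(c(5, 25), c(1, 2), alpha_hat = c(0.4, 0.6))
  expect_equal(nco_loglik(k2, mix2), 2 * nco_loglik(k1, mix2))
  # matches a direct evaluation of the likelihood on a small toy
  d5 <- tiny_dataset(300, c(30, 80, 130, 180, 230),
                     list(30, 80, c(130, 180), 230, c(30, 80)))
  k5 <- nco_kernel(d5$tracts, d5$markers, d5$genome, 0.5, X_max = 200)
  direct <- 0
  for (i in 1:5) {
    lik_t <- 0
    for (j in 1:2) {
      f <- nb_pmf(mix2$components[[j]], seq_len(200))
      lik_t <- lik_t + mix2$alpha_hat[j] *
        sum(as.numeric(k5$Tmat[i, ]) * f) / sum(k5$D * f)
    }
    direct <- direct + log(lik_t)
  }
  expect_equal(nco_loglik(k5, mix2), direct, tolerance = 1e-10)
})

test_that("E-step weights follow the posterior component probabilities", {
  d <- tiny_dataset(300, c(30, 80, 130, 180, 230), list(80, c(130, 180)))
  k <- nco_kernel(d$tracts, d$markers, d$genome, 0.5, X_max = 200)
  # single component: all weights 1
  w1 <- e_step(k, nco_mixture(10, 1, alpha_hat = 1))
  expect_equal(as.numeric(w1), c(1, 1))
  # two identical components split evenly
  w2 <- e_step(k, nco_mixture(c(10, 10), c(1, 1), alpha_hat = c(0.5, 0.5)))
  expect_true(all(abs(w2 - 0.5) < 1e-12))
  # matches the posterior formula built from per-component tract
  # probabilities (for tract probs (0.2, 0.6) at equal weights this is the
  # textbook 0.25/0.75 split)
  mixh <- nco_mixture(c(5, 60), c(1, 2), alpha_hat = c(0.3, 0.7))
  P <- cbind(tract_prob(k$Tmat, k$D, mixh$components[[1]]),
             tract_prob(k$Tmat, k$D, mixh$components[[2]]))
  A <- sweep(P, 2, mixh$alpha_hat, "*")
  w3 <- e_step(k, mixh)
  expect_equal(w3, A / rowSums(A), tolerance = 1e-12)
  expect_equal(rowSums(w3), c(1, 1))
})

test_that("M-step maximizes the weighted objective", {
  set.seed(31)
  g <- nco_genome(c(chr1 = 50000))
  mk <- synth_markers(g, spacing = 25, seed = 5)
  sim <- nco_simulate(g, mk, nco_mixture(40, 2, alpha = 1), 1,
                      n_tracts = 80, seed = 6)
  k <- nco_kernel(sim$dataset$tracts, mk, g, 1, X_max = 600)
  w <- matrix(1, nrow(k$Tmat), 1)
  mix0 <- nco_mixture(30, 1, alpha_hat = 1)
  up <- m_step(k, w, mix0)
  obj <- function(cmp) sum(log(tract_prob(k$Tmat, k$D, cmp)))
  v_new <- obj(up$components[[1]])
  expect_gte(v_new, obj(mix0$components[[1]]))
  # the returned parameters beat 20 random probes
  for (i in 1:20) {
    probe <- nb_component(stats::runif(1, 5, 400), exp(stats::runif(1, -1, 2)))
    expect_gte(v_new + 1e-7, obj(probe))
  }
  # an all-zero weight column collapses its component
  w2 <- cbind(1, 0)[rep(1, nrow(k$Tmat)), , drop = FALSE]
  up2 <- m_step(k, w2, nco_mixture(c(30, 300), c(1, 1),
                                   alpha_hat = c(0.5, 0.5)))
  expect_true(attr(up2, "collapsed")[2])
  expect_equal(up2$alpha_hat[2], 0)
})

test_that("EM fits converge monotonically and reproducibly", {
  set.seed(41)
  g <- nco_genome(c(chr1 = 100000))
  mk <- synth_markers(g, spacing = 25, seed = 7)
  sim <- nco_simulate(g, mk, nco_mixture(60, 2, alpha = 1), 1,
                      n_tracts = 120, seed = 8)
  fit <- nco_fit(sim$dataset, penetrance = 1,
                 control = nco_control(seed = 9))
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) > -1e-8))
  expect_equal(rowSums(fit$weights), rep(1, fit$n_tracts))
  # default convergence tolerance is 1e-7 on relative parameter changes
  expect_equal(nco_control()$tol, 1e-7)
  expect_equal(formals(nco_fit)$control, quote(nco_control()))
  # bitwise determinism under a fixed seed
  fit2 <- nco_fit(sim$dataset, penetrance = 1,
                  control = nco_control(seed = 9))
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$logLik, fit2$logLik)
  expect_identical(fit$trace, fit2$trace)
})

test_that("likelihood machinery is invariant to the kernel normalization", {
  d <- tiny_dataset(300, c(30, 80, 130, 180, 230),
                    list(80, c(130, 180), 230))
  k <- nco_kernel(d$tracts, d$markers, d$genome, 0.5, X_max = 200)
  k2 <- k
  cscale <- 3.7
  k2$D <- k$D * cscale
  k2$Tmat <- k$Tmat * cscale
  mix <- nco_mixture(c(5, 60), c(1, 2), alpha_hat = c(0.3, 0.7))
  expect_equal(nco_loglik(k2, mix), nco_loglik(k, mix), tolerance = 1e-10)
  expect_equal(e_step(k2, mix), e_step(k, mix), tolerance = 1e-12)
})

test_that("span-quantile initialization survives extreme span mixes", {
  # many single-marker tracts plus one very long span: the starting
  # geometric component must still give the long tract positive mass
  spans <- c(rep(1, 500), 2500)
  ini <- ncolen:::init_mixture(spans, 0.5, 1)
  f <- nb_pmf(ini$components[[1]], 2500)
  expect_gt(f, 0)
})
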
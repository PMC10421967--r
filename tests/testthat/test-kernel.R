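test_that("penetrance is the interior converted-marker fraction", {
  g <- nco_genome(c(chr1 = 100))
  mk <- nco_markers(list(P1 = list(chr1 = c(10, 20, 30, 40, 50))),
                    genome = g)
  tr <- nco_tracts("t1", "P1", "chr1", list(c(10, 30, 50)), markers = mk)
  pen <- estimate_penetrance(tr, mk)
  expect_equal(pen$p, 1 / 3)   # interior {20,30,40}, converted interior {30}
  expect_equal(pen$n_interior, 3)
  expect_equal(pen$n_converted_interior, 1)
  # every interior marker converted -> p = 1
  tr2 <- nco_tracts("t1", "P1", "chr1", list(c(10, 20, 30, 40, 50)),
                    markers = mk)
  expect_equal(estimate_penetrance(tr2, mk)$p, 1)
  # 1-2 marker tracts carry no information about p
  tr3 <- nco_tracts(c("a", "b"), c("P1", "P1"), c("chr1", "chr1"),
                    list(10, c(40, 50)), markers = mk)
  expect_error(estimate_penetrance(tr3, mk), "cannot estimate penetrance")
})

test_that("detection given n markers is 1-(1-p)^n", {
  expect_equal(detect_prob_given_n(0, 0.7), 0)
  expect_equal(detect_prob_given_n(1, 0.5), 0.5)
  expect_equal(detect_prob_given_n(3, 0.9), 0.999)
  expect_error(detect_prob_given_n(1, 0), "penetrance")
  expect_error(detect_prob_given_n(1, 1.5), "penetrance")
  expect_error(detect_prob_given_n(-1, 0.5), "nonnegative")
})

test_that("detection function matches hand-enumerated single-marker cases", {
  g <- nco_genome(c(chr1 = 100))
  mk <- nco_markers(list(P1 = list(chr1 = 50)), genome = g)
  D <- detection_function(mk, g, p = 0.5, X_max = 30)
  expect_equal(D[1], 0.5 / 100)
  expect_equal(D[10], 10 * 0.5 / 91)
  # marker at every position with p = 1: every placement is detected
  mk2 <- nco_markers(list(P1 = list(chr1 = 1:60)), genome = nco_genome(c(chr1 = 60)))
  D2 <- detection_function(mk2, nco_genome(c(chr1 = 60)), 1, 20)
  expect_equal(D2, rep(1, 20))
  expect_error(detection_function(mk, g, 0.5, 100), "shortest chromosome")
})

test_that("tract function matches hand-enumerated cases", {
  g <- nco_genome(c(chr1 = 100))
  T1 <- tract_function(50, 50, g, "chr1", 0.5, 30)
  D1 <- detection_function(nco_markers(list(P1 = list(chr1 = 50)), genome = g),
                           g, 0.5, 30)
  expect_equal(T1, D1)   # the only possible tract
  T2 <- tract_function(c(50, 52), c(50, 52), g, "chr1", 0.5, 30)
  expect_equal(T2[10], 8 * 0.25 / 91)
  T3 <- tract_function(50, c(50, 52), g, "chr1", 0.5, 30)
  expect_equal(T3[10], (2 * 0.5 + 8 * 0.25) / 91)
  # length-1 window covers only the converted marker itself
  expect_equal(T3[1], 0.5 / 100)
  # zero below the span
  expect_equal(T2[1:2], c(0, 0))
})

test_that("sliding-window kernels equal brute-force enumeration", {
  set.seed(101)
  for (rep in 1:12) {
    cs <- random_tiny_case()
    g <- nco_genome(c(chr1 = cs$G))
    mk <- nco_markers(list(P1 = list(chr1 = cs$pos)), genome = g)
    D <- detection_function(mk, g, cs$p, cs$X)
    expect_lt(max(abs(D - naive_detection(cs$pos, cs$G, cs$p, cs$X))), 1e-12)
    # a random realizable tract
    i <- sample(length(cs$pos), 1)
    j <- sample(i:length(cs$pos), 1)
    sub <- cs$pos[cs$pos >= cs$pos[i] & cs$pos <= cs$pos[j]]
    s <- sort(unique(c(cs$pos[i], cs$pos[j],
                       sub[stats::runif(length(sub)) < 0.5])))
    Tt <- tract_function(s, cs$pos, g, "chr1", cs$p, cs$X)
    expect_lt(max(abs(Tt - naive_tract(s, cs$pos, cs$G, cs$p, cs$X))), 1e-12)
    expect_true(all(Tt <= D + 1e-12))
  }
})

test_that("tract functions are complete: sums over all tracts give D", {
  set.seed(7)
  for (rep in 1:4) {
    G <- sample(40:120, 1)
    pos <- sort(sample.int(G, sample(3:6, 1)))
    p <- sample(c(0.3, 0.5, 1), 1)
    X <- 15
    g <- nco_genome(c(chr1 = G))
    D <- detection_function(nco_markers(list(P1 = list(chr1 = pos)),
                                        genome = g), g, p, X)
    all_tracts <- enumerate_tracts(pos, X)
    Tsum <- Reduce(`+`, lapply(all_tracts, function(s)
      tract_function(s, pos, g, "chr1", p, X)))
    expect_lt(max(abs(Tsum - D)), 1e-9)
  }
})

test_that("detection is nondecreasing in event length away from edges", {
  set.seed(11)
  g <- nco_genome(c(chr1 = 5000))
  pos <- sort(sample.int(4000, 40) + 500)
  mk <- nco_markers(list(P1 = list(chr1 = pos)), genome = g)
  D <- detection_function(mk, g, 0.5, 40)
  expect_true(all(diff(D) >= -1e-12))
})

test_that("multi-parent detection averages by meiosis count", {
  g <- nco_genome(c(chr1 = 100))
  mk <- nco_markers(list(P1 = list(chr1 = 50), P2 = list(chr1 = numeric(0))),
                    meioses = c(P1 = 1, P2 = 3), genome = g)
  D <- detection_function(mk, g, 0.5, 10)
  D1 <- detection_function(nco_markers(list(P1 = list(chr1 = 50)),
                                       genome = g), g, 0.5, 10)
  expect_equal(D, D1 / 4)   # P2 contributes zero detection with weight 3
})

test_that("kernel tables bundle D, tract functions and extend consistently", {
  d <- tiny_dataset(300, c(60, 100, 140, 220), list(c(60, 100), 220))
  k <- nco_kernel(d$tracts, d$markers, d$genome, p = 0.5, X_max = 60)
  expect_s3_class(k, "nco_kernel")
  expect_equal(dim(k$Tmat), c(2L, 60L))
  expect_equal(as.numeric(k$Tmat[1, ]),
               tract_function(c(60, 100), c(60, 100, 140, 220), d$genome,
                              "chr1", 0.5, 60))
  expect_true(all(as.matrix(k$Tmat) <= matrix(k$D, 2, 60, byrow = TRUE) + 1e-12))
  k2 <- extend_kernel(k, 90)
  expect_equal(k2$X_max, 90)
  expect_equal(k2$D[1:60], k$D)
  expect_equal(as.numeric(k2$Tmat[2, 1:60]), as.numeric(k$Tmat[2, ]))
  # cache round-trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_kernel(k, f)
  kc <- read_kernel(f, p = 0.5)
  expect_equal(kc$D, k$D, tolerance = 1e-12)
  expect_equal(as.matrix(kc$Tmat), as.matrix(k$Tmat), tolerance = 1e-12,
               ignore_attr = TRUE)
})
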
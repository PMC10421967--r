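#' Likelihood-ratio test between nested length models
#'
#' Compares a smaller model nested in a larger one: geometric inside a
#' single negative binomial (1 extra degree of freedom) or an `n`-component
#' mixture inside an `n + 1`-component mixture (3 extra degrees of freedom:
#' one weight and two component parameters).  The statistic
#' `2 (ll_large - ll_small)` is referred to the upper tail of a chi-squared
#' distribution; this reference is approximate for mixture boundaries but is
#' the conventional choice.
#'
#' @param ll_small,ll_large maximized log-likelihoods of the nested fits on
#'   the same tracts and kernel.
#' @param df degrees of freedom, 1 or 3.
#' @return An object of class `nco_lrt`: list with `statistic` (clamped at
#'   0), `df` and `p_value`.
#' @export
nco_lrt <- function(ll_small, ll_large, df) {
  if (!df %in% c(1, 3))
    stop("df must be 1 (geometric vs negative binomial) or 3 (extra component)")
  stat <- max(2 * (ll_large - ll_small), 0)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "nco_lrt")
}

#' @export
print.nco_lrt <- function(x, ...) {
  cat(sprintf("LRT: statistic %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Select the number of mixture components by likelihood-ratio ladder
#'
#' Fits a geometric model, then a single negative binomial (tested against
#' the geometric on 1 df), then adds one component at a time (each tested on
#' 3 df), stopping at the first test with `p >= alpha`.  Returns the last
#' accepted model together with the whole test ladder.
#'
#' @inheritParams nco_fit
#' @param alpha per-test significance level, default 0.05.
#' @param max_components largest mixture size attempted.
#' @return An object of class `nco_select`: list with `fit` (chosen model),
#'   `fits` (all fitted rungs), `tests` (list of [nco_lrt()] results) and
#'   `n_components` (0 denotes the geometric model).
#' @export
nco_select <- function(tracts, markers = NULL, genome = NULL,
                       penetrance = NULL, alpha = 0.05, max_components = 4,
                       kernel = NULL, n_meioses = NULL,
                       control = nco_control()) {
  if (inherits(tracts, "nco_dataset")) {
    dat <- tracts
    tracts <- dat$tracts; markers <- dat$markers; genome <- dat$genome
    if (is.null(n_meioses)) n_meioses <- dat$n_meioses
  }
  if (is.null(penetrance)) penetrance <- estimate_penetrance(tracts, markers)$p
  fit_g <- nco_fit(tracts, markers, genome, n_components = 1,
                   penetrance = penetrance, geometric = TRUE,
                   kernel = kernel, n_meioses = n_meioses, control = control)
  kernel <- fit_g$kernel
  fits <- list(geometric = fit_g)
  tests <- list()
  chosen <- fit_g
  fit_prev <- fit_g
  for (n in seq_len(max_components)) {
    fit_n <- nco_fit(tracts, markers, genome, n_components = n,
                     penetrance = penetrance, kernel = kernel,
                     n_meioses = n_meioses, control = control)
    kernel <- fit_n$kernel
    fits[[paste0("nb", n)]] <- fit_n
    tests[[length(tests) + 1]] <-
      nco_lrt(fit_prev$logLik, fit_n$logLik, df = if (n == 1) 1 else 3)
    if (tests[[length(tests)]]$p_value >= alpha) break
    chosen <- fit_n
    fit_prev <- fit_n
  }
  n_chosen <- if (chosen$geometric) 0 else length(chosen$mixture$components)
  structure(list(fit = chosen, fits = fits, tests = tests,
                 n_components = n_chosen, alpha = alpha),
            class = "nco_select")
}

#' @export
print.nco_select <- function(x, ...) {
  cat("Model selection ladder (level", x$alpha, "):\n")
  for (i in seq_along(x$tests)) {
    lab <- if (i == 1) "geometric -> 1 NB" else
      paste(i - 1, "NB ->", i, "NB")
    t <- x$tests[[i]]
    cat(sprintf("  %-18s stat %8.3f  df %d  p %.3g\n",
                lab, t$statistic, t$df, t$p_value))
  }
  cat("Chosen model:",
      if (x$n_components == 0) "geometric" else
        paste0(x$n_components, "-component negative binomial mixture"), "\n")
  invisible(x)
}

#' Estimate the number of NCO events from a fit
#'
#' Only a fraction `Pr(S != 0) = sum_i alpha_i d_i` of NCO events produce an
#' observable tract, so the expected total number of events behind
#' `n_tracts` observed tracts is `n_tracts / Pr(S != 0)` (inverse-detection
#' plug-in), and dividing by the number of meioses gives the per-meiosis
#' event rate.
#'
#' @param fit an [nco_fit()] result, or an [nco_mixture()] with `alpha` and
#'   `d` populated (then supply `n_tracts`).
#' @param n_meioses number of meioses; defaults to the fit's.
#' @param n_tracts number of observed tracts; defaults to the fit's.
#' @return An object of class `nco_count`: list with `p_detect`, `total`
#'   and `per_meiosis`.  `total >= n_tracts` always.
#' @export
nco_count <- function(fit, n_meioses = NULL, n_tracts = NULL) {
  if (inherits(fit, "nco_fit")) {
    mix <- fit$mixture
    if (is.null(n_tracts)) n_tracts <- fit$n_tracts
    if (is.null(n_meioses)) n_meioses <- fit$n_meioses
  } else mix <- fit
  if (is.null(mix$alpha) || is.null(mix$d))
    stop("mixture must carry alpha and detection masses (attach_weights)")
  if (is.null(n_tracts) || is.null(n_meioses))
    stop("n_tracts and n_meioses are required")
  p_det <- sum(mix$alpha * mix$d)
  if (p_det <= 0) stop("overall detection probability is 0")
  structure(list(p_detect = p_det, total = n_tracts / p_det,
                 per_meiosis = n_tracts / p_det / n_meioses,
                 n_tracts = n_tracts, n_meioses = n_meioses),
            class = "nco_count")
}

#' @export
print.nco_count <- function(x, ...) {
  cat(sprintf(
    "NCO events: %.1f total (%.2f per meiosis) from %d tracts, Pr(detect) = %.4g\n",
    x$total, x$per_meiosis, x$n_tracts, x$p_detect))
  invisible(x)
}

#' Bootstrap confidence intervals for a fitted model
#'
#' Resamples the observed tracts with replacement (same size), refits the
#' mixture on each resample (reusing the precomputed detection and tract
#' functions and warm-starting at the full-data estimate), and reports
#' percentile confidence intervals for the mean event length, the total
#' event count and each component parameter.  The penetrance is held fixed
#' at the full-data value.
#'
#' @param fit an [nco_fit()] result.
#' @param B number of bootstrap replicates (200 is a sensible default).
#' @param level confidence level of the percentile intervals.
#' @param seed integer seed; replicates are reproducible given the seed.
#' @return An object of class `nco_boot`: list with `ci` (data frame of
#'   point estimate, lower, upper per summary), `replicates` (data frame of
#'   per-replicate estimates), `n_failed`.
#' @export
nco_boot <- function(fit, B = 200, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "nco_fit"), B >= 2, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)
  kernel <- fit$kernel
  n <- fit$n_tracts
  ctrl <- fit$control
  ctrl$restarts <- 1
  reps <- vector("list", B)
  n_failed <- 0
  kb <- kernel
  kb$tracts <- NULL   # no extension during replicate fits
  # with a single component there are no latent membership weights, so one
  # M-step from the full-data estimate is already the complete ML refit
  single <- length(fit$mixture$components) == 1
  w1 <- matrix(1, n, 1)
  for (b in seq_len(B)) {
    # resampling tracts with replacement = refitting with multiplicity
    # weights; the kernel table is left untouched
    counts <- tabulate(sample.int(n, n, replace = TRUE), n)
    res <- tryCatch({
      em <- if (single) {
        list(mixture = m_step(kb, w1, fit$mixture,
                              geometric = fit$geometric, control = ctrl,
                              freq = counts))
      } else {
        run_em(kb, fit$mixture, fit$geometric, ctrl, freq = counts)
      }
      mix <- tryCatch(
        attach_weights(em$mixture, kb$D, tail_tol = ctrl$tail_tol),
        error = function(e) {
          m <- em$mixture
          m$d <- vapply(m$components, function(cp)
            sum(kb$D * nb_pmf(cp, seq_along(kb$D))), 0)
          m$alpha <- invert_weights(m$alpha_hat, m$d)
          m
        })
      cnt <- nco_count(mix, n_meioses = fit$n_meioses, n_tracts = n)
      means <- vapply(mix$components, `[[`, 0, "mean")
      sizes <- vapply(mix$components, `[[`, 0, "size")
      c(mean_length = mixture_mean(mix), total_events = cnt$total,
        per_meiosis = cnt$per_meiosis,
        stats::setNames(means, paste0("mean_", seq_along(means))),
        stats::setNames(sizes, paste0("size_", seq_along(sizes))),
        stats::setNames(mix$alpha, paste0("alpha_", seq_along(mix$alpha))))
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1 else reps[[b]] <- res
  }
  reps <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  if (is.null(reps) || !nrow(reps))
    stop("all bootstrap replicates failed")
  if (n_failed > 0.1 * B)
    warning(n_failed, " of ", B, " bootstrap replicate fits failed")
  a <- (1 - level) / 2
  cnt0 <- nco_count(fit)
  point <- c(mean_length = mixture_mean(fit$mixture),
             total_events = cnt0$total, per_meiosis = cnt0$per_meiosis)
  ci <- data.frame(
    summary = colnames(reps),
    estimate = c(point[colnames(reps)[1:3]],
                 rep(NA_real_, ncol(reps) - 3)),
    lower = apply(reps, 2, stats::quantile, probs = a),
    upper = apply(reps, 2, stats::quantile, probs = 1 - a),
    row.names = NULL)
  est <- coef(fit)
  ci$estimate[ci$summary %in% paste0("mean_", est$component)] <- est$mean
  ci$estimate[ci$summary %in% paste0("size_", est$component)] <- est$size
  ci$estimate[ci$summary %in% paste0("alpha_", est$component)] <- est$alpha
  structure(list(ci = ci, replicates = as.data.frame(reps),
                 n_failed = n_failed, B = B, level = level),
            class = "nco_boot")
}

#' @export
print.nco_boot <- function(x, ...) {
  cat(sprintf("Bootstrap (%d replicates, %d failed), %.0f%% percentile CIs:\n",
              x$B, x$n_failed, 100 * x$level))
  print(x$ci, digits = 4, row.names = FALSE)
  invisible(x)
}
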
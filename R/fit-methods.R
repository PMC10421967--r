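#' @export
print.nco_fit <- function(x, ...) {
  n <- length(x$mixture$components)
  cat("NCO event-length fit (", if (x$geometric) "geometric" else
    paste0(n, "-component negative binomial mixture"), ")\n", sep = "")
  cat(sprintf("  tracts: %d   penetrance: %.4g   meioses: %g\n",
              x$n_tracts, x$penetrance, x$n_meioses))
  print(x$mixture)
  cat(sprintf("log-likelihood %.4f after %d EM iteration(s)%s\n",
              x$logLik, x$iterations,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
coef.nco_fit <- function(object, ...) {
  mix <- object$mixture
  data.frame(
    component = seq_along(mix$components),
    mean = vapply(mix$components, `[[`, 0, "mean"),
    size = vapply(mix$components, `[[`, 0, "size"),
    alpha = mix$alpha,
    alpha_hat = mix$alpha_hat,
    detect_mass = mix$d)
}

#' @export
logLik.nco_fit <- function(object, ...) {
  n_par <- length(object$mixture$components) * (if (object$geometric) 1 else 2) +
    length(object$mixture$components) - 1
  structure(object$logLik, df = n_par, nobs = object$n_tracts,
            class = "logLik")
}

#' Summary of an NCO length fit
#'
#' Combines the fitted mixture with the derived quantities of interest: the
#' mean length of the underlying event distribution, the overall detection
#' probability and the implied number of NCO events (total and per meiosis).
#'
#' @param object an [nco_fit()] result.
#' @param ... unused.
#' @return An object of class `summary.nco_fit`.
#' @export
summary.nco_fit <- function(object, ...) {
  cnt <- nco_count(object)
  structure(list(fit = object, coef = coef(object),
                 mean_length = mixture_mean(object$mixture),
                 count = cnt), class = "summary.nco_fit")
}

#' @export
print.summary.nco_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Mean NCO event length: %.4g bp\n", x$mean_length))
  cat(sprintf("Detection probability Pr(S != 0): %.4g\n", x$count$p_detect))
  cat(sprintf("Estimated NCO events: %.1f total, %.2f per meiosis\n",
              x$count$total, x$count$per_meiosis))
  invisible(x)
}

#' Simulate new tract datasets from a fitted model
#'
#' Draws complete synthetic datasets (events placed uniformly, markers
#' converted with the fitted penetrance, undetected events discarded) from
#' the fitted length mixture on the marker map and genome the model was fit
#' to.  Requires the fit's kernel to carry its marker/genome objects (fits
#' from a TSV kernel cache cannot simulate).
#'
#' @param object an [nco_fit()] result.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n_tracts tracts per simulated dataset (default: as observed).
#' @param ... unused.
#' @return A list of `nsim` [nco_simulate()] results.
#' @export
simulate.nco_fit <- function(object, nsim = 1, seed = NULL,
                             n_tracts = object$n_tracts, ...) {
  k <- object$kernel
  if (is.null(k$markers) || is.null(k$genome))
    stop("fit kernel lacks marker/genome objects; cannot simulate")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, nsim)
  lapply(seeds, function(s)
    nco_simulate(k$genome, k$markers, object$mixture,
                 penetrance = object$penetrance, n_tracts = n_tracts,
                 seed = s))
}

#' Diagnostic plot of a fitted length distribution
#'
#' Left: fitted probability mass of the underlying event-length mixture
#' (log-x), with component means marked.  Right: detection function and the
#' detection-skewed length distribution of observed events.
#'
#' @param x an [nco_fit()] result.
#' @param xmax largest length shown (default: 99.9% quantile of the fit).
#' @param ... passed to [graphics::plot()].
#' @export
plot.nco_fit <- function(x, xmax = NULL, ...) {
  mix <- x$mixture
  if (is.null(xmax)) xmax <- truncation_point(mix, 1e-3)
  xs <- seq_len(min(xmax, x$kernel$X_max))
  f <- mixture_pmf(mix, xs)
  D <- x$kernel$D[xs]
  fdet <- f * D / sum(mixture_pmf(mix, seq_len(x$kernel$X_max)) * x$kernel$D)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(xs, f, type = "l", log = "x", xlab = "event length (bp)",
                 ylab = "probability", main = "underlying length pmf", ...)
  graphics::abline(v = vapply(mix$components, `[[`, 0, "mean"),
                   lty = 3, col = "grey40")
  graphics::plot(xs, D, type = "l", log = "x", ylim = c(0, 1),
                 xlab = "event length (bp)", ylab = "probability",
                 main = "detection function", col = "red3")
  graphics::lines(xs, fdet / max(fdet), col = "blue3")
  graphics::legend("topleft", bty = "n", col = c("red3", "blue3"), lty = 1,
                   legend = c("D(x)", "detected-length pmf (scaled)"))
  invisible(x)
}
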
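#' Negative binomial length component
#'
#' Event lengths are at least 1 bp, so a component with mean `m` models
#' `L - 1` as negative binomial with size (dispersion) `r` and mean `m - 1`.
#' `r = 1` recovers the geometric distribution on `{1, 2, ...}` with mean
#' `m`.  Alternatively the dispersion can be given as `k`, the variance of
#' the component expressed as `mean^2 * k`; on the shifted scale
#' `variance = (m-1) + (m-1)^2 / r`, so `r = (m-1)^2 / (m^2 k - (m-1))`.
#'
#' @param mean component mean length in bp (`> 1`; `mean = 1` is the point
#'   mass at 1).
#' @param size negative binomial size (dispersion) parameter, `> 0`.
#' @param k alternative to `size`: variance specified as `mean^2 * k`.
#' @return An object of class `nb_component`: list with `mean` and `size`.
#' @examples
#' geom2 <- nb_component(mean = 2, size = 1)   # geometric, Pr(L=1) = 0.5
#' nb_pmf(geom2, 1:3)
#' @export
nb_component <- function(mean, size = NULL, k = NULL) {
  if (!is.finite(mean) || mean < 1) stop("component mean must be >= 1")
  if (is.null(size) == is.null(k)) stop("give exactly one of size or k")
  if (!is.null(k)) {
    v <- mean^2 * k
    mp <- mean - 1
    if (v <= mp)
      stop("variance mean^2*k = ", v, " is not attainable: a shifted ",
           "negative binomial with mean ", mean, " has variance > ", mp)
    size <- mp^2 / (v - mp)
  }
  if (!is.finite(size) || size <= 0) stop("size must be > 0")
  structure(list(mean = mean, size = size), class = "nb_component")
}

#' Probability mass function of a length component
#'
#' @param comp an [nb_component()].
#' @param x integer lengths, `x >= 1`.
#' @param log logical; return log probabilities.
#' @return `Pr(L = x)` (or its log).
#' @export
nb_pmf <- function(comp, x, log = FALSE) {
  if (any(x < 1)) stop("lengths are >= 1")
  stats::dnbinom(x - 1, size = comp$size, mu = comp$mean - 1, log = log)
}

# pmf over the contiguous grid x = 1..X via the one-term recurrence
# f(k+1)/f(k) = (r + k) / (k + 1) * mu / (r + mu); an order of magnitude
# faster than X independent dnbinom evaluations and accurate to ~X * eps
nb_pmf_seq <- function(size, mu, X) {
  if (mu <= 0) return(c(1, numeric(X - 1)))
  pr <- mu / (size + mu)
  f0 <- exp(size * log1p(-pr))
  if (X == 1) return(f0)
  k <- 0:(X - 2)
  f0 * cumprod(c(1, (size + k) / (k + 1) * pr))
}

#' Truncation point of the infinite length sums
#'
#' All sums over event lengths are truncated where the remaining upper-tail
#' mass of every component drops below `tail_tol`.  Returns the smallest
#' `X` with `Pr(L > X) < tail_tol` (the maximum over components for a
#' mixture).
#'
#' @param obj an [nb_component()] or [nco_mixture()].
#' @param tail_tol upper-tail tolerance, default `1e-9`.
#' @return Integer truncation point.
#' @export
truncation_point <- function(obj, tail_tol = 1e-9) {
  stopifnot(tail_tol > 0, tail_tol < 1)
  if (inherits(obj, "nco_mixture"))
    return(max(vapply(obj$components, truncation_point, 0, tail_tol = tail_tol)))
  # Pr(L > X) = Pr(NB > X - 1) < tol  <=>  X - 1 >= qnbinom(1 - tol)
  as.integer(stats::qnbinom(tail_tol, size = obj$size, mu = obj$mean - 1,
                            lower.tail = FALSE)) + 1L
}

#' Detection mass of a component
#'
#' The probability that an event drawn from the component produces any
#' tract: `d = sum_x D(x) * f(x)`, the denominator of the per-component
#' tract probability.
#'
#' @param comp an [nb_component()].
#' @param D detection function vector, tabulated at least to the component's
#'   truncation point.
#' @param tail_tol tail tolerance used to determine the required tabulation.
#' @return Probability `d` in `[0, 1]`.
#' @export
detection_mass <- function(comp, D, tail_tol = 1e-9) {
  X <- truncation_point(comp, tail_tol)
  if (length(D) < X)
    stop("detection function tabulated to ", length(D),
         " but the component needs X_max >= ", X)
  sum(D * nb_pmf(comp, seq_along(D)))
}

#' Convert between underlying and detected-space mixture weights
#'
#' If `alpha` are the mixture weights of the underlying event-length
#' distribution and `d` the per-component detection masses, then among
#' *detected* events component `i` has weight
#' `alpha_hat_i = alpha_i d_i / sum_j alpha_j d_j`.  `invert_weights()`
#' performs the inverse mapping.
#'
#' @param alpha weight vector on the simplex.
#' @param d per-component detection masses, all `> 0` where `alpha > 0`.
#' @return Weight vector on the simplex.
#' @export
convert_weights <- function(alpha, d) {
  check_simplex(alpha)
  if (any(d == 0 & alpha > 0))
    stop("component with positive weight is undetectable (d = 0)")
  w <- alpha * d
  w / sum(w)
}

#' @rdname convert_weights
#' @param alpha_hat detected-space weight vector on the simplex.
#' @export
invert_weights <- function(alpha_hat, d) {
  check_simplex(alpha_hat)
  if (any(d == 0 & alpha_hat > 0))
    stop("component with positive detected weight has d = 0")
  w <- ifelse(alpha_hat > 0, alpha_hat / d, 0)
  w / sum(w)
}

check_simplex <- function(a, tol = 1e-10) {
  if (any(a < -tol) || abs(sum(a) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to 1")
  invisible(a)
}

#' Negative binomial mixture
#'
#' A mixture length distribution carries two weight systems: the underlying
#' weights `alpha` (over all events) and the detected-space weights
#' `alpha_hat` (over events that produced a tract).  They are linked through
#' the per-component detection masses `d`; either system can be stored alone
#' and the other derived once a detection function is available (see
#' [attach_weights()]).
#'
#' @param components list of [nb_component()] objects, or a numeric vector
#'   of means combined with `sizes`.
#' @param sizes numeric vector of sizes when `components` is a vector of means.
#' @param alpha_hat detected-space weights (simplex).
#' @param alpha underlying weights (simplex).
#' @param d optional per-component detection masses.
#' @return An object of class `nco_mixture`.
#' @export
nco_mixture <- function(components, sizes = NULL, alpha_hat = NULL,
                        alpha = NULL, d = NULL) {
  if (is.numeric(components))
    components <- Map(nb_component, components, sizes)
  stopifnot(all(vapply(components, inherits, TRUE, "nb_component")))
  n <- length(components)
  if (is.null(alpha_hat) && is.null(alpha)) {
    alpha_hat <- rep(1 / n, n)
  }
  if (!is.null(alpha_hat)) check_simplex(alpha_hat)
  if (!is.null(alpha)) check_simplex(alpha)
  structure(list(components = components, alpha_hat = alpha_hat,
                 alpha = alpha, d = d), class = "nco_mixture")
}

#' Derive detection masses and the missing weight system
#'
#' Computes the per-component detection masses from a detection function and
#' fills in whichever of `alpha` / `alpha_hat` the mixture lacks.
#'
#' @param mix an [nco_mixture()].
#' @param D detection function vector.
#' @param tail_tol tail tolerance for the detection-mass sums.
#' @return The mixture with `d`, `alpha` and `alpha_hat` all populated.
#' @export
attach_weights <- function(mix, D, tail_tol = 1e-9) {
  mix$d <- vapply(mix$components, detection_mass, 0, D = D,
                  tail_tol = tail_tol)
  if (is.null(mix$alpha)) mix$alpha <- invert_weights(mix$alpha_hat, mix$d)
  if (is.null(mix$alpha_hat)) mix$alpha_hat <- convert_weights(mix$alpha, mix$d)
  mix
}

#' Mean length of the underlying event distribution
#'
#' `sum_i alpha_i * mean_i`, the mean of the *underlying* NCO event-length
#' distribution (not of the detection-skewed distribution of observed
#' events).  Requires underlying weights `alpha`; use [attach_weights()]
#' first if the mixture only carries detected-space weights.
#'
#' @param mix an [nco_mixture()].
#' @return Mean length in bp.
#' @export
mixture_mean <- function(mix) {
  if (is.null(mix$alpha))
    stop("mixture lacks underlying weights alpha; call attach_weights() first")
  sum(mix$alpha * vapply(mix$components, `[[`, 0, "mean"))
}

#' Mixture pmf
#'
#' Probability mass function of the underlying mixture (weights `alpha`) or
#' of the detected-event mixture (weights `alpha_hat`, each component
#' reweighted by its detection profile is *not* applied here: this is the
#' plain mixture over component pmfs with the chosen weight system).
#'
#' @param mix an [nco_mixture()].
#' @param x integer lengths.
#' @param weights `"alpha"` (underlying, default) or `"alpha_hat"`.
#' @return Probability vector.
#' @export
mixture_pmf <- function(mix, x, weights = c("alpha", "alpha_hat")) {
  weights <- match.arg(weights)
  w <- mix[[weights]]
  if (is.null(w)) stop("mixture lacks ", weights, " weights")
  out <- numeric(length(x))
  for (i in seq_along(mix$components))
    out <- out + w[i] * nb_pmf(mix$components[[i]], x)
  out
}

#' @export
print.nco_mixture <- function(x, ...) {
  n <- length(x$components)
  cat("Negative binomial mixture,", n, "component(s):\n")
  df <- data.frame(
    mean = vapply(x$components, `[[`, 0, "mean"),
    size = vapply(x$components, `[[`, 0, "size"))
  if (!is.null(x$alpha)) df$alpha <- x$alpha
  if (!is.null(x$alpha_hat)) df$alpha_hat <- x$alpha_hat
  if (!is.null(x$d)) df$detect_mass <- x$d
  print(df, digits = 4)
  if (!is.null(x$alpha))
    cat(sprintf("Mean event length: %.4g bp\n", mixture_mean(x)))
  invisible(x)
}

#' Write or read mixture parameters
#'
#' Structured TSV with one row per component: `mean`, `size`, `alpha`,
#' `alpha_hat`, `d` (empty fields for weight systems not populated).
#'
#' @param mix an [nco_mixture()].
#' @param path file path.
#' @export
write_mixture <- function(mix, path) {
  n <- length(mix$components)
  df <- data.frame(
    mean = vapply(mix$components, `[[`, 0, "mean"),
    size = vapply(mix$components, `[[`, 0, "size"),
    alpha = if (is.null(mix$alpha)) rep(NA_real_, n) else mix$alpha,
    alpha_hat = if (is.null(mix$alpha_hat)) rep(NA_real_, n) else mix$alpha_hat,
    d = if (is.null(mix$d)) rep(NA_real_, n) else mix$d)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mixture
#' @export
read_mixture <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  nco_mixture(df$mean, df$size,
              alpha_hat = if (!anyNA(df$alpha_hat)) df$alpha_hat,
              alpha = if (!anyNA(df$alpha)) df$alpha,
              d = if (!anyNA(df$d)) df$d)
}
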
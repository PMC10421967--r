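#' Probability of an observed tract under one length component
#'
#' The probability of observing tract `t` given that the generating event
#' was detected, under length distribution `f`:
#' `Pr(O = o_t | detected) = sum_x T_t(x) f(x) / sum_x D(x) f(x)`.
#' The placement-normalization constant shared by `T_t` and `D` cancels in
#' the ratio.
#'
#' @param Tt tract function vector for one tract, or an `n_tracts` by
#'   `X_max` (sparse) matrix of tract functions.
#' @param D detection function vector of the same length.
#' @param comp an [nb_component()].
#' @return Probability (or vector of probabilities, one per tract).
#' @export
tract_prob <- function(Tt, D, comp) {
  f <- nb_pmf_seq(comp$size, comp$mean - 1, length(D))
  denom <- sum(D * f)
  if (denom <= 0)
    stop("component is undetectable over the tabulated lengths ",
         "(sum D(x) f(x) = 0)")
  if (is.matrix(Tt) || inherits(Tt, "Matrix"))
    as.numeric(Tt %*% f) / denom
  else
    sum(Tt * f) / denom
}

# per-component tract probabilities for all tracts: n_tracts x n matrix,
# plus the detection-mass denominators
tract_prob_matrix <- function(kernel, mix) {
  n <- length(mix$components)
  P <- matrix(0, nrow(kernel$Tmat), n)
  denom <- numeric(n)
  for (i in seq_len(n)) {
    f <- nb_pmf_seq(mix$components[[i]]$size, mix$components[[i]]$mean - 1,
                    kernel$X_max)
    denom[i] <- sum(kernel$D * f)
    if (denom[i] <= 0)
      stop("component ", i, " is undetectable over the tabulated lengths")
    P[, i] <- as.numeric(kernel$Tmat %*% f) / denom[i]
  }
  list(P = P, denom = denom)
}

#' Log-likelihood of a mixture given a kernel table
#'
#' `sum_t log sum_i alpha_hat_i * Pr(O = o_t | detected, component i)`.
#'
#' @param kernel an [nco_kernel()].
#' @param mix an [nco_mixture()] with detected-space weights `alpha_hat`.
#' @return Log-likelihood; `-Inf` (with a warning naming the tract) if some
#'   tract is impossible under every component.
#' @export
nco_loglik <- function(kernel, mix) {
  if (is.null(mix$alpha_hat)) stop("mixture lacks alpha_hat weights")
  lik <- as.numeric(tract_prob_matrix(kernel, mix)$P %*% mix$alpha_hat)
  if (any(lik == 0)) {
    warning("tract(s) impossible under every component: ",
            paste(kernel$tract_id[lik == 0], collapse = ", "))
    return(-Inf)
  }
  sum(log(lik))
}

#' E-step: membership weights
#'
#' For each tract the posterior probability that each mixture component
#' generated it:
#' `w_it = alpha_hat_i P_i(t) / sum_j alpha_hat_j P_j(t)`.
#'
#' @param kernel an [nco_kernel()].
#' @param mix an [nco_mixture()] with `alpha_hat`.
#' @return `n_tracts` by `n_components` matrix with rows summing to 1.
#' @export
e_step <- function(kernel, mix) {
  P <- tract_prob_matrix(kernel, mix)$P
  W <- sweep(P, 2, mix$alpha_hat, "*")
  rs <- rowSums(W)
  if (any(rs == 0))
    stop("tract(s) impossible under the current model: ",
         paste(kernel$tract_id[rs == 0], collapse = ", "))
  W / rs
}

# weighted per-component objective: sum_t w_t log Pr(O = o_t | theta, det.)
# logpar = c(log(mean - 1), log(size)); returns a large negative value for
# invalid or degenerate parameters so derivative-free search stays in bounds
mstep_objective <- function(logpar, kernel, wt, fixed_size = NULL,
                            span_need = kernel$X_max) {
  mp <- exp(logpar[1])
  r <- if (is.null(fixed_size)) exp(logpar[2]) else fixed_size
  if (!is.finite(mp) || !is.finite(r) || mp > 1e8 ||
      r < 1e-4 || r > 1e6) return(-1e12)
  mstep_obj_cpp(mp, r, kernel$Tmat, kernel$D, wt, span_need)
}

#' M-step: weight and parameter updates
#'
#' Updates the detected-space weights to the mean membership weights and
#' each component's `(mean, size)` to the maximizer of the weighted
#' log-probability of the tracts, found by bounded derivative-free search
#' (Nelder-Mead) in `(log(mean - 1), log(size))` space.  If the search fails
#' to improve on the current parameters they are kept, which preserves the
#' EM monotonicity guarantee.
#'
#' @param kernel an [nco_kernel()].
#' @param w membership-weight matrix from [e_step()].
#' @param mix current [nco_mixture()] (used as warm start and fallback).
#' @param geometric logical; hold all component sizes fixed at 1.
#' @param control list from [nco_control()].
#' @param freq optional per-tract frequency weights (e.g. bootstrap
#'   multiplicities); default 1 per tract.
#' @return Updated [nco_mixture()] with attribute `"collapsed"` flagging
#'   components whose weight vanished.
#' @export
m_step <- function(kernel, w, mix, geometric = FALSE,
                   control = nco_control(), freq = NULL) {
  n <- length(mix$components)
  if (is.null(freq)) {
    alpha_hat <- colMeans(w)
  } else {
    alpha_hat <- as.numeric(crossprod(w, freq)) / sum(freq)
  }
  collapsed <- alpha_hat < control$collapse_tol
  comps <- mix$components
  for (i in seq_len(n)) {
    if (collapsed[i]) next
    wt <- if (is.null(freq)) w[, i] else w[, i] * freq
    # tracts with negligible posterior weight on this component contribute
    # below numerical resolution; dropping them lets the objective use the
    # component's own (short) evaluation range
    wt[wt < 1e-12] <- 0
    if (!any(wt > 0)) next
    span_need <- max(kernel$spans[wt > 0])
    old <- comps[[i]]
    par0 <- c(log(max(old$mean - 1, 1e-9)), log(old$size))
    obj0 <- mstep_objective(par0, kernel, wt,
                            fixed_size = if (geometric) 1,
                            span_need = span_need)
    if (geometric) {
      opt <- stats::optimize(
        function(lm) mstep_objective(c(lm, 0), kernel, wt, fixed_size = 1,
                                     span_need = span_need),
        interval = c(par0[1] - 8, par0[1] + 8), maximum = TRUE,
        tol = control$mstep_tol)
      new_par <- c(opt$maximum, 0)
      new_val <- opt$objective
    } else {
      # search relative to the warm start: z = 0 makes Nelder-Mead open
      # with steps of 0.1 * h log-units, small enough that near-converged
      # EM iterations (and bootstrap refits) finish in few evaluations
      # while cold starts still reach far points through simplex expansion
      h <- 0.05
      opt <- stats::optim(
        c(0, 0), function(z) mstep_objective(par0 + z * h, kernel, wt,
                                             span_need = span_need),
        method = "Nelder-Mead",
        control = list(fnscale = -1, reltol = control$mstep_tol,
                       maxit = control$mstep_maxit))
      new_par <- par0 + opt$par * h
      new_val <- opt$value
    }
    if (is.finite(new_val) && new_val >= obj0) {
      comps[[i]] <- nb_component(mean = 1 + exp(new_par[1]),
                                 size = if (geometric) 1 else exp(new_par[2]))
    } else if (!is.finite(new_val) || obj0 - new_val > 1e-6) {
      # a genuine optimizer failure; at a converged fixpoint the search
      # routinely returns the same value and falling back is silent
      warning("M-step optimizer failed to improve component ", i,
              "; keeping previous parameters")
    }
  }
  out <- nco_mixture(comps, alpha_hat = alpha_hat / sum(alpha_hat))
  attr(out, "collapsed") <- collapsed
  out
}

#' EM fit control parameters
#'
#' @param tol convergence tolerance: the EM loop stops when the Euclidean
#'   norm of the relative changes of all parameters (`alpha_hat`,
#'   `log(mean)`, `log(size)`) drops below `tol`.  Default `1e-7`.
#' @param max_iter maximum EM iterations (default 200; informative fits
#'   converge far earlier, the cap mainly stops overparameterized models
#'   drifting along flat likelihood ridges).
#' @param restarts number of EM starts; the first uses the deterministic
#'   span-quantile initialization, the rest random jitters of it.
#' @param seed random seed driving the restart jitters (and nothing else).
#' @param tail_tol upper-tail mass at which the infinite length sums are
#'   truncated; the kernel table is extended on the fly whenever the current
#'   parameters need more room.
#' @param collapse_tol detected-space weight below which a component is
#'   declared collapsed, dropped, and the model refitted.
#' @param mstep_tol,mstep_maxit inner optimizer tolerance and evaluation cap.
#' @param X_max_cap hard ceiling on on-the-fly kernel extension (the table
#'   also never exceeds the shortest chromosome); beyond it the length sums
#'   stay truncated.
#' @return List of control parameters.
#' @export
nco_control <- function(tol = 1e-7, max_iter = 200, restarts = 1,
                        seed = NULL, tail_tol = 1e-9, collapse_tol = 1e-6,
                        mstep_tol = 1e-10, mstep_maxit = 400,
                        X_max_cap = 65536L) {
  stopifnot(tol > 0, max_iter >= 1, restarts >= 1, tail_tol > 0)
  list(tol = tol, max_iter = max_iter, restarts = restarts, seed = seed,
       tail_tol = tail_tol, collapse_tol = collapse_tol,
       mstep_tol = mstep_tol, mstep_maxit = mstep_maxit,
       X_max_cap = as.integer(X_max_cap))
}

# deterministic initialization: component means at evenly spaced quantiles
# of the observed spans inflated by 1/p (spans lower-bound event lengths),
# sizes 1, uniform detected-space weights; jitter > 0 adds log-normal noise
init_mixture <- function(spans, p, n, geometric = FALSE, jitter = 0) {
  qs <- (seq_len(n) * 2 - 1) / (2 * n)
  means <- 1 + stats::quantile(spans, qs, names = FALSE) / p
  if (n > 1) # enforce distinct, log-spaced starting means
    means <- sort(means) * exp(seq(-0.1, 0.1, length.out = n))
  if (jitter > 0) {
    means <- 1 + (means - 1) * exp(stats::rnorm(n, 0, jitter))
    sizes <- exp(stats::rnorm(n, 0, jitter))
  } else sizes <- rep(1, n)
  if (geometric) sizes <- rep(1, n)
  # every tract must have positive probability under the starting values:
  # keep the geometric tail from underflowing at the largest span
  means <- pmax(means, 1 + 1e-6, 1 + max(spans) / 200)
  nco_mixture(means, sizes, alpha_hat = rep(1 / n, n))
}

# parameter vector used for the convergence norm
par_vector <- function(mix) {
  c(mix$alpha_hat,
    log(vapply(mix$components, `[[`, 0, "mean")),
    log(vapply(mix$components, `[[`, 0, "size")))
}

#' Fit an NCO event-length mixture by expectation-maximization
#'
#' Estimates the length distribution of NCO events (a mixture of shifted
#' negative binomial distributions) and its detected-space mixture weights
#' from observed gene conversion tracts, correcting for the fact that only
#' events converting at least one informative marker are observable.
#'
#' @param tracts an [nco_tracts()] object, or an [nco_dataset()] (in which
#'   case `markers` and `genome` are taken from it).
#' @param markers an [nco_markers()] object.
#' @param genome an [nco_genome()] object.
#' @param n_components number of mixture components.
#' @param penetrance per-marker conversion probability in (0, 1]; estimated
#'   from the tracts via [estimate_penetrance()] when `NULL`.
#' @param geometric logical; constrain all component sizes to 1 (geometric
#'   length distribution), the classical single-parameter model.
#' @param kernel optional precomputed [nco_kernel()] (its `p` must match).
#' @param init optional [nco_mixture()] used as the sole starting point
#'   (overrides the quantile initialization and restarts).
#' @param n_meioses number of meioses the tracts were collected from, used
#'   by [nco_count()]; defaults to the marker map's total meiosis count.
#' @param control list from [nco_control()].
#' @return An object of class `nco_fit` with components `mixture` (an
#'   [nco_mixture()] with both weight systems and detection masses),
#'   `logLik`, `trace` (per-iteration log-likelihood), `weights` (per-tract
#'   membership), `converged`, `iterations`, `kernel`, `penetrance`,
#'   `n_tracts`, `n_meioses`.
#' @seealso [nco_select()] for choosing `n_components`, [nco_count()] for
#'   the implied number of events, [nco_boot()] for confidence intervals.
#' @examples
#' g <- nco_genome(c(chr1 = 200000))
#' mk <- synth_markers(g, spacing = 50, seed = 1)
#' sim <- nco_simulate(g, mk, nco_mixture(300, 2, alpha = 1),
#'                     penetrance = 1, n_tracts = 150, seed = 2)
#' fit <- nco_fit(sim$dataset, penetrance = 1)
#' fit
#' @export
nco_fit <- function(tracts, markers = NULL, genome = NULL, n_components = 1,
                    penetrance = NULL, geometric = FALSE, kernel = NULL,
                    init = NULL, n_meioses = NULL, control = nco_control()) {
  if (inherits(tracts, "nco_dataset")) {
    dat <- tracts
    tracts <- dat$tracts; markers <- dat$markers; genome <- dat$genome
    if (is.null(n_meioses)) n_meioses <- dat$n_meioses
  }
  if (!nrow(tracts)) stop("no tracts to fit")
  pen_obj <- NULL
  if (is.null(penetrance)) {
    pen_obj <- estimate_penetrance(tracts, markers)
    penetrance <- pen_obj$p
    if (penetrance <= 0)
      stop("estimated penetrance is 0; supply penetrance explicitly")
  }
  if (is.null(kernel)) {
    kernel <- nco_kernel(tracts, markers, genome, penetrance)
  } else if (abs(kernel$p - penetrance) > 1e-12) {
    stop("kernel was computed with p = ", kernel$p,
         " but the fit uses p = ", penetrance)
  }
  if (is.null(n_meioses))
    n_meioses <- if (!is.null(markers)) sum(attr(markers, "meioses")) else 1
  if (!is.null(control$seed)) set.seed(control$seed)
  starts <- if (!is.null(init)) {
    list(init)
  } else {
    c(list(init_mixture(kernel$spans, penetrance, n_components, geometric)),
      lapply(seq_len(control$restarts - 1), function(j)
        init_mixture(kernel$spans, penetrance, n_components, geometric,
                     jitter = 0.5)))
  }
  best <- NULL
  for (s in seq_along(starts)) {
    res <- run_em(kernel, starts[[s]], geometric, control)
    kernel <- res$kernel   # keep any extension for subsequent restarts
    if (is.null(best) || res$logLik > best$logLik + 1e-9) {
      best <- res
      best$restart <- s
    }
  }
  mix <- tryCatch(
    attach_weights(best$mixture, best$kernel$D, tail_tol = control$tail_tol),
    error = function(e) {
      # table capped by chromosome length: fall back to truncated sums
      warning("detection masses computed over a truncated length table: ",
              conditionMessage(e))
      m <- best$mixture
      m$d <- vapply(m$components, function(cp)
        sum(best$kernel$D * nb_pmf(cp, seq_along(best$kernel$D))), 0)
      m$alpha <- invert_weights(m$alpha_hat, m$d)
      m
    })
  structure(list(mixture = mix, logLik = best$logLik, trace = best$trace,
                 weights = best$weights, converged = best$converged,
                 stalled = best$stalled,
                 iterations = best$iterations, collapsed = best$collapsed,
                 kernel = best$kernel, penetrance = penetrance,
                 penetrance_estimate = pen_obj, geometric = geometric,
                 n_tracts = nrow(kernel$Tmat), n_meioses = n_meioses,
                 restart = best$restart, control = control,
                 call = match.call()),
            class = "nco_fit")
}

# single EM run from one starting mixture; extends the kernel table whenever
# the current parameters put non-negligible tail mass beyond it.  Plain EM
# steps are interleaved with SQUAREM-style extrapolation cycles (two EM
# steps define a secant direction; the extrapolated point is kept only if a
# further EM step from it improves the log-likelihood), which preserves the
# monotone trace while cutting the iteration count severalfold on slowly
# converging mixtures
run_em <- function(kernel, mix, geometric, control, freq = NULL) {
  X_cap <- min(min(kernel$genome %||% Inf) - 1,
               max(control$X_max_cap %||% 65536L, kernel$X_max))
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  wsum <- function(v) if (is.null(freq)) sum(v) else sum(freq * v)
  collapse_signal <- function(new_mix) {
    keep <- !attr(new_mix, "collapsed")
    warning("dropping ", sum(!keep), " collapsed component(s) and refitting")
    sub <- nco_mixture(new_mix$components[keep],
                       alpha_hat = new_mix$alpha_hat[keep] /
                         sum(new_mix$alpha_hat[keep]))
    res <- run_em(kernel, sub, geometric, control, freq = freq)
    res$collapsed <- TRUE
    res
  }
  loglik_of <- function(m) {
    lik <- as.numeric(tract_prob_matrix(kernel, m)$P %*% m$alpha_hat)
    if (any(lik == 0 & (is.null(freq) | freq > 0))) return(-Inf)
    wsum(log(pmax(lik, 1e-300)))
  }
  # one E+M cycle; returns the updated mixture and the input's
  # log-likelihood; freq carries per-tract frequency weights (bootstrap
  # resamples reweight the tracts instead of duplicating matrix rows)
  one_step <- function(m) {
    pm <- tract_prob_matrix(kernel, m)
    lik <- as.numeric(pm$P %*% m$alpha_hat)
    bad <- lik == 0 & (if (is.null(freq)) TRUE else freq > 0)
    if (any(bad))
      stop("tract(s) with no detection overlap under the model: ",
           paste(kernel$tract_id[bad], collapse = ", "))
    W <- sweep(pm$P, 2, m$alpha_hat, "*") / pmax(lik, 1e-300)
    list(mix = m_step(kernel, W, m, geometric = geometric,
                      control = control, freq = freq),
         ll_in = wsum(log(pmax(lik, 1e-300))), W = W)
  }
  # returns TRUE if the table was extended (trace restarts: log-likelihoods
  # on different tabulation grids are not comparable at 1e-8 resolution)
  maybe_extend <- function(m) {
    need <- truncation_point_mix(m, control$tail_tol)
    if (need > kernel$X_max && kernel$X_max < X_cap &&
        !is.null(kernel$tracts)) {
      kernel <<- extend_kernel(kernel, min(ceiling(need * 1.2), X_cap))
      trace <<- numeric(0)
      TRUE
    } else FALSE
  }
  stalled <- FALSE
  # flat-ridge guard: when successive accepted iterates no longer move the
  # log-likelihood at numerical resolution (relative 1e-10), further
  # parameter drift is not informative; a single free component needs only
  # one resolution-level gain because its M-step maximizes the full
  # likelihood directly
  check_stall <- function() {
    win <- if (length(mix$components) == 1 && !geometric) 2L else 4L
    if (length(trace) < win + 1) return(FALSE)
    gains <- diff(utils::tail(trace, win))
    all(abs(gains) < 1e-10 * (1 + abs(trace[length(trace)])))
  }
  repeat {
    s1 <- one_step(mix)
    iter <- iter + 1
    trace[length(trace) + 1] <- s1$ll_in
    if (check_stall()) { mix <- s1$mix; stalled <- TRUE; break }
    if (any(attr(s1$mix, "collapsed"))) return(collapse_signal(s1$mix))
    if (maybe_extend(s1$mix)) { mix <- s1$mix; next }
    delta <- rel_change(par_vector(s1$mix), par_vector(mix))
    if (delta < control$tol) { mix <- s1$mix; converged <- TRUE; break }
    if (iter >= control$max_iter) { mix <- s1$mix; break }
    # second step of the extrapolation cycle
    s2 <- one_step(s1$mix)
    iter <- iter + 1
    trace[length(trace) + 1] <- s2$ll_in
    if (check_stall()) { mix <- s2$mix; stalled <- TRUE; break }
    if (any(attr(s2$mix, "collapsed"))) return(collapse_signal(s2$mix))
    if (maybe_extend(s2$mix)) { mix <- s2$mix; next }
    delta <- rel_change(par_vector(s2$mix), par_vector(s1$mix))
    if (delta < control$tol) { mix <- s2$mix; converged <- TRUE; break }
    if (iter >= control$max_iter) { mix <- s2$mix; break }
    mix_new <- s2$mix
    # extrapolation pays off only when membership weights evolve; a single
    # component's M-step already maximizes the full likelihood directly
    if (!geometric && length(mix$components) > 1) {
      p0 <- par_vector_log(mix)
      r <- par_vector_log(s1$mix) - p0
      v <- (par_vector_log(s2$mix) - par_vector_log(s1$mix)) - r
      if (sum(v^2) > 0) {
        a <- min(-1, -sqrt(sum(r^2) / sum(v^2)))
        cand <- unpar_vector_log(p0 - 2 * a * r + a^2 * v, mix)
        s3 <- if (is.null(cand)) NULL else
          tryCatch(one_step(cand), error = function(e) NULL)
        if (!is.null(s3) && !any(attr(s3$mix, "collapsed"))) {
          ll2 <- loglik_of(s2$mix)
          ll3 <- loglik_of(s3$mix)
          if (is.finite(ll3) && ll3 >= ll2) {
            iter <- iter + 1
            trace[length(trace) + 1] <- ll2
            mix_new <- s3$mix
            if (maybe_extend(mix_new)) { mix <- mix_new; next }
            delta <- rel_change(par_vector(mix_new), par_vector(s2$mix))
            if (delta < control$tol) {
              mix <- mix_new; converged <- TRUE; break
            }
          }
        }
      }
    }
    mix <- mix_new
    if (iter >= control$max_iter) break
  }
  pm <- tract_prob_matrix(kernel, mix)
  lik <- as.numeric(pm$P %*% mix$alpha_hat)
  W <- sweep(pm$P, 2, mix$alpha_hat, "*") / pmax(lik, 1e-300)
  ll <- wsum(log(pmax(lik, 1e-300)))
  trace[length(trace) + 1] <- ll
  list(mixture = mix, logLik = ll, trace = trace, weights = W,
       converged = converged || stalled, stalled = stalled,
       iterations = iter, collapsed = FALSE, kernel = kernel)
}

# unconstrained parameterization used by the extrapolation cycle
par_vector_log <- function(mix) {
  c(log(mix$alpha_hat),
    log(vapply(mix$components, `[[`, 0, "mean") - 1 + 1e-12),
    log(vapply(mix$components, `[[`, 0, "size")))
}

unpar_vector_log <- function(p, template) {
  n <- length(template$components)
  if (any(!is.finite(p))) return(NULL)
  ah <- exp(p[seq_len(n)])
  mp <- exp(p[n + seq_len(n)])
  r <- exp(p[2 * n + seq_len(n)])
  if (any(mp > 1e8) || any(r < 1e-4) || any(r > 1e6) ||
      any(ah <= 0) || !is.finite(sum(ah))) return(NULL)
  nco_mixture(1 + mp, r, alpha_hat = ah / sum(ah))
}

truncation_point_mix <- function(mix, tail_tol)
  max(vapply(mix$components, truncation_point, 0, tail_tol = tail_tol))

# relative change per parameter, guarded so parameters sitting at 0 (e.g.
# log size = 0 for a geometric component) are measured on an absolute scale
rel_change <- function(new, old) sqrt(sum(((new - old) / pmax(abs(old), 1))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
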
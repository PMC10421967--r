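#' Estimate penetrance from tracts
#'
#' Penetrance `p` is the probability that an informative marker overlapped
#' by an NCO event is actually gene converted.  It is estimated as the
#' fraction of converted markers among the informative markers lying
#' strictly between the first and the last converted marker of each tract.
#' Boundary markers (the outermost converted marker on either side) are
#' excluded because they are converted by construction and would bias the
#' estimate upward.
#'
#' @param tracts an [nco_tracts()] object.
#' @param markers an [nco_markers()] object.
#' @return An object of class `nco_penetrance`: list with elements `p`,
#'   `n_interior` (informative markers strictly inside tract spans, converted
#'   or not) and `n_converted_interior`.
#' @export
estimate_penetrance <- function(tracts, markers) {
  n_int <- 0
  n_conv <- 0
  for (i in seq_len(nrow(tracts))) {
    s <- tracts$positions[[i]]
    if (length(s) < 2) next
    mk <- markers[[tracts$parent_id[i]]][[tracts$chrom[i]]]
    a <- min(s); b <- max(s)
    n_int <- n_int + sum(mk > a & mk < b)
    n_conv <- n_conv + (length(s) - 2L)
  }
  if (n_int == 0)
    stop("cannot estimate penetrance: no tract has an informative marker ",
         "strictly between its outermost converted markers; supply the ",
         "penetrance explicitly")
  structure(list(p = n_conv / n_int, n_interior = n_int,
                 n_converted_interior = n_conv), class = "nco_penetrance")
}

#' @export
print.nco_penetrance <- function(x, ...) {
  cat(sprintf("Penetrance estimate: %.4g (%d of %d interior markers converted)\n",
              x$p, x$n_converted_interior, x$n_interior))
  invisible(x)
}

#' Probability of detection given marker overlap
#'
#' An event overlapping `n` informative markers produces at least one gene
#' conversion with probability `1 - (1 - p)^n`: every overlapped marker is
#' converted independently with probability `p`.
#'
#' @param n number of informative markers inside the event (vectorized).
#' @param p penetrance in (0, 1].
#' @return Probability vector.
#' @export
detect_prob_given_n <- function(n, p) {
  check_penetrance(p)
  if (any(n < 0)) stop("n must be nonnegative")
  1 - (1 - p)^n
}

check_penetrance <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p <= 0 || p > 1)
    stop("penetrance must be a single number in (0, 1]")
  invisible(p)
}

#' Detection function
#'
#' `D(x)` is the probability that a random NCO event of length `x`, placed
#' uniformly over all positions where it fits inside a chromosome, converts
#' at least one informative marker and is hence observable.  For a placement
#' overlapping `n` markers that probability is `1 - (1-p)^n`; `D(x)`
#' averages it over all `sum(len - x + 1)` placements, pooling chromosomes,
#' and then averages parents weighted by their meiosis counts.
#'
#' The computation is exact.  For each parent-chromosome the sum of
#' `(1-p)^n` over window starts is updated from length `x` to `x + 1` by
#' correcting only the windows whose right edge gains a marker, so the whole
#' table costs time proportional to the number of marker pairs closer than
#' `X_max` rather than to genome length times `X_max`.
#'
#' @param markers an [nco_markers()] object.
#' @param genome an [nco_genome()] object.
#' @param p penetrance in (0, 1].
#' @param X_max largest event length to tabulate; must be smaller than the
#'   shortest chromosome.
#' @return Numeric vector `D` of length `X_max`, `D[x] = Pr(detected | L = x)`.
#' @export
detection_function <- function(markers, genome, p, X_max) {
  check_penetrance(p)
  X_max <- check_xmax(X_max, genome)
  w <- attr(markers, "meioses")
  if (!length(markers)) stop("marker map has no parents")
  D <- numeric(X_max)
  for (par in names(markers)) {
    A <- numeric(X_max)          # sum over chroms of sum_m (1-p)^{n(m,x)}
    for (chr in names(genome)) {
      pos <- markers[[par]][[chr]]
      if (is.null(pos)) pos <- numeric(0)
      A <- A + window_qsum(pos, genome[[chr]], 1 - p, X_max)
    }
    N <- placements(genome, X_max)
    D <- D + w[[par]] * (N - A) / N
  }
  D / sum(w)
}

# number of valid placements of an event of length x, pooled over chromosomes
placements <- function(genome, X_max) {
  N <- numeric(X_max)
  for (g in genome) N <- N + pmax(g - seq_len(X_max) + 1, 0)
  N
}

check_xmax <- function(X_max, genome) {
  if (X_max < 1) stop("X_max must be >= 1")
  if (X_max >= min(genome))
    stop("X_max (", X_max, ") must be smaller than the shortest chromosome (",
         min(genome), "); the uniform placement convention requires events ",
         "to fit inside a chromosome")
  as.integer(X_max)
}

# S(x) = sum_{m=1}^{G-x+1} q^{n(m,x)} for x = 1..X_max, where n(m,x) is the
# number of markers in [m, m+x-1].  Incremental over x:
#   S(x+1) = S(x) - q^{tail(x)} - (1-q) * sum_{k: pos_k > x} q^{c_k(x)}
# with tail(x) = #markers in [G-x+1, G] and c_k(x) = #markers in
# [pos_k - x, pos_k - 1].  The inner sum is maintained incrementally via the
# marker-pair change schedule, so total work is O(#pairs within X_max).
window_qsum <- function(pos, G, q, X_max) {
  K <- length(pos)
  S <- numeric(X_max)
  if (K == 0) { S[] <- G - seq_len(X_max) + 1; return(S) }
  qp <- q^(0:K)
  # once q^{c_k} underflows to exactly 0 further increments of c_k cannot
  # change the sum, so only the first c_cap neighbours of a marker matter;
  # for q = 0 (full penetrance) that is just the adjacent marker
  c_cap <- if (q == 0) 1L else {
    z <- which(qp == 0)
    if (length(z)) z[1] - 1L else K
  }
  # the change schedule (c_k increases by 1 at x = pos_k - pos_j) is
  # generated in chunks of the x axis to bound memory on dense maps
  nxt <- pmin(seq_len(K) + 1L, K + 1L)   # next neighbour k to emit, per j
  span_per_x <- max(1, K^2 / (pos[K] - pos[1] + 1))
  step <- max(256L, as.integer(4e6 / span_per_x))
  chunk_hi <- 0L
  ev_d <- integer(0); ev_k <- integer(0); ev_ptr <- 1L
  load_chunk <- function() {
    xhi <- min(chunk_hi + step, X_max)
    hi <- pmin(pmin(seq_len(K) + c_cap, K),
               findInterval(pos + xhi, pos))
    cnt <- pmax(hi - nxt + 1L, 0L)
    jj <- rep.int(seq_len(K), cnt)
    kk <- sequence(cnt) + rep.int(nxt - 1L, cnt)
    dd <- as.integer(pos[kk] - pos[jj])
    nxt <<- pmax(nxt, hi + 1L)
    ord <- order(dd)
    ev_d <<- dd[ord]; ev_k <<- kk[ord]; ev_ptr <<- 1L
    chunk_hi <<- xhi
  }
  # markers leave the inner sum when pos_k <= x
  lv_ptr <- 1L
  cvec <- integer(K)               # c_k(x) for current x
  qv <- qp[cvec + 1L]              # q^{c_k}
  Ssum <- sum(qv)                  # over k with pos_k > x
  # tail(x): markers in [G-x+1, G]
  tail_cnt <- 0L
  tl_ptr <- K
  S[1] <- (G - K) + K * q
  if (X_max >= 2) for (x in 1:(X_max - 1)) {
    while (chunk_hi < x) load_chunk()
    # bring the schedule up to date (c_k changes at distance x)
    while (ev_ptr <= length(ev_d) && ev_d[ev_ptr] <= x) {
      if (ev_d[ev_ptr] == x) {
        k <- ev_k[ev_ptr]
        if (pos[k] > x && cvec[k] < c_cap) {
          Ssum <- Ssum - qv[k] + qp[cvec[k] + 2L]
          cvec[k] <- cvec[k] + 1L
          qv[k] <- qp[cvec[k] + 1L]
        }
      }
      ev_ptr <- ev_ptr + 1L
    }
    while (lv_ptr <= K && pos[lv_ptr] <= x) {
      Ssum <- Ssum - qv[lv_ptr]
      lv_ptr <- lv_ptr + 1L
    }
    while (tl_ptr >= 1L && pos[tl_ptr] >= G - x + 1) {
      tail_cnt <- tail_cnt + 1L
      tl_ptr <- tl_ptr - 1L
    }
    S[x + 1] <- S[x] - qp[tail_cnt + 1L] - (1 - q) * Ssum
  }
  S
}

#' Tract function
#'
#' `T[x]` is the probability that a random NCO event of length `x`, placed
#' uniformly over all positions where it fits inside a chromosome, produces
#' exactly the observed tract `t`: the placement must cover all converted
#' markers of `t`, those markers are converted (probability `p` each) and
#' every other informative marker inside the placement is left unconverted
#' (probability `1 - p` each).  The same placement normalization as
#' [detection_function()] is used, so `0 <= T[x] <= D(x)`, and `T[x] = 0`
#' for `x` below the tract span.
#'
#' @param tract converted marker positions of the tract (strictly increasing).
#' @param positions informative-marker positions of the transmitting parent
#'   on the tract's chromosome (must contain `tract`).
#' @param genome an [nco_genome()]; the tract's chromosome is `chrom`.
#' @param chrom chromosome the tract is on.
#' @param p penetrance in (0, 1].
#' @param X_max largest event length to tabulate.
#' @return Numeric vector `T` of length `X_max`.
#' @export
tract_function <- function(tract, positions, genome, chrom, p, X_max) {
  check_penetrance(p)
  X_max <- check_xmax(X_max, genome)
  if (!chrom %in% names(genome)) stop("unknown chromosome ", chrom)
  if (length(setdiff(tract, positions)))
    stop("tract positions must be informative markers")
  N <- placements(genome, X_max)
  tract_raw(sort(tract), positions, genome[[chrom]], p, X_max) / N
}

# unnormalized tract function: sum over placements [m, m+x-1] covering the
# tract of p^{|s|} (1-p)^{#other markers in placement}.  The other-marker
# count splits into interior (constant), left of the tract (depends on m
# only) and right of the tract (depends on m+x-1 only), so the sum over
# placements is a cross-correlation of two step vectors.  Returns the
# nonzero entries only (list of x and value): with high penetrance the
# support is a narrow band above the span and a dense vector would waste
# most of its length.
tract_raw_sparse <- function(s, pos, G, p, X_max) {
  q <- 1 - p
  a <- min(s); b <- max(s)
  span <- b - a + 1
  none <- list(x = integer(0), v = numeric(0))
  if (span > X_max) return(none)
  other <- pos[match(pos, s, 0L) == 0L]
  n_int <- sum(other > a & other < b)
  const <- p^length(s) * q^n_int
  if (const == 0) return(none)
  mlo <- max(1, b - X_max + 1); mhi <- a          # window starts
  elo <- b; ehi <- min(G, a + X_max - 1)          # window ends
  ms <- mlo:mhi
  es <- elo:ehi
  # q^{#other markers in [m, a-1]} and q^{#other in [b+1, e]}
  nl <- findInterval(a - 1, other) - findInterval(ms - 1, other)
  nr <- findInterval(es, other) - findInterval(b, other)
  Lv <- q^nl
  Rv <- q^nr
  # Lv is nondecreasing and Rv nonincreasing, so zero entries (p = 1 or
  # underflow) form a prefix / suffix; trimming them leaves the lag
  # arithmetic unchanged because the index below depends only on a - b
  nzL <- which(Lv > 0); nzR <- which(Rv > 0)
  if (!length(nzL) || !length(nzR)) return(none)
  Lv <- Lv[nzL[1]:length(Lv)]
  Rv <- Rv[1:nzR[length(nzR)]]
  mlo <- mlo + nzL[1] - 1L
  # C[d] = sum_j Lv[j] * Rv[j + d]; window of length x pairs m with
  # e = m + x - 1, i.e. lag d = x - 1 + mlo - elo
  C <- cross_correlate(Lv, Rv)
  # x values whose lag falls inside C's support, clipped to [span, X_max]
  x_lo <- max(span, 2 + elo - mlo - length(Lv))
  x_hi <- min(X_max, length(C) + 1 + elo - mlo - length(Lv))
  if (x_hi < x_lo) return(none)
  xs <- x_lo:x_hi
  v <- pmax(C[xs - 1 + mlo - elo + length(Lv)], 0) * const
  keep <- v > 0
  list(x = xs[keep], v = v[keep])
}

tract_raw <- function(s, pos, G, p, X_max) {
  out <- numeric(X_max)
  sp <- tract_raw_sparse(s, pos, G, p, X_max)
  out[sp$x] <- sp$v
  out
}

# cross-correlation C[d] = sum_j a[j] b[j + d], d = 1-len(a) .. len(b)-1,
# returned as a vector indexed by d - (1 - len(a)) + 1.  Direct when small,
# FFT with power-of-two padding when large.
cross_correlate <- function(a, b) {
  na <- length(a); nb <- length(b)
  n <- na + nb - 1L
  if (as.double(na) * nb <= 262144) {
    # C_ab[d] = C_ba[-d]: loop over the shorter side
    if (nb < na) return(rev(cross_correlate(b, a)))
    out <- numeric(n)
    for (j in seq_len(na)) {
      idx <- j:(j + nb - 1L) # d = (1:nb) - j  -> position d + na
      out[(na - j + 1L):(na - j + nb)] <- out[(na - j + 1L):(na - j + nb)] +
        a[j] * b
    }
    return(out)
  }
  nn <- 2^ceiling(log2(n))
  A <- stats::fft(c(rev(a), numeric(nn - na)))
  B <- stats::fft(c(b, numeric(nn - nb)))
  Re(stats::fft(A * B, inverse = TRUE))[seq_len(n)] / nn
}

#' Precompute the detection and tract function table
#'
#' Tabulates the detection function `D(x)` and the tract function of every
#' tract for event lengths `x = 1..X_max`.  These are the fixed inputs of
#' the EM algorithm; they do not depend on the length distribution.
#'
#' @param tracts an [nco_tracts()] object.
#' @param markers an [nco_markers()] object.
#' @param genome an [nco_genome()] object.
#' @param p penetrance in (0, 1], e.g. from [estimate_penetrance()].
#' @param X_max largest tabulated event length.  The default covers the
#'   largest tract span with generous headroom; [nco_fit()] extends the
#'   table automatically when the fitted distribution needs more.
#' @param D optional precomputed [detection_function()] vector (length
#'   `>= X_max`), useful when many datasets share one marker map.
#' @return An object of class `nco_kernel`: list with `D` (length `X_max`),
#'   `Tmat` (sparse `n_tracts` by `X_max` matrix of tract functions), `N`
#'   (placement counts), `p`, `X_max`, `spans`, `tract_id`.
#' @export
nco_kernel <- function(tracts, markers, genome, p, X_max = NULL, D = NULL) {
  check_penetrance(p)
  spans <- tract_span(tracts)
  if (is.null(X_max)) {
    X_max <- if (!is.null(D)) length(D) else
      min(ceiling(4 * stats::quantile(spans, 0.99) / p) + 200,
          min(genome) - 1)
  }
  X_max <- check_xmax(X_max, genome)
  if (max(spans) > X_max)
    stop("X_max (", X_max, ") is smaller than the largest tract span (",
         max(spans), ")")
  if (is.null(D)) {
    D <- detection_function(markers, genome, p, X_max)
  } else if (length(D) < X_max) {
    stop("precomputed D is shorter than X_max")
  } else D <- D[seq_len(X_max)]
  N <- placements(genome, X_max)
  trip <- vector("list", nrow(tracts))
  # pre-restrict each tract to the markers it can ever see (one vectorized
  # lookup per parent-chromosome group instead of per-tract scans)
  grp <- paste(tracts$parent_id, tracts$chrom, sep = "\r")
  for (gkey in unique(grp)) {
    idx <- which(grp == gkey)
    pos <- markers[[tracts$parent_id[idx[1]]]][[tracts$chrom[idx[1]]]]
    G <- genome[[tracts$chrom[idx[1]]]]
    aa <- vapply(tracts$positions[idx], min, 0)
    bb <- vapply(tracts$positions[idx], max, 0)
    lo <- findInterval(pmax(bb - X_max, 1) - 1, pos) + 1L
    hi <- findInterval(pmin(aa + X_max, G), pos)
    for (j in seq_along(idx)) {
      i <- idx[j]
      sp <- tract_raw_sparse(tracts$positions[[i]], pos[lo[j]:hi[j]], G, p,
                             X_max)
      trip[[i]] <- list(j = sp$x, x = sp$v / N[sp$x])
    }
  }
  i_idx <- rep(seq_len(nrow(tracts)), vapply(trip, function(t) length(t$j), 0L))
  Tmat <- Matrix::sparseMatrix(
    i = i_idx, j = unlist(lapply(trip, `[[`, "j")),
    x = unlist(lapply(trip, `[[`, "x")),
    dims = c(nrow(tracts), X_max))
  structure(list(D = D, Tmat = Tmat, N = N, p = p, X_max = X_max,
                 spans = spans, tract_id = tracts$tract_id,
                 tracts = tracts, markers = markers, genome = genome),
            class = "nco_kernel")
}

#' @export
print.nco_kernel <- function(x, ...) {
  cat("Kernel table:", nrow(x$Tmat), "tracts, X_max =", x$X_max,
      sprintf(", p = %.4g\n", x$p))
  invisible(x)
}

#' Extend a kernel table to a larger maximum event length
#'
#' @param kernel an [nco_kernel()] object.
#' @param X_max new (larger) maximum tabulated length.
#' @return A new `nco_kernel` with the same tracts tabulated to `X_max`.
#' @export
extend_kernel <- function(kernel, X_max) {
  if (X_max <= kernel$X_max) return(kernel)
  nco_kernel(kernel$tracts, kernel$markers, kernel$genome, kernel$p,
             X_max = X_max)
}

#' Write or read a kernel cache
#'
#' Plain TSV cache of a kernel table so repeated fits need not recompute it:
#' columns `x`, `N`, `D`, then one column per tract id.  Zero entries of the
#' tract functions are stored as 0.
#'
#' @param kernel an [nco_kernel()].
#' @param path file path.
#' @return `read_kernel()` returns a list with `D`, `Tmat`, `N`, `p`,
#'   `X_max`, `tract_id` (no tract/marker objects, so it cannot be extended).
#' @export
write_kernel <- function(kernel, path) {
  df <- data.frame(x = seq_len(kernel$X_max), N = kernel$N, D = kernel$D)
  Tm <- as.matrix(Matrix::t(kernel$Tmat))
  colnames(Tm) <- kernel$tract_id
  utils::write.table(cbind(df, Tm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @param p penetrance the cache was computed with.
#' @export
read_kernel <- function(path, p) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  Tmat <- Matrix::Matrix(t(as.matrix(df[, -(1:3), drop = FALSE])),
                         sparse = TRUE)
  structure(list(D = df$D, Tmat = Tmat, N = df$N, p = p, X_max = nrow(df),
                 spans = apply(Tmat > 0, 1, which.max),
                 tract_id = colnames(df)[-(1:3)]),
            class = "nco_kernel")
}
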
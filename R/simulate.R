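#' Generate a synthetic informative-marker map
#'
#' Two marker models are available.  Density mode places markers by a
#' homogeneous (binomial) process with a target mean spacing, emulating the
#' spacing statistics of a human heterozygous-marker set.  Allele-frequency
#' mode takes candidate sites with population allele frequencies `f` and
#' keeps each independently with the heterozygosity probability
#' `2 f (1 - f)`.
#'
#' @param genome an [nco_genome()].
#' @param spacing target mean distance in bp between consecutive markers
#'   (density mode).  The human-like default is 1465 bp.
#' @param median_spacing optional target median gap, `< spacing`.  Real
#'   heterozygous-marker sets are strongly clustered (the human-like
#'   reference has mean gap 1465 bp but median 754 bp); when given, gaps
#'   are drawn log-normally with exactly this mean/median pair instead of
#'   the memoryless homogeneous model.
#' @param sites,freqs allele-frequency mode: list (per chromosome) of
#'   candidate positions and matching allele frequencies.
#' @param parent_id parent identifier for the resulting map.
#' @param meioses meiosis count of the parent.
#' @param seed integer seed; the map is deterministic given the seed.
#' @return An [nco_markers()] object with a single parent.
#' @export
synth_markers <- function(genome, spacing = 1465, median_spacing = NULL,
                          sites = NULL, freqs = NULL,
                          parent_id = "P1", meioses = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sites) != is.null(freqs))
    stop("sites and freqs must be given together")
  pos <- if (is.null(sites)) {
    if (spacing <= 1) stop("spacing must be > 1")
    if (!is.null(median_spacing)) {
      if (median_spacing >= spacing || median_spacing < 1)
        stop("median_spacing must be in [1, spacing)")
      # log-normal gaps: median = exp(mu), mean = exp(mu + sigma^2/2)
      mu <- log(median_spacing)
      sigma <- sqrt(2 * log(spacing / median_spacing))
      lapply(as.list(genome), function(G) {
        out <- numeric(0)
        at <- 0
        while (at < G) {
          gaps <- pmax(round(stats::rlnorm(ceiling((G - at) / spacing) + 50,
                                           mu, sigma)), 1)
          new <- at + cumsum(gaps)
          out <- c(out, new)
          at <- new[length(new)]
        }
        out[out <= G]
      })
    } else {
      lapply(as.list(genome), function(G) {
        keep <- which(stats::runif(G) < 1 / spacing)
        as.numeric(keep)
      })
    }
  } else {
    if (!all(names(sites) %in% names(genome)))
      stop("candidate sites on unknown chromosome(s)")
    Map(function(s, f) {
      if (length(s) != length(f)) stop("sites/freqs length mismatch")
      p_in <- 2 * f * (1 - f)
      sort(as.numeric(s[stats::runif(length(s)) < p_in]))
    }, sites, freqs)
  }
  if (!sum(lengths(pos))) stop("no markers generated; increase density")
  names(pos) <- names(genome)[seq_along(pos)]
  nco_markers(stats::setNames(list(pos[lengths(pos) > 0]), parent_id),
              meioses = stats::setNames(meioses, parent_id), genome = genome)
}

#' Simulate NCO events and their gene conversion tracts
#'
#' Draws NCO events from a length mixture, places each uniformly over all
#' positions where it fits inside a chromosome (the same placement measure
#' the kernel module integrates over), converts every overlapped informative
#' marker independently with probability `penetrance`, and emits a tract for
#' each event that converted at least one marker.  Undetected events are
#' counted but produce no tract.
#'
#' @param genome an [nco_genome()].
#' @param markers an [nco_markers()] object; events are assigned to parents
#'   proportionally to their meiosis counts.
#' @param mixture an [nco_mixture()]; components are drawn with the
#'   *underlying* weights `alpha` (use [invert_weights()] if you start from
#'   detected-space weights).
#' @param penetrance per-marker conversion probability in (0, 1].
#' @param n_tracts stop once this many tracts have been produced
#'   (mutually exclusive with `n_events`).
#' @param n_events simulate exactly this many events.
#' @param seed integer seed; output is deterministic given the seed.
#' @param max_events safety cap when `n_tracts` is requested but detection
#'   is (near) zero.
#' @return An object of class `nco_sim`: list with `dataset` (an
#'   [nco_dataset()]), `truth` (data frame per event: component, chromosome,
#'   start, length, tract id or `NA`), `n_events`, `n_events_component`,
#'   `mixture`, `penetrance`.
#' @export
nco_simulate <- function(genome, markers, mixture, penetrance,
                         n_tracts = NULL, n_events = NULL, seed = NULL,
                         max_events = 1e7) {
  check_penetrance(penetrance)
  if (is.null(n_tracts) == is.null(n_events))
    stop("give exactly one stopping rule: n_tracts or n_events")
  if (is.null(mixture$alpha))
    stop("mixture must carry underlying weights alpha ",
         "(the simulator draws events, not detected events)")
  if (!is.null(seed)) set.seed(seed)
  n_comp <- length(mixture$components)
  mei <- attr(markers, "meioses")
  parents <- names(markers)
  truth <- list()
  tr_pos <- list(); tr_par <- character(0); tr_chr <- character(0)
  tot_events <- 0
  comp_events <- integer(n_comp)
  target <- if (is.null(n_tracts)) n_events else n_tracts
  batch <- as.integer(max(64, min(ceiling(target * 2), 65536)))
  repeat {
    if (!is.null(n_tracts) && length(tr_pos) >= n_tracts) break
    if (!is.null(n_events) && tot_events >= n_events) break
    if (tot_events >= max_events)
      stop("event cap (", max_events, ") reached before ", n_tracts,
           " tracts were produced; the mixture is (near) undetectable")
    b <- if (is.null(n_tracts)) min(batch, n_events - tot_events) else batch
    z <- sample.int(n_comp, b, replace = TRUE,
                    prob = if (n_comp > 1) mixture$alpha else NULL)
    L <- numeric(b)
    for (i in seq_len(n_comp)) {
      ni <- sum(z == i)
      if (ni) L[z == i] <- 1 + stats::rnbinom(
        ni, size = mixture$components[[i]]$size,
        mu = mixture$components[[i]]$mean - 1)
    }
    par <- if (length(parents) == 1) rep(parents, b) else
      sample(parents, b, replace = TRUE, prob = mei)
    # uniform placement over valid starts pooled across chromosomes:
    # draw u uniform on (0, total placements], locate the chromosome by the
    # cumulative placement counts and take the remainder as the start
    npl <- vapply(as.list(genome), function(G) pmax(G - L + 1, 0), numeric(b))
    npl <- matrix(npl, nrow = b)
    cum <- npl
    if (ncol(npl) > 1) for (cc in 2:ncol(npl)) cum[, cc] <- cum[, cc - 1] + npl[, cc]
    tot <- cum[, ncol(cum)]
    valid <- tot > 0   # draws longer than every chromosome cannot be placed
    u <- stats::runif(b) * tot
    chr_i <- rowSums(u > cum) + 1L
    off <- cum[cbind(seq_len(b), chr_i)] - npl[cbind(seq_len(b), chr_i)]
    start <- pmin(pmax(ceiling(u - off), 1), npl[cbind(seq_len(b), chr_i)])
    ends <- start + L - 1
    # convert overlapped informative markers with probability p
    conv <- vector("list", b)
    for (pp in unique(par)) {
      for (ch in unique(names(genome)[chr_i[valid & par == pp]])) {
        mk <- markers[[pp]][[ch]]
        if (is.null(mk) || !length(mk)) next
        jj <- which(valid & par == pp & names(genome)[chr_i] == ch)
        lo <- findInterval(start[jj] - 1, mk) + 1L
        hi <- findInterval(ends[jj], mk)
        for (t in which(hi >= lo)) {
          inside <- mk[lo[t]:hi[t]]
          cv <- inside[stats::runif(length(inside)) < penetrance]
          if (length(cv)) conv[[jj[t]]] <- cv
        }
      }
    }
    # honour the stopping rule exactly: keep events up to (and including)
    # the one that fills the tract quota, discard the rest of the batch
    detected <- !vapply(conv, is.null, TRUE)
    if (!is.null(n_tracts)) {
      need <- n_tracts - length(tr_pos)
      cum_det <- cumsum(detected & valid)
      last <- if (max(cum_det) >= need) which(cum_det == need)[1] else b
    } else last <- b
    use <- which(valid & seq_len(b) <= last)
    tid <- rep(NA_character_, b)
    for (j in use[detected[use]]) {
      tr_pos[[length(tr_pos) + 1L]] <- conv[[j]]
      tr_par <- c(tr_par, par[j])
      tr_chr <- c(tr_chr, names(genome)[chr_i[j]])
      tid[j] <- paste0("t", length(tr_pos))
    }
    tot_events <- tot_events + length(use)
    comp_events <- comp_events + tabulate(z[use], n_comp)
    truth[[length(truth) + 1L]] <- data.frame(
      component = z[use], chrom = names(genome)[chr_i[use]],
      start = start[use], length = L[use], tract_id = tid[use],
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (!length(tr_pos))
    stop("no tracts produced")
  tracts <- nco_tracts(paste0("t", seq_along(tr_pos)), tr_par, tr_chr,
                       tr_pos, markers = markers)
  structure(list(
    dataset = nco_dataset(genome, markers, tracts),
    truth = truth, n_events = nrow(truth),
    n_events_component = comp_events,
    mixture = mixture, penetrance = penetrance), class = "nco_sim")
}

#' @export
print.nco_sim <- function(x, ...) {
  cat("Simulated NCO dataset:", x$n_events, "events,",
      nrow(x$dataset$tracts), "tracts (detection fraction",
      sprintf("%.3g)\n", nrow(x$dataset$tracts) / x$n_events))
  invisible(x)
}

#' Simulation grids for the recovery experiments
#'
#' `e1_grid()` returns the 63 single-component configurations crossing
#' component means {100, 300, 1000} bp, seven dispersion levels
#' (`variance = mean^2 * k` with `k` in `c(0.125, 0.25, 0.5, 1, 2, 4, 8)`)
#' and penetrances {0.5, 0.75, 1}, each targeting 1000 tracts.
#' `e2_grid()` pairs the mean-100 and mean-1000 components across the same
#' seven dispersion levels each and three penetrances (147 configurations);
#' both components produce tracts with equal probability (detected-space
#' weights 1/2, realized as a quota of 1000 tracts per component).
#'
#' @param k_grid dispersion grid; `variance = mean^2 * k`.
#' @param penetrances penetrance grid.
#' @param n_tracts tracts per dataset (per component for `e2_grid`).
#' @return A data frame of configurations, one row per parameter
#'   combination.
#' @export
e1_grid <- function(k_grid = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                    penetrances = c(0.5, 0.75, 1), n_tracts = 1000) {
  g <- expand.grid(mean = c(100, 300, 1000), k = k_grid,
                   penetrance = penetrances)
  g$n_tracts <- n_tracts
  g
}

#' @rdname e1_grid
#' @export
e2_grid <- function(k_grid = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                    penetrances = c(0.5, 0.75, 1), n_tracts = 1000) {
  g <- expand.grid(mean1 = 100, k1 = k_grid, mean2 = 1000, k2 = k_grid,
                   penetrance = penetrances)
  g$n_tracts_per_component <- n_tracts
  g
}

#' Simulate one E2-style two-component dataset
#'
#' Draws tracts from the two components separately until each has produced
#' its quota, then merges them, giving the two components exactly equal
#' detected-space weight as in the mixture experiments.
#'
#' @param genome,markers,penetrance,seed as in [nco_simulate()].
#' @param comp1,comp2 [nb_component()] objects.
#' @param n_per_component tract quota per component.
#' @return An `nco_sim` object whose `truth` carries the originating
#'   component of every event.
#' @export
nco_simulate_mixture2 <- function(genome, markers, comp1, comp2, penetrance,
                                  n_per_component = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s1 <- nco_simulate(genome, markers, nco_mixture(list(comp1), alpha = 1),
                     penetrance, n_tracts = n_per_component)
  s2 <- nco_simulate(genome, markers, nco_mixture(list(comp2), alpha = 1),
                     penetrance, n_tracts = n_per_component)
  t1 <- s1$dataset$tracts; t2 <- s2$dataset$tracts
  t2$tract_id <- paste0("c2_", t2$tract_id)
  t1$tract_id <- paste0("c1_", t1$tract_id)
  tracts <- rbind(t1, t2)
  class(tracts) <- c("nco_tracts", "data.frame")
  s2$truth$component <- 2L
  s2$truth$tract_id <- ifelse(is.na(s2$truth$tract_id), NA,
                              paste0("c2_", s2$truth$tract_id))
  s1$truth$tract_id <- ifelse(is.na(s1$truth$tract_id), NA,
                              paste0("c1_", s1$truth$tract_id))
  structure(list(
    dataset = nco_dataset(genome, markers, tracts),
    truth = rbind(s1$truth, s2$truth),
    n_events = s1$n_events + s2$n_events,
    n_events_component = c(s1$n_events, s2$n_events),
    mixture = nco_mixture(list(comp1, comp2),
                          alpha = c(s1$n_events, s2$n_events) /
                            (s1$n_events + s2$n_events)),
    penetrance = penetrance), class = "nco_sim")
}

#' Write a simulated dataset and its ground truth to TSV files
#'
#' @param sim an `nco_sim` object.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$dataset$genome, file.path(dir, "genome.tsv"))
  write_markers(sim$dataset$markers, file.path(dir, "markers.tsv"))
  write_tracts(sim$dataset$tracts, file.path(dir, "tracts.tsv"))
  tr <- sim$truth
  tr$tract_id[is.na(tr$tract_id)] <- "NONE"
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
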
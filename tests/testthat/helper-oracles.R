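# Brute-force oracles and tiny dataset builders shared across the suite.
# The oracles enumerate every placement (and, where needed, every conversion
# outcome) directly from the definitions, independent of the sliding-window
# and cross-correlation implementations they check.

# detection function by enumeration of all placements on one chromosome
naive_detection <- function(pos, G, p, X_max) {
  vapply(seq_len(X_max), function(x) {
    ms <- seq_len(G - x + 1)
    n <- vapply(ms, function(m) sum(pos >= m & pos <= m + x - 1), 0)
    mean(1 - (1 - p)^n)
  }, 0)
}

# tract function by enumeration of all placements covering the tract
naive_tract <- function(s, pos, G, p, X_max) {
  a <- min(s); b <- max(s)
  vapply(seq_len(X_max), function(x) {
    ms <- seq_len(G - x + 1)
    tot <- 0
    for (m in ms) {
      e <- m + x - 1
      if (m > a || e < b) next
      inside <- pos[pos >= m & pos <= e]
      tot <- tot + p^length(s) * (1 - p)^(length(inside) - length(s))
    }
    tot / (G - x + 1)
  }, 0)
}

# all distinct non-empty tracts that any placement of length <= X_max could
# produce on a single-chromosome marker map
enumerate_tracts <- function(pos, X_max) {
  out <- list()
  seen <- character(0)
  K <- length(pos)
  for (i in seq_len(K)) for (j in i:K) {
    if (pos[j] - pos[i] + 1 > X_max) break
    sub <- pos[i:j]
    for (mask in seq_len(2^length(sub)) - 1) {
      pick <- sub[bitwAnd(bitwShiftR(mask, seq_along(sub) - 1), 1) == 1]
      if (!length(pick)) next
      if (min(pick) != pos[i] || max(pick) != pos[j]) next
      key <- paste(pick, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1]] <- pick
      }
    }
  }
  out
}

# single-parent, single-chromosome dataset wrapper
tiny_dataset <- function(G, pos, tract_list, p = NULL) {
  genome <- nco_genome(c(chr1 = G))
  markers <- nco_markers(list(P1 = list(chr1 = pos)), genome = genome)
  tracts <- nco_tracts(paste0("t", seq_along(tract_list)),
                       rep("P1", length(tract_list)),
                       rep("chr1", length(tract_list)),
                       tract_list, markers = markers)
  nco_dataset(genome, markers, tracts)
}

# random small kernel test case
random_tiny_case <- function() {
  G <- sample(60:300, 1)
  K <- sample(1:10, 1)
  pos <- sort(sample.int(G, K))
  p <- sample(c(0.3, 0.5, 1.0), 1)
  X <- sample(5:30, 1)
  list(G = G, pos = pos, p = p, X = X)
}
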
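# Internal machinery for footprint-restricted ("grouped") forward passes.
#
# For a footprint f = f_1..f_k we build a layered model with one group of
# states per footprint entry (group g = states labelled f_g).  Transitions
# run within a group or to the next group only, so any path from group 1 to
# group k makes exactly the k-1 required label changes.  Per-position active
# windows restrict where each group may appear; with windows derived from a
# centre labelling's borders and a radius r this computes border-shift ball
# probabilities.

# Build the layered model; NULL if some footprint label has no states.
.grouped_model <- function(hmm, footprint) {
  k <- length(footprint)
  groups <- lapply(footprint, function(f) which(hmm$labels == f))
  if (any(vapply(groups, length, 1L) == 0L)) return(NULL)
  sizes <- vapply(groups, length, 1L)
  S <- sum(sizes)
  group <- rep(seq_len(k), sizes)
  orig <- unlist(groups)
  Tm <- matrix(0, S, S)
  off <- c(0L, cumsum(sizes))
  for (g in seq_len(k)) {
    ig <- (off[g] + 1L):off[g + 1L]
    Tm[ig, ig] <- hmm$A[groups[[g]], groups[[g]], drop = FALSE]
    if (g < k) {
      jg <- (off[g + 1L] + 1L):off[g + 2L]
      Tm[ig, jg] <- hmm$A[groups[[g]], groups[[g + 1L]], drop = FALSE]
    }
  }
  init <- numeric(S)
  init[group == 1L] <- hmm$A[hmm$start, groups[[1L]]]
  list(k = k, S = S, sizes = sizes, group = group, orig = orig,
       groups = groups, Tm = Tm, Tt = t(Tm), init = init,
       footprint = footprint)
}

# Active windows for a border-shift ball: group g may occupy positions
# max(1, b[g-1] - r) .. min(n, b[g] + r - 1), with b_0 = 1 and b_k = n + 1.
# r = 0 pins the centre labelling; r >= n leaves the windows unconstrained.
.ball_windows <- function(borders, k, n, r) {
  bext <- c(1L, as.integer(borders), n + 1L)
  cbind(lo = pmax(1L, bext[seq_len(k)] - r),
        hi = pmin(n, bext[seq_len(k) + 1L] + r - 1L))
}

.unconstrained_windows <- function(k, n) {
  cbind(lo = rep(1L, k), hi = rep(n, k))
}

# logical S-vector: which stacked states are allowed at position p
.gm_active <- function(gm, windows, p) {
  windows[gm$group, "lo"] <= p & p <= windows[gm$group, "hi"]
}

# Scaled forward pass over the layered model.  Returns total log probability
# of emitting y while respecting groups and windows and ending in group k;
# with keep = TRUE also the scaled column matrix and normalizers needed for
# incremental re-evaluation (local search caching).
.gm_forward <- function(gm, hmm, yidx, windows, keep = FALSE) {
  n <- length(yidx)
  Eo <- hmm$E[gm$orig, yidx, drop = FALSE]
  phi <- if (keep) matrix(0, gm$S, n) else NULL
  logc <- numeric(n)
  v <- gm$init * Eo[, 1L] * .gm_active(gm, windows, 1L)
  for (p in seq_len(n)) {
    if (p > 1L)
      v <- as.vector(gm$Tt %*% v) * Eo[, p] * .gm_active(gm, windows, p)
    s <- sum(v)
    if (s == 0) {
      logc[p:n] <- -Inf
      return(list(log_prob = -Inf, phi = phi, logc = logc, Eo = Eo))
    }
    v <- v / s
    logc[p] <- log(s)
    if (keep) phi[, p] <- v
  }
  tail_mass <- sum(v[gm$group == gm$k])
  lp <- if (tail_mass > 0) sum(logc) + log(tail_mass) else -Inf
  list(log_prob = lp, phi = phi, logc = logc, Eo = Eo)
}

# Scaled backward pass: beta[, p] is (up to scaling) the probability of
# emitting y_p..y_n and finishing in group k, given the chain is in each
# stacked state at position p - 1.  logd holds per-column log scale factors;
# logd[n + 1] = 0.
.gm_backward <- function(gm, hmm, yidx, windows) {
  n <- length(yidx)
  Eo <- hmm$E[gm$orig, yidx, drop = FALSE]
  beta <- matrix(0, gm$S, n + 1L)
  logd <- numeric(n + 1L)
  v <- as.numeric(gm$group == gm$k)
  beta[, n + 1L] <- v
  for (p in rev(seq_len(n))) {
    v <- as.vector(gm$Tm %*% (Eo[, p] * .gm_active(gm, windows, p) * v))
    s <- max(v)
    if (s == 0) {
      logd[seq_len(p)] <- -Inf
      return(list(beta = beta, logd = logd))
    }
    v <- v / s
    beta[, p] <- v
    logd[p] <- log(s)
  }
  list(beta = beta, logd = logd)
}

# Recompute forward columns lo..hi under modified windows, starting from the
# cached scaled column at lo - 1, and close with the cached backward column
# at hi + 1.  Returns the full-ball log probability for the modified windows.
# Assumes the windows differ from the cached ones only at positions lo..hi.
.gm_splice <- function(gm, cache, windows, lo, hi) {
  Eo <- cache$Eo
  n <- ncol(Eo)
  if (lo == 1L) {
    v <- gm$init * Eo[, 1L] * .gm_active(gm, windows, 1L)
    p0 <- 1L
  } else {
    v <- as.vector(gm$Tt %*% cache$phi[, lo - 1L]) * Eo[, lo] *
      .gm_active(gm, windows, lo)
    p0 <- lo
  }
  lsum <- 0
  for (p in p0:hi) {
    if (p > p0)
      v <- as.vector(gm$Tt %*% v) * Eo[, p] * .gm_active(gm, windows, p)
    s <- sum(v)
    if (s == 0) return(-Inf)
    v <- v / s
    lsum <- lsum + log(s)
  }
  dot <- sum(v * cache$beta[, hi + 1L])
  if (dot == 0) return(-Inf)
  cache$prefC[lo] + lsum + log(dot) + cache$sufD[hi + 1L]
}
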
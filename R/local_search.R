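#' Local search over border positions for border-shift balls
#'
#' Steepest-ascent local search for a high-probability border-shift ball
#' centre.  The neighbourhood of a labelling consists of every labelling
#' that matches it in all borders but one, which is shifted by one position
#' left or right.  Each iteration evaluates all valid neighbours, moves to
#' the best one if it improves the ball probability, and stops when no move
#' improves (or after `max_iters` iterations).
#'
#' Neighbour balls are scored incrementally: the forward and backward
#' vectors of the windowed layered model are cached for the current centre,
#' and shifting border `t` by one changes the active windows only at
#' positions `b[t] - r - 1 .. b[t] + r`, so only those forward columns are
#' recomputed and closed with the cached backward column.  After an accepted
#' move the caches are rebuilt from scratch, which also guards the
#' incremental arithmetic.
#'
#' A move is skipped if it would empty a feature or push a border outside
#' `[2, n]`; ties are broken towards the smallest border index, leftward
#' shift before rightward.  Improvements must exceed `eps` on the log scale
#' (relative on probabilities), so accepted moves strictly increase the ball
#' probability.
#'
#' @param hmm an `hmm` object.
#' @param y observation sequence.
#' @param labelling initial centre labelling (length `n`).
#' @param r ball radius (border shift distance).
#' @param max_iters maximum number of accepted moves; `<= 0` returns the
#'   initial labelling unchanged.
#' @param eps minimal log-probability improvement for accepting a move.
#' @param audit if `TRUE`, record every neighbour evaluation of every
#'   iteration in the returned `trace`.
#' @return list with `labelling`, `log_prob`, `prob` (ball probability of
#'   the returned centre), `iterations` (accepted moves), `history`
#'   (log ball probability of the start and of each accepted centre), and
#'   `trace` (if `audit`): one element per iteration holding the iteration's
#'   centre borders and a data frame of neighbour evaluations (`border`,
#'   `delta`, `log_prob` as computed incrementally, `accepted`).
#' @export
local_search <- function(hmm, y, labelling, r, max_iters = 80L,
                         eps = 1e-12, audit = FALSE) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  labelling <- .as_labelling(labelling)
  if (length(labelling) != n)
    stop("labelling length does not match sequence length")
  r <- .check_radius(r)
  f <- footprint_of(labelling)
  b <- as.integer(borders_of(labelling))
  k <- length(f)
  gm <- .grouped_model(hmm, f)
  lp0 <- if (is.null(gm)) -Inf else
    .gm_forward(gm, hmm, yidx, .ball_windows(b, k, n, r))$log_prob
  res <- list(labelling = labelling, log_prob = lp0,
              prob = exp(lp0), iterations = 0L, history = lp0,
              trace = if (audit) list() else NULL)
  if (k == 1L || max_iters <= 0L || is.null(gm)) return(res)

  cur_lp <- lp0
  history <- lp0
  iters <- 0L
  trace <- if (audit) list() else NULL
  repeat {
    cache <- .ls_cache(gm, hmm, yidx, .ball_windows(b, k, n, r))
    best_lp <- -Inf
    best_move <- NULL
    step <- if (audit)
      data.frame(border = integer(0), delta = integer(0),
                 log_prob = numeric(0), accepted = logical(0))
    for (t in seq_len(k - 1L)) {
      for (delta in c(-1L, 1L)) {
        nb <- b
        nb[t] <- b[t] + delta
        lower <- if (t > 1L) b[t - 1L] + 1L else 2L
        upper <- if (t < k - 1L) b[t + 1L] - 1L else n
        if (nb[t] < lower || nb[t] > upper) next
        w2 <- .ball_windows(nb, k, n, r)
        lp <- if (is.null(cache)) {
          .gm_forward(gm, hmm, yidx, w2)$log_prob
        } else {
          lo <- max(1L, b[t] - r - 1L)
          hi <- min(n, b[t] + r)
          .gm_splice(gm, cache, w2, lo, hi)
        }
        if (audit)
          step <- rbind(step, data.frame(border = t, delta = delta,
                                         log_prob = lp, accepted = FALSE))
        if (lp > best_lp) {           # strict > : first in order wins ties
          best_lp <- lp
          best_move <- c(t, delta)
        }
      }
    }
    improved <- is.finite(best_lp) &&
      (best_lp > cur_lp + eps || (cur_lp == -Inf && best_lp > -Inf))
    if (audit) {
      if (improved && nrow(step))
        step$accepted <- step$border == best_move[1] &
          step$delta == best_move[2]
      trace[[length(trace) + 1L]] <- list(borders = b, moves = step)
    }
    if (!improved) break
    b[best_move[1]] <- b[best_move[1]] + best_move[2]
    cur_lp <- .gm_forward(gm, hmm, yidx, .ball_windows(b, k, n, r))$log_prob
    history <- c(history, cur_lp)
    iters <- iters + 1L
    if (iters >= max_iters) break
  }
  lab <- labelling_from_borders(f, b, n)
  list(labelling = lab, log_prob = cur_lp, prob = exp(cur_lp),
       iterations = iters, history = history, trace = trace)
}

# Forward/backward caches for incremental neighbour evaluation; NULL when
# the current centre's ball has probability 0 (fall back to full passes).
.ls_cache <- function(gm, hmm, yidx, windows) {
  fw <- .gm_forward(gm, hmm, yidx, windows, keep = TRUE)
  if (!is.finite(fw$log_prob)) return(NULL)
  bw <- .gm_backward(gm, hmm, yidx, windows)
  n <- length(yidx)
  list(phi = fw$phi, Eo = fw$Eo,
       prefC = c(0, cumsum(fw$logc)),            # prefC[p] = sum logc[1..p-1]
       beta = bw$beta,
       sufD = c(rev(cumsum(rev(bw$logd))), 0))   # sufD[p] = sum logd[p..n+1]
}

#' Multi-start ball decoding
#'
#' Runs [local_search()] from several initial centres and returns the best
#' result.  By default the initial centres are labellings of state paths
#' sampled from the posterior `Pr[x | y]` (forward-filtering
#' backward-sampling), the natural way to seed the search with
#' high-probability footprints.  Deterministic given `seed`.
#'
#' @inheritParams local_search
#' @param n_starts number of restarts when sampling initial centres.
#' @param init `NULL` to sample initial centres from the posterior, or a
#'   list of labellings (a single labelling may be given unwrapped).
#' @param seed optional integer seed.
#' @return the best [local_search()] result, with additional elements
#'   `start` (index of the winning start) and `starts` (per-start log
#'   probabilities).
#' @export
decode_with_restarts <- function(hmm, y, r, n_starts = 10L, init = NULL,
                                 seed = NULL, max_iters = 80L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    X <- sample_path_posterior(hmm, y, n_draws = n_starts)
    if (n_starts == 1L) X <- matrix(X, nrow = 1L)
    inits <- lapply(seq_len(n_starts), function(i) path_labelling(hmm, X[i, ]))
  } else {
    inits <- if (is.list(init)) init else list(init)
  }
  runs <- lapply(inits, function(lab)
    local_search(hmm, y, lab, r, max_iters = max_iters))
  lps <- vapply(runs, function(z) z$log_prob, 1)
  best <- which.max(lps)
  out <- runs[[best]]
  out$start <- best
  out$starts <- lps
  out
}
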
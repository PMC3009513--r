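#' Exact decoding of regular state-path balls
#'
#' Finds the most probable border-shift ball of *state paths* (each state
#' its own label) among centres that are `(2r+1)`-regular: every maximal run
#' of a single state lasts at least `2r + 1` positions.  Such long runs
#' guarantee that all members of the ball agree with the centre's state at
#' any position at least `r` inside a run, which makes an exact dynamic
#' program possible even though the general centre-optimization problem is
#' intractable.
#'
#' The DP maintains `F[j, s]`, the log probability of the best weakly
#' `(2r+1)`-regular ball over positions `1..j` whose centre is in state `s`
#' at position `j` (weak regularity relaxes the final run to length
#' `>= r + 1`, which pins every member to state `s` at position `j`).  A
#' value arises either by extending the final run by one position, or by
#' placing a border at position `j - r`: members may then switch from the
#' previous state `s'` to `s` anywhere in `j - 2r .. j`, and the summed
#' probability of those switch points over the window is the quantity
#' `Q(s, s', j)`.  Placing the border consumes positions `j - 2r .. j`, and
#' combining with `F[j - 2r - 1, s']` (final run `>= r + 1`) makes the
#' completed `s'` run at least `2r + 1` long, so the centre stays regular.
#' Values at `j = n - r` are extended in state `s` through position `n`,
#' which restores strong regularity of the final run, and the best total is
#' traced back to its centre path.
#'
#' `Q` windows are evaluated directly in log space (log-sum-exp over the
#' `2r + 1` switch points) rather than by sliding-window updates, trading a
#' factor `r` of work for numerical robustness.
#'
#' At `r = 0` the recursion is exactly Viterbi's, and the returned centre
#' and probability match the Viterbi path.
#'
#' @param hmm an `hmm` object.
#' @param y observation sequence of length `n >= 2r + 1`.
#' @param r ball radius.
#' @return list with `path` (the centre, `x0..xn`), `log_prob`, `prob` (the
#'   ball probability of the centre), and `runs` (data frame of the centre's
#'   maximal state runs: `state`, `start`, `end`).
#' @export
regular_ball_dp <- function(hmm, y, r) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  r <- .check_radius(r)
  if (n < 2L * r + 1L)
    stop("sequence length ", n, " is shorter than 2r + 1 = ", 2L * r + 1L,
         ": no (2r+1)-regular path exists")
  m <- nrow(hmm$A)
  logA <- log(hmm$A)
  logE <- log(hmm$E)
  # self[s, i] = log(a_ss e_s(y_i)): run-extension factors
  self <- logA[cbind(seq_len(m), seq_len(m))] + logE[, yidx, drop = FALSE]
  jmax <- n - r
  Fmat <- matrix(-Inf, m, jmax)
  # choice: 0 = single-run seed, 1 = extend, s' > 0 stored as -s'
  choice <- matrix(NA_integer_, m, jmax)
  Srun <- matrix(-Inf, m, jmax)            # single-run log probabilities
  Srun[, 1L] <- logA[hmm$start, ] + logE[, yidx[1L]]
  if (jmax > 1L)
    for (j in 2L:jmax) Srun[, j] <- Srun[, j - 1L] + self[, j]

  for (j in seq_len(jmax)) {
    jprev <- j - 2L * r - 1L
    for (s in seq_len(m)) {
      best <- -Inf
      ch <- NA_integer_
      # candidates in predecessor-state order, ties to the lowest index
      for (sp in seq_len(m)) {
        if (sp == s) {
          if (j >= r + 1L && Srun[s, j] > best) {  # single run so far
            best <- Srun[s, j]
            ch <- 0L
          }
          if (j > 1L) {
            ext <- Fmat[s, j - 1L] + self[s, j]
            if (ext > best) {
              best <- ext
              ch <- 1L
            }
          }
        } else if (jprev >= 1L && Fmat[sp, jprev] > -Inf) {
          cand <- Fmat[sp, jprev] + .logQ(s, sp, j, r, logA, logE, yidx)
          if (cand > best) {
            best <- cand
            ch <- -sp
          }
        }
      }
      Fmat[s, j] <- best
      choice[s, j] <- ch
    }
  }
  # extend each state from n - r through n; strong regularity of final run
  ext_tail <- if (r > 0L)
    rowSums(self[, (jmax + 1L):n, drop = FALSE]) else 0
  total <- unname(Fmat[, jmax] + ext_tail)
  s_best <- which.max(total)
  lp <- total[s_best]
  if (!is.finite(lp))
    return(list(path = NULL, log_prob = -Inf, prob = 0, runs = NULL))
  # traceback
  path <- integer(n)
  path[(jmax):n] <- s_best
  j <- jmax
  s <- s_best
  repeat {
    ch <- choice[s, j]
    if (ch == 0L) {                      # single run fills the prefix
      path[seq_len(j)] <- s
      break
    } else if (ch == 1L) {
      path[j] <- s
      j <- j - 1L
    } else {
      sp <- -ch
      path[(j - r):j] <- s
      if (r > 0L) path[(j - 2L * r):(j - r - 1L)] <- sp
      j <- j - 2L * r - 1L
      s <- sp
    }
  }
  path <- c(hmm$start, path)
  rl <- rle(path[-1L])
  runs <- data.frame(state = rl$values,
                     end = cumsum(rl$lengths))
  runs$start <- runs$end - rl$lengths + 1L
  runs <- runs[, c("state", "start", "end")]
  list(path = path, log_prob = lp, prob = exp(lp), runs = runs)
}

# log Q(s, s', j): summed probability that the chain emits y_{j-2r}..y_j
# using only states s' then s with a single forced s' -> s transition whose
# first s-position (the border) lies anywhere in the window j-2r..j,
# conditioned on being in s' at position j - 2r - 1.
.logQ <- function(s, sp, j, r, logA, logE, yidx) {
  w <- (j - 2L * r):j
  sA <- logA[sp, sp] + logE[sp, yidx[w]]     # stay in s' and emit
  sS <- logA[s, s] + logE[s, yidx[w]]        # stay in s and emit
  nw <- length(w)
  pre <- c(0, cumsum(sA[-nw]))               # emissions in s' before border
  post <- rev(c(0, cumsum(rev(sS[-1L]))))    # emissions in s after border
  terms <- pre + logA[sp, s] + logE[s, yidx[w]] + post
  .logsumexp(terms)
}

.logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}
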
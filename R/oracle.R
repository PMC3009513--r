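# Brute-force reference implementations.  These enumerate the full path
# space and are intended for validating the constrained-forward and DP
# algorithms on toy instances; a budget guard refuses anything larger.

.check_budget <- function(m, n, max_total_paths) {
  total <- m^n
  if (total > max_total_paths)
    stop("enumeration refused: m^n = ", format(total),
         " exceeds the budget of ", format(max_total_paths), " paths")
  total
}

#' Enumerate all state paths and their joint probabilities
#'
#' Lists every path `x0, x1, ..., xn` (all `m^n` assignments of emitting
#' states, `x0` fixed at the start state) together with
#' [joint_probability()].  The probabilities sum to `Pr[y]`.
#'
#' @param hmm an `hmm` object.
#' @param y observation sequence.
#' @param max_total_paths refuse enumeration beyond this many paths.
#' @return list with `paths` (`m^n x (n+1)` integer matrix, first column the
#'   start state) and `prob` (numeric vector).
#' @export
enumerate_path_probabilities <- function(hmm, y, max_total_paths = 1e6) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  m <- nrow(hmm$A)
  .check_budget(m, n, max_total_paths)
  grid <- as.matrix(expand.grid(rep(list(seq_len(m)), n),
                                KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  p <- unname(hmm$A[hmm$start, grid[, 1L]]) * hmm$E[cbind(grid[, 1L], yidx[1L])]
  if (n > 1L)
    for (i in 2L:n)
      p <- p * hmm$A[cbind(grid[, i - 1L], grid[, i])] *
        hmm$E[cbind(grid[, i], yidx[i])]
  list(paths = cbind(hmm$start, grid), prob = p)
}

#' Enumerate labellings and their probabilities
#'
#' Groups the enumerated paths by their induced labelling; the resulting
#' probabilities are the exact labelling probabilities, and they sum to
#' `Pr[y]`.
#'
#' @inheritParams enumerate_path_probabilities
#' @return data frame with columns `labelling` (labels joined by `";"`) and
#'   `prob`, restricted to labellings carried by at least one path.
#' @export
enumerate_labelling_probabilities <- function(hmm, y, max_total_paths = 1e6) {
  en <- enumerate_path_probabilities(hmm, y, max_total_paths)
  labs <- matrix(hmm$labels[en$paths[, -1L]], nrow = nrow(en$paths))
  key <- apply(labs, 1L, paste, collapse = ";")
  agg <- tapply(en$prob, key, sum)
  data.frame(labelling = names(agg), prob = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

.split_key <- function(key) strsplit(key, ";", fixed = TRUE)[[1L]]

#' Brute-force ball probability
#'
#' Sums the enumerated labelling probabilities over every labelling the ball
#' contains ([ball_contains()]).  Exact reference for the constrained
#' forward ball algorithms on toy instances.
#'
#' @inheritParams enumerate_path_probabilities
#' @param spec a [ball_spec()].
#' @return the ball probability.
#' @export
brute_ball_probability <- function(hmm, y, spec, max_total_paths = 1e6) {
  tab <- enumerate_labelling_probabilities(hmm, y, max_total_paths)
  if (nrow(tab) == 0L) return(0)
  inside <- vapply(tab$labelling,
                   function(k) ball_contains(spec, .split_key(k)), TRUE)
  sum(tab$prob[inside])
}

# All (2r+1)-regular state paths of length n: compositions of n into runs of
# length >= 2r+1 with distinct adjacent states.  Returns a list of integer
# vectors (emitting positions only).
.regular_paths <- function(m, n, r) {
  minrun <- 2L * r + 1L
  out <- list()
  recurse <- function(prefix, last_state, remaining) {
    if (remaining == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    if (remaining < minrun) return(invisible())
    for (len in minrun:remaining) {
      if (remaining - len != 0L && remaining - len < minrun) next
      for (s in seq_len(m)) {
        if (!is.na(last_state) && s == last_state) next
        recurse(c(prefix, rep(s, len)), s, remaining - len)
      }
    }
    invisible()
  }
  recurse(integer(0), NA_integer_, n)
  out
}

#' Brute-force best regular path ball
#'
#' Enumerates every `(2r+1)`-regular state path, scores the border-shift
#' ball of state paths around each by summing the enumerated joint
#' probabilities of member paths, and returns the maximum.  Exact reference
#' for [regular_ball_dp()] on toy instances.
#'
#' @inheritParams enumerate_path_probabilities
#' @param r ball radius.
#' @return list with `path` (centre `x0..xn`, `NULL` if no regular path
#'   exists), `prob` and `log_prob`.
#' @export
brute_best_regular_ball <- function(hmm, y, r, max_total_paths = 1e6) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  m <- nrow(hmm$A)
  r <- .check_radius(r)
  centres <- .regular_paths(m, n, r)
  if (length(centres) == 0L)
    return(list(path = NULL, prob = 0, log_prob = -Inf))
  en <- enumerate_path_probabilities(hmm, y, max_total_paths)
  emit <- en$paths[, -1L, drop = FALSE]
  # index enumerated paths by footprint of states, with their border vectors
  fps <- character(nrow(emit))
  bset <- vector("list", nrow(emit))
  for (i in seq_len(nrow(emit))) {
    rl <- rle(emit[i, ])
    fps[i] <- paste(rl$values, collapse = ";")
    kk <- length(rl$lengths)
    bset[[i]] <- if (kk > 1L) cumsum(rl$lengths)[-kk] + 1L else integer(0)
  }
  by_fp <- split(seq_len(nrow(emit)), fps)
  best_lp <- -Inf
  best <- NULL
  for (ctr in centres) {
    rl <- rle(ctr)
    key <- paste(rl$values, collapse = ";")
    idx <- by_fp[[key]]
    if (is.null(idx)) next
    kk <- length(rl$lengths)
    cb <- if (kk > 1L) cumsum(rl$lengths)[-kk] + 1L else integer(0)
    member <- vapply(idx, function(i) {
      if (kk == 1L) TRUE else max(abs(bset[[i]] - cb)) <= r
    }, TRUE)
    p <- sum(en$prob[idx[member]])
    if (p > 0 && log(p) > best_lp) {
      best_lp <- log(p)
      best <- ctr
    }
  }
  if (is.null(best)) return(list(path = NULL, prob = 0, log_prob = -Inf))
  list(path = c(hmm$start, best), prob = exp(best_lp), log_prob = best_lp)
}
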
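#' Construct a labelled hidden Markov model
#'
#' A labelled HMM couples an `m`-state Markov chain with per-state emission
#' distributions over a finite alphabet and a labelling function mapping each
#' state to a feature label (several states may share a label).  The start
#' state is silent: a path `x0, x1, ..., xn` emits symbols only from
#' `x1, ..., xn`, symbol `yi` being drawn from the emission row of `xi`.
#'
#' @param transitions numeric `m x m` matrix; row `i` holds the transition
#'   probabilities out of state `i`.  Rows must sum to 1 within `1e-9`; an
#'   all-zero row is tolerated for a designated dead ("dump") state.
#' @param emissions numeric `m x K` matrix of emission probabilities, columns
#'   ordered as `alphabet`.  Same row-sum rule as `transitions`.
#' @param alphabet character vector of emission symbols (single tokens).
#' @param labels character vector of length `m`: the label of each state.
#' @param start_state state index (1-based) or state name of the silent start.
#' @param state_names optional character vector of state identifiers; defaults
#'   to row names of `transitions` or `S1..Sm`.
#'
#' @return An object of class `hmm`: a list with elements `A`, `E`,
#'   `alphabet`, `labels`, `start`, `states`.
#' @export
hmm <- function(transitions, emissions, alphabet, labels, start_state,
                state_names = NULL) {
  A <- as.matrix(transitions)
  E <- as.matrix(emissions)
  m <- nrow(A)
  if (is.null(state_names)) {
    state_names <- rownames(A)
    if (is.null(state_names)) state_names <- paste0("S", seq_len(m))
  }
  dimnames(A) <- list(state_names, state_names)
  dimnames(E) <- list(state_names, alphabet)
  if (is.character(start_state)) {
    start <- match(start_state, state_names)
    if (is.na(start)) stop("unknown start state: ", start_state)
  } else {
    start <- as.integer(start_state)
  }
  obj <- structure(
    list(A = A, E = E, alphabet = as.character(alphabet),
         labels = as.character(labels), start = start, states = state_names),
    class = "hmm")
  validate_hmm(obj)
  obj
}

#' Validate a labelled HMM
#'
#' Checks matrix shapes, stochasticity of rows (tolerance `1e-9`; all-zero
#' rows permitted for dead states), probability bounds and the start index.
#' Errors name the offending state or row.
#'
#' @param x an `hmm` object.
#' @param tol row-sum tolerance.
#' @return `x`, invisibly, if valid.
#' @export
validate_hmm <- function(x, tol = 1e-9) {
  m <- nrow(x$A)
  if (ncol(x$A) != m) stop("transition matrix is not square")
  if (nrow(x$E) != m) stop("emission matrix has ", nrow(x$E),
                           " rows but the model has ", m, " states")
  if (ncol(x$E) != length(x$alphabet))
    stop("emission matrix columns do not match the alphabet")
  if (length(x$labels) != m) stop("labels must have one entry per state")
  if (anyNA(x$A) || anyNA(x$E)) stop("probabilities must not be NA")
  if (any(x$A < 0) || any(x$A > 1) || any(x$E < 0) || any(x$E > 1))
    stop("all probabilities must lie in [0, 1]")
  rsA <- rowSums(x$A)
  bad <- which(abs(rsA - 1) > tol & rsA != 0)
  if (length(bad))
    stop("transition row for state '", x$states[bad[1]],
         "' sums to ", format(rsA[bad[1]]), ", not 1")
  rsE <- rowSums(x$E)
  bad <- which(abs(rsE - 1) > tol & rsE != 0)
  if (length(bad))
    stop("emission row for state '", x$states[bad[1]],
         "' sums to ", format(rsE[bad[1]]), ", not 1")
  if (is.na(x$start) || x$start < 1 || x$start > m)
    stop("start state index out of range")
  invisible(x)
}

#' @export
print.hmm <- function(x, ...) {
  cat("Labelled HMM:", nrow(x$A), "states,",
      length(unique(x$labels)), "labels, alphabet {",
      paste(x$alphabet, collapse = ", "), "}\n")
  cat("start state:", x$states[x$start], "\n")
  invisible(x)
}

# Map a character observation sequence to 1-based alphabet indices.
.encode_obs <- function(hmm, y) {
  if (length(y) == 1L && nchar(y[1]) > 1L) y <- strsplit(y, "")[[1]]
  idx <- match(y, hmm$alphabet)
  if (anyNA(idx))
    stop("symbol(s) not in the model alphabet: ",
         paste(unique(y[is.na(idx)]), collapse = ", "))
  if (length(idx) < 1L) stop("observation sequence must be non-empty")
  idx
}

# m x n matrix of emission probabilities for each state at each position.
.emis_matrix <- function(hmm, yidx) hmm$E[, yidx, drop = FALSE]

#' Joint probability of a state path and a sequence
#'
#' Computes `prod_i a[x(i-1), x(i)] * e[x(i), y(i)]` for a path
#' `x0, x1, ..., xn` and sequence `y1, ..., yn`; the silent start `x0` emits
#' nothing.  Returns 0 if any factor is 0.
#'
#' @param hmm an `hmm` object.
#' @param y observation sequence: character vector of symbols or a single
#'   string.
#' @param path integer vector of state indices of length `n + 1`, starting
#'   with the model's start state.
#' @return the joint probability, a single numeric.
#' @export
joint_probability <- function(hmm, y, path) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  path <- as.integer(path)
  if (length(path) != n + 1L)
    stop("path has length ", length(path), " but a sequence of length ", n,
         " requires length ", n + 1L)
  if (path[1] != hmm$start)
    stop("path must begin at the start state")
  from <- path[-(n + 1L)]
  to <- path[-1L]
  prod(hmm$A[cbind(from, to)] * hmm$E[cbind(to, yidx)])
}

#' Forward algorithm with per-column scaling
#'
#' Computes scaled forward vectors `phi_i(k) = Pr[y1..yi, xi = k]` (each
#' column rescaled to sum to 1) together with the per-column log normalizers,
#' so that `Pr[y] = exp(sum(logc))`.
#'
#' @inheritParams joint_probability
#' @return An object of class `hmm_forward`: list with `phi` (`m x n` scaled
#'   matrix), `logc` (length-`n` log normalizers), `log_prob`, `prob`.
#' @export
forward <- function(hmm, y) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  m <- nrow(hmm$A)
  Eo <- .emis_matrix(hmm, yidx)
  phi <- matrix(0, m, n)
  logc <- numeric(n)
  v <- hmm$A[hmm$start, ] * Eo[, 1]
  for (i in seq_len(n)) {
    if (i > 1L) v <- as.vector(crossprod(hmm$A, v)) * Eo[, i]
    s <- sum(v)
    if (s == 0) {
      # impossible event: zero out the tail and stop
      logc[i:n] <- -Inf
      phi[, i:n] <- 0
      return(structure(list(phi = phi, logc = logc, log_prob = -Inf, prob = 0),
                       class = "hmm_forward"))
    }
    v <- v / s
    phi[, i] <- v
    logc[i] <- log(s)
  }
  lp <- sum(logc)
  structure(list(phi = phi, logc = logc, log_prob = lp, prob = exp(lp)),
            class = "hmm_forward")
}

#' Backward algorithm with per-column scaling
#'
#' Computes scaled backward vectors `beta_i(k) = Pr[yi..yn | x(i-1) = k]`
#' for `i = 1..n+1` (`beta_{n+1} = 1`), each column rescaled, with per-column
#' log normalizers `logd`.  For any position `i`,
#' `log Pr[y] = sum(logc[1:i]) + log(phi_i . beta_{i+1}) + sum(logd[(i+1):(n+1)])`.
#'
#' @inheritParams joint_probability
#' @return An object of class `hmm_backward`: list with `beta`
#'   (`m x (n+1)` scaled matrix) and `logd` (length `n + 1`).
#' @export
backward <- function(hmm, y) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  m <- nrow(hmm$A)
  Eo <- .emis_matrix(hmm, yidx)
  beta <- matrix(0, m, n + 1L)
  logd <- numeric(n + 1L)
  v <- rep(1, m)
  beta[, n + 1L] <- v
  for (i in rev(seq_len(n))) {
    v <- as.vector(hmm$A %*% (Eo[, i] * v))
    s <- max(v)
    if (s == 0) {
      logd[seq_len(i)] <- -Inf
      beta[, seq_len(i)] <- 0
      return(structure(list(beta = beta, logd = logd), class = "hmm_backward"))
    }
    v <- v / s
    beta[, i] <- v
    logd[i] <- log(s)
  }
  structure(list(beta = beta, logd = logd), class = "hmm_backward")
}

#' Viterbi decoding
#'
#' Returns the state path maximizing the joint probability with the sequence.
#' Ties at any argmax are broken towards the lowest state index.
#'
#' @inheritParams joint_probability
#' @return list with `path` (integer vector `x0..xn`), `log_prob`, `prob`.
#' @export
viterbi <- function(hmm, y) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  m <- nrow(hmm$A)
  logA <- log(hmm$A)
  logE <- log(hmm$E)
  V <- matrix(-Inf, m, n)
  ptr <- matrix(NA_integer_, m, n)
  V[, 1] <- logA[hmm$start, ] + logE[, yidx[1]]
  for (i in seq_len(n)[-1]) {
    for (k in seq_len(m)) {
      cand <- V[, i - 1L] + logA[, k]
      j <- which.max(cand)            # first max = lowest index
      ptr[k, i] <- j
      V[k, i] <- cand[j] + logE[k, yidx[i]]
    }
  }
  path <- integer(n + 1L)
  path[1] <- hmm$start
  path[n + 1L] <- which.max(V[, n])
  if (n > 1L)
    for (i in rev(seq_len(n)[-1])) path[i] <- ptr[path[i + 1L], i]
  lp <- V[path[n + 1L], n]
  list(path = path, log_prob = lp, prob = exp(lp))
}

#' Posterior state probabilities
#'
#' For each emitting position `i = 1..n`, the conditional distribution of the
#' state `xi` given the whole sequence:
#' `Pr[xi = k | y] = phi_i(k) * beta_{i+1}(k) / Pr[y]`.
#'
#' @inheritParams joint_probability
#' @return an `m x n` matrix whose columns sum to 1.
#' @export
posterior_state_probs <- function(hmm, y) {
  fw <- forward(hmm, y)
  if (fw$prob == 0 && is.infinite(fw$log_prob))
    stop("sequence has probability 0 under the model")
  bw <- backward(hmm, y)
  n <- ncol(fw$phi)
  P <- fw$phi * bw$beta[, -1L, drop = FALSE]
  P / rep(colSums(P), each = nrow(P))
}

#' Sample state paths from the posterior
#'
#' Forward-filtering backward-sampling: draws state paths from the
#' conditional distribution `Pr[x | y]`.  Deterministic given `seed`.
#'
#' @inheritParams joint_probability
#' @param n_draws number of independent paths to draw.
#' @param seed optional integer seed (set via [set.seed()]).
#' @return if `n_draws == 1`, an integer path `x0..xn`; otherwise an
#'   `n_draws x (n+1)` integer matrix, one path per row.
#' @export
sample_path_posterior <- function(hmm, y, n_draws = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fw <- forward(hmm, y)
  if (is.infinite(fw$log_prob))
    stop("cannot sample: the sequence has probability 0 under the model")
  n <- ncol(fw$phi)
  m <- nrow(fw$phi)
  X <- matrix(NA_integer_, n_draws, n + 1L)
  X[, 1] <- hmm$start
  X[, n + 1L] <- sample.int(m, n_draws, replace = TRUE, prob = fw$phi[, n])
  if (n > 1L) {
    for (i in rev(seq_len(n - 1L))) {
      nxt <- X[, i + 2L]
      for (v in unique(nxt)) {
        rows <- which(nxt == v)
        w <- fw$phi[, i] * hmm$A[, v]
        if (sum(w) == 0) stop("posterior sampling reached an impossible state")
        X[rows, i + 1L] <- sample.int(m, length(rows), replace = TRUE, prob = w)
      }
    }
  }
  if (n_draws == 1L) X[1, ] else X
}

#' Labelling induced by a state path
#'
#' Maps each emitting state of a path through the model's label function,
#' yielding the per-position labelling `l(x1), ..., l(xn)` (the silent start
#' position is dropped).
#'
#' @param hmm an `hmm` object.
#' @param path integer state path `x0..xn`.
#' @return character vector of length `n`.
#' @export
path_labelling <- function(hmm, path) {
  hmm$labels[path[-1L]]
}
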
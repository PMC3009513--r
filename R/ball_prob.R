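#' Probability of a labelling
#'
#' Sum of the joint probabilities of all state paths whose labelling equals
#' the given one: a forward pass in which position `i` is restricted to
#' states carrying label `lambda_i` (so only transitions between states
#' labelled `lambda_{i-1}` and `lambda_i` survive).  An infeasible labelling
#' has probability 0.
#'
#' @param hmm an `hmm` object.
#' @param y observation sequence (character vector or single string).
#' @param labelling per-position labels, length `n` (or a string of
#'   single-character labels).
#' @param log return the natural log probability instead.
#' @return probability (or log probability).
#' @export
labelling_probability <- function(hmm, y, labelling, log = FALSE) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  labelling <- .as_labelling(labelling)
  if (length(labelling) != n)
    stop("labelling length ", length(labelling),
         " does not match sequence length ", n)
  Eo <- .emis_matrix(hmm, yidx)
  logc <- 0
  v <- hmm$A[hmm$start, ] * Eo[, 1L] * (hmm$labels == labelling[1L])
  for (i in seq_len(n)) {
    if (i > 1L)
      v <- as.vector(crossprod(hmm$A, v)) * Eo[, i] *
        (hmm$labels == labelling[i])
    s <- sum(v)
    if (s == 0) return(if (log) -Inf else 0)
    v <- v / s
    logc <- logc + log(s)
  }
  if (log) logc else exp(logc)
}

#' Probability of a footprint
#'
#' Sum of [labelling_probability()] over every labelling whose footprint is
#' `footprint`: a forward pass over the layered model with one group of
#' states per footprint entry, transitions allowed only within a group or to
#' the next group, entry in group 1 and exit from group `k`.
#'
#' @inheritParams labelling_probability
#' @param footprint character vector of feature labels, no two consecutive
#'   equal.
#' @return probability (or log probability).
#' @export
footprint_probability <- function(hmm, y, footprint, log = FALSE) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  footprint <- .as_labelling(footprint)
  if (any(footprint[-1L] == footprint[-length(footprint)]))
    stop("a footprint cannot repeat a label consecutively")
  if (length(footprint) > n) return(if (log) -Inf else 0)
  gm <- .grouped_model(hmm, footprint)
  if (is.null(gm)) return(if (log) -Inf else 0)
  lp <- .gm_forward(gm, hmm, yidx, .unconstrained_windows(gm$k, n))$log_prob
  if (log) lp else exp(lp)
}

#' Probability of a border-shift ball
#'
#' Sum of [labelling_probability()] over all labellings within border shift
#' distance `r` of the centre: the layered footprint model with group `g`
#' active only on positions `b[g-1] - r .. b[g] + r - 1` (clamped to
#' `1..n`), where `b` are the centre's borders.  At `r = 0` this equals the
#' centre's labelling probability; for `r >= n` it equals the footprint
#' probability.
#'
#' @inheritParams labelling_probability
#' @param r non-negative integer radius.
#' @return probability (or log probability).
#' @export
ball_prob_border_shift <- function(hmm, y, labelling, r, log = FALSE) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  labelling <- .as_labelling(labelling)
  if (length(labelling) != n)
    stop("labelling length does not match sequence length")
  r <- .check_radius(r)
  f <- footprint_of(labelling)
  gm <- .grouped_model(hmm, f)
  if (is.null(gm)) return(if (log) -Inf else 0)
  w <- .ball_windows(borders_of(labelling), gm$k, n, r)
  lp <- .gm_forward(gm, hmm, yidx, w)$log_prob
  if (log) lp else exp(lp)
}

.check_radius <- function(r) {
  r <- as.integer(r)
  if (is.na(r) || r < 0L) stop("radius must be a non-negative integer")
  r
}

#' Probability of a border-shift-sum ball
#'
#' Sum of [labelling_probability()] over all labellings whose total border
#' displacement from the centre is at most `r`.  The layered model gains a
#' budget coordinate `d` in `0..r`: moving from group `g` to `g + 1` at
#' position `p` places border `g` at `p` and costs `|p - b[g]|` budget;
#' transitions that would exceed `r` are dropped.  At `r = 0` this is the
#' centre's labelling probability, and the result never exceeds the
#' border-shift ball of equal radius.
#'
#' @inheritParams ball_prob_border_shift
#' @return probability (or log probability).
#' @export
ball_prob_border_shift_sum <- function(hmm, y, labelling, r, log = FALSE) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  labelling <- .as_labelling(labelling)
  if (length(labelling) != n)
    stop("labelling length does not match sequence length")
  r <- .check_radius(r)
  f <- footprint_of(labelling)
  gm <- .grouped_model(hmm, f)
  if (is.null(gm)) return(if (log) -Inf else 0)
  b <- borders_of(labelling)
  w <- .ball_windows(b, gm$k, n, r)
  Eo <- hmm$E[gm$orig, yidx, drop = FALSE]
  k <- gm$k
  off <- c(0L, cumsum(gm$sizes))
  grp_idx <- lapply(seq_len(k), function(g) (off[g] + 1L):off[g + 1L])
  # within-group transition blocks, transposed once
  Wt <- lapply(seq_len(k), function(g)
    t(hmm$A[gm$groups[[g]], gm$groups[[g]], drop = FALSE]))
  Ct <- if (k > 1L)
    lapply(seq_len(k - 1L), function(g)
      t(hmm$A[gm$groups[[g]], gm$groups[[g + 1L]], drop = FALSE]))
  Phi <- matrix(0, gm$S, r + 1L)          # column d+1 holds budget d
  act1 <- .gm_active(gm, w, 1L)
  Phi[grp_idx[[1L]], 1L] <- hmm$A[hmm$start, gm$groups[[1L]]]
  Phi[, 1L] <- Phi[, 1L] * Eo[, 1L] * act1
  tot <- sum(Phi)
  if (tot == 0) return(if (log) -Inf else 0)
  Phi <- Phi / tot
  logc <- log(tot)
  for (p in seq_len(n)[-1L]) {
    act <- .gm_active(gm, w, p)
    New <- matrix(0, gm$S, r + 1L)
    for (g in seq_len(k)) {
      ig <- grp_idx[[g]]
      New[ig, ] <- Wt[[g]] %*% Phi[ig, , drop = FALSE]
      if (g > 1L) {
        cost <- abs(p - b[g - 1L])
        if (cost <= r) {
          src <- 1L:(r + 1L - cost)
          New[ig, src + cost] <- New[ig, src + cost] +
            Ct[[g - 1L]] %*% Phi[grp_idx[[g - 1L]], src, drop = FALSE]
        }
      }
    }
    New <- New * Eo[, p] * act
    tot <- sum(New)
    if (tot == 0) return(if (log) -Inf else 0)
    Phi <- New / tot
    logc <- logc + log(tot)
  }
  tail_mass <- sum(Phi[gm$group == k, ])
  lp <- if (tail_mass > 0) logc + log(tail_mass) else -Inf
  if (log) lp else exp(lp)
}

#' Probability of a generalized-Hamming ball
#'
#' Sum of [labelling_probability()] over all labellings within generalized
#' Hamming distance `r` of the centre under penalty matrix `H`.  The forward
#' pass runs on a product automaton with states `(state, d)`, `d` in `0..r`
#' the distance accumulated so far: entering state `s` at position `i` costs
#' `H[centre_i, label(s)]`, and transitions that would push `d` past `r` are
#' dropped.  With `H` identically zero this equals `Pr[y]` for any radius.
#'
#' @inheritParams ball_prob_border_shift
#' @param H square non-negative integer penalty matrix with label dimnames;
#'   `H[i, j]` is the cost of labelling with `j` a position the centre
#'   labels `i`.
#' @return probability (or log probability).
#' @export
ball_prob_generalized_hamming <- function(hmm, y, labelling, r, H,
                                          log = FALSE) {
  yidx <- .encode_obs(hmm, y)
  n <- length(yidx)
  labelling <- .as_labelling(labelling)
  if (length(labelling) != n)
    stop("labelling length does not match sequence length")
  r <- .check_radius(r)
  .check_H(H, unique(c(labelling, hmm$labels)))
  if (any(H != round(H))) stop("H entries must be integers")
  m <- nrow(hmm$A)
  Eo <- .emis_matrix(hmm, yidx)
  D <- matrix(0, m, r + 1L)
  logc <- 0
  for (i in seq_len(n)) {
    M1 <- if (i == 1L) {
      cbind(hmm$A[hmm$start, ], matrix(0, m, r))
    } else {
      crossprod(hmm$A, D)
    }
    h <- H[cbind(labelling[i], hmm$labels)]
    New <- matrix(0, m, r + 1L)
    for (hv in unique(h)) {
      rows <- which(h == hv)
      if (hv <= r)
        New[rows, (hv + 1L):(r + 1L)] <- M1[rows, 1L:(r + 1L - hv), drop = FALSE]
    }
    New <- New * Eo[, i]
    tot <- sum(New)
    if (tot == 0) return(if (log) -Inf else 0)
    D <- New / tot
    logc <- logc + log(tot)
  }
  if (log) logc else exp(logc)
}

#' Ball probability for a [ball_spec()]
#'
#' Dispatches to the metric-specific constrained forward pass.
#'
#' @inheritParams labelling_probability
#' @param spec a [ball_spec()].
#' @return probability (or log probability).
#' @export
ball_probability <- function(hmm, y, spec, log = FALSE) {
  switch(spec$metric,
    border_shift =
      ball_prob_border_shift(hmm, y, spec$centre, spec$radius, log = log),
    border_shift_sum =
      ball_prob_border_shift_sum(hmm, y, spec$centre, spec$radius, log = log),
    generalized_hamming =
      ball_prob_generalized_hamming(hmm, y, spec$centre, spec$radius,
                                    spec$H, log = log))
}

#' Border-shift ball probability of a state path
#'
#' Treats every state as its own label (the "paths, not labellings" view)
#' and computes the border-shift ball probability of the path's induced
#' labelling.  Used to score centres of regular path balls.
#'
#' @param hmm an `hmm` object.
#' @param y observation sequence.
#' @param path integer state path `x0..xn`.
#' @param r ball radius.
#' @param log return log probability.
#' @return probability (or log probability).
#' @export
path_ball_probability <- function(hmm, y, path, r, log = FALSE) {
  h2 <- .identity_label_hmm(hmm)
  ball_prob_border_shift(h2, y, h2$labels[path[-1L]], r, log = log)
}

# each state its own label
.identity_label_hmm <- function(hmm) {
  hmm$labels <- hmm$states
  hmm
}
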
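#' Seeded random HMM
#'
#' Draws transition and emission rows from flat Dirichlet distributions and
#' assigns labels so that every label class is non-empty.  State 1 is the
#' (silent) start state.  Deterministic given `seed`.
#'
#' @param m number of states.
#' @param alphabet_size number of emission symbols (named `a`, `b`, ...).
#' @param num_labels number of label classes (named `A`, `B`, ...);
#'   must not exceed `m`.
#' @param seed optional integer seed.
#' @return an `hmm` object.
#' @export
random_hmm <- function(m, alphabet_size = 2L, num_labels = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (num_labels > m) stop("cannot use more labels than states")
  A <- matrix(stats::rgamma(m * m, 1), m, m)
  A <- A / rowSums(A)
  E <- matrix(stats::rgamma(m * alphabet_size, 1), m, alphabet_size)
  E <- E / rowSums(E)
  alphabet <- letters[seq_len(alphabet_size)]
  lab_pool <- LETTERS[seq_len(num_labels)]
  labels <- c(lab_pool,
              if (m > num_labels)
                sample(lab_pool, m - num_labels, replace = TRUE))
  labels <- sample(labels)              # shuffle which states get which label
  hmm(A, E, alphabet, labels, start_state = 1L)
}

#' Toy membrane-topology HMM
#'
#' A small labelled HMM emulating the structure of alpha-helical
#' transmembrane topology models: cytoplasmic (`i`) and non-cytoplasmic
#' (`o`) loops alternate, separated by membrane (`M`) helices.  The membrane
#' label is realised by two directed chains of `min_membrane_run` states
#' (inside-to-out and out-to-in) ending in a self-looping state, so every
#' membrane run lasts at least `min_membrane_run` positions, with mean run
#' length `mean_membrane_run`; the chain direction enforces the alternation
#' of the two loop sides.  Loop states self-loop with mean run length
#' `mean_loop_run`.
#'
#' Emissions use a reduced 4-letter residue alphabet — `h` hydrophobic,
#' `p` polar, `c` positively charged, `a` other — with a hydrophobic-rich
#' membrane distribution and a positively-charged bias in the cytoplasmic
#' loop (the positive-inside rule), which is what makes the topology
#' recoverable from the sequence.
#'
#' @param min_membrane_run minimum membrane run length (structural).
#' @param mean_membrane_run mean membrane run length; must exceed
#'   `min_membrane_run - 1`.
#' @param mean_loop_run mean loop run length.
#' @return an `hmm` object with labels `i`, `M`, `o`.
#' @export
toy_topology_hmm <- function(min_membrane_run = 15L, mean_membrane_run = 21,
                             mean_loop_run = 15) {
  L <- as.integer(min_membrane_run)
  extra <- mean_membrane_run - L       # mean of the geometric tail
  if (extra < 0) stop("mean_membrane_run must be at least min_membrane_run")
  p_stay <- extra / (extra + 1)
  p_loop <- 1 - 1 / mean_loop_run
  states <- c("begin", "in", "out",
              paste0("mio", seq_len(L)), paste0("moi", seq_len(L)))
  m <- length(states)
  labels <- c("i", "i", "o", rep("M", 2L * L))
  A <- matrix(0, m, m, dimnames = list(states, states))
  A["begin", "in"] <- 0.5
  A["begin", "out"] <- 0.5
  A["in", "in"] <- p_loop
  A["in", "mio1"] <- 1 - p_loop
  A["out", "out"] <- p_loop
  A["out", "moi1"] <- 1 - p_loop
  for (j in seq_len(L - 1L)) {
    A[paste0("mio", j), paste0("mio", j + 1L)] <- 1
    A[paste0("moi", j), paste0("moi", j + 1L)] <- 1
  }
  A[paste0("mio", L), paste0("mio", L)] <- p_stay
  A[paste0("mio", L), "out"] <- 1 - p_stay
  A[paste0("moi", L), paste0("moi", L)] <- p_stay
  A[paste0("moi", L), "in"] <- 1 - p_stay
  alphabet <- c("h", "p", "c", "a")
  e_mem <- c(h = 0.70, p = 0.08, c = 0.02, a = 0.20)
  e_in <- c(h = 0.20, p = 0.35, c = 0.25, a = 0.20)
  e_out <- c(h = 0.25, p = 0.40, c = 0.05, a = 0.30)
  E <- rbind(rep(0.25, 4),              # begin is silent; row unused
             e_in, e_out,
             matrix(e_mem, 2L * L, 4L, byrow = TRUE))
  hmm(A, E, alphabet, labels, start_state = "begin", state_names = states)
}

#' Simulate sequences and true labellings from a model
#'
#' Runs the generative process of the HMM: sample a state path of the
#' requested length from the start state, emitting one symbol per step.
#' Deterministic given `seed`.
#'
#' @param hmm an `hmm` object.
#' @param n_seqs number of sequences.
#' @param length_range inclusive range of sequence lengths, sampled
#'   uniformly.
#' @param seed optional integer seed.
#' @return an object of class `hmm_dataset`: a list of records, each with
#'   `id`, `y` (character vector), `labelling`, `path`.
#' @export
simulate_dataset <- function(hmm, n_seqs, length_range = c(80L, 160L),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(hmm$A)
  K <- length(hmm$alphabet)
  lo <- as.integer(length_range[1])
  hi <- as.integer(length_range[length(length_range)])
  recs <- lapply(seq_len(n_seqs), function(idx) {
    n <- if (hi > lo) sample(lo:hi, 1L) else lo
    path <- integer(n + 1L)
    y <- character(n)
    path[1L] <- hmm$start
    for (i in seq_len(n)) {
      path[i + 1L] <- sample.int(m, 1L, prob = hmm$A[path[i], ])
      y[i] <- hmm$alphabet[sample.int(K, 1L, prob = hmm$E[path[i + 1L], ])]
    }
    list(id = sprintf("seq%03d", idx), y = y,
         labelling = hmm$labels[path[-1L]], path = path)
  })
  structure(recs, class = "hmm_dataset")
}

#' @export
print.hmm_dataset <- function(x, ...) {
  cat("Simulated dataset:", length(x), "sequences, lengths",
      paste(range(vapply(x, function(r) length(r$y), 1L)), collapse = "-"),
      "\n")
  invisible(x)
}

#' Topology prediction correctness
#'
#' Two per-sequence correctness measures for segment-structured labellings:
#'
#' * `"overlap"`: correct iff the footprints are equal and each predicted
#'   segment carrying `segment_label` overlaps its true counterpart in at
#'   least `min_overlap` positions (the criterion transmembrane predictors
#'   use, applied to membrane segments only; loop borders are unconstrained
#'   beyond footprint equality).
#' * `"tau"`: correct iff the border shift distance to the truth is at most
#'   `tau` — a stricter notion, since every border of every feature must be
#'   nearly right.
#'
#' @param truth,pred labellings of equal length.
#' @param measure `"overlap"` or `"tau"`.
#' @param tau border shift tolerance for the `"tau"` measure.
#' @param segment_label label whose segments the overlap criterion applies
#'   to.
#' @param min_overlap minimum per-segment overlap for the `"overlap"`
#'   measure.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_prediction <- function(truth, pred, measure = c("overlap", "tau"),
                                tau = 5L, segment_label = "M",
                                min_overlap = 5L) {
  measure <- match.arg(measure)
  truth <- .as_labelling(truth)
  pred <- .as_labelling(pred)
  .check_same_length(truth, pred)
  if (measure == "tau")
    return(border_shift_distance(truth, pred) <= tau)
  if (!identical(footprint_of(truth), footprint_of(pred))) return(FALSE)
  ts <- .segments(truth, segment_label)
  ps <- .segments(pred, segment_label)
  if (nrow(ts) == 0L) return(TRUE)
  all(pmin(ts$end, ps$end) - pmax(ts$start, ps$start) + 1L >= min_overlap)
}

.segments <- function(labelling, label) {
  rl <- rle(labelling)
  end <- cumsum(rl$lengths)
  start <- end - rl$lengths + 1L
  keep <- rl$values == label
  data.frame(start = start[keep], end = end[keep])
}

#' Aggregate accuracy of predictions over a dataset
#'
#' @param dataset an `hmm_dataset` (provides the true labellings).
#' @param predictions list of predicted labellings, parallel to `dataset`.
#' @inheritParams evaluate_prediction
#' @return fraction of sequences judged correct.
#' @export
topology_accuracy <- function(dataset, predictions,
                              measure = c("overlap", "tau"), tau = 5L,
                              segment_label = "M", min_overlap = 5L) {
  measure <- match.arg(measure)
  stopifnot(length(dataset) == length(predictions))
  ok <- mapply(function(rec, pred)
    evaluate_prediction(rec$labelling, pred, measure = measure, tau = tau,
                        segment_label = segment_label,
                        min_overlap = min_overlap),
    dataset, predictions)
  mean(ok)
}
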
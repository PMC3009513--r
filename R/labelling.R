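#' Labellings, footprints and borders
#'
#' A labelling assigns a feature label to each emitting position `1..n` of a
#' sequence.  It is represented as a plain character vector of length `n`;
#' the silent start position carries the start state's label and is excluded
#' from footprints, borders and all distances.
#'
#' The footprint is the run-length compression of the labelling: the ordered
#' sequence of distinct consecutive labels, with boundary positions
#' discarded.
#'
#' @param labelling character vector of per-position labels (or one string of
#'   single-character labels).
#' @return `footprint_of`: character vector of feature labels (no two
#'   consecutive entries equal).
#' @export
footprint_of <- function(labelling) {
  labelling <- .as_labelling(labelling)
  rle(labelling)$values
}

#' @rdname footprint_of
#' @return `borders_of`: integer vector of border positions; the `i`-th entry
#'   is the 1-based position of the first emission carrying footprint label
#'   `i + 1`.  Empty for a single-feature labelling.
#' @export
borders_of <- function(labelling) {
  labelling <- .as_labelling(labelling)
  len <- rle(labelling)$lengths
  k <- length(len)
  if (k == 1L) return(integer(0))
  cumsum(len)[-k] + 1L
}

.as_labelling <- function(labelling) {
  if (length(labelling) == 1L && nchar(labelling[1]) > 1L)
    labelling <- strsplit(labelling, "")[[1]]
  as.character(labelling)
}

#' Rebuild a labelling from its footprint and borders
#'
#' Inverse of ([footprint_of()], [borders_of()]) for a given length.
#'
#' @param footprint character vector of feature labels.
#' @param borders strictly increasing integer border positions
#'   (length `length(footprint) - 1`).
#' @param n sequence length.
#' @return character labelling of length `n`.
#' @export
labelling_from_borders <- function(footprint, borders, n) {
  k <- length(footprint)
  if (length(borders) != k - 1L)
    stop("need exactly one border fewer than footprint entries")
  bounds <- c(1L, as.integer(borders), n + 1L)
  if (any(diff(bounds) < 1L))
    stop("borders must be strictly increasing within [2, n]")
  rep(footprint, times = diff(bounds))
}

.check_same_length <- function(a, b) {
  if (length(a) != length(b))
    stop("labellings compare only at equal length (", length(a),
         " vs ", length(b), ")")
}

#' Border shift distance
#'
#' For two labellings of the same sequence sharing a footprint, the maximum
#' absolute difference between corresponding border positions; `Inf` when the
#' footprints differ (incompatible labellings).
#'
#' @param a,b labellings (character vectors of equal length, or strings).
#' @return non-negative integer distance, or `Inf`.
#' @export
border_shift_distance <- function(a, b) {
  a <- .as_labelling(a); b <- .as_labelling(b)
  .check_same_length(a, b)
  if (!identical(footprint_of(a), footprint_of(b))) return(Inf)
  ba <- borders_of(a); bb <- borders_of(b)
  if (length(ba) == 0L) return(0L)
  max(abs(ba - bb))
}

#' Border shift sum distance
#'
#' The sum of absolute border displacements between two labellings sharing a
#' footprint; `Inf` when the footprints differ.  Always at least the border
#' shift distance.
#'
#' @inheritParams border_shift_distance
#' @return non-negative integer distance, or `Inf`.
#' @export
border_shift_sum_distance <- function(a, b) {
  a <- .as_labelling(a); b <- .as_labelling(b)
  .check_same_length(a, b)
  if (!identical(footprint_of(a), footprint_of(b))) return(Inf)
  ba <- borders_of(a); bb <- borders_of(b)
  if (length(ba) == 0L) return(0L)
  sum(abs(ba - bb))
}

#' Generalized Hamming distance
#'
#' Position-wise sum of label-pair penalties `H[a_i, b_i]` over emitting
#' positions, for a non-negative integer penalty matrix `H` indexed by label
#' names.  With the 0/1 matrix (zero diagonal) this is the plain Hamming
#' distance between the labellings.
#'
#' @inheritParams border_shift_distance
#' @param H square non-negative numeric matrix with row and column names
#'   covering all labels in `a` and `b`; `H[i, j]` is the penalty for the
#'   reference label `i` facing label `j`.
#' @return non-negative numeric distance.
#' @export
generalized_hamming_distance <- function(a, b, H) {
  a <- .as_labelling(a); b <- .as_labelling(b)
  .check_same_length(a, b)
  .check_H(H, unique(c(a, b)))
  sum(H[cbind(a, b)])
}

.check_H <- function(H, labels = NULL) {
  if (!is.matrix(H) || nrow(H) != ncol(H))
    stop("H must be a square matrix")
  if (is.null(rownames(H)) || is.null(colnames(H)))
    stop("H must have label names on rows and columns")
  if (any(H < 0)) stop("H entries must be non-negative")
  if (!is.null(labels)) {
    missing <- setdiff(labels, rownames(H))
    if (length(missing))
      stop("H lacks entries for label(s): ", paste(missing, collapse = ", "))
  }
  invisible(H)
}

#' The 0/1 Hamming penalty matrix for a label set
#'
#' @param labels character vector of label names.
#' @return a `length(labels)`-square matrix with 0 on the diagonal and 1 off
#'   it.
#' @export
hamming_matrix <- function(labels) {
  k <- length(labels)
  H <- matrix(1, k, k, dimnames = list(labels, labels))
  diag(H) <- 0
  H
}

#' Specify a ball of labellings
#'
#' A ball `B_d(centre, r)` is the set of labellings within distance `r` of a
#' centre labelling under a chosen metric.
#'
#' @param centre centre labelling (character vector or string).
#' @param radius non-negative integer radius.
#' @param metric one of `"border_shift"`, `"border_shift_sum"`,
#'   `"generalized_hamming"`.
#' @param H penalty matrix, required for `generalized_hamming`.
#' @return an object of class `ball_spec`.
#' @export
ball_spec <- function(centre, radius,
                      metric = c("border_shift", "border_shift_sum",
                                 "generalized_hamming"),
                      H = NULL) {
  metric <- match.arg(metric)
  centre <- .as_labelling(centre)
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 0L) stop("radius must be a non-negative integer")
  if (metric == "generalized_hamming") {
    if (is.null(H)) stop("generalized_hamming requires a penalty matrix H")
    .check_H(H, unique(centre))
  }
  structure(list(centre = centre, radius = radius, metric = metric, H = H),
            class = "ball_spec")
}

#' Ball membership
#'
#' @param spec a [ball_spec()].
#' @param labelling candidate labelling of the same length as the centre.
#' @return `TRUE` iff the labelling lies within the ball.
#' @export
ball_contains <- function(spec, labelling) {
  labelling <- .as_labelling(labelling)
  d <- switch(spec$metric,
    border_shift = border_shift_distance(spec$centre, labelling),
    border_shift_sum = border_shift_sum_distance(spec$centre, labelling),
    generalized_hamming =
      generalized_hamming_distance(spec$centre, labelling, spec$H))
  d <= spec$radius
}
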
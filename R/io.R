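#' Read and write the HMM JSON model format
#'
#' The model file is a JSON object with keys `alphabet` (array of symbols),
#' `states` (array of `{id, label, emissions: {symbol: prob}}`),
#' `start_state` (a state id) and `transitions` (array of
#' `{from, to, p}`).  Emission symbols absent from a state's map default to
#' probability 0, as do unlisted transitions.  Reading validates the model
#' and round-trips with [write_hmm_json()].
#'
#' @param path file path.
#' @return an `hmm` object.
#' @export
read_hmm_json <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("alphabet", "states", "start_state", "transitions"))
    if (is.null(spec[[key]])) stop("model file lacks required key '", key, "'")
  alphabet <- vapply(spec$alphabet, as.character, "")
  ids <- vapply(spec$states, function(s) as.character(s$id), "")
  if (anyDuplicated(ids))
    stop("duplicate state id: ", ids[duplicated(ids)][1])
  labels <- vapply(spec$states, function(s) as.character(s$label), "")
  m <- length(ids)
  E <- matrix(0, m, length(alphabet), dimnames = list(ids, alphabet))
  for (i in seq_len(m)) {
    em <- spec$states[[i]]$emissions
    for (sym in names(em)) {
      if (!sym %in% alphabet)
        stop("state '", ids[i], "' emits unknown symbol '", sym, "'")
      E[i, sym] <- as.numeric(em[[sym]])
    }
  }
  A <- matrix(0, m, m, dimnames = list(ids, ids))
  for (tr in spec$transitions) {
    if (!tr$from %in% ids || !tr$to %in% ids)
      stop("transition references unknown state: ", tr$from, " -> ", tr$to)
    A[tr$from, tr$to] <- as.numeric(tr$p)
  }
  hmm(A, E, alphabet, labels, start_state = as.character(spec$start_state),
      state_names = ids)
}

#' @rdname read_hmm_json
#' @param hmm an `hmm` object.
#' @export
write_hmm_json <- function(hmm, path) {
  states <- lapply(seq_along(hmm$states), function(i) {
    em <- hmm$E[i, ]
    list(id = hmm$states[i], label = hmm$labels[i],
         emissions = as.list(em[em > 0]))
  })
  nz <- which(hmm$A > 0, arr.ind = TRUE)
  transitions <- lapply(seq_len(nrow(nz)), function(j)
    list(from = hmm$states[nz[j, 1]], to = hmm$states[nz[j, 2]],
         p = hmm$A[nz[j, 1], nz[j, 2]]))
  jsonlite::write_json(
    list(alphabet = hmm$alphabet, states = states,
         start_state = hmm$states[hmm$start], transitions = transitions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file (wrapped lines and multiple records allowed).
#' @return named list of character vectors, one symbol per element.
#' @export
read_fasta_seqs <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  lapply(seqs, function(s) strsplit(s, "")[[1]])
}

#' @rdname read_fasta_seqs
#' @param seqs named list of character vectors (or strings).
#' @export
write_fasta_seqs <- function(seqs, path) {
  seqinr::write.fasta(lapply(seqs, function(s) .as_labelling(s)),
                      names = names(seqs), file.out = path, nbchar = 60)
  invisible(path)
}

# Labelling files are tab-separated with '#'-prefixed header lines.  An
# optional map header '#map<TAB>char=label;char=label' translates the
# single-character strings in the body to label names; without it the
# characters are the labels.  Body lines: '<seq_id>\t<label string>'.

#' Read and write per-position labelling tables
#'
#' @param path file path.
#' @return named list of character label vectors.
#' @export
read_labelling_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  map <- NULL
  mline <- grep("^#map\t", hdr, value = TRUE)
  if (length(mline)) {
    pairs <- strsplit(strsplit(sub("^#map\t", "", mline[1]), ";")[[1]], "=")
    map <- vapply(pairs, `[`, "", 2L)
    names(map) <- vapply(pairs, `[`, "", 1L)
  }
  out <- list()
  for (ln in body) {
    fields <- strsplit(ln, "\t")[[1]]
    if (length(fields) != 2L)
      stop("malformed labelling line: ", ln)
    lab <- strsplit(fields[2], "")[[1]]
    if (!is.null(map)) {
      unknown <- setdiff(lab, names(map))
      if (length(unknown))
        stop("labelling character(s) missing from the #map header: ",
             paste(unknown, collapse = ", "))
      lab <- unname(map[lab])
    }
    out[[fields[1]]] <- lab
  }
  out
}

#' @rdname read_labelling_tsv
#' @param labellings named list of character label vectors.
#' @export
write_labelling_tsv <- function(labellings, path) {
  labels <- sort(unique(unlist(labellings)))
  chars <- labels
  if (any(nchar(labels) != 1L)) chars <- LETTERS[seq_along(labels)]
  names(labels) <- chars
  inv <- stats::setNames(chars, labels)
  lines <- c(
    paste0("#map\t", paste0(chars, "=", labels, collapse = ";")),
    "#seq_id\tlabelling",
    vapply(names(labellings), function(id)
      paste0(id, "\t", paste(inv[labellings[[id]]], collapse = "")), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write interval labelling tables
#'
#' Interval tables carry one feature per row — `seq_id`, `start`, `end`
#' (1-based inclusive), `label` — and must tile each sequence contiguously
#' from position 1.
#'
#' @param path file path.
#' @return named list of character label vectors.
#' @export
read_interval_tsv <- function(path) {
  lines <- readLines(path)
  body <- grep("^#", lines[nzchar(lines)], value = TRUE, invert = TRUE)
  if (length(body) == 0L) return(list())
  df <- utils::read.delim(text = body, header = FALSE,
                          col.names = c("seq_id", "start", "end", "label"),
                          stringsAsFactors = FALSE)
  out <- list()
  for (id in unique(df$seq_id)) {
    d <- df[df$seq_id == id, ]
    d <- d[order(d$start), ]
    if (d$start[1] != 1L || any(d$start[-1] != d$end[-nrow(d)] + 1L))
      stop("intervals for '", id, "' do not tile the sequence contiguously")
    out[[id]] <- rep(d$label, times = d$end - d$start + 1L)
  }
  out
}

#' @rdname read_interval_tsv
#' @param labellings named list of character label vectors.
#' @export
write_interval_tsv <- function(labellings, path) {
  lines <- "#seq_id\tstart\tend\tlabel"
  for (id in names(labellings)) {
    rl <- rle(labellings[[id]])
    end <- cumsum(rl$lengths)
    start <- end - rl$lengths + 1L
    lines <- c(lines, paste(id, start, end, rl$values, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a label penalty matrix
#'
#' Tab-separated square matrix: header line `#<TAB>lab1<TAB>lab2...`, then
#' one row per label starting with its name.
#'
#' @param path file path.
#' @return numeric matrix with label dimnames.
#' @export
read_H_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  cols <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  cols <- cols[nzchar(cols)]
  df <- utils::read.delim(text = lines[-1], header = FALSE,
                          stringsAsFactors = FALSE)
  H <- as.matrix(df[, -1, drop = FALSE])
  dimnames(H) <- list(df[[1]], cols)
  storage.mode(H) <- "numeric"
  .check_H(H)
  H
}

#' @rdname read_H_tsv
#' @param H numeric penalty matrix with label dimnames.
#' @export
write_H_tsv <- function(H, path) {
  .check_H(H)
  lines <- c(paste0("#\t", paste(colnames(H), collapse = "\t")),
             vapply(seq_len(nrow(H)), function(i)
               paste(c(rownames(H)[i], H[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}
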
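# Small deterministic fixtures shared across tests.

# single emitting state, self-loop, emits 'a' with certainty
one_state_hmm <- function() {
  hmm(matrix(1, 1, 1), matrix(1, 1, 1), alphabet = "a", labels = "A",
      start_state = 1)
}

# two states, two symbols, two labels; parameters chosen small and exact
two_state_hmm <- function() {
  hmm(rbind(c(0.7, 0.3), c(0.4, 0.6)),
      rbind(c(0.9, 0.1), c(0.2, 0.8)),
      alphabet = c("a", "b"), labels = c("A", "B"), start_state = 1)
}

# deterministic chain 1 -> 2 -> 3 -> 3, each state emitting its own symbol;
# state 1 is the silent start, so the unique path for "yzz..." is (1,2,3,3..)
chain_hmm <- function() {
  A <- rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 1))
  E <- diag(3)
  hmm(A, E, alphabet = c("x", "y", "z"), labels = c("A", "B", "C"),
      start_state = 1)
}

# state 2 can never be reached from the start
unreachable_hmm <- function() {
  hmm(rbind(c(1, 0), c(0, 1)), rbind(c(1, 0), c(0, 1)),
      alphabet = c("a", "b"), labels = c("A", "B"), start_state = 1)
}

rel_err <- function(x, ref) {
  if (ref == 0) return(abs(x))
  abs(x - ref) / abs(ref)
}

# the standard tiny fixture battery used by the oracle-equivalence checks
tiny_fixture <- function(seed) {
  h <- random_hmm(m = 2L + seed %% 3L, alphabet_size = 2L, num_labels = 2L,
                  seed = seed)
  set.seed(seed + 1000L)
  n <- sample(4:7, 1L)
  list(hmm = h, y = sample(h$alphabet, n, replace = TRUE))
}

# highest-probability labelling of a tiny instance (a natural ball centre)
top_labelling <- function(hmm, y) {
  tab <- enumerate_labelling_probabilities(hmm, y)
  strsplit(tab$labelling[which.max(tab$prob)], ";", fixed = TRUE)[[1]]
}
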
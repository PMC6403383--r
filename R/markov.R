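#' Count adjacent nucleotide pairs in a sequence record
#'
#' Tallies every ordered adjacent pair (s_i, s_j) of residues, in the fixed
#' state order S = (A, T, G, C). Positions removed during cleaning (ambiguity
#' codes, gaps) break adjacency, so pairs are counted within contiguous
#' segments only.
#'
#' @param record One record of an [dataset()] (`list(id=, segments=)`), or a
#'   plain character string of A/C/G/T residues.
#' @return A 4x4 integer matrix of pair counts with dimnames
#'   `list(from = c("A","T","G","C"), to = ...)`.
#' @examples
#' count_dinucleotides("ATAT")
#' @export
count_dinucleotides <- function(record) {
  segments <- if (is.character(record)) record else record$segments
  id <- if (is.character(record)) "<string>" else record$id
  counts <- matrix(0L, 4L, 4L, dimnames = list(from = FISIM_STATES, to = FISIM_STATES))
  for (seg in segments) {
    n <- nchar(seg)
    if (n < 2L) next
    idx <- match(strsplit(seg, "")[[1]], FISIM_STATES)
    if (anyNA(idx)) stop("record '", id, "' contains non-ACGT residues after cleaning")
    tab <- table(factor(idx[-n], levels = 1:4), factor(idx[-1L], levels = 1:4))
    counts <- counts + as.integer(tab)
  }
  if (sum(counts) == 0L) stop("record '", id, "' has no countable adjacent pairs")
  counts
}

#' Estimate the 1-step transition matrix from pair counts
#'
#' Maximum-likelihood row normalisation: `p_ij = N_ij / sum_j N_ij`. Rows
#' with no observed outgoing pairs (possible for short sequences) are filled
#' per `zero_row_policy`: `"uniform"` sets the row to 0.25 each,
#' `"pseudocount"` adds one to every cell of the matrix before normalising.
#'
#' @param counts 4x4 count matrix from [count_dinucleotides()].
#' @param zero_row_policy `"uniform"` (default) or `"pseudocount"`.
#' @return A `fi_transition` object: 4x4 row-stochastic matrix with
#'   attribute `step = 1`.
#' @examples
#' estimate_transition_matrix(count_dinucleotides("ATAT"))
#' @export
estimate_transition_matrix <- function(counts,
                                       zero_row_policy = c("uniform", "pseudocount")) {
  zero_row_policy <- match.arg(zero_row_policy)
  stopifnot(is.matrix(counts), all(dim(counts) == 4L), all(counts >= 0))
  counts <- matrix(as.numeric(counts), 4L, 4L)
  if (zero_row_policy == "pseudocount") counts <- counts + 1
  totals <- rowSums(counts)
  p <- counts / ifelse(totals > 0, totals, 1)
  p[totals == 0, ] <- 0.25
  transition_matrix(p, step = 1L)
}

#' Construct a transition-matrix object
#'
#' @param p 4x4 numeric matrix, rows summing to 1 (tolerance `1e-8`).
#' @param step Positive integer step k the matrix represents.
#' @return A `fi_transition` object (matrix with dimnames in the fixed
#'   A, T, G, C order and a `step` attribute).
#' @export
transition_matrix <- function(p, step = 1L) {
  p <- unclass(as.matrix(p))
  stopifnot(all(dim(p) == 4L))
  if (any(p < -1e-12)) stop("transition probabilities must be non-negative")
  if (max(abs(rowSums(p) - 1)) > 1e-8) stop("each row must sum to 1")
  p[p < 0] <- 0
  dimnames(p) <- list(from = FISIM_STATES, to = FISIM_STATES)
  structure(p, step = as.integer(step), class = c("fi_transition", "matrix"))
}

#' @export
print.fi_transition <- function(x, digits = 4, ...) {
  cat(sprintf("%d-step transition matrix (states A, T, G, C)\n", transition_step(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Step (k) of a transition matrix
#' @param p A `fi_transition`.
#' @return Integer step.
#' @export
transition_step <- function(p) attr(p, "step")

#' k-step transition matrix by Chapman-Kolmogorov
#'
#' Raises a 1-step transition matrix to its k-th matrix power by iterated
#' multiplication, giving the probability of reaching state j from state i
#' in exactly k steps. Row-stochasticity is preserved.
#'
#' @param p A 1-step `fi_transition` (or plain row-stochastic 4x4 matrix).
#' @param k Positive integer step.
#' @return A `fi_transition` with `step = k`.
#' @export
k_step <- function(p, k) {
  if (length(k) != 1L || is.na(k) || k != round(k) || k < 1) {
    stop("k must be a positive integer")
  }
  base <- attr(p, "step")
  if (!is.null(base) && base != 1L) stop("k_step expects a 1-step matrix")
  m <- unclass(as.matrix(p))
  if (k == 1L) return(transition_matrix(m, step = 1L))
  out <- m
  for (i in seq_len(k - 1L)) out <- out %*% m
  # renormalise away accumulated rounding so downstream row sums are exact
  out <- out / rowSums(out)
  transition_matrix(out, step = as.integer(k))
}
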
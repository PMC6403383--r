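#' All-pairs fuzzy-integral distance matrix at step k
#'
#' Estimates each sequence's 1-step transition matrix once, raises it to
#' step `k`, and evaluates the fuzzy distance for every unordered pair
#' (mirrored into a symmetric matrix with zero diagonal).
#'
#' @param x An `fi_dataset` (from [read_fasta()] or [dataset()]) with at
#'   least 2 records, or a list of pre-computed 1-step `fi_transition`
#'   matrices named by taxon.
#' @param k Positive integer step.
#' @param zero_row_policy Passed to [estimate_transition_matrix()].
#' @return An `fi_dist` object: the symmetric distance matrix (taxon
#'   dimnames) with attribute `step = k`.
#' @examples
#' ds <- dataset(c(s1 = "ACGTACGTAC", s2 = "ATATATATAT"))
#' distance_matrix(ds, k = 1)
#' @export
distance_matrix <- function(x, k = 1L, zero_row_policy = "uniform") {
  tm <- transition_set(x, zero_row_policy)
  if (length(tm) < 2L) stop("need at least 2 sequences for a distance matrix")
  tm_k <- lapply(tm, k_step, k = k)
  fi_dist_from_transitions(tm_k, k)
}

transition_set <- function(x, zero_row_policy = "uniform") {
  if (inherits(x, "fi_dataset")) {
    setNames(lapply(x, function(r) {
      estimate_transition_matrix(count_dinucleotides(r), zero_row_policy)
    }), dataset_ids(x))
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "fi_transition"))) {
    if (is.null(names(x))) stop("transition-matrix list must be named by taxon")
    x
  } else {
    stop("x must be an fi_dataset or a named list of fi_transition matrices")
  }
}

fi_dist_from_transitions <- function(tm_k, k) {
  n <- length(tm_k)
  labels <- names(tm_k)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      d[a, b] <- d[b, a] <- fuzzy_distance(tm_k[[a]], tm_k[[b]])
    }
  }
  structure(d, step = as.integer(k), class = c("fi_dist", "matrix"))
}

#' @export
print.fi_dist <- function(x, digits = 4, ...) {
  cat(sprintf("fuzzy-integral distance matrix: %d taxa, step k = %d\n",
              nrow(x), attr(x, "step")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' @method as.matrix fi_dist
#' @export
as.matrix.fi_dist <- function(x, ...) {
  structure(unclass(x), step = NULL)
}

#' Root-mean-square difference between two distance matrices
#'
#' Computed over the strict upper triangle (the diagonal is identically
#' zero and is excluded). Zero exactly when the matrices are equal.
#'
#' @param d1,d2 Distance matrices with identical taxa in identical order.
#' @return A non-negative number.
#' @export
rmsd <- function(d1, d2) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2)) || !identical(rownames(m1), rownames(m2))) {
    stop("distance matrices must share taxa and order")
  }
  ut <- upper.tri(m1)
  sqrt(mean((m1[ut] - m2[ut])^2))
}

#' Select the optimal step k by distance-matrix convergence
#'
#' Computes distance matrices D_1, D_2, ... and stops at the smallest step h
#' for which `rmsd(D_h, D_{h+1}) <= tol`: at that point the k-step matrices
#' have stopped changing the pairwise distances and h is taken as the
#' optimal step. If no step up to `max_k` converges, the result carries
#' `converged = FALSE` (with a warning) and the matrix at `max_k`.
#'
#' @inheritParams distance_matrix
#' @param tol Convergence tolerance on the RMSD between consecutive-step
#'   matrices; the default `1e-6` matches the six-decimal PHYLIP
#'   serialization of the matrices.
#' @param max_k Largest step to try.
#' @return A list of class `fi_convergence`: `optimal_k`, `converged`,
#'   `tol`, `max_k`, `rmsd_trace` (data frame of k and RMSD(D_k, D_{k+1})),
#'   and `distance` (the `fi_dist` at `optimal_k`).
#' @export
find_optimal_k <- function(x, tol = 1e-6, max_k = 30L, zero_row_policy = "uniform") {
  stopifnot(tol > 0, max_k >= 1L)
  tm1 <- transition_set(x, zero_row_policy)
  if (length(tm1) < 2L) stop("need at least 2 sequences")
  p1 <- lapply(tm1, function(p) unclass(as.matrix(p)))
  powers <- p1
  d_prev <- fi_dist_from_transitions(lapply(tm1, k_step, 1L), 1L)
  trace_k <- integer(0); trace_rmsd <- numeric(0)
  optimal <- NULL
  for (k in seq_len(max_k)) {
    powers <- lapply(seq_along(powers), function(i) {
      m <- powers[[i]] %*% p1[[i]]
      m / rowSums(m)
    })
    names(powers) <- names(p1)
    d_next <- fi_dist_from_transitions(
      lapply(powers, transition_matrix, step = k + 1L), k + 1L)
    r <- rmsd(d_prev, d_next)
    trace_k <- c(trace_k, k); trace_rmsd <- c(trace_rmsd, r)
    if (r <= tol) {
      optimal <- list(k = k, d = d_prev)
      break
    }
    d_prev <- d_next
  }
  converged <- !is.null(optimal)
  if (!converged) {
    warning("no convergence by max_k = ", max_k,
            "; returning the distance matrix at max_k")
    optimal <- list(k = max_k, d = d_prev)
  }
  structure(list(optimal_k = optimal$k, converged = converged, tol = tol,
                 max_k = as.integer(max_k),
                 rmsd_trace = data.frame(k = trace_k, rmsd = trace_rmsd),
                 distance = optimal$d),
            class = "fi_convergence")
}

#' @export
print.fi_convergence <- function(x, ...) {
  cat(sprintf("optimal step k = %d (%s, tol = %g, max_k = %d)\n",
              x$optimal_k, if (x$converged) "converged" else "NOT converged",
              x$tol, x$max_k))
  cat("rmsd trace (D_k vs D_{k+1}):\n")
  print(x$rmsd_trace, row.names = FALSE)
  invisible(x)
}

#' Run the full alignment-free pipeline on a FASTA file or dataset
#'
#' Reads (or accepts) the sequences, computes the fuzzy-integral distance
#' matrix at a fixed step or at the automatically selected optimal step,
#' builds a tree, and writes the requested PHYLIP / Newick / JSON outputs.
#'
#' @param input Path to a FASTA file or an `fi_dataset`.
#' @param k `"auto"` (default) to select the step by [find_optimal_k()],
#'   or a positive integer.
#' @param tree_method `"upgma"` (default) or `"nj"`.
#' @param phylip,newick,report Optional output paths for the PHYLIP square
#'   distance matrix, the Newick tree, and a JSON run report.
#' @param tol,max_k,zero_row_policy See [find_optimal_k()].
#' @param relaxed_phylip Passed to [write_phylip_distance()].
#' @return A list of class `fi_run`: `distance` (`fi_dist`), `tree`
#'   (`phylo`), `optimal_k`, `convergence` (`fi_convergence` or `NULL` when
#'   `k` was fixed), and the output paths written.
#' @export
run_fisim <- function(input, k = "auto", tree_method = c("upgma", "nj"),
                      phylip = NULL, newick = NULL, report = NULL,
                      tol = 1e-6, max_k = 30L, zero_row_policy = "uniform",
                      relaxed_phylip = FALSE) {
  tree_method <- match.arg(tree_method)
  ds <- if (inherits(input, "fi_dataset")) input else read_fasta(input)
  convergence <- NULL
  if (identical(k, "auto")) {
    convergence <- find_optimal_k(ds, tol = tol, max_k = max_k,
                                  zero_row_policy = zero_row_policy)
    d <- convergence$distance
    k_used <- convergence$optimal_k
  } else {
    k_used <- as.integer(k)
    d <- distance_matrix(ds, k = k_used, zero_row_policy = zero_row_policy)
  }
  tree <- if (tree_method == "upgma") upgma(d) else neighbor_joining(d)
  if (!is.null(phylip)) write_phylip_distance(d, phylip, relaxed = relaxed_phylip)
  if (!is.null(newick)) writeLines(to_newick(tree), newick)
  if (!is.null(report)) {
    rep <- list(n_taxa = nrow(d), k = k_used,
                k_mode = if (identical(k, "auto")) "auto" else "fixed",
                tree_method = tree_method, tol = tol, max_k = max_k,
                zero_row_policy = zero_row_policy,
                converged = if (is.null(convergence)) NA else convergence$converged,
                rmsd_trace = if (is.null(convergence)) NULL else convergence$rmsd_trace)
    jsonlite::write_json(rep, report, auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(list(distance = d, tree = tree, optimal_k = k_used,
                 convergence = convergence,
                 paths = list(phylip = phylip, newick = newick, report = report)),
            class = "fi_run")
}

#' @export
print.fi_run <- function(x, ...) {
  cat(sprintf("fisim run: %d taxa, step k = %d\n", nrow(x$distance), x$optimal_k))
  if (!is.null(x$convergence)) print(x$convergence)
  invisible(x)
}
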
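#' Membership grid between two k-step transition matrices
#'
#' Cellwise evidence of agreement: `h_ij = 1 - |P1_ij - P2_ij|`, one value
#' per nucleotide pair position (16 cells). Symmetric in its two arguments.
#'
#' @param p1,p2 `fi_transition` matrices of the same step.
#' @return 4x4 numeric matrix with values in `[0, 1]`.
#' @export
membership_grid <- function(p1, p2) {
  check_same_step(p1, p2)
  h <- 1 - abs(unclass(as.matrix(p1)) - unclass(as.matrix(p2)))
  dimnames(h) <- list(from = FISIM_STATES, to = FISIM_STATES)
  h
}

#' Density grid between two k-step transition matrices
#'
#' Cellwise fuzzy densities: `mu_ij = max(P1_ij, P2_ij)`, the conservation
#' level of each nucleotide pair position. Because each input row sums to 1,
#' every density row sums to at least 1.
#'
#' @inheritParams membership_grid
#' @return 4x4 numeric matrix with values in `[0, 1]`.
#' @export
density_grid <- function(p1, p2) {
  check_same_step(p1, p2)
  mu <- pmax(unclass(as.matrix(p1)), unclass(as.matrix(p2)))
  dimnames(mu) <- list(from = FISIM_STATES, to = FISIM_STATES)
  mu
}

check_same_step <- function(p1, p2) {
  s1 <- attr(p1, "step"); s2 <- attr(p2, "step")
  if (!is.null(s1) && !is.null(s2) && s1 != s2) {
    stop("transition matrices have different steps (", s1, " vs ", s2, ")")
  }
  invisible(NULL)
}

#' Solve for the lambda of a lambda-fuzzy measure
#'
#' Given the four singleton densities mu of one row, finds the normalising
#' lambda > -1 satisfying `prod(1 + lambda * mu) = 1 + lambda`, so that the
#' measure of the full row is 1. When the densities sum to 1 the measure is
#' additive and lambda = 0. When they sum to more than 1 (always the case
#' for densities formed as elementwise maxima of two stochastic rows) the
#' unique non-trivial root lies in (-1, 0) and is found by bisection, run
#' down to machine precision. Degenerate density patterns (e.g. exact 0/1
#' rows) admit only the trivial roots 0 and -1; these fall back to
#' lambda = 0 and rely on the cumulative-measure clamp in [row_measure()].
#'
#' @param densities Numeric vector of 4 densities in `[0, 1]`.
#' @param tol Sum-to-one tolerance below which lambda is exactly 0.
#' @return A single number, lambda, in `(-1, 0]`.
#' @export
solve_lambda <- function(densities, tol = 1e-9) {
  mu <- as.numeric(densities)
  stopifnot(length(mu) == 4L)
  if (anyNA(mu) || any(mu < 0) || any(mu > 1)) {
    stop("densities must lie in [0, 1]")
  }
  s <- sum(mu)
  if (abs(s - 1) <= tol) return(0)
  if (s < 1) {
    # sum < 1 would need lambda > 0; not reachable for max-of-stochastic-rows
    # densities, but handled for completeness via uniroot on (0, big).
    g <- function(l) prod(1 + l * mu) - 1 - l
    hi <- 1
    while (g(hi) < 0 && hi < 1e12) hi <- hi * 2
    if (g(hi) < 0) stop("no normalising lambda found for densities summing below 1")
    return(stats::uniroot(g, c(1e-12, hi), tol = 1e-15)$root)
  }
  g <- function(l) prod(1 + l * mu) - 1 - l
  lo <- -1 + 1e-12
  hi <- -1e-12
  glo <- g(lo); ghi <- g(hi)
  if (sign(glo) == sign(ghi)) return(0) # degenerate: only trivial roots
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (gm == 0 || (hi - lo) < 1e-15) return(mid)
    if (sign(gm) == sign(glo)) {
      lo <- mid; glo <- gm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Cumulative lambda-fuzzy measure for one row
#'
#' Jointly sorts the row's (membership, density) pairs by descending
#' membership (stable; ties keep the original A, T, G, C column order),
#' solves for lambda, and accumulates the measure of the nested sets
#' A_1 = {y_(1)}, A_2 = {y_(1), y_(2)}, ... by the lambda-measure union rule
#' `mu(A_j) = mu(A_{j-1}) + g_j + lambda * mu(A_{j-1}) * g_j`. Values are
#' clamped to 1, and the final measure is snapped to exactly 1 when it lands
#' within `1e-9` of it (the measure of the full set must be 1).
#'
#' @param h_row Numeric vector of 4 membership values in `[0, 1]`.
#' @param density_row Numeric vector of 4 densities in `[0, 1]`.
#' @return A list of class `fi_row_measure`: `h` (sorted memberships),
#'   `densities` (correspondingly sorted), `order` (permutation applied),
#'   `lambda`, and `cumulative` (non-decreasing, ending at 1 in all
#'   non-degenerate cases).
#' @export
row_measure <- function(h_row, density_row) {
  h_row <- as.numeric(h_row); density_row <- as.numeric(density_row)
  stopifnot(length(h_row) == 4L, length(density_row) == 4L)
  ord <- order(-h_row, seq_along(h_row), method = "radix")
  h <- h_row[ord]
  mu <- density_row[ord]
  lam <- solve_lambda(density_row)
  cum <- numeric(4L)
  cum[1L] <- mu[1L]
  for (j in 2:4) cum[j] <- cum[j - 1L] + mu[j] + lam * cum[j - 1L] * mu[j]
  cum <- pmin(cum, 1)
  if (abs(cum[4L] - 1) <= 1e-9) cum[4L] <- 1
  structure(list(h = h, densities = mu, order = ord, lambda = lam,
                 cumulative = cum),
            class = "fi_row_measure")
}

#' Sugeno integral of one row measure
#'
#' `S = max_j min(h_(j), mu(A_j))` over the four nested sets of the sorted
#' row: the largest evidence level jointly supported by the measure.
#'
#' @param measure A `fi_row_measure` from [row_measure()].
#' @return A number in `[0, 1]`.
#' @export
sugeno_row <- function(measure) {
  max(pmin(measure$h, measure$cumulative))
}

#' Fuzzy-integral similarity between two k-step transition matrices
#'
#' Builds the membership grid (`1 - |difference|`) and density grid
#' (cellwise maxima), computes the Sugeno integral of each of the four
#' rows under its lambda-fuzzy measure, and aggregates by the maximum over
#' rows. Equal matrices score exactly 1; the score is symmetric in its
#' arguments and lies in `[0, 1]`.
#'
#' @inheritParams membership_grid
#' @return Similarity in `[0, 1]`.
#' @seealso [fuzzy_distance()]
#' @export
fisim <- function(p1, p2) {
  h <- membership_grid(p1, p2)
  mu <- density_grid(p1, p2)
  max(vapply(1:4, function(i) sugeno_row(row_measure(h[i, ], mu[i, ])),
             numeric(1)))
}

#' Fuzzy-integral distance between two k-step transition matrices
#'
#' `D = 1 - fisim(p1, p2)`; zero for identical matrices, symmetric, bounded
#' by `[0, 1]`.
#'
#' @inheritParams membership_grid
#' @return Distance in `[0, 1]`.
#' @export
fuzzy_distance <- function(p1, p2) {
  1 - fisim(p1, p2)
}
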
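#' UPGMA tree from a distance matrix
#'
#' Standard agglomeration with arithmetic-mean (size-weighted) cluster
#' distances, producing a rooted ultrametric tree: every leaf sits at the
#' same distance from the root, and each merge places its node at half the
#' merged cluster distance. Tie-breaking is deterministic: among equal
#' minimal distances the pair with the lowest (row, column) index in the
#' current matrix order is merged first.
#'
#' @param d An `fi_dist`, `dist`, or symmetric numeric matrix with taxon
#'   dimnames (2 or more taxa).
#' @return An [ape::read.tree()]-style `phylo` object (rooted).
#' @examples
#' m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' to_newick(upgma(m))
#' @export
upgma <- function(d) {
  m <- dist_input(d)
  n <- nrow(m)
  labels <- rownames(m)
  # active clusters: newick fragment, height, size
  nwk <- labels
  height <- rep(0, n)
  size <- rep(1L, n)
  while (nrow(m) > 1L) {
    ij <- min_pair(m)
    i <- ij[1L]; j <- ij[2L]
    h_new <- m[i, j] / 2
    nwk_new <- sprintf("(%s:%s,%s:%s)",
                       nwk[i], fmt_len(h_new - height[i]),
                       nwk[j], fmt_len(h_new - height[j]))
    rest <- setdiff(seq_len(nrow(m)), c(i, j))
    d_new <- (size[i] * m[i, rest] + size[j] * m[j, rest]) / (size[i] + size[j])
    m <- rbind(cbind(m[rest, rest, drop = FALSE], d_new),
               c(d_new, 0))
    nwk <- c(nwk[rest], nwk_new)
    height <- c(height[rest], h_new)
    size <- c(size[rest], size[i] + size[j])
  }
  ape::read.tree(text = paste0(nwk[1L], ";"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' `Q_ij = (r - 2) d_ij - R_i - R_j` (R = row sums over the r active
#' clusters), producing an unrooted tree. Tie-breaking follows [upgma()]
#' (lowest index pair). Negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to zero with a warning.
#'
#' @inheritParams upgma
#' @param d Distance matrix over 3 or more taxa.
#' @return An unrooted `phylo` object.
#' @export
neighbor_joining <- function(d) {
  m <- dist_input(d)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  nwk <- rownames(m)
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  while (nrow(m) > 3L) {
    r <- nrow(m)
    R <- rowSums(m)
    q <- (r - 2) * m - outer(R, R, `+`)
    diag(q) <- Inf
    ij <- min_pair(q)
    i <- ij[1L]; j <- ij[2L]
    bi <- clamp(m[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    bj <- clamp(m[i, j] - bi)
    nwk_new <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt_len(bi), nwk[j], fmt_len(bj))
    rest <- setdiff(seq_len(r), c(i, j))
    d_new <- (m[i, rest] + m[j, rest] - m[i, j]) / 2
    m <- rbind(cbind(m[rest, rest, drop = FALSE], d_new), c(d_new, 0))
    nwk <- c(nwk[rest], nwk_new)
  }
  # resolve the final three clusters around a central node (three-point rule)
  b1 <- clamp((m[1, 2] + m[1, 3] - m[2, 3]) / 2)
  b2 <- clamp((m[1, 2] + m[2, 3] - m[1, 3]) / 2)
  b3 <- clamp((m[1, 3] + m[2, 3] - m[1, 2]) / 2)
  if (clamped) warning("negative NJ branch length(s) clamped to zero")
  text <- sprintf("(%s:%s,%s:%s,%s:%s);",
                  nwk[1L], fmt_len(b1), nwk[2L], fmt_len(b2), nwk[3L], fmt_len(b3))
  ape::read.tree(text = text)
}

# smallest entry of a symmetric criterion matrix; ties -> lowest (i, j)
min_pair <- function(m) {
  n <- nrow(m)
  best <- c(NA_integer_, NA_integer_)
  best_v <- Inf
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (m[i, j] < best_v) {
        best_v <- m[i, j]
        best <- c(i, j)
      }
    }
  }
  best
}

fmt_len <- function(x) sprintf("%.12g", x)

dist_input <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  m <- as.matrix(d)
  check_distance_matrix(m)
  rownames(m) <- colnames(m) <- gsub("[[:space:]]", "_", rownames(m))
  m
}

#' Serialize a tree as a Newick string
#'
#' Branch lengths are written with a fixed number of decimals (six by
#' default, matching the package's PHYLIP interchange precision). Labels
#' containing whitespace are underscored (default) or single-quoted.
#'
#' @param tree A `phylo` object.
#' @param precision Decimal places for branch lengths.
#' @param spaces How to protect labels containing whitespace:
#'   `"underscore"` or `"quote"`.
#' @return A single Newick string terminated by `;`.
#' @export
to_newick <- function(tree, precision = 6L, spaces = c("underscore", "quote")) {
  spaces <- match.arg(spaces)
  stopifnot(inherits(tree, "phylo"))
  lab <- tree$tip.label
  lab <- if (spaces == "underscore") {
    gsub("[[:space:]]", "_", lab)
  } else {
    ifelse(grepl("[[:space:]]", lab), paste0("'", lab, "'"), lab)
  }
  n_tip <- length(lab)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- paste0("%.", precision, "f")
  rec <- function(node) {
    if (node <= n_tip) return(lab[[node]])
    kids <- children[[as.character(node)]]
    paste0("(", paste(vapply(kids, function(e) {
      paste0(rec(tree$edge[e, 2L]), ":",
             sprintf(fmt, tree$edge.length[[e]]))
    }, character(1)), collapse = ","), ")")
  }
  paste0(rec(root), ";")
}
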
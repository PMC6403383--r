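#' Robinson-Foulds distance between two trees
#'
#' Number of bipartitions present in exactly one of the two trees
#' (symmetric difference of their split sets). Computed on unrooted
#' topologies — rooted inputs are unrooted first — so the value is 0 if and
#' only if the two trees have the same unrooted topology; branch lengths
#' are ignored.
#'
#' @param t1,t2 `phylo` objects over identical leaf sets.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have different leaf sets")
  }
  t1 <- ape::unroot(t1)
  t2 <- ape::unroot(t2)
  as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' ROC curve and AUC of a distance matrix against group labels
#'
#' Scores every unordered taxon pair by `1 - distance` and asks how well
#' these scores separate within-group pairs (positives) from cross-group
#' pairs (negatives): a sweep over score thresholds gives the ROC curve,
#' and the area under it (trapezoid rule, midpoint convention for ties —
#' equivalently the normalised Mann-Whitney U statistic) summarises the
#' grouping power of the distances.
#'
#' @param d Distance matrix (`fi_dist` or plain symmetric matrix with taxon
#'   dimnames).
#' @param groups Group membership: a named vector (names = taxa), or a
#'   two-column data frame `(taxon, group)`.
#' @return A list of class `fi_roc`: `auc`, `curve` (data frame of
#'   `fpr`/`tpr` points), and `pairs` (data frame with one row per taxon
#'   pair: taxa, distance, score, same_group).
#' @export
roc_auc <- function(d, groups) {
  m <- as.matrix(d)
  check_distance_matrix(m)
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups[[2L]]), as.character(groups[[1L]]))
  }
  taxa <- rownames(m)
  missing <- setdiff(taxa, names(groups))
  if (length(missing)) {
    stop("no group label for: ", paste(missing, collapse = ", "))
  }
  g <- groups[taxa]
  idx <- which(upper.tri(m), arr.ind = TRUE)
  pairs <- data.frame(
    taxon1 = taxa[idx[, 1L]],
    taxon2 = taxa[idx[, 2L]],
    distance = m[idx],
    same_group = g[idx[, 1L]] == g[idx[, 2L]],
    row.names = NULL
  )
  pairs$score <- 1 - pairs$distance
  if (!any(pairs$same_group) || all(pairs$same_group)) {
    stop("ROC needs at least one within-group and one cross-group pair")
  }
  roc <- pROC::roc(response = pairs$same_group, predictor = pairs$score,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = 1 - roc$specificities, tpr = roc$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), , drop = FALSE]
  structure(list(auc = as.numeric(pROC::auc(roc)), curve = curve, pairs = pairs),
            class = "fi_roc")
}

#' @export
print.fi_roc <- function(x, ...) {
  cat(sprintf("ROC over %d taxon pairs (%d within-group): AUC = %.4f\n",
              nrow(x$pairs), sum(x$pairs$same_group), x$auc))
  invisible(x)
}

#' Read a two-column taxon-to-group TSV file
#'
#' @param path TSV with columns taxon and group (no header required; a
#'   `taxon<TAB>group` header line is tolerated and dropped).
#' @return Named character vector mapping taxon to group.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("group file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("taxon", "group"),
                           colClasses = "character", comment.char = "#")
  if (nrow(tab) && identical(tolower(tab$taxon[[1L]]), "taxon")) {
    tab <- tab[-1L, , drop = FALSE]
  }
  if (!nrow(tab)) stop("empty group file: ", path)
  setNames(tab$group, tab$taxon)
}
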
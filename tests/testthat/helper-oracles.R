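# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: polynomial roots instead of bisection, exhaustive subset
# enumeration instead of the sorted max-min recursion, character loops
# instead of vectorised counting.

states4 <- c("A", "T", "G", "C")

# normalising lambda via polyroot on prod(1 + lambda*mu) = 1 + lambda
oracle_lambda <- function(mu) {
  e1 <- sum(mu)
  e2 <- sum(mu[1] * mu[2:4], mu[2] * mu[3:4], mu[3] * mu[4])
  e3 <- mu[1] * mu[2] * mu[3] + mu[1] * mu[2] * mu[4] +
    mu[1] * mu[3] * mu[4] + mu[2] * mu[3] * mu[4]
  e4 <- prod(mu)
  coef <- c(0, e1 - 1, e2, e3, e4)
  if (all(abs(coef[3:5]) < 1e-300)) return(0)
  r <- polyroot(coef)
  real <- Re(r[abs(Im(r)) < 1e-9])
  cand <- real[real > -1 + 1e-9 & real < -1e-9]
  if (length(cand) == 0L) 0 else cand[[which.max(abs(cand))]]
}

# lambda-measure of an index subset from singleton densities
oracle_measure <- function(idx, mu, lam) {
  if (length(idx) == 0L) return(0)
  m <- if (abs(lam) < 1e-300) sum(mu[idx]) else (prod(1 + lam * mu[idx]) - 1) / lam
  min(m, 1)
}

# Sugeno integral by exhaustive max over all 2^4 subsets
oracle_sugeno <- function(h, mu, lam = oracle_lambda(mu)) {
  best <- 0
  for (bits in 1:15) {
    idx <- which(bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L)
    best <- max(best, min(min(h[idx]), oracle_measure(idx, mu, lam)))
  }
  best
}

# dinucleotide counts by a character-by-character loop (no adjacency breaks)
oracle_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- matrix(0, 4, 4, dimnames = list(states4, states4))
  for (i in seq_len(length(chars) - 1L)) {
    n[chars[[i]], chars[[i + 1L]]] <- n[chars[[i]], chars[[i + 1L]]] + 1
  }
  n
}

oracle_transition <- function(counts) {
  p <- matrix(0.25, 4, 4, dimnames = dimnames(counts))
  for (i in 1:4) {
    tot <- sum(counts[i, ])
    if (tot > 0) p[i, ] <- counts[i, ] / tot
  }
  p
}

oracle_power <- function(p, k) {
  out <- diag(4)
  for (i in seq_len(k)) out <- out %*% p
  out
}

# full pairwise fuzzy distance, everything recomputed by brute force
oracle_fuzzy_distance <- function(pa, pb) {
  best <- 0
  for (i in 1:4) {
    h <- 1 - abs(pa[i, ] - pb[i, ])
    mu <- pmax(pa[i, ], pb[i, ])
    best <- max(best, oracle_sugeno(h, mu))
  }
  1 - best
}

oracle_distance_matrix <- function(seqs, k) {
  p <- lapply(seqs, function(s) oracle_power(oracle_transition(oracle_counts(s)), k))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      d[a, b] <- d[b, a] <- oracle_fuzzy_distance(p[[a]], p[[b]])
    }
  }
  d
}

oracle_rmsd <- function(m1, m2) {
  acc <- 0; cnt <- 0
  for (a in seq_len(nrow(m1) - 1L)) {
    for (b in (a + 1L):ncol(m1)) {
      acc <- acc + (m1[a, b] - m2[a, b])^2
      cnt <- cnt + 1
    }
  }
  sqrt(acc / cnt)
}

# AUC as the normalised Mann-Whitney U by exhaustive pair comparison
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

random_stochastic <- function() {
  m <- matrix(stats::rexp(16), 4, 4)
  transition_matrix(m / rowSums(m))
}
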
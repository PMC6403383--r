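#' Specification of a Markov chain to simulate from
#'
#' @param p 4x4 row-stochastic matrix (1-step transition probabilities) or
#'   an `fi_transition`; defaults to [example_transition()].
#' @param initial Length-4 probability vector over (A, T, G, C) for the
#'   first residue (sums to 1); default uniform.
#' @param length Sequence length (>= 2).
#' @param seed Integer seed; all randomness of the simulation flows from it.
#' @return A list of class `fi_chain_spec`.
#' @export
chain_spec <- function(p = example_transition(), initial = rep(0.25, 4),
                       length = 1000L, seed = 1L) {
  p <- transition_matrix(as.matrix(p), step = 1L)
  initial <- as.numeric(initial)
  stopifnot(length(initial) == 4L, all(initial >= 0))
  if (abs(sum(initial) - 1) > 1e-12) stop("initial probabilities must sum to 1")
  if (length < 2L) stop("length must be at least 2")
  structure(list(p = p, initial = initial, length = as.integer(length),
                 seed = as.integer(seed)),
            class = "fi_chain_spec")
}

#' A strongly structured ergodic example chain
#'
#' A 1-step transition matrix with pronounced nearest-neighbour preferences
#' (every state favours itself and one other state), used as the default
#' simulation fixture; all entries are positive, so the chain is ergodic.
#'
#' @return A 1-step `fi_transition`.
#' @export
example_transition <- function() {
  transition_matrix(matrix(c(
    0.45, 0.15, 0.30, 0.10,
    0.10, 0.45, 0.15, 0.30,
    0.30, 0.10, 0.45, 0.15,
    0.15, 0.30, 0.10, 0.45
  ), 4L, 4L, byrow = TRUE), step = 1L)
}

#' Simulate a DNA sequence from a Markov chain
#'
#' The first residue is drawn from the initial distribution and every
#' subsequent residue from the transition-matrix row of its predecessor.
#' Reproducible: the same spec (including seed) always yields the same
#' sequence, and the caller's RNG state is left untouched.
#'
#' @param spec An [chain_spec()].
#' @param id Record id for the returned sequence.
#' @return A single-record `fi_dataset` record: `list(id =, segments =)`.
#' @export
simulate_sequence <- function(spec, id = "sim") {
  stopifnot(inherits(spec, "fi_chain_spec"))
  states <- with_seed(spec$seed, simulate_chain_states(spec))
  list(id = id, segments = paste(FISIM_STATES[states], collapse = ""))
}

simulate_chain_states <- function(spec) {
  n <- spec$length
  cum <- t(apply(unclass(spec$p), 1L, cumsum))
  cum[, 4L] <- 1
  u <- runif(n)
  states <- integer(n)
  states[1L] <- findInterval(u[1L], cumsum(spec$initial)) + 1L
  if (states[1L] > 4L) states[1L] <- 4L
  for (t in 2:n) {
    row <- cum[states[t - 1L], ]
    states[t] <- findInterval(u[t], row) + 1L
  }
  states
}

#' Evolve a family of sequences along a guide tree
#'
#' Simulates a root sequence from `root_spec`, then walks the guide tree
#' from the root: along each branch every site is substituted independently
#' with probability `1 - exp(-subst_rate * branch_length)`, the replacement
#' drawn uniformly from the three other bases (Jukes-Cantor-like). The leaf
#' sequences are returned as a dataset named by the tip labels.
#'
#' @param root_spec An [chain_spec()] for the root sequence (its `seed` is
#'   ignored in favour of `seed`).
#' @param guide_tree A `phylo` tree with branch lengths.
#' @param subst_rate Substitution rate per unit branch length (> 0); with
#'   the default 1, branch lengths are read directly as expected
#'   substitutions per site.
#' @param seed Integer seed for the whole simulation.
#' @return An `fi_dataset` of the leaf sequences, in tip-label order.
#' @export
evolve_family <- function(root_spec, guide_tree, subst_rate = 1, seed = 1L) {
  stopifnot(inherits(root_spec, "fi_chain_spec"), inherits(guide_tree, "phylo"))
  if (subst_rate <= 0) stop("subst_rate must be positive")
  if (is.null(guide_tree$edge.length)) stop("guide tree needs branch lengths")
  with_seed(seed, {
    root_states <- simulate_chain_states(root_spec)
    tree <- ape::reorder.phylo(guide_tree, "cladewise")
    n_tip <- length(tree$tip.label)
    node_seq <- vector("list", n_tip + tree$Nnode)
    node_seq[[n_tip + 1L]] <- root_states
    leaves <- vector("list", n_tip)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      s <- node_seq[[parent]]
      q <- 1 - exp(-subst_rate * tree$edge.length[[e]])
      hit <- which(runif(length(s)) < q)
      if (length(hit)) {
        # uniform among the 3 other bases: offset 1..3 added mod 4
        s[hit] <- ((s[hit] - 1L + sample(1:3, length(hit), replace = TRUE)) %% 4L) + 1L
      }
      if (child <= n_tip) leaves[[child]] <- s else node_seq[[child]] <- s
    }
    seqs <- vapply(leaves, function(s) paste(FISIM_STATES[s], collapse = ""),
                   character(1))
    dataset(setNames(seqs, tree$tip.label))
  })
}

#' Balanced binary guide tree for simulation studies
#'
#' Builds a rooted ultrametric tree of `2^depth` leaves from nested
#' cherries. Branch lengths are given per level, terminal level first, in
#' expected substitutions per site (so [evolve_family()] with its default
#' `subst_rate = 1` applies them directly). The default geometry is a
#' recent-radiation shape — very short terminal branches, a short middle
#' level, and long basal branches — which gives the three depth classes of
#' leaf pairs widely separated expected divergences.
#'
#' @param depth Number of cherry levels; the tree has `2^depth` leaves.
#' @param branch_length Branch length per level (terminal level first);
#'   recycled if a single value is given.
#' @param labels Optional tip labels (default `t1..t2^depth`).
#' @return A rooted ultrametric `phylo` tree.
#' @export
guide_tree_balanced <- function(depth = 3L, branch_length = c(0.001, 0.04, 0.8),
                                labels = NULL) {
  stopifnot(depth >= 1L)
  if (length(branch_length) == 1L) branch_length <- rep(branch_length, depth)
  if (length(branch_length) != depth) {
    stop("branch_length must have length 1 or depth")
  }
  n <- 2L^depth
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  stopifnot(length(labels) == n)
  nodes <- labels
  for (level in seq_len(depth)) {
    bl <- branch_length[[level]]
    nodes <- vapply(seq_len(length(nodes) / 2L), function(i) {
      sprintf("(%s:%s,%s:%s)", nodes[[2L * i - 1L]], fmt_len(bl),
              nodes[[2L * i]], fmt_len(bl))
    }, character(1))
  }
  ape::read.tree(text = paste0(nodes[[1L]], ";"))
}

#' Write simulated FASTA fixtures with a JSON manifest
#'
#' @param specs Named list of [chain_spec()]s; one FASTA record per spec.
#' @param fasta,manifest Output paths.
#' @return `fasta`, invisibly.
#' @export
write_simulated_fasta <- function(specs, fasta, manifest = NULL) {
  stopifnot(length(specs) >= 1L, !is.null(names(specs)))
  recs <- lapply(names(specs), function(nm) simulate_sequence(specs[[nm]], id = nm))
  ds <- dataset(setNames(vapply(recs, function(r) r$segments, character(1)),
                         names(specs)))
  write_fasta(ds, fasta)
  if (!is.null(manifest)) {
    desc <- lapply(specs, function(s) {
      list(p = apply(unclass(s$p), 1L, function(r) as.numeric(r), simplify = FALSE),
           initial = s$initial, length = s$length, seed = s$seed)
    })
    jsonlite::write_json(desc, manifest, auto_unbox = TRUE, digits = NA)
  }
  invisible(fasta)
}
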
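test_that("dinucleotide counts match hand enumeration", {
  n <- count_dinucleotides("AAAA")
  expect_equal(n["A", "A"], 3L, ignore_attr = TRUE)
  expect_equal(sum(n), 3L)

  n <- count_dinucleotides("ATAT")
  expect_equal(unname(c(n["A", "T"], n["T", "A"])), c(2L, 1L))
  expect_equal(sum(n), 3L)

  n <- count_dinucleotides("ACGT")
  expect_equal(unname(c(n["A", "C"], n["C", "G"], n["G", "T"])), c(1L, 1L, 1L))
  expect_equal(sum(n), 3L)

  expect_error(count_dinucleotides(list(id = "x", segments = c("A", "C"))),
               "countable")
})

test_that("counting agrees with a character-loop oracle on random sequences", {
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "T", "G", "C"), 50, replace = TRUE), collapse = "")
    expect_equal(unclass(count_dinucleotides(s)), unclass(oracle_counts(s)),
                 ignore_attr = TRUE)
  }
})

test_that("transition estimation normalises rows and honours zero-row policy", {
  p <- estimate_transition_matrix(count_dinucleotides("AAAA"))
  expect_equal(unname(p["A", ]), c(1, 0, 0, 0))
  expect_equal(unname(p["T", ]), rep(0.25, 4)) # unseen state, uniform policy
  expect_equal(rowSums(p), rep(1, 4), ignore_attr = TRUE)

  p <- estimate_transition_matrix(count_dinucleotides("ATAT"))
  expect_equal(unname(p["A", ]), c(0, 1, 0, 0))
  expect_equal(unname(p["T", ]), c(1, 0, 0, 0))

  p <- estimate_transition_matrix(count_dinucleotides("AAAA"), "pseudocount")
  expect_equal(unname(p["A", ]), c(4, 1, 1, 1) / 7)
  expect_equal(unname(p["G", ]), rep(0.25, 4))
})

test_that("k_step equals the naive repeated-multiplication oracle", {
  p <- transition_matrix(matrix(c(0, 1, 0, 0,
                                  1, 0, 0, 0,
                                  0, 0, 1, 0,
                                  0, 0, 0, 1), 4, byrow = TRUE))
  expect_equal(unclass(k_step(p, 2)), diag(4), ignore_attr = TRUE)
  expect_error(k_step(p, 0), "positive")

  set.seed(9)
  for (i in 1:10) {
    p <- random_stochastic()
    expect_identical(unclass(k_step(p, 1)), unclass(p))
    expect_lt(max(abs(unclass(k_step(p, 5)) - oracle_power(unclass(p), 5))), 1e-12)
  }
})

test_that("k_step preserves row-stochasticity and the semigroup property", {
  set.seed(21)
  for (i in 1:10) {
    p <- random_stochastic()
    for (k in c(2, 7, 20)) {
      expect_lt(max(abs(rowSums(k_step(p, k)) - 1)), 1e-10)
    }
    ab <- unclass(k_step(p, 9))
    a_b <- unclass(k_step(p, 4)) %*% unclass(k_step(p, 5))
    expect_lt(max(abs(ab - a_b)), 1e-10)
  }
})

test_that("rows of P^k approach a common stationary vector for ergodic P", {
  p <- example_transition()
  spread <- sapply(c(1, 4, 8, 16), function(k) {
    m <- unclass(k_step(p, k))
    max(apply(m, 2, max) - apply(m, 2, min))
  })
  expect_true(all(diff(spread) < 0))
  expect_lt(spread[[4]], 1e-4)
})

test_that("long simulated sequences recover the generating chain", {
  spec <- chain_spec(length = 100000L, seed = 101L)
  rec <- simulate_sequence(spec)
  p_hat <- estimate_transition_matrix(count_dinucleotides(rec))
  expect_lt(max(abs(unclass(p_hat) - unclass(example_transition()))), 0.01)
})
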
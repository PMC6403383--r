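test_that("membership and density grids follow the forced arithmetic", {
  p1 <- transition_matrix(matrix(c(1, 0, 0, 0), 4, 4, byrow = TRUE))
  p2 <- transition_matrix(matrix(c(0, 1, 0, 0), 4, 4, byrow = TRUE))
  h <- membership_grid(p1, p2)
  expect_equal(unname(h[1, ]), c(0, 0, 1, 1))
  expect_equal(membership_grid(p1, p1), matrix(1, 4, 4), ignore_attr = TRUE)
  expect_identical(membership_grid(p1, p2), membership_grid(p2, p1))

  mu <- density_grid(p1, p2)
  expect_equal(unname(mu[1, ]), c(1, 1, 0, 0))
  expect_equal(unclass(density_grid(p1, p1)), unclass(p1), ignore_attr = TRUE)
  expect_true(all(mu >= unclass(p1) & mu >= unclass(p2)))

  p2k <- k_step(p2, 3)
  expect_error(membership_grid(p1, p2k), "step")
  expect_error(density_grid(p1, p2k), "step")
})

test_that("solve_lambda matches the polynomial-root oracle", {
  expect_identical(solve_lambda(c(0.25, 0.25, 0.25, 0.25)), 0)
  # root of lambda^3/16 + lambda^2/2 + 3 lambda/2 + 1 in (-1, 0)
  lam <- solve_lambda(c(0.5, 0.5, 0.5, 0.5))
  expect_equal(lam, -0.91262, tolerance = 1e-5)
  expect_lt(abs(prod(1 + lam * rep(0.5, 4)) - 1 - lam), 1e-12)
  # degenerate: only trivial roots, fall back to 0
  expect_identical(solve_lambda(c(1, 1, 0, 0)), 0)
  expect_error(solve_lambda(c(1.2, 0, 0, 0)), "\\[0, 1\\]")

  set.seed(31)
  for (i in 1:200) {
    a <- stats::rexp(4); b <- stats::rexp(4)
    mu <- pmax(a / sum(a), b / sum(b))
    lam <- solve_lambda(mu)
    expect_gt(lam, -1)
    expect_lte(lam, 0)
    expect_lt(abs(prod(1 + lam * mu) - 1 - lam), 1e-12)
    expect_equal(lam, oracle_lambda(mu), tolerance = 1e-9)
  }
})

test_that("row_measure sorts stably, accumulates and clamps", {
  m <- row_measure(c(1, 1, 1, 1), c(0.25, 0.25, 0.25, 0.25))
  expect_identical(m$order, 1:4) # ties keep A,T,G,C order
  expect_equal(m$cumulative, c(0.25, 0.5, 0.75, 1))
  expect_identical(m$lambda, 0)

  m <- row_measure(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_identical(m$order, c(3L, 4L, 1L, 2L))
  expect_equal(m$cumulative, c(0, 0, 1, 1)) # clamped at 1 in the fallback

  set.seed(41)
  for (i in 1:100) {
    a <- stats::rexp(4); b <- stats::rexp(4)
    m <- row_measure(stats::runif(4), pmax(a / sum(a), b / sum(b)))
    expect_true(all(diff(m$cumulative) >= 0))
    expect_identical(m$cumulative[[1]], m$densities[[1]])
    expect_equal(m$cumulative[[4]], 1)
  }
})

test_that("sugeno_row equals the exhaustive-subset Sugeno oracle", {
  set.seed(51)
  for (i in 1:300) {
    h <- stats::runif(4)
    a <- stats::rexp(4); b <- stats::rexp(4)
    mu <- pmax(a / sum(a), b / sum(b))
    got <- sugeno_row(row_measure(h, mu))
    expect_lt(abs(got - oracle_sugeno(h, mu)), 1e-12)
  }
})

test_that("fisim and fuzzy_distance behave as a bounded symmetric similarity", {
  p1 <- transition_matrix(matrix(c(1, 0, 0, 0), 4, 4, byrow = TRUE))
  p2 <- transition_matrix(matrix(c(0, 1, 0, 0), 4, 4, byrow = TRUE))
  expect_identical(fisim(p1, p2), 0) # fully non-overlapping rows
  expect_identical(fuzzy_distance(p1, p2), 1)

  set.seed(61)
  for (i in 1:50) {
    pa <- random_stochastic(); pb <- random_stochastic()
    expect_identical(fisim(pa, pa), 1)
    expect_identical(fuzzy_distance(pa, pa), 0)
    s <- fisim(pa, pb)
    expect_identical(s, fisim(pb, pa)) # bit-exact symmetry
    expect_gte(s, 0); expect_lte(s, 1)
    expect_lt(abs(fuzzy_distance(pa, pb) - oracle_fuzzy_distance(unclass(pa), unclass(pb))),
              1e-12)
  }
})

test_that("sequences from one chain are closer than sequences from distant chains", {
  p_far <- transition_matrix(matrix(c(
    0.85, 0.05, 0.05, 0.05,
    0.05, 0.85, 0.05, 0.05,
    0.05, 0.05, 0.85, 0.05,
    0.05, 0.05, 0.05, 0.85), 4, byrow = TRUE))
  same1 <- simulate_sequence(chain_spec(length = 50000L, seed = 1L))
  same2 <- simulate_sequence(chain_spec(length = 50000L, seed = 2L))
  far <- simulate_sequence(chain_spec(p = p_far, length = 50000L, seed = 3L))
  tm <- lapply(list(same1, same2, far), function(r) {
    estimate_transition_matrix(count_dinucleotides(r))
  })
  d_same <- fuzzy_distance(tm[[1]], tm[[2]])
  d_far <- fuzzy_distance(tm[[1]], tm[[3]])
  expect_lt(d_same, d_far)
})
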
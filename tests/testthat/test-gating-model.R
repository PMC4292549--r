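# Generator assembly, transition matrices, propagation and stationary
# distributions.

test_that("generator assembly follows the edge rates and row-sum rule", {
  Q <- build_generator(two_state_model(1, 2))
  expect_equal(unname(Q), matrix(c(-1, 1, 2, -2), 2, 2, byrow = TRUE))

  Qw <- build_generator(vdac_model("WT"))
  off <- Qw; diag(off) <- 0
  expect_identical(sum(off > 0), 8L)
  expect_lt(max(abs(rowSums(Qw))), 1e-12)
  # non-edges stay zero
  expect_identical(unname(Qw["S1", "S2"]), 0)
  expect_identical(unname(Qw["S2", "S3"]), 0)
  expect_identical(unname(Qw["S5", "S4"]), 0)
  # published s^-1 values arrive as ms^-1
  expect_equal(unname(Qw["S1", "S3"]), 0.1416)
  expect_equal(unname(Qw["S4", "S2"]), 4e-4)
})

test_that("invalid models are rejected", {
  expect_error(two_state_model(-0.1, 1), "finite and >= 0")
  expect_error(
    gating_model(c("A", "B", "C"), c(A = "O", B = "C", C = "O_S"),
                 cbind("A", "B"), c("A->B" = 1, "B->A" = 1),
                 acyclic = FALSE),
    "not connected"
  )
  expect_error(
    gating_model(c("A", "B"), c(A = "O", B = "banana"),
                 cbind("A", "B"), c("A->B" = 1)),
    "conductance class"
  )
  expect_error(transition_matrix(matrix(c(-1, 1, 2, -2), 2, byrow = TRUE),
                                 tau = -1), "positive")
  Qbad <- matrix(c(-1, NaN, 2, -2), 2, byrow = TRUE)
  expect_error(transition_matrix(Qbad, 1), "finite")
})

test_that("transition matrix matches closed forms and stays stochastic", {
  # symmetric two-state relaxes to uniform
  Qs <- build_generator(two_state_model(1, 1))
  As <- transition_matrix(Qs, 1000)
  expect_lt(max(abs(As - 0.5)), 1e-9)

  # closed-form 2-state oracle at the recording time step
  Q <- build_generator(two_state_model(1, 2))
  expect_lt(max(abs(transition_matrix(Q, 0.2) - A2_closed_form(1, 2, 0.2))),
            1e-12)

  # first-order limit A ~ I + Q tau
  Qw <- build_generator(vdac_model("WT"))
  expect_lt(max(abs(transition_matrix(Qw, 1e-9) -
                      (diag(5) + Qw * 1e-9))), 1e-8)

  # row-stochastic with entries in [0, 1], and independent Pade oracle
  for (s in 1:5) {
    m <- random_tree_model(n = 3 + s %% 3, seed = s)
    Qm <- build_generator(m)
    A <- transition_matrix(Qm, 0.7 * s)
    expect_lt(max(abs(rowSums(A) - 1)), 1e-10)
    expect_true(all(A >= 0 & A <= 1 + 1e-12))
    ref <- as.matrix(Matrix::expm(Matrix::Matrix(Qm * 0.7 * s)))
    expect_lt(max(abs(A - ref)), 1e-11)
  }
})

test_that("semigroup property holds: A(t1 + t2) = A(t1) A(t2)", {
  for (s in 1:5) {
    m <- random_tree_model(n = 4, seed = 10 + s)
    Q <- build_generator(m)
    t1 <- 0.3 * s; t2 <- 1.1
    expect_lt(max(abs(transition_matrix(Q, t1 + t2) -
                        transition_matrix(Q, t1) %*%
                          transition_matrix(Q, t2))), 1e-9)
  }
})

test_that("propagation solves the master equation", {
  Q <- build_generator(two_state_model(1, 2))
  p0 <- c(1, 0)
  expect_identical(unname(propagate(Q, p0, 0)), p0)
  expect_error(propagate(Q, p0, -1), "non-negative")
  expect_error(propagate(Q, c(0.7, 0.7), 1), "probability")

  # closed-form 2-state occupancy: p1(t) = q21/s + (p1(0) - q21/s) e^(-s t)
  for (t in c(0.1, 0.5, 2, 10)) {
    p <- propagate(Q, p0, t)
    expect_equal(unname(p[1L]), 2 / 3 + (1 - 2 / 3) * exp(-3 * t),
                 tolerance = 1e-12)
    expect_lt(abs(sum(p) - 1), 1e-10)
  }

  # ergodic limit
  expect_lt(max(abs(propagate(Q, p0, 50) - stationary_distribution(Q))),
            1e-8)
})

test_that("stationary distribution solves pi Q = 0 and detailed balance", {
  Q <- build_generator(two_state_model(1, 2))
  expect_equal(unname(stationary_distribution(Q)), c(2 / 3, 1 / 3),
               tolerance = 1e-12)

  for (cond in c("WT", "PPN25", "PPN100", "rVDAC", "S137E")) {
    m <- vdac_model(cond)
    Qc <- build_generator(m)
    pi_ <- stationary_distribution(Qc)
    expect_lt(max(abs(pi_ %*% Qc)), 1e-12)
    expect_equal(sum(pi_), 1, tolerance = 1e-12)
    # nullspace solve against independent detailed-balance chaining
    expect_lt(max(abs(pi_ - detailed_balance_distribution(m))), 1e-10)
    # edgewise detailed balance
    for (k in seq_len(nrow(m$edges))) {
      a <- m$edges[k, 1L]; b <- m$edges[k, 2L]
      expect_lt(abs(pi_[a] * Qc[a, b] - pi_[b] * Qc[b, a]), 1e-10)
    }
    # fixed point of the sampling-interval transition matrix
    expect_lt(max(abs(pi_ %*% transition_matrix(Qc, 0.2) - pi_)), 1e-9)
  }
})

test_that("the nitrosated channel is locked closed once S4 is excluded", {
  pi_ <- stationary_distribution(build_generator(vdac_model("PPN25")))
  r <- restricted_stationary(pi_, c("S1", "S2", "S3", "S5"))
  expect_equal(unname(r[["S2"]]), 0.99, tolerance = 0.005)
})

test_that("restricted stationary renormalizes correctly", {
  pi_ <- stationary_distribution(build_generator(vdac_model("WT")))
  expect_equal(restricted_stationary(pi_, names(pi_)), pi_)
  expect_identical(unname(restricted_stationary(pi_, "S3")), 1)
  expect_error(restricted_stationary(pi_, character()), "non-empty")
  expect_error(restricted_stationary(pi_, "S9"), "unknown")
})

test_that("model files round-trip through YAML, converting s^-1 to ms^-1", {
  m <- vdac_model("PPN100")
  f <- tempfile(fileext = ".yaml")
  write_model_file(m, f)
  m2 <- read_model_file(f)
  expect_equal(m2$rates[names(m$rates)], m$rates)
  expect_identical(m2$classes[m$states], m$classes[m$states])

  # the packaged default topology matches the built-in WT model
  pkgd <- read_model_file(system.file("extdata", "vdac5_wt.yaml",
                                      package = "gatingmcmc"))
  wt <- vdac_model("WT")
  expect_equal(pkgd$rates[names(wt$rates)], wt$rates)
  expect_error(read_model_file(tempfile()), "no such file")
})
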
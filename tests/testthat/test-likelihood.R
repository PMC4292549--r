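# Projection matrices and the forward-filtered aggregated likelihood.

test_that("projection matrices select class states and sum to identity", {
  m <- vdac_model("WT")
  pr <- projection_set(m)
  expect_identical(unname(pr$index$O), 3L)
  expect_identical(unname(pr$index$C), 2L)
  expect_identical(unname(pr$index$O_S), c(1L, 4L, 5L))
  expect_equal(pr$theta$O + pr$theta$O_S + pr$theta$C, diag(5))

  pr2 <- projection_set(two_state_model())
  expect_equal(pr2$theta$O_S, matrix(0, 2, 2))
})

test_that("a single event has log-likelihood zero after conditioning", {
  m <- vdac_model("WT")
  Q <- build_generator(m)
  pr <- projection_set(m)
  for (cl in c("O", "O_S", "C")) {
    s <- event_sequence(cl, 1, 0.2)
    expect_identical(log_likelihood(s, Q, pr), 0)
    expect_identical(log_likelihood(s, Q, pr, method = "sample"), 0)
  }
})

test_that("forward filter equals exhaustive path enumeration", {
  # every class string up to length 5 on the 2-state chain
  m2 <- two_state_model(1, 2)
  Q2 <- build_generator(m2)
  pr2 <- projection_set(m2)
  for (n in 1:5) {
    for (cls in all_class_strings(c("O", "C"), n)) {
      s <- seq_from_string(cls)
      expect_equal(log_likelihood(s, Q2, pr2),
                   brute_force_loglik(cls, m2), tolerance = 1e-12)
    }
  }
  # all three-class strings up to length 4 on the 5-state model
  m5 <- vdac_model("WT")
  Q5 <- build_generator(m5)
  pr5 <- projection_set(m5)
  for (n in 1:4) {
    for (cls in all_class_strings(c("O", "O_S", "C"), n)) {
      s <- seq_from_string(cls)
      expect_equal(log_likelihood(s, Q5, pr5),
                   brute_force_loglik(cls, m5), tolerance = 1e-10)
    }
  }
})

test_that("run-compressed and per-sample recursions agree on long data", {
  fx <- make_fixture("WT", duration = 4e3, seed = 21, noise_sd = 0)
  Q <- build_generator(fx$model)
  pr <- projection_set(fx$model)
  lr <- log_likelihood(fx$events, Q, pr, method = "run")
  ls <- log_likelihood(fx$events, Q, pr, method = "sample")
  expect_lt(abs(lr - ls) / abs(ls), 1e-9)

  # unscaled direct product on a short prefix as a second reference
  short <- event_sequence(fx$events$classes[1:3],
                          pmin(fx$events$lengths[1:3], 10), 0.2)
  A <- transition_matrix(Q, 0.2)
  cls <- rep(short$classes, short$lengths)
  p0 <- stationary_distribution(Q)
  v <- rep(0, 5); ix <- pr$index[[cls[1]]]
  v[ix] <- p0[ix]; v <- v / sum(v)
  for (k in seq_along(cls)[-1]) {
    v <- as.numeric(v %*% A)
    w <- rep(0, 5); w[pr$index[[cls[k]]]] <- v[pr$index[[cls[k]]]]
    v <- w
  }
  expect_equal(log_likelihood(short, Q, pr), log(sum(v)),
               tolerance = 1e-10)
})

test_that("likelihood identifies the generating rates on simulated data", {
  fx <- make_fixture("WT", duration = 2e3, seed = 31, noise_sd = 0)
  m <- fx$model
  pr <- projection_set(m)
  ll_true <- log_likelihood(fx$events, build_generator(m), pr)
  doubled <- set_model_rates(m, model_rates(m) * 2)
  ll_doubled <- log_likelihood(fx$events, build_generator(doubled), pr)
  expect_gt(ll_true, ll_doubled)
})

test_that("identity projections conserve total probability", {
  # with every state allowed at every step the filter sums to one
  m <- vdac_model("WT")
  Q <- build_generator(m)
  pr <- projection_set(m)
  pr$index <- lapply(pr$index, function(i) 1:5)
  pr$theta <- lapply(pr$theta, function(th) diag(5))
  s <- event_sequence(c("O", "C", "O_S"), c(10, 20, 30), 0.2)
  expect_equal(log_likelihood(s, Q, pr), 0, tolerance = 1e-10)
})

test_that("likelihood is invariant to relabeling states within a class", {
  # swap the hidden labels S1 <-> S5 (both sub-conductance) with their rates
  r <- model_rates(vdac_model("WT"))
  swapped <- gating_model(
    paste0("S", 1:5),
    c(S1 = "O_S", S2 = "C", S3 = "O", S4 = "O_S", S5 = "O_S"),
    rbind(c("S5", "S3"), c("S5", "S1"), c("S3", "S4"), c("S2", "S4")),
    c("S5->S3" = unname(r["S1->S3"]), "S3->S5" = unname(r["S3->S1"]),
      "S5->S1" = unname(r["S1->S5"]), "S1->S5" = unname(r["S5->S1"]),
      "S3->S4" = unname(r["S3->S4"]), "S4->S3" = unname(r["S4->S3"]),
      "S2->S4" = unname(r["S2->S4"]), "S4->S2" = unname(r["S4->S2"]))
  )
  fx <- make_fixture("WT", duration = 2e3, seed = 41, noise_sd = 0)
  ll1 <- log_likelihood(fx$events, build_generator(vdac_model("WT")),
                        projection_set(vdac_model("WT")))
  ll2 <- log_likelihood(fx$events, build_generator(swapped),
                        projection_set(swapped))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("structurally impossible sequences get -Inf", {
  m2 <- two_state_model()  # no sub-conductance state
  s <- seq_from_string(c("O", "O_S", "C"))
  expect_identical(log_likelihood(s, build_generator(m2),
                                  projection_set(m2)), -Inf)
})

test_that("joint likelihood is additive over independent traces", {
  fx <- make_fixture("PPN25", duration = 2e3, seed = 51, noise_sd = 0)
  Q <- build_generator(fx$model)
  pr <- projection_set(fx$model)
  one <- log_likelihood(fx$events, Q, pr)
  j2 <- joint_log_likelihood(list(fx$events, fx$events), Q, pr)
  expect_equal(j2$value, 2 * one, tolerance = 1e-12)

  seqs <- lapply(1:5, function(k) {
    f <- make_fixture("PPN25", duration = 1e3, seed = 60 + k,
                      noise_sd = 0)
    f$events
  })
  jj <- joint_log_likelihood(seqs, Q, pr)
  expect_equal(jj$value, sum(vapply(seqs, log_likelihood, 0, Q = Q,
                                    proj = pr)), tolerance = 1e-12)
  expect_identical(length(jj$per_trace), 5L)

  expect_error(joint_log_likelihood(list(), Q, pr), "non-empty")
  mixed <- list(seqs[[1]], event_sequence("O", 5, 0.4))
  expect_error(joint_log_likelihood(mixed, Q, pr), "sampling interval")
})
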
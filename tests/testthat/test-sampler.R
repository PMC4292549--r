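# Prior, proposal, acceptance rule and the Metropolis-Hastings chain.

test_that("log prior is the exponential rate penalty", {
  m <- two_state_model(0, 0)
  expect_identical(log_prior(build_generator(m)), 0)
  m30 <- two_state_model(30, 30)
  expect_equal(log_prior(build_generator(m30), prior_spec(30)), -2,
               tolerance = 1e-12)
  # doubling rates decreases the log prior
  Q1 <- build_generator(two_state_model(1, 2))
  Q2 <- build_generator(two_state_model(2, 4))
  expect_lt(log_prior(Q2), log_prior(Q1))
  expect_error(prior_spec(0), "positive")
})

test_that("proposals perturb every rate uniformly and flag negatives", {
  r <- c("A->B" = 0.5, "B->A" = 0.3)
  # tiny delta: proposal is essentially the current point
  p <- propose_rates(r, proposal_spec(1e-12))
  expect_true(p$ok)
  expect_equal(p$rates, r, tolerance = 1e-10)

  # a near-zero rate with a wide proposal goes negative and is flagged
  set.seed(2)
  flags <- replicate(200, propose_rates(c("A->B" = 1e-4, "B->A" = 0.5),
                                        proposal_spec(0.05))$ok)
  expect_true(any(!flags))
  expect_true(mean(!flags) > 0.3 && mean(!flags) < 0.7)

  # empirical distribution of one coordinate is U[q - delta, q + delta]
  set.seed(3)
  draws <- replicate(1e5, propose_rates(r, proposal_spec(0.01))$rates[1L])
  ks <- suppressWarnings(stats::ks.test(draws, "punif", 0.49, 0.51))
  expect_gt(ks$p.value, 0.01)

  # per-rate delta schedule
  set.seed(4)
  pr <- propose_rates(r, proposal_spec(c("A->B" = 1e-9, "B->A" = 0.1)))
  expect_lt(abs(pr$rates["A->B"] - 0.5), 1e-8)
})

test_that("acceptance probability implements the MH ratio", {
  expect_identical(acceptance_probability(-10, -10), 1)
  expect_identical(acceptance_probability(-10, -Inf), 0)
  expect_equal(acceptance_probability(-10, -10 - log(2)), 0.5,
               tolerance = 1e-12)
  expect_identical(acceptance_probability(-10, -5), 1)
})

test_that("chains are bitwise reproducible given a seed", {
  fx <- make_fixture("WT", duration = 1e3, seed = 71, noise_sd = 0)
  m <- vdac_model("WT")
  ch1 <- run_chain(fx$events, m, n_iter = 300, burn_in = 100, seed = 99)
  ch2 <- run_chain(fx$events, m, n_iter = 300, burn_in = 100, seed = 99)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$accepted, ch2$accepted)
  expect_identical(ch1$log_post, ch2$log_post)
})

test_that("acceptance decisions depend only on log-posterior differences", {
  m <- two_state_model(0.2, 0.2)
  base <- function(Q) -50 * ((Q[1, 2] - 0.2)^2 + (Q[2, 1] - 0.2)^2)
  ch1 <- run_chain(list(event_sequence("O", 2, 0.2)), m, n_iter = 500,
                   burn_in = 100, seed = 7, loglik_fn = base)
  ch2 <- run_chain(list(event_sequence("O", 2, 0.2)), m, n_iter = 500,
                   burn_in = 100, seed = 7,
                   loglik_fn = function(Q) base(Q) + 1234.5)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$accepted, ch2$accepted)
})

test_that("a chain that can accept nothing warns with delta guidance", {
  m <- two_state_model(0.1, 0.1)
  sharp <- function(Q) -1e8 * ((Q[1, 2] - 0.1)^2 + (Q[2, 1] - 0.1)^2)
  expect_warning(
    run_chain(list(event_sequence("O", 2, 0.2)), m, n_iter = 1000,
              burn_in = 10, seed = 5, proposal = proposal_spec(0.05),
              loglik_fn = sharp),
    "delta"
  )
})

test_that("chain marginals match dense quadrature of the posterior", {
  # two-state toy: the posterior over (q12, q21) is low-dimensional enough
  # to integrate numerically on a grid and compare with the sampler
  m <- two_state_model(0.5, 0.25)
  fxQ <- build_generator(m)
  pr <- projection_set(m)
  set.seed(13)
  path <- gillespie_path(m, duration = 100, seed = 13)
  seq <- discretize(path, 0.2, m)
  prior <- prior_spec(30)

  lp_fun <- function(q12, q21) {
    mq <- set_model_rates(m, c("A->B" = q12, "B->A" = q21))
    Qq <- build_generator(mq)
    log_likelihood(seq, Qq, pr) + log_prior(Qq, prior)
  }
  g <- seq(0.01, 1.8, length.out = 70)
  lp <- outer(g, g, Vectorize(lp_fun))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  quad_mean_q12 <- sum(rowSums(w) * g)
  quad_mean_q21 <- sum(colSums(w) * g)

  ch <- run_chain(seq, m, n_iter = 20000, burn_in = 5000,
                  proposal = proposal_spec(0.08), seed = 17)
  s <- summary(ch)$table
  expect_gt(ch$acceptance_rate, 0.05)
  # agree within a few Monte-Carlo standard errors
  expect_lt(abs(s$mean[s$rate == "A->B"] - quad_mean_q12),
            6 * s$se[s$rate == "A->B"] + 0.02)
  expect_lt(abs(s$mean[s$rate == "B->A"] - quad_mean_q21),
            6 * s$se[s$rate == "B->A"] + 0.02)
})

test_that("summaries use post-burn-in samples and validate their input", {
  m <- two_state_model(0.3, 0.3)
  ch <- run_chain(list(event_sequence("O", 2, 0.2)), m, n_iter = 600,
                  burn_in = 200, seed = 23, loglik_fn = function(Q) 0,
                  proposal = proposal_spec(5))
  s <- summary(ch)
  expect_identical(s$n, 400L)
  expect_identical(nrow(s$table), 2L)
  expect_true(all(s$table$lower <= s$table$mean))
  expect_true(all(s$table$upper >= s$table$mean))
  expect_identical(length(s$histograms), 2L)

  expect_error(run_chain(list(event_sequence("O", 2, 0.2)), m,
                         n_iter = 100, burn_in = 100), "burn_in")
  ch$burn_in <- 550
  expect_error(summary(ch), "100 post-burn-in")
})

test_that("proposal tuning reaches the target acceptance window", {
  fx <- make_fixture("WT", duration = 3e4, seed = 81, noise_sd = 0)
  m <- vdac_model("WT")
  pil <- tune_proposal(fx$events, m, n_sweeps = 500, seed = 3)
  expect_true(all(pil$delta >= 1e-5 & pil$delta <= 0.05))
  expect_true(all(pil$rates >= 0))
  # the slow exit rates out of the dominant sub-conductance state are the
  # best-identified parameters: the pilot must have pulled them well below
  # the neutral 0.1 ms^-1 start toward the generating ~(2-4)e-4 ms^-1
  expect_lt(pil$rates["S4->S2"], 0.05)
  expect_lt(pil$rates["S4->S3"], 0.05)
})

test_that("topology comparison ranks candidates and flags impossibility", {
  fx <- make_fixture("WT", duration = 1e4, seed = 91, noise_sd = 0)
  m5 <- vdac_model("WT")
  m2 <- two_state_model(0.1, 0.1)
  cmp <- compare_topologies(fx$events, list(full = m5, oc_only = m2),
                            n_iter = 400, burn_in = 200, seed = 1)
  expect_s3_class(cmp, "topology_comparison")
  expect_identical(cmp$model[nrow(cmp)], "oc_only")
  expect_identical(cmp$max_log_post[nrow(cmp)], -Inf)
  expect_true(is.finite(cmp$max_log_post[1L]))
  expect_identical(cmp$model[1L], "full")

  expect_error(compare_topologies(fx$events, list(only = m5)),
               "at least two")
})
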
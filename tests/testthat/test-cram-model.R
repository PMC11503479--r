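test_that("migration probability is the probit of the liability predictor", {
  expect_equal(psi_prob(0, 0, 0), 0.5)
  expect_equal(psi_prob(1.3, 0, 0), psi_prob(0, 1.3, 0))
  expect_equal(psi_prob(1.0, 0.5, -0.2), pnorm(1.3))
  expect_error(psi_prob(Inf), "finite")
})

test_that("transition rows are the stated kernels and sum to one", {
  # certain survival, certain residence
  tm <- transition_matrix(0, 0.5, 0.2, 1, 1)
  expect_equal(unname(tm["R", ]), c(1, 0, 0, 0))
  expect_equal(unname(tm["M1", ]), c(1, 0, 0, 0))
  # certain death
  tm <- transition_matrix(0.5, 0.5, 0.2, 0, 0)
  for (st in c("R", "M1", "M2")) {
    expect_equal(unname(tm[st, ]), c(0, 0, 0, 1))
  }
  # dead absorbing, stochastic rows in general
  set.seed(33)
  for (k in 1:25) {
    tm <- transition_matrix(runif(1), runif(1), runif(1), runif(1), runif(1))
    expect_equal(unname(rowSums(tm)), rep(1, 4), tolerance = 1e-12)
    expect_equal(unname(tm["Dead", ]), c(0, 0, 0, 1))
    expect_true(all(tm >= 0))
  }
  # settlement and switching structure
  tm <- transition_matrix(1, 0.3, 0.1, 1, 1)
  expect_equal(unname(tm["R", c("M1", "M2")]), c(0.3, 0.7))
  expect_equal(unname(tm["M1", c("M1", "M2")]), c(0.9, 0.1))
  expect_equal(unname(tm["M2", c("M1", "M2")]), c(0.1, 0.9))
  expect_error(transition_matrix(1.2, 0.5, 0.5, 0.5, 0.5), "psi")
})

test_that("emission probabilities follow the detection model", {
  expect_equal(emission_prob("R", "R", 0.7), 0.7)
  expect_equal(emission_prob("R", "0", 0.7), 0.3)
  expect_equal(emission_prob("R", "M1", 0.7), 0)
  expect_equal(emission_prob("M2", "M2", 0.15), 0.15)
  expect_equal(emission_prob("Dead", "0", 0.7), 1)
  expect_equal(emission_prob("Dead", "R", 0.7), 0)
  # emission distribution over events sums to one for every state
  for (st in c("R", "M1", "M2", "Dead")) {
    tot <- sum(vapply(c("0", "R", "M1", "M2"),
                      function(e) emission_prob(st, e, 0.4), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("forward log-likelihood equals brute-force path enumeration", {
  params <- random_params(101)
  set.seed(202)
  worst <- 0
  for (k in 1:50) {
    ev <- random_events()
    coh <- sample(params$cohorts, 1)
    a <- rnorm(2, 0, 0.7); b <- rnorm(2, 0, 0.7)
    ll <- individual_loglik(ev, coh, params, a, b)
    worst <- max(worst, abs(ll - oracle_path_loglik(ev, coh, params, a, b)))
  }
  expect_lt(worst, 1e-10)
})

test_that("degenerate parameter sets give exact likelihoods", {
  C <- 1L
  params <- cram_params(2010L, mu = matrix(-20, 4, C), sigma_a = c(0, 0),
                        sigma_b = c(0, 0), phi_R = matrix(1, 5, C),
                        phi_M = matrix(1, 4, C), delta = matrix(0.5, 4, C),
                        gamma = matrix(0.2, 3, C),
                        p = array(1, c(3, 4, C)), p6 = 1)
  # certain survival + detection + residence: all-seen-R has probability 1
  ev <- c("R", "R", "R", "R", "R", "1")
  expect_equal(individual_loglik(ev, 2010L, params), 0)

  # a never-seen-again history is impossible under certain detection and
  # survival, but likely under low survival
  never <- c("R", "0", "0", "0", "0", "0")
  expect_error(individual_loglik(never, 2010L, params), "underflow")
  low_phi <- params
  low_phi$phi_R[] <- 0.3; low_phi$phi_M[] <- 0.3
  expect_gt(individual_loglik(never, 2010L, low_phi), log(0.5))
})

test_that("likelihood is invariant to relabelling M1/M2 with delta, p swap", {
  params <- random_params(77)
  swapped <- params
  swapped$delta <- 1 - params$delta
  swapped$p[c(2, 3), , ] <- params$p[c(3, 2), , ]
  swap_ev <- c(R = "R", M1 = "M2", M2 = "M1", "0" = "0", "1" = "1")
  set.seed(88)
  for (k in 1:20) {
    ev <- random_events()
    coh <- sample(params$cohorts, 1)
    ll1 <- individual_loglik(ev, coh, params)
    ll2 <- individual_loglik(unname(swap_ev[ev]), coh, swapped)
    expect_equal(ll1, ll2, tolerance = 1e-12)
  }
})

test_that("C++ batch likelihood matches the R forward algorithm", {
  params <- random_params(55)
  set.seed(66)
  n <- 40L
  hh <- data.frame(
    id = sprintf("x%02d", 1:n),
    cohort = sample(params$cohorts, n, replace = TRUE),
    e1 = "R",
    e2 = sample(c("R", "M1", "M2", "0"), n, replace = TRUE),
    e3 = sample(c("R", "M1", "M2", "0"), n, replace = TRUE),
    e4 = sample(c("R", "M1", "M2", "0"), n, replace = TRUE),
    e5 = sample(c("R", "M1", "M2", "0"), n, replace = TRUE),
    e6 = sample(c("0", "1"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  class(hh) <- c("encounter_histories", "data.frame")
  a <- matrix(rnorm(2 * n, 0, 0.5), n, 2, dimnames = list(hh$id, NULL))
  b <- matrix(rnorm(2 * n, 0, 0.5), n, 2, dimnames = list(hh$id, NULL))
  llR <- cram_loglik(hh, params, a, b)
  llC <- cramr:::cram_loglik_cpp(
    cramr:::encode_events(hh), match(hh$cohort, params$cohorts) - 1L,
    c(0L, 0L, 1L, 1L), params$mu, params$phi_R, params$phi_M,
    params$delta, params$gamma, matrix(params$p, nrow = 12), params$p6,
    a, b)
  expect_equal(llR, llC, tolerance = 1e-12)
})

test_that("the structural prior has the stated support and shape", {
  params <- random_params(9)
  cfg <- cram_config()
  expect_true(is.finite(log_prior(params, cfg)))

  neg <- params; neg$sigma_a[1] <- -0.5
  expect_identical(log_prior(neg, cfg), -Inf)
  oob <- params; oob$phi_R[1, 1] <- 1.4
  expect_identical(log_prior(oob, cfg), -Inf)

  # doubling the t scale flattens the intercept prior: the density drops
  # less at large |mu| than at zero
  p0 <- params; p0$mu[] <- 0
  pL <- params; pL$mu[] <- 8
  wide <- cram_config(priors = list(mu_scale = 5))
  drop0 <- log_prior(p0, cfg) - log_prior(p0, wide)
  dropL <- log_prior(pL, cfg) - log_prior(pL, wide)
  expect_gt(drop0, dropL)

  # M2 detection prior mass concentrates at low probabilities
  lo <- params; lo$p[3, , ] <- 0.05
  hi <- params; hi$p[3, , ] <- 0.9
  expect_gt(log_prior(lo, cfg), log_prior(hi, cfg))
})

test_that("prior-predictive migration probability is median 0.5", {
  # mu* ~ t is symmetric about 0, so with a = b = 0 the implied psi has
  # median Phi(0) = 0.5
  set.seed(12)
  mu <- 2.5 * rt(20000, df = 3)
  psi <- psi_prob(mu)
  expect_equal(median(psi), 0.5, tolerance = 0.02)
})

test_that("fits are reproducible and expose diagnostics", {
  sc <- default_scenario(n_cohorts = 1L)
  sc$n_founders <- 24L; sc$n_generations <- 2L; sc$mean_brood <- 2.2
  dat <- simulate_cram_data(sc, seed = 15)
  cfg <- cram_config(chains = 2L, warmup = 60L, iter = 60L)
  f1 <- suppressWarnings(suppressMessages(
    cram_fit(dat$histories, dat$pedigree, cfg, seed = 5, A = dat$A)))
  f2 <- suppressWarnings(suppressMessages(
    cram_fit(dat$histories, dat$pedigree, cfg, seed = 5, A = dat$A)))
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 120L)
  expect_true(all(c("rhat", "ess") %in% names(f1$diagnostics)))
  expect_true(all(grepl("^(mu|sigma|phi|delta|gamma|p|loglik)", f1$pars)))
  # draws file round trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(f1, path)
  rd <- read_draws(path)
  expect_equal(unname(rd$draws), unname(f1$draws), tolerance = 1e-8)
  expect_equal(rd$seasons, c("autumn", "winter"))
})
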
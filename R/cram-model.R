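#' Migration probability from liability components
#'
#' The probability that an individual expresses the migrant phenotype at an
#' occasion is the probability that its latent liability exceeds the
#' threshold. On the standardized liability scale (threshold 0, residual SD
#' 1) this is the probit-inverse of the linear predictor:
#' \deqn{\psi = \Phi(\mu^* + a^* + b^*)}
#' with occasion-by-cohort intercept \eqn{\mu^*}, season-specific breeding
#' value \eqn{a^*} and permanent individual effect \eqn{b^*}.
#'
#' @param mu_star,a_star,b_star Liability components (standardized scale).
#' @return Migration probability in (0, 1). Vectorized.
#' @export
psi_prob <- function(mu_star, a_star = 0, b_star = 0) {
  eta <- mu_star + a_star + b_star
  if (any(!is.finite(eta))) stopf("non-finite liability predictor")
  stats::pnorm(eta)
}

# state order used throughout: 1 = R, 2 = M1, 3 = M2, 4 = Dead
STATES <- c("R", "M1", "M2", "Dead")

#' Between-occasion state-transition matrix
#'
#' Builds the 4x4 transition kernel over states \{R, M1, M2, Dead\} for one
#' between-occasion interval. A surviving individual (probability
#' `phi_R`/`phi_M` by current state class) expresses migration with
#' probability `psi` or residence with `1 - psi`. A new migrant settles at
#' the regularly surveyed site M1 with probability `delta`, else at an
#' irregularly surveyed site M2; a continuing migrant switches site class
#' with probability `gamma`. Dead is absorbing.
#'
#' @param psi Migration probability for the target occasion.
#' @param delta Probability a newly migrant individual settles in M1.
#' @param gamma Site-switching probability between M1 and M2.
#' @param phi_R,phi_M Survival probabilities from a resident / migrant state.
#' @return 4x4 matrix, rows = current state, columns = next state; each row
#'   sums to 1.
#' @export
transition_matrix <- function(psi, delta, gamma, phi_R, phi_M) {
  for (nm in c("psi", "delta", "gamma", "phi_R", "phi_M")) {
    assert_prob(get(nm), nm)
  }
  m <- rbind(
    R    = c(phi_R * (1 - psi), phi_R * psi * delta,
             phi_R * psi * (1 - delta), 1 - phi_R),
    M1   = c(phi_M * (1 - psi), phi_M * psi * (1 - gamma),
             phi_M * psi * gamma, 1 - phi_M),
    M2   = c(phi_M * (1 - psi), phi_M * psi * gamma,
             phi_M * psi * (1 - gamma), 1 - phi_M),
    Dead = c(0, 0, 0, 1))
  colnames(m) <- STATES
  m
}

#' Resighting emission probability
#'
#' Probability of an event code given the latent state: an alive individual
#' is seen in its current state with its state-specific detection
#' probability, never in another state, and missed otherwise; dead
#' individuals are never seen.
#'
#' @param state One of `"R"`, `"M1"`, `"M2"`, `"Dead"`.
#' @param event One of `"R"`, `"M1"`, `"M2"` (seen in that state) or `"0"`
#'   (not seen).
#' @param p_state Detection probability for the individual's current state.
#' @return Emission probability.
#' @export
emission_prob <- function(state, event, p_state) {
  state <- match.arg(state, STATES)
  event <- match.arg(event, c("0", "R", "M1", "M2"))
  assert_prob(p_state)
  if (state == "Dead") return(if (event == "0") 1 else 0)
  if (event == "0") return(1 - p_state)
  if (event == state) p_state else 0
}

#' Structural CRAM parameter set
#'
#' Collects all structural probabilities and liability components for a
#' model with occasions 1–6 (events observed at 2–5, a state-free "ever
#' after" occasion 6) and `C` cohorts. Between-occasion intervals are
#' numbered 1–5 (interval `t` leads into occasion `t + 1`).
#'
#' @param cohorts Cohort labels (length `C`).
#' @param mu 4 x C matrix of liability intercepts for occasions 2–5.
#' @param sigma_a,sigma_b Additive genetic / permanent individual SDs, one
#'   per season (standardized liability scale).
#' @param phi_R 5 x C survival probabilities from state R for intervals 1–5.
#' @param phi_M 4 x C survival from the migrant states for intervals 2–5
#'   (no individual can be migrant before occasion 2).
#' @param delta 4 x C settlement probabilities (into occasions 2–5).
#' @param gamma 3 x C site-switching probabilities (into occasions 3–5).
#' @param p 3 x 4 x C detection probabilities (state R/M1/M2 by occasion
#'   2–5 by cohort).
#' @param p6 Ever-after detection probability per cohort.
#' @param season_of_occ Season index of occasions 2–5; the default
#'   `c(1, 1, 2, 2)` is the autumn/winter split, `rep(1, 4)` gives the
#'   annual variance structure.
#' @return A validated `cram_params` list.
#' @export
cram_params <- function(cohorts, mu, sigma_a, sigma_b, phi_R, phi_M,
                        delta, gamma, p, p6,
                        season_of_occ = c(1L, 1L, 2L, 2L)) {
  C <- length(cohorts)
  mu <- matrix(mu, 4L, C); phi_R <- matrix(phi_R, 5L, C)
  phi_M <- matrix(phi_M, 4L, C); delta <- matrix(delta, 4L, C)
  gamma <- matrix(gamma, 3L, C)
  p <- array(p, dim = c(3L, 4L, C))
  stopifnot(length(p6) == C)
  S <- max(season_of_occ)
  stopifnot(length(sigma_a) == S, length(sigma_b) == S,
            all(season_of_occ %in% seq_len(S)))
  if (any(c(sigma_a, sigma_b) < 0)) stopf("liability SDs must be >= 0")
  for (nm in c("phi_R", "phi_M", "delta", "gamma", "p", "p6")) {
    assert_prob(get(nm), nm)
  }
  structure(list(cohorts = cohorts, mu = mu, sigma_a = sigma_a,
                 sigma_b = sigma_b, phi_R = phi_R, phi_M = phi_M,
                 delta = delta, gamma = gamma, p = p, p6 = p6,
                 season_of_occ = as.integer(season_of_occ)),
            class = "cram_params")
}

#' Marginal log-likelihood of one encounter history
#'
#' Forward-algorithm marginalization over all latent state paths through
#' occasions 2–6, conditional on the known occasion-1 state R. Probabilities
#' are renormalized at every step with log-space accumulation, so long
#' never-seen histories cannot underflow.
#'
#' @param events Character vector of 6 event codes (`"R"`, `"M1"`, `"M2"`,
#'   `"0"` for occasions 1–5; `"1"`/`"0"` for occasion 6), or a single row of
#'   an `encounter_histories` data frame.
#' @param cohort Cohort label (matched against `params$cohorts`).
#' @param params A `cram_params` object.
#' @param a,b The individual's season-specific breeding values and
#'   individual effects (length = number of seasons; default 0).
#' @return Log-probability of the history.
#' @export
individual_loglik <- function(events, cohort, params, a = NULL, b = NULL) {
  if (is.data.frame(events)) {
    cohort <- events$cohort
    events <- unlist(events[paste0("e", 1:6)], use.names = FALSE)
  }
  stopifnot(length(events) == 6L)
  S <- length(params$sigma_a)
  a <- a %||% numeric(S); b <- b %||% numeric(S)
  ci <- match(cohort, params$cohorts)
  if (is.na(ci)) stopf("cohort %s not in params", cohort)

  alpha <- c(1, 0, 0, 0)           # occasion 1: R with certainty
  ll <- 0
  for (t in 1:4) {                 # interval t -> occasion o = t + 1
    s <- params$season_of_occ[t]
    psi <- psi_prob(params$mu[t, ci], a[s], b[s])
    tm <- transition_matrix(psi,
                            params$delta[t, ci],
                            if (t >= 2) params$gamma[t - 1L, ci] else 0,
                            params$phi_R[t, ci],
                            if (t >= 2) params$phi_M[t - 1L, ci] else 1)
    alpha <- as.numeric(alpha %*% tm)
    ev <- events[t + 1L]
    pdet <- params$p[, t, ci]
    emis <- switch(ev,
                   "0" = c(1 - pdet, 1),
                   "R" = c(pdet[1], 0, 0, 0),
                   "M1" = c(0, pdet[2], 0, 0),
                   "M2" = c(0, 0, pdet[3], 0),
                   stopf("invalid event code '%s' at occasion %d", ev, t + 1L))
    alpha <- alpha * emis
    norm <- sum(alpha)
    if (!is.finite(norm) || norm < 1e-300) {
      stopf("forward probability underflow/invalid at occasion %d", t + 1L)
    }
    ll <- ll + log(norm)
    alpha <- alpha / norm
  }
  # occasion 6: state-dependent survival over interval 5, state-free detection
  phiR5 <- params$phi_R[5L, ci]; phiM5 <- params$phi_M[4L, ci]
  alive <- alpha[1] * phiR5 + (alpha[2] + alpha[3]) * phiM5
  dead <- alpha[4] + alpha[1] * (1 - phiR5) +
    (alpha[2] + alpha[3]) * (1 - phiM5)
  pr6 <- if (events[6] == "1") alive * params$p6[ci]
         else alive * (1 - params$p6[ci]) + dead
  if (!is.finite(pr6) || pr6 < 1e-300) {
    stopf("forward probability underflow/invalid at occasion 6")
  }
  ll + log(pr6)
}

#' Log-likelihood of a set of encounter histories
#'
#' @param histories An `encounter_histories` data frame.
#' @param params A `cram_params` object.
#' @param a,b Optional matrices (individuals x seasons, rownames = ids) of
#'   breeding values and individual effects; zero when omitted.
#' @return Numeric vector of per-individual log-likelihoods.
#' @export
cram_loglik <- function(histories, params, a = NULL, b = NULL) {
  S <- length(params$sigma_a)
  n <- nrow(histories)
  get_re <- function(m, i) {
    if (is.null(m)) numeric(S)
    else m[match(histories$id[i], rownames(m)), ]
  }
  vapply(seq_len(n), function(i) {
    individual_loglik(unlist(histories[i, paste0("e", 1:6)], use.names = FALSE),
                      histories$cohort[i], params,
                      a = get_re(a, i), b = get_re(b, i))
  }, numeric(1))
}

#' Sampler and prior configuration
#'
#' @param structure `"seasonal"` (two independent additive-genetic /
#'   individual variance pairs, autumn and winter) or `"annual"` (a single
#'   pair spanning occasions 2–5).
#' @param extra_effect Optional additional iid random effect on the
#'   liability: `"none"`, `"brood"` (sire-dam-cohort group), `"maternal"`
#'   (dam) or `"paternal"` (sire); used to check robustness of the additive
#'   variance to common-environment resemblance among close kin.
#' @param chains,warmup,iter,thin MCMC run lengths. Totals are per chain;
#'   `iter` draws are retained after `warmup` adaptation iterations.
#' @param priors Prior hyperparameters: Student-t(df, 0, scale) on the
#'   intercepts, half-t(df, 0, scale) on the SDs, uniform(0,1) on all
#'   structural probabilities except M2 detection, which gets a
#'   Beta(`pM2_shape`) prior representing known-low detection at
#'   irregularly surveyed sites.
#' @param rhat_max,ess_min Convergence tolerance applied by [cram_fit()];
#'   `on_bad_convergence` chooses between `"warn"` and `"error"`.
#' @return A `cram_config` list.
#' @export
cram_config <- function(structure = c("seasonal", "annual"),
                        extra_effect = c("none", "brood", "maternal", "paternal"),
                        chains = 4L, warmup = 1000L, iter = 2000L, thin = 1L,
                        priors = list(), rhat_max = 1.1, ess_min = 100,
                        on_bad_convergence = c("warn", "error")) {
  pr <- utils::modifyList(list(mu_df = 3, mu_scale = 2.5,
                               sigma_df = 3, sigma_scale = 2.5,
                               pM2_shape = c(1, 9)), priors)
  structure(list(structure = match.arg(structure),
                 extra_effect = match.arg(extra_effect),
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin),
                 priors = pr, rhat_max = rhat_max, ess_min = ess_min,
                 on_bad_convergence = match.arg(on_bad_convergence)),
            class = "cram_config")
}

# log density of the half-t prior on an SD parameter
log_half_t <- function(x, df, scale) {
  ifelse(x < 0, -Inf,
         log(2) + stats::dt(x / scale, df, log = TRUE) - log(scale))
}

#' Joint log-prior of the structural parameters
#'
#' Uniform(0,1) on all probability parameters except M2 detection
#' (Beta prior, defaults to mean 0.1), Student-t on the liability
#' intercepts and half-t on the liability SDs. Individual random effects
#' are part of the hierarchical likelihood, not of this prior.
#'
#' @param params A `cram_params` object.
#' @param config A `cram_config` (for hyperparameters).
#' @return Log prior density; `-Inf` outside the support.
#' @export
log_prior <- function(params, config = cram_config()) {
  pr <- config$priors
  probs <- c(params$phi_R, params$phi_M, params$delta, params$gamma,
             params$p, params$p6)
  if (any(probs < 0 | probs > 1) || any(c(params$sigma_a, params$sigma_b) < 0)) {
    return(-Inf)
  }
  pM2 <- params$p[3, , , drop = FALSE]
  lp <- sum(stats::dbeta(pM2, pr$pM2_shape[1], pr$pM2_shape[2], log = TRUE))
  lp <- lp + sum(stats::dt(params$mu / pr$mu_scale, pr$mu_df, log = TRUE) -
                   log(pr$mu_scale))
  lp + sum(log_half_t(c(params$sigma_a, params$sigma_b),
                      pr$sigma_df, pr$sigma_scale))
}
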
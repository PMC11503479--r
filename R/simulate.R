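# Synthetic-data generator: pedigrees, liabilities, latent state
# trajectories and imperfect-detection encounter histories with exactly the
# statistical structure the CRAM assumes, for testing and parameter-recovery
# calibration.

#' Default desk-scale simulation scenario
#'
#' A multi-generation pedigree whose final generation (about 600 juveniles
#' in 2 cohorts) is phenotyped, with liability and observation parameters in
#' the ranges typical of partially migratory seabird resighting studies:
#' additive genetic variances 0.8 (autumn) / 0.5 (winter), individual
#' variances 2.3 / 3.5, liability intercepts ramping from -0.5 to +1 across
#' occasions 2-5 (residence giving way to migration through the year),
#' survival 0.75-0.85, resident/M1 detection 0.5-0.7 with low (0.1)
#' detection at irregularly surveyed migrant sites.
#'
#' @param n_cohorts Number of phenotyped cohorts.
#' @param base_year First cohort year.
#' @return List with pedigree-growth settings and the true `cram_params`.
#' @export
default_scenario <- function(n_cohorts = 2L, base_year = 2010L) {
  cohorts <- base_year + seq_len(n_cohorts) - 1L
  C <- n_cohorts
  params <- cram_params(
    cohorts = cohorts,
    mu = matrix(c(-0.5, 0, 0.5, 1), 4L, C),
    sigma_a = sqrt(c(0.8, 0.5)),
    sigma_b = sqrt(c(2.3, 3.5)),
    phi_R = matrix(0.85, 5L, C),
    phi_M = matrix(0.75, 4L, C),
    delta = matrix(0.6, 4L, C),
    gamma = matrix(0.2, 3L, C),
    p = array(rep(c(0.7, 0.5, 0.1), 4L * C), dim = c(3L, 4L, C)),
    p6 = rep(0.7, C))
  list(n_founders = 350L, n_generations = 3L, mean_brood = 2.3,
       n_cohorts = n_cohorts, base_year = as.integer(base_year),
       params = params)
}

#' Simulate a discrete-generation pedigree
#'
#' Founders pair monogamously at random within each generation; each pair
#' produces a Poisson-distributed brood (minimum 1). The final generation is
#' the phenotyped ("focal") one and its broods are assigned whole to one of
#' `n_cohorts` consecutive cohort years, so the focal set carries dense
#' full-sib and cross-generation links, as in colony-based ringing studies.
#'
#' @param n_founders Founder population size (at least 2).
#' @param n_generations Number of offspring generations.
#' @param mean_brood Poisson mean brood size.
#' @param n_cohorts Cohort years spanned by the final generation.
#' @param base_year First focal cohort year; earlier generations get
#'   spaced-out earlier years.
#' @param seed Integer seed (byte-identical output for equal seeds).
#' @return A parent-ordered `cram_pedigree` with an extra `generation`
#'   column (0 = founder); focal individuals are
#'   `generation == n_generations`.
#' @export
simulate_pedigree <- function(n_founders, n_generations, mean_brood,
                              n_cohorts = 1L, base_year = 2010L, seed) {
  stopifnot(n_founders >= 2L, mean_brood >= 1, n_generations >= 1L)
  with_seed(seed, {
    gen_year <- function(g) {
      if (g < n_generations) base_year - 5L * (n_generations - g) else base_year
    }
    id <- sprintf("F%04d", seq_len(n_founders))
    ped <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                      cohort = rep(gen_year(0L), n_founders),
                      generation = 0L, stringsAsFactors = FALSE)
    current <- id
    for (g in seq_len(n_generations)) {
      shuffled <- sample(current)
      n_pairs <- length(shuffled) %/% 2L
      if (n_pairs < 1L) break
      sires <- shuffled[seq_len(n_pairs)]
      dams <- shuffled[n_pairs + seq_len(n_pairs)]
      brood <- pmax(1L, stats::rpois(n_pairs, mean_brood))
      coh <- if (g == n_generations) {
        base_year + sample.int(n_cohorts, n_pairs, replace = TRUE) - 1L
      } else {
        rep(gen_year(g), n_pairs)
      }
      kids <- data.frame(
        id = sprintf("G%d_%05d", g, seq_len(sum(brood))),
        sire = rep(sires, brood), dam = rep(dams, brood),
        cohort = rep(coh, brood), generation = g,
        stringsAsFactors = FALSE)
      ped <- rbind(ped, kids)
      current <- kids$id
    }
    class(ped) <- c("cram_pedigree", "data.frame")
    ped
  })
}

#' Simulate breeding values along a pedigree
#'
#' Generates season-specific breeding values by Mendelian sampling:
#' founders are iid `N(0, sigma_a^2)`, and each non-founder is the parent
#' average plus a Mendelian deviation with variance
#' `sigma_a^2 * (0.5 - 0.25 (F_sire + F_dam))` (both parents known; an
#' unknown parent contributes 0 with its `sigma_a^2 / 4` variance share
#' returned to the deviation). This is an O(n) exact draw from
#' `N(0, sigma_a^2 A)`.
#'
#' @param ped Parent-ordered `cram_pedigree`.
#' @param sigma_a Vector of per-season additive genetic SDs.
#' @param seed Integer seed.
#' @param A Optional precomputed [make_A()] (for the inbreeding
#'   coefficients); computed if absent.
#' @return Matrix (individuals x seasons) with `ped$id` rownames.
#' @export
simulate_breeding_values <- function(ped, sigma_a, seed, A = NULL) {
  if (!is_parent_ordered(ped)) stopf("pedigree must be parent-ordered")
  n <- nrow(ped)
  S <- length(sigma_a)
  if (is.null(A)) A <- make_A(ped)
  f <- as.numeric(Matrix::diag(A$A)) - 1
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  with_seed(seed, {
    out <- matrix(0, n, S, dimnames = list(ped$id, NULL))
    for (s in seq_len(S)) {
      if (sigma_a[s] == 0) next
      z <- stats::rnorm(n)
      a <- numeric(n)
      for (i in seq_len(n)) {
        pa <- 0; v <- 1
        if (!is.na(si[i]) && !is.na(di[i])) {
          pa <- 0.5 * (a[si[i]] + a[di[i]])
          v <- 0.5 - 0.25 * (f[si[i]] + f[di[i]])
        } else if (!is.na(si[i])) {
          pa <- 0.5 * a[si[i]]
          v <- 0.75 - 0.25 * f[si[i]]
        } else if (!is.na(di[i])) {
          pa <- 0.5 * a[di[i]]
          v <- 0.75 - 0.25 * f[di[i]]
        }
        a[i] <- pa + sigma_a[s] * sqrt(v) * z[i]
      }
      out[, s] <- a
    }
    out
  })
}

#' Simulate latent states and encounter histories
#'
#' Individuals start in state R at occasion 1 and evolve by exactly the
#' CRAM transition law ([transition_matrix()]); resightings are drawn by the
#' emission law ([emission_prob()]), with occasion 6 collapsed to
#' observed / not observed. Dead is absorbing.
#'
#' @param ped A `cram_pedigree`; individuals whose cohort appears in
#'   `params$cohorts` are phenotyped.
#' @param params True `cram_params`.
#' @param a,b Breeding values / individual effects: matrices
#'   (individuals x seasons) with id rownames; missing ids get 0.
#' @param seed Integer seed.
#' @return List: `histories` (an `encounter_histories` data frame) and
#'   `truth` (`states` matrix over occasions 1-6 with codes
#'   R/M1/M2/Dead, plus the `a` and `b` used).
#' @export
simulate_histories <- function(ped, params, a = NULL, b = NULL, seed) {
  focal <- ped$id[ped$cohort %in% params$cohorts]
  if (!length(focal)) stopf("no individuals in the parameter cohorts")
  S <- length(params$sigma_a)
  get_re <- function(m, id) {
    if (is.null(m)) return(numeric(S))
    k <- match(id, rownames(m))
    if (is.na(k)) numeric(S) else m[k, ]
  }
  with_seed(seed, {
    n <- length(focal)
    states <- matrix("R", n, 6L, dimnames = list(focal, NULL))
    events <- matrix("0", n, 6L)
    events[, 1] <- "R"
    cohort <- ped$cohort[match(focal, ped$id)]
    for (k in seq_len(n)) {
      ci <- match(cohort[k], params$cohorts)
      av <- get_re(a, focal[k]); bv <- get_re(b, focal[k])
      st <- "R"
      for (t in 1:4) {                       # interval t -> occasion t + 1
        if (st == "Dead") { states[k, t + 1L] <- "Dead"; next }
        phi <- if (st == "R") params$phi_R[t, ci] else params$phi_M[t - 1L, ci]
        if (stats::runif(1) > phi) {
          st <- "Dead"
        } else {
          s <- params$season_of_occ[t]
          psi <- psi_prob(params$mu[t, ci], av[s], bv[s])
          if (stats::runif(1) < psi) {       # migrant phenotype
            st <- if (st == "R") {
              if (stats::runif(1) < params$delta[t, ci]) "M1" else "M2"
            } else if (stats::runif(1) < params$gamma[t - 1L, ci]) {
              if (st == "M1") "M2" else "M1"
            } else st
          } else {
            st <- "R"
          }
        }
        states[k, t + 1L] <- st
        if (st != "Dead") {
          pdet <- params$p[match(st, c("R", "M1", "M2")), t, ci]
          if (stats::runif(1) < pdet) events[k, t + 1L] <- st
        }
      }
      # occasion 6
      if (states[k, 5L] == "Dead") {
        states[k, 6L] <- "Dead"
      } else {
        phi <- if (states[k, 5L] == "R") params$phi_R[5L, ci]
               else params$phi_M[4L, ci]
        states[k, 6L] <- if (stats::runif(1) < phi) "Alive" else "Dead"
        if (states[k, 6L] == "Alive" && stats::runif(1) < params$p6[ci]) {
          events[k, 6L] <- "1"
        }
      }
    }
    hh <- data.frame(id = focal, cohort = cohort,
                     e1 = events[, 1], e2 = events[, 2], e3 = events[, 3],
                     e4 = events[, 4], e5 = events[, 5], e6 = events[, 6],
                     stringsAsFactors = FALSE)
    class(hh) <- c("encounter_histories", "data.frame")
    list(histories = hh,
         truth = list(states = states, a = a, b = b))
  })
}

#' Generate a complete synthetic data set
#'
#' Pedigree, breeding values, individual effects and encounter histories
#' under one scenario; the building block for recovery runs and fixtures.
#'
#' @param scenario A scenario list, e.g. [default_scenario()].
#' @param seed Integer seed controlling every stage.
#' @return List: `pedigree`, `A`, `histories`, `truth` (breeding values,
#'   individual effects, latent states) and the true `params`.
#' @export
simulate_cram_data <- function(scenario = default_scenario(), seed) {
  params <- scenario$params
  ped <- simulate_pedigree(scenario$n_founders, scenario$n_generations,
                           scenario$mean_brood, scenario$n_cohorts,
                           scenario$base_year, seed = seed)
  ped <- sort_pedigree(ped)
  A <- make_A(ped)
  a <- simulate_breeding_values(ped, params$sigma_a, seed = seed + 1L, A = A)
  focal <- ped$id[ped$cohort %in% params$cohorts]
  S <- length(params$sigma_b)
  b <- with_seed(seed + 2L, {
    matrix(stats::rnorm(length(focal) * S), length(focal), S,
           dimnames = list(focal, NULL)) %*% diag(params$sigma_b, S)
  })
  rownames(b) <- focal
  sim <- simulate_histories(ped, params, a, b, seed = seed + 3L)
  list(pedigree = ped, A = A, histories = sim$histories,
       truth = list(a = a, b = b, states = sim$truth$states),
       params = params)
}

#' Parameter-recovery calibration run
#'
#' Simulates a data set from known parameters, fits the CRAM, refits with a
#' randomized (permuted) relatedness matrix as the null check, and reports
#' posterior summaries against the generating truth. The permuted-A refit
#' should concentrate the additive genetic variance near zero; the headline
#' check is that its posterior mean is well below the true-A fit's.
#'
#' @param scenario Scenario list ([default_scenario()]).
#' @param config A [cram_config()] sized for the available time budget.
#' @param seed Integer seed for simulation, fits and permutation.
#' @return List: `report` (per-variance-component truth, posterior mean,
#'   95% CI, coverage indicator), `null_report` (permuted-A posterior means
#'   of the additive variances and their ratio to the true-A fit),
#'   `fit`, `null_fit`, and the simulated `data`.
#' @export
recovery_harness <- function(scenario = default_scenario(),
                             config = cram_config(), seed) {
  dat <- simulate_cram_data(scenario, seed)
  fit <- cram_fit(dat$histories, dat$pedigree, config, seed = seed + 10L,
                  A = dat$A)
  keep <- setdiff(dat$histories$id, fit$dropped)
  hh <- dat$histories[match(keep, dat$histories$id), ]
  A_perm <- permute_A(dat$A, seed = seed + 20L)
  null_fit <- cram_fit(hh, dat$pedigree, config, seed = seed + 30L,
                       A = A_perm, prune = FALSE)

  seasons <- fit$seasons
  truth <- c(dat$params$sigma_a^2, dat$params$sigma_b^2)
  names(truth) <- c(sprintf("sigma_a2[%s]", seasons),
                    sprintf("sigma_b2[%s]", seasons))
  rows <- lapply(names(truth), function(nm) {
    col <- sub("2\\[", "[", nm)         # draws are on the SD scale
    x <- draws_of(fit, paste0("^", gsub("\\[", "\\\\[", col)))^2
    qs <- stats::quantile(x, c(0.025, 0.975))
    data.frame(parameter = nm, truth = truth[[nm]], mean = mean(x),
               lo95 = qs[[1]], hi95 = qs[[2]],
               covered = truth[[nm]] >= qs[[1]] && truth[[nm]] <= qs[[2]],
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)

  null_sa2 <- vapply(seasons, function(s) {
    mean(draws_of(null_fit, sprintf("^sigma_a\\[%s\\]", s))^2)
  }, numeric(1))
  true_sa2 <- report$mean[grepl("^sigma_a2", report$parameter)]
  null_report <- data.frame(season = seasons, null_mean = null_sa2,
                            true_fit_mean = true_sa2,
                            ratio = null_sa2 / true_sa2,
                            stringsAsFactors = FALSE)
  list(report = report, null_report = null_report, fit = fit,
       null_fit = null_fit, data = dat)
}
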
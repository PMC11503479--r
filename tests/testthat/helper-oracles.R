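# Independent oracles and fixture builders used across the suite. These are
# deliberately written from first principles (recursive kinship, explicit
# path enumeration, plain Monte Carlo) so they share no code path with the
# package implementations they check.

# recursive kinship coefficient with memoization; A = 2 * kinship
oracle_kinship_matrix <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      0.5 * (1 + (if (!is.na(si[i]) && !is.na(di[i])) phi(si[i], di[i]) else 0))
    } else {
      # j is the later individual in a parent-ordered pedigree
      ps <- if (!is.na(si[j])) phi(i, si[j]) else 0
      pd <- if (!is.na(di[j])) phi(i, di[j]) else 0
      0.5 * (ps + pd)
    }
    memo[[key]] <- val
    val
  }
  m <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    m[i, j] <- m[j, i] <- phi(i, j)
  }
  2 * m
}

# explicit sum over all latent state paths through occasions 2-5 plus the
# alive/dead dichotomy at occasion 6
oracle_path_loglik <- function(events, cohort, params, a = NULL, b = NULL) {
  S <- length(params$sigma_a)
  a <- if (is.null(a)) numeric(S) else a
  b <- if (is.null(b)) numeric(S) else b
  ci <- match(cohort, params$cohorts)
  states <- c("R", "M1", "M2", "Dead")
  emis <- function(st, evn, t) {
    if (st == "Dead") return(if (evn == "0") 1 else 0)
    pd <- params$p[match(st, states), t, ci]
    if (evn == "0") 1 - pd else if (evn == st) pd else 0
  }
  step_prob <- function(from, to, t) {
    s <- params$season_of_occ[t]
    psi <- stats::pnorm(params$mu[t, ci] + a[s] + b[s])
    de <- params$delta[t, ci]
    ga <- if (t >= 2) params$gamma[t - 1, ci] else 0
    phi <- if (from == "R") params$phi_R[t, ci]
           else if (from %in% c("M1", "M2")) {
             if (t >= 2) params$phi_M[t - 1, ci] else NA
           } else NA
    if (from == "Dead") return(if (to == "Dead") 1 else 0)
    switch(to,
           R = phi * (1 - psi),
           M1 = if (from == "R") phi * psi * de
                else if (from == "M1") phi * psi * (1 - ga)
                else phi * psi * ga,
           M2 = if (from == "R") phi * psi * (1 - de)
                else if (from == "M1") phi * psi * ga
                else phi * psi * (1 - ga),
           Dead = 1 - phi)
  }
  tot <- 0
  for (s2 in states) for (s3 in states) for (s4 in states) for (s5 in states) {
    path <- c("R", s2, s3, s4, s5)
    pr <- 1
    for (t in 1:4) {
      pr <- pr * step_prob(path[t], path[t + 1], t) *
        emis(path[t + 1], events[t + 1], t)
      if (pr == 0) break
    }
    if (pr == 0) next
    st5 <- path[5]
    for (alive in c(TRUE, FALSE)) {
      psur <- if (st5 == "Dead") {
        if (alive) 0 else 1
      } else {
        phi <- if (st5 == "R") params$phi_R[5, ci] else params$phi_M[4, ci]
        if (alive) phi else 1 - phi
      }
      pobs <- if (alive) {
        if (events[6] == "1") params$p6[ci] else 1 - params$p6[ci]
      } else {
        if (events[6] == "1") 0 else 1
      }
      tot <- tot + pr * psur * pobs
    }
  }
  log(tot)
}

# random structural parameter set for likelihood tests
random_params <- function(seed, C = 2L, cohorts = c(2010L, 2011L)) {
  set.seed(seed)
  cram_params(
    cohorts = cohorts[seq_len(C)],
    mu = matrix(stats::rnorm(4 * C), 4, C),
    sigma_a = stats::runif(2, 0.3, 1),
    sigma_b = stats::runif(2, 0.5, 2),
    phi_R = matrix(stats::runif(5 * C, 0.4, 0.95), 5, C),
    phi_M = matrix(stats::runif(4 * C, 0.4, 0.95), 4, C),
    delta = matrix(stats::runif(4 * C, 0.2, 0.8), 4, C),
    gamma = matrix(stats::runif(3 * C, 0.05, 0.4), 3, C),
    p = array(stats::runif(12 * C, 0.1, 0.9), c(3, 4, C)),
    p6 = stats::runif(C, 0.3, 0.9))
}

random_events <- function() {
  c("R", sample(c("R", "M1", "M2", "0"), 4, replace = TRUE),
    sample(c("0", "1"), 1))
}

# random valid pedigree: sequential individuals pick earlier parents (or
# none), so the result is parent-ordered by construction
random_pedigree <- function(n, seed, p_known = 0.7) {
  set.seed(seed)
  id <- sprintf("I%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in 3:n) {
    if (stats::runif(1) < p_known) {
      pick <- sample(i - 1L, 2L)
      sire[i] <- id[pick[1]]; dam[i] <- id[pick[2]]
    }
  }
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    cohort = NA_integer_, stringsAsFactors = FALSE)
  class(ped) <- c("cram_pedigree", "data.frame")
  ped
}

trio_pedigree <- function() {
  as_pedigree(data.frame(id = c("A", "B", "C"), sire = c(NA, NA, "A"),
                         dam = c(NA, NA, "B")))
}

# Independent Monte-Carlo Sobol oracle for the threshold-indicator
# decomposition: paired-copy covariance estimators with block standard
# errors. Written from the definitions, sharing no code with the package's
# quadrature / closed-form / monte-carlo paths.
oracle_mc_sobol <- function(mu, sa2, sb2, n = 1e7, blocks = 20L, seed = 1) {
  set.seed(seed)
  nb <- as.integer(n / blocks)
  comp <- c("zbar", "Va", "Vb", "Ve", "Vab", "Vae", "Vbe", "Vabe", "Vz")
  est <- matrix(NA_real_, blocks, length(comp),
                dimnames = list(NULL, comp))
  sda <- sqrt(sa2); sdb <- sqrt(sb2)
  for (k in seq_len(blocks)) {
    a <- rnorm(nb, 0, sda);  b <- rnorm(nb, 0, sdb);  e <- rnorm(nb)
    a2 <- rnorm(nb, 0, sda); b2 <- rnorm(nb, 0, sdb); e2 <- rnorm(nb)
    y <- (mu + a + b + e) > 0
    zb <- mean(y)
    cv <- function(y2) mean(y & y2) - zb^2
    Va <- cv((mu + a + b2 + e2) > 0)
    Vb <- cv((mu + a2 + b + e2) > 0)
    Ve <- cv((mu + a2 + b2 + e) > 0)
    Vab <- cv((mu + a + b + e2) > 0) - Va - Vb
    Vae <- cv((mu + a + b2 + e) > 0) - Va - Ve
    Vbe <- cv((mu + a2 + b + e) > 0) - Vb - Ve
    Vz <- zb * (1 - zb)
    est[k, ] <- c(zb, Va, Vb, Ve, Vab, Vae, Vbe,
                  Vz - Va - Vb - Ve - Vab - Vae - Vbe, Vz)
  }
  list(mean = colMeans(est),
       se = apply(est, 2, stats::sd) / sqrt(blocks))
}
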
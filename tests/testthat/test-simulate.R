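test_that("pedigree growth has the stated structure and is deterministic", {
  ped <- simulate_pedigree(2L, 1L, 3L, seed = 1)
  expect_gte(nrow(ped), 3L)            # 2 founders + at least one brood
  kids <- ped[ped$generation == 1L, ]
  expect_true(all(kids$sire == "F0001" | kids$sire == "F0002"))
  # same seed, same pedigree
  expect_identical(simulate_pedigree(40L, 3L, 2.2, 2L, 2010L, seed = 7),
                   simulate_pedigree(40L, 3L, 2.2, 2L, 2010L, seed = 7))
  # close kin per focal individual increase with brood size
  links <- function(brood, seed) {
    ped <- sort_pedigree(simulate_pedigree(80L, 3L, brood, seed = seed))
    A <- make_A(ped)
    focal <- ped$id[ped$generation == 3L]
    s <- summarize_links(A, focal)
    expect_gt(s$proportion_ge_threshold, 0)
    m <- as.matrix(A)[match(focal, A$ids), match(focal, A$ids)]
    sum(m[upper.tri(m)] >= 0.25) / length(focal)
  }
  small <- mean(vapply(1:3, function(s) links(1.2, s), numeric(1)))
  big <- mean(vapply(1:3, function(s) links(4, s), numeric(1)))
  expect_gt(big, small)
})

test_that("breeding values follow the pedigree covariance structure", {
  ped <- sort_pedigree(simulate_pedigree(30L, 2L, 2.5, seed = 3))
  expect_identical(simulate_breeding_values(ped, c(1, 0.5), seed = 2),
                   simulate_breeding_values(ped, c(1, 0.5), seed = 2))
  expect_true(all(simulate_breeding_values(ped, c(0, 0), seed = 2) == 0))

  # founder-only pedigree: iid with variance sigma_a^2
  fo <- as_pedigree(data.frame(id = sprintf("f%04d", 1:8000),
                               sire = NA, dam = NA))
  a <- simulate_breeding_values(fo, c(1.5), seed = 9)  # SD 1.5
  v <- var(a[, 1])
  se <- 1.5^2 * sqrt(2 / (nrow(fo) - 1))
  expect_lt(abs(v - 1.5^2), 3 * se)

  # sibling covariance approaches 0.5 sigma_a^2: replicate a fixed trio
  reps <- 4000
  sib_prod <- replicate(reps, {
    ped <- trio_pedigree()
    ped <- rbind(ped, data.frame(id = "D", sire = "A", dam = "B",
                                 cohort = NA_integer_))
    class(ped) <- c("cram_pedigree", "data.frame")
    a <- simulate_breeding_values(ped, 1, seed = sample.int(1e7, 1))
    a["C", 1] * a["D", 1]
  })
  se <- sd(sib_prod) / sqrt(reps)
  expect_lt(abs(mean(sib_prod) - 0.5), 3 * se)
})

test_that("history simulation honours degenerate parameter settings", {
  C <- 1L
  base <- cram_params(2010L, mu = matrix(-30, 4, C), sigma_a = c(0, 0),
                      sigma_b = c(0, 0), phi_R = matrix(1, 5, C),
                      phi_M = matrix(1, 4, C), delta = matrix(0.5, 4, C),
                      gamma = matrix(0.1, 3, C), p = array(1, c(3, 4, C)),
                      p6 = 1)
  ped <- data.frame(id = sprintf("x%03d", 1:50), sire = NA_character_,
                    dam = NA_character_, cohort = 2010L)
  class(ped) <- c("cram_pedigree", "data.frame")

  # certain survival & detection, certain residence -> all seen in R
  sim <- simulate_histories(ped, base, seed = 5)
  expect_true(all(sim$histories$e2 == "R" & sim$histories$e5 == "R"))
  expect_true(all(sim$histories$e6 == "1"))
  expect_true(all(sim$truth$states[, 2:5] == "R"))

  # zero detection: nothing seen after ringing, but states still recorded
  dark <- base; dark$p[] <- 0; dark$p6[] <- 0
  sim <- simulate_histories(ped, dark, seed = 5)
  expect_true(all(unlist(sim$histories[paste0("e", 2:6)]) == "0"))
  expect_true(all(sim$truth$states[, 2:5] == "R"))

  expect_identical(simulate_histories(ped, base, seed = 8),
                   simulate_histories(ped, base, seed = 8))
})

test_that("empirical transition frequencies match the transition law", {
  # common psi (no random effects), one cohort; compare occasion-4 -> 5
  # empirical transitions from the recorded latent states to the kernel
  C <- 1L
  params <- cram_params(2010L, mu = matrix(c(0.3, 0.1, -0.2, 0.4), 4, C),
                        sigma_a = c(0, 0), sigma_b = c(0, 0),
                        phi_R = matrix(0.9, 5, C), phi_M = matrix(0.8, 4, C),
                        delta = matrix(0.65, 4, C),
                        gamma = matrix(0.25, 3, C),
                        p = array(0.5, c(3, 4, C)), p6 = 0.5)
  n <- 60000L
  ped <- data.frame(id = sprintf("x%05d", 1:n), sire = NA_character_,
                    dam = NA_character_, cohort = 2010L)
  class(ped) <- c("cram_pedigree", "data.frame")
  sim <- simulate_histories(ped, params, seed = 77)
  st <- sim$truth$states
  psi5 <- psi_prob(params$mu[4, 1])
  expected <- transition_matrix(psi5, params$delta[4, 1], params$gamma[3, 1],
                                params$phi_R[4, 1], params$phi_M[3, 1])
  for (from in c("R", "M1", "M2")) {
    sel <- st[, 4] == from
    n_from <- sum(sel)
    expect_gt(n_from, 500)
    emp <- table(factor(st[sel, 5], levels = c("R", "M1", "M2", "Dead"))) /
      n_from
    for (to in c("R", "M1", "M2", "Dead")) {
      p0 <- expected[from, to]
      se <- sqrt(max(p0 * (1 - p0), 1e-10) / n_from)
      expect_lt(abs(emp[[to]] - p0), 3 * se + 1e-9)
    }
  }
})

test_that("migrant proportions link the simulator to the phenotypic mean", {
  # detection and survival 1: the observed migrant fraction at each occasion
  # matches the marginal threshold-crossing probability
  C <- 1L
  params <- cram_params(2010L, mu = matrix(c(-0.5, 0, 0.5, 1), 4, C),
                        sigma_a = c(sqrt(0.8), sqrt(0.5)),
                        sigma_b = c(sqrt(2.3), sqrt(3.5)),
                        phi_R = matrix(1, 5, C), phi_M = matrix(1, 4, C),
                        delta = matrix(0.6, 4, C), gamma = matrix(0.2, 3, C),
                        p = array(1, c(3, 4, C)), p6 = 1)
  n <- 20000L
  ped <- data.frame(id = sprintf("x%05d", 1:n), sire = NA_character_,
                    dam = NA_character_, cohort = 2010L)
  class(ped) <- c("cram_pedigree", "data.frame")
  a <- simulate_breeding_values(ped, params$sigma_a, seed = 1)
  b <- matrix(rnorm(2 * n), n, 2) %*% diag(params$sigma_b)
  rownames(b) <- ped$id
  sim <- simulate_histories(ped, params, a, b, seed = 3)
  st <- sim$truth$states
  for (o in 2:5) {
    zbar <- expected_phenotype(params$mu[o - 1, 1],
                               params$sigma_a[ifelse(o <= 3, 1, 2)]^2,
                               params$sigma_b[ifelse(o <= 3, 1, 2)]^2)
    emp <- mean(st[, o] %in% c("M1", "M2"))
    se <- sqrt(zbar * (1 - zbar) / n)
    # individual effects persist across occasions, so use a mildly wider
    # band than iid binomial sampling error
    expect_lt(abs(emp - zbar), 4 * se)
  }
})

test_that("the full synthetic bundle is coherent", {
  sc <- default_scenario()
  sc$n_founders <- 60L
  dat <- simulate_cram_data(sc, seed = 13)
  expect_true(cramr:::is_parent_ordered(dat$pedigree))
  expect_setequal(unique(dat$histories$cohort), sc$params$cohorts)
  expect_true(all(dat$histories$id %in% dat$pedigree$id))
  expect_equal(rownames(dat$truth$a), dat$pedigree$id)
  expect_setequal(rownames(dat$truth$b), dat$histories$id)
})
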
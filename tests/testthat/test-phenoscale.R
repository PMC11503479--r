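test_that("expected migrant proportion is the marginal probit", {
  expect_equal(expected_phenotype(0, 0.7, 2.1), 0.5)
  expect_equal(expected_phenotype(0, 4, 6), 0.5)
  expect_equal(expected_phenotype(1, 0, 0), pnorm(1))
  expect_error(expected_phenotype(0, -1, 0), "non-negative")
  # Monte-Carlo cross-check of the marginalization
  set.seed(4)
  n <- 2e6
  y <- (0.8 + rnorm(n, 0, sqrt(0.79)) + rnorm(n, 0, sqrt(2.29)) + rnorm(n)) > 0
  se <- sqrt(var(y) / n)
  expect_lt(abs(expected_phenotype(0.8, 0.79, 2.29) - mean(y)), 3 * se)
})

test_that("degenerate decompositions collapse as expected", {
  # no genetic variance: every genetic component vanishes
  d <- decompose_phenotype(0.3, 0, 1.5)
  for (q in c("Va", "VA", "VNA", "Vab", "Vae", "Vabe", "h2_z")) {
    expect_equal(d[[q]], 0)
  }
  expect_gt(d$Vb, 0); expect_gt(d$Ve, 0)

  # extreme intercept: fixed phenotype, all components vanish
  d <- decompose_phenotype(30, 0.8, 2.3)
  expect_equal(d$zbar, 1)
  expect_lt(d$Vz, 1e-12)
  expect_lt(max(abs(unlist(d[c("Va", "Vb", "Ve", "Vab", "Vae", "Vbe",
                               "Vabe")]))), 1e-12)
  expect_equal(d$h2_z, 0)
  expect_error(decompose_phenotype(0, -0.1, 1), "non-negative")
})

test_that("Sobol completeness and component bounds hold on a grid", {
  for (mu in c(-3, -1, 0, 1, 3)) {
    for (sa2 in c(0, 1.7, 4)) {
      for (sb2 in c(0, 2.9, 6)) {
        d <- decompose_phenotype(mu, sa2, sb2)  # errors if sum off by >1e-6
        comp_sum <- d$Va + d$Vb + d$Ve + d$Vab + d$Vae + d$Vbe + d$Vabe
        expect_lt(abs(comp_sum - d$Vz), 1e-6)
        expect_lte(d$VA, d$Va + 1e-12)
        expect_true(all(unlist(d[c("Va", "Vb", "Ve", "Vab", "Vae", "Vbe",
                                   "Vabe", "VA", "VNA")]) >= -1e-12))
        expect_equal(d$Vz, d$zbar * (1 - d$zbar), tolerance = 1e-12)
      }
    }
  }
})

test_that("the decomposition is symmetric under sign reversal of the mean", {
  for (sa2 in c(0.5, 2)) {
    dpos <- decompose_phenotype(1.2, sa2, 3)
    dneg <- decompose_phenotype(-1.2, sa2, 3)
    expect_equal(dpos$Vz, dneg$Vz, tolerance = 1e-8)
    for (q in c("Va", "Vb", "Ve", "Vab", "Vae", "Vbe", "Vabe", "VA")) {
      expect_equal(dpos[[q]], dneg[[q]], tolerance = 1e-8)
    }
    expect_equal(dpos$zbar, 1 - dneg$zbar, tolerance = 1e-12)
  }
})

test_that("quadrature, closed form and package Monte Carlo agree", {
  for (mu in c(-0.8, 0.5)) {
    dq <- decompose_phenotype(mu, 0.79, 2.29, method = "quadrature")
    dc <- decompose_phenotype(mu, 0.79, 2.29, method = "closed-form")
    dm <- decompose_phenotype(mu, 0.79, 2.29, method = "monte-carlo",
                              n_mc = 2e6, seed = 8)
    for (q in c("zbar", "Vz", "Va", "Vb", "Ve", "Vab", "Vae", "Vbe", "Vabe")) {
      expect_lt(abs(dq[[q]] - dc[[q]]), 1e-8)   # deterministic routes agree
      expect_lt(abs(dq[[q]] - dm[[q]]), 2e-3)   # MC route within noise
    }
  }
})

test_that("the two VNA bookkeepings differ by the genetic interactions", {
  d1 <- decompose_phenotype(0.4, 0.8, 2.3, vna = "main")
  d2 <- decompose_phenotype(0.4, 0.8, 2.3, vna = "interactions")
  expect_equal(d1$VNA, d1$Va - d1$VA, tolerance = 1e-12)
  expect_equal(d2$VNA - d1$VNA, d1$Vab + d1$Vae + d1$Vabe, tolerance = 1e-12)
})

test_that("posterior decomposition matches direct calls and labels cells", {
  # degenerate single-draw input equals a direct decompose call
  draws <- cbind("mu[2,2010]" = 0.4, "mu[3,2010]" = 0.8,
                 "mu[4,2010]" = -0.2, "mu[5,2010]" = 1.1,
                 "sigma_a[autumn]" = sqrt(0.8), "sigma_a[winter]" = sqrt(0.5),
                 "sigma_b[autumn]" = sqrt(2.3), "sigma_b[winter]" = sqrt(3.5))
  pd <- posterior_decompose(draws)
  expect_equal(nrow(pd$cell_index), 4L)
  expect_equal(pd$cell_index$season, c("autumn", "autumn", "winter", "winter"))
  direct <- decompose_phenotype(-0.2, 0.5, 3.5, method = "closed-form")
  cell4 <- pd$cells[pd$cells$occasion == 4 & pd$cells$component == "Va", ]
  expect_equal(cell4$mean, direct$Va, tolerance = 1e-10)
  h4 <- pd$cells[pd$cells$occasion == 4 & pd$cells$component == "h2_z", ]
  expect_equal(h4$mean, direct$h2_z, tolerance = 1e-10)

  # all-zero intercepts, zero variances: Vz = 1/4 everywhere
  z <- draws; z[1, ] <- c(0, 0, 0, 0, 0, 0, 0, 0)
  pz <- posterior_decompose(z)
  vz <- pz$cells[pz$cells$component == "Vz", ]
  expect_equal(vz$mean, rep(0.25, 4))
  zb <- pz$cells[pz$cells$component == "zbar", ]
  expect_equal(zb$mean, rep(0.5, 4))
  expect_error(posterior_decompose(draws[, -1, drop = FALSE]), "occasion")
})

test_that("seasonal grand means average cells and contrast seasons", {
  # two cohorts, hand-built draws
  mk <- function(coh, v) {
    out <- cbind(v[1], v[2], v[3], v[4])
    colnames(out) <- sprintf("mu[%d,%s]", 2:5, coh)
    out
  }
  draws <- cbind(mk(2010, c(0.2, 0.4, 0.1, 0.3)),
                 mk(2011, c(-0.2, 0, 0.5, 0.7)),
                 "sigma_a[autumn]" = 1, "sigma_a[winter]" = 1,
                 "sigma_b[autumn]" = 1, "sigma_b[winter]" = 1)
  draws <- rbind(draws, draws)  # two identical draws
  pd <- posterior_decompose(draws)
  gm <- seasonal_grand_means(pd, quantities = "zbar")
  aut <- gm[gm$season == "autumn", ]
  manual <- mean(pnorm(c(0.2, 0.4, -0.2, 0) / sqrt(3)))
  expect_equal(aut$mean, manual, tolerance = 1e-10)
  diffrow <- gm[grepl(" - ", gm$season), ]
  win <- mean(pnorm(c(0.1, 0.3, 0.5, 0.7) / sqrt(3)))
  expect_equal(diffrow$mean, manual - win, tolerance = 1e-10)
  # identical cells across seasons: contrast 0, tie-probability one half
  same <- draws
  same[, 1:8] <- 0.3
  gms <- seasonal_grand_means(posterior_decompose(same), quantities = "zbar")
  dr <- gms[grepl(" - ", gms$season), ]
  expect_equal(dr$mean, 0, tolerance = 1e-12)
  expect_equal(dr$prob_greater, 0.5)
  # grand mean invariant to cohort relabelling
  swapped <- draws[, c(5:8, 1:4, 9:12)]
  colnames(swapped) <- colnames(draws)
  gm2 <- seasonal_grand_means(posterior_decompose(swapped),
                              quantities = "zbar")
  expect_equal(gm2$mean[gm2$season == "autumn"], aut$mean, tolerance = 1e-10)
})
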
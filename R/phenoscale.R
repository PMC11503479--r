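# Back-transformation of liability-scale estimates to phenotypic-scale
# (observed 0/1 migration) means and variance components.
#
# The phenotype is the threshold indicator y = 1{mu* + a + b + e > 0} with
# independent a ~ N(0, sa2), b ~ N(0, sb2), e ~ N(0, 1). Because the inputs
# are independent, the functional-ANOVA (Sobol) decomposition of y is exact
# and its pieces have closed forms in the bivariate normal CDF at equal
# arguments: for a subset T of inputs with total variance v,
#   Var(E[y | x_T]) = Phi2(m, m; v / s2) - Phi(m)^2,
# where s2 = 1 + sa2 + sb2 and m = mu* / sqrt(s2). Interaction components
# follow by inclusion-exclusion and the three-way term by completeness
# (the seven components sum to Vz = zbar (1 - zbar)).

#' Expected proportion of migrants
#'
#' Marginal threshold-crossing probability for given liability intercept and
#' variance components (unit residual variance):
#' \deqn{\bar z = \Phi\!\left(\mu^* / \sqrt{1 + \sigma_a^{*2} + \sigma_b^{*2}}\right).}
#'
#' @param mu_star Liability intercept (standardized scale); vectorized.
#' @param sa2,sb2 Additive genetic and individual liability variances.
#' @return Expected migrant proportion.
#' @export
expected_phenotype <- function(mu_star, sa2, sb2) {
  if (any(sa2 < 0) || any(sb2 < 0)) stopf("variances must be non-negative")
  stats::pnorm(mu_star / sqrt(1 + sa2 + sb2))
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

# Gauss-Hermite nodes/weights for weight exp(-x^2) (Golub-Welsch)
gauss_hermite <- function(n) {
  k <- seq_len(n - 1)
  beta <- sqrt(k / 2)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# P(Z1 < m, Z2 < m) for standard bivariate normal with correlation rho,
# via the correlation-integral identity
#   Phi2(m, m; rho) = Phi(m)^2 + int_0^rho phi2(m, m; r) dr,
# with phi2(m, m; r) = exp(-m^2 / (1 + r)) / (2 pi sqrt(1 - r^2)).
# Vectorized over (m, rho) pairs; 96 Gauss-Legendre nodes give ~1e-12
# accuracy for rho <= 0.995 (here rho = v / (1 + sa2 + sb2) < 1 always).
pbinorm_diag <- function(m, rho, gl = gauss_legendre(96L)) {
  stopifnot(all(rho >= 0), all(rho < 1))
  n <- max(length(m), length(rho))
  m <- rep_len(m, n); rho <- rep_len(rho, n)
  r <- outer(rho / 2, gl$nodes + 1)            # n x nodes, in (0, rho)
  dens <- exp(-m^2 / (1 + r)) / (2 * pi * sqrt(1 - r^2))
  stats::pnorm(m)^2 + as.numeric(dens %*% gl$weights) * rho / 2
}

# Var(E[y | x_T]) for a subset with variance v, total variance s2.
# Closed form via pbinorm_diag; quadrature via 1-D Gauss-Hermite over the
# subset sum (E[y | x_T] depends on x_T only through its normal sum).
subset_main_variance <- function(mu, v, s2, method, nodes) {
  zbar <- stats::pnorm(mu / sqrt(s2))
  out <- numeric(length(mu))
  vr <- s2 - v
  # remainder variance 0 (subset = all inputs with positive variance): the
  # conditional expectation is the threshold indicator itself, so the
  # subset variance is the full Vz
  full <- v > 0 & vr < 1e-10
  out[full] <- zbar[full] * (1 - zbar[full])
  pos <- v > 0 & !full
  if (!any(pos)) return(pmax(out, 0))
  if (method == "closed-form") {
    out[pos] <- pbinorm_diag(mu[pos] / sqrt(s2[pos]), (v / s2)[pos]) -
      zbar[pos]^2
  } else {
    # the integrand's feature width scales with sqrt(vr/v); grow the rule
    # with the variance ratio so accuracy stays uniform over the domain
    n_eff <- max(nodes, ceiling(31 * sqrt(1 + max(v[pos] / vr[pos]))))
    gh <- gauss_hermite(n_eff)
    x <- outer(sqrt(2 * v[pos]), gh$nodes)       # draws of the subset sum
    f2 <- stats::pnorm((mu[pos] + x) / sqrt(vr[pos]))^2
    out[pos] <- as.numeric(f2 %*% gh$weights) / sqrt(pi) - zbar[pos]^2
  }
  pmax(out, 0)
}

pheno_components <- function(mu, sa2, sb2, method = "closed-form",
                             nodes = 61L) {
  n <- max(length(mu), length(sa2), length(sb2))
  mu <- rep_len(mu, n); sa2 <- rep_len(sa2, n); sb2 <- rep_len(sb2, n)
  s2 <- 1 + sa2 + sb2
  m <- mu / sqrt(s2)
  zbar <- stats::pnorm(m)
  Vz <- zbar * (1 - zbar)
  V <- function(v) subset_main_variance(mu, v, s2, method, nodes)
  Va <- V(sa2); Vb <- V(sb2); Ve <- V(rep_len(1, n))
  Vab <- pmax(V(sa2 + sb2) - Va - Vb, 0)
  Vae <- pmax(V(sa2 + 1) - Va - Ve, 0)
  Vbe <- pmax(V(sb2 + 1) - Vb - Ve, 0)
  Vabe <- pmax(Vz - Va - Vb - Ve - Vab - Vae - Vbe, 0)
  VA <- sa2 * stats::dnorm(m)^2 / s2              # (best linear predictor)^2
  VA <- pmin(VA, Va)
  list(zbar = zbar, Vz = Vz, Va = Va, Vb = Vb, Ve = Ve,
       Vab = Vab, Vae = Vae, Vbe = Vbe, Vabe = Vabe, VA = VA)
}

#' Phenotypic-scale variance decomposition of migration versus residence
#'
#' Decomposes the variance of the dichotomous migration phenotype
#' \eqn{y = 1\{\mu^* + a + b + \varepsilon > 0\}} into the seven Sobol
#' components generated by the three independent liability-scale inputs:
#' main effects `Va`, `Vb`, `Ve`, two-way interactions `Vab`, `Vae`, `Vbe`
#' and the three-way term `Vabe`, which together sum to the total phenotypic
#' variance `Vz = zbar (1 - zbar)`. The purely additive phenotypic genetic
#' variance is the squared best-linear-predictor contribution
#' \eqn{V_A = \sigma_a^{*2}\,\varphi(m)^2 / s^2}; the remaining genetic
#' variance `VNA` is of genetic origin but non-additive on the phenotypic
#' scale. Phenotypic heritability is `h2_z = VA / Vz` and repeatability
#' `rho_z = (Va + Vb + Vab) / Vz` (the among-individual share).
#'
#' @param mu_star Liability intercept.
#' @param sa2,sb2 Liability-scale additive genetic and individual variances.
#' @param method `"quadrature"` (Gauss-Hermite, default), `"closed-form"`
#'   (bivariate-normal identities) or `"monte-carlo"`.
#' @param nodes Gauss-Hermite node count for the quadrature method.
#' @param n_mc Monte-Carlo sample size.
#' @param vna `"main"` defines `VNA = Va - VA`; `"interactions"` also
#'   assigns the genetic-interaction components:
#'   `VNA = Va - VA + Vab + Vae + Vabe`.
#' @param tol Completeness tolerance: the seven components must sum to `Vz`
#'   within `tol` (error otherwise).
#' @param seed Seed for the Monte-Carlo method.
#' @return One-row data frame: `zbar`, `Vz`, `Va`, `Vb`, `Ve`, `Vab`,
#'   `Vae`, `Vbe`, `Vabe`, `VA`, `VNA`, `h2_z`, `rho_z`.
#' @export
decompose_phenotype <- function(mu_star, sa2, sb2,
                                method = c("quadrature", "closed-form",
                                           "monte-carlo"),
                                nodes = 61L, n_mc = 1e6,
                                vna = c("main", "interactions"),
                                tol = 1e-6, seed = 1L) {
  method <- match.arg(method)
  vna <- match.arg(vna)
  if (sa2 < 0 || sb2 < 0) stopf("variances must be non-negative")
  if (method == "monte-carlo") {
    comp <- mc_components(mu_star, sa2, sb2, n_mc, seed)
  } else {
    comp <- pheno_components(mu_star, sa2, sb2, method, nodes)
    ssum <- comp$Va + comp$Vb + comp$Ve + comp$Vab + comp$Vae + comp$Vbe +
      comp$Vabe
    if (abs(ssum - comp$Vz) > tol) {
      stopf("component sum deviates from Vz by %.3g (tolerance %.3g)",
            abs(ssum - comp$Vz), tol)
    }
  }
  comp$VNA <- if (vna == "main") comp$Va - comp$VA
              else comp$Va - comp$VA + comp$Vab + comp$Vae + comp$Vabe
  small <- comp$Vz < 1e-12
  comp$h2_z <- ifelse(small, 0, comp$VA / comp$Vz)
  comp$rho_z <- ifelse(small, 0, (comp$Va + comp$Vb + comp$Vab) / comp$Vz)
  as.data.frame(comp)
}

# Sobol estimation by paired copies sharing the conditioning subset:
# Var(E[y|x_T]) = Cov(y, y') with x_T common and the remainder redrawn.
mc_components <- function(mu, sa2, sb2, n, seed) {
  with_seed(seed, {
    a <- stats::rnorm(n, 0, sqrt(sa2)); b <- stats::rnorm(n, 0, sqrt(sb2))
    e <- stats::rnorm(n)
    a2 <- stats::rnorm(n, 0, sqrt(sa2)); b2 <- stats::rnorm(n, 0, sqrt(sb2))
    e2 <- stats::rnorm(n)
    y <- as.numeric(mu + a + b + e > 0)
    zbar <- mean(y)
    cov0 <- function(y2) mean(y * y2) - zbar^2
    Va <- cov0(as.numeric(mu + a + b2 + e2 > 0))
    Vb <- cov0(as.numeric(mu + a2 + b + e2 > 0))
    Ve <- cov0(as.numeric(mu + a2 + b2 + e > 0))
    Vab <- cov0(as.numeric(mu + a + b + e2 > 0)) - Va - Vb
    Vae <- cov0(as.numeric(mu + a + b2 + e > 0)) - Va - Ve
    Vbe <- cov0(as.numeric(mu + a2 + b + e > 0)) - Vb - Ve
    Vz <- zbar * (1 - zbar)
    s2 <- 1 + sa2 + sb2
    m <- mu / sqrt(s2)
    list(zbar = zbar, Vz = Vz, Va = Va, Vb = Vb, Ve = Ve, Vab = Vab,
         Vae = Vae, Vbe = Vbe,
         Vabe = Vz - Va - Vb - Ve - Vab - Vae - Vbe,
         VA = sa2 * stats::dnorm(m)^2 / s2)
  })
}

#' Posterior phenotypic decomposition per occasion and cohort
#'
#' Applies the phenotypic variance decomposition per posterior draw and
#' occasion-by-cohort cell (intercept of the cell, variance components of
#' the cell's season) and summarizes the posteriors. The per-draw
#' back-transformation uses the closed-form components, which agree with
#' the default quadrature to near machine precision.
#'
#' @param draws A `cram_draws` object (or anything [summarize_liability()]
#'   accepts that also carries `mu[o,c]` columns).
#' @param vna See [decompose_phenotype()].
#' @return A `pheno_decomposition`: list with `cells` (long data frame:
#'   occasion, cohort, season, component, mean, lo95, hi95), `cell_index`,
#'   and `draws` (list of per-component draw matrices, draws x cells) used
#'   by [seasonal_grand_means()].
#' @export
posterior_decompose <- function(draws, vna = c("main", "interactions")) {
  vna <- match.arg(vna)
  m <- if (inherits(draws, "cram_draws")) draws$draws else as.matrix(draws)
  mu_cols <- grep("^mu\\[", colnames(m), value = TRUE)
  if (!length(mu_cols)) stopf("draws lack mu[o,c] columns")
  occ <- as.integer(sub("^mu\\[(\\d),.*$", "\\1", mu_cols))
  coh <- sub("^mu\\[\\d,(.*)\\]$", "\\1", mu_cols)
  sa_cols <- grep("^sigma_a\\[", colnames(m), value = TRUE)
  sb_cols <- grep("^sigma_b\\[", colnames(m), value = TRUE)
  seasons <- gsub("^sigma_a\\[|\\]$", "", sa_cols)
  if (any(!2:5 %in% occ)) stopf("missing occasion intercepts")
  season_of_occ <- if (length(seasons) == 1L) rep(1L, 4L) else c(1L, 1L, 2L, 2L)

  cells <- data.frame(occasion = occ, cohort = coh,
                      season = seasons[season_of_occ[occ - 1L]],
                      col = mu_cols, stringsAsFactors = FALSE)
  cells <- cells[order(cells$cohort, cells$occasion), ]
  comp_names <- c("zbar", "Vz", "Va", "Vb", "Ve", "Vab", "Vae", "Vbe",
                  "Vabe", "VA", "VNA", "h2_z", "rho_z")
  dr <- lapply(comp_names, function(x)
    matrix(NA_real_, nrow(m), nrow(cells)))
  names(dr) <- comp_names

  for (k in seq_len(nrow(cells))) {
    s <- match(cells$season[k], seasons)
    sa2 <- m[, sa_cols[s]]^2; sb2 <- m[, sb_cols[s]]^2
    comp <- pheno_components(m[, cells$col[k]], sa2, sb2)
    comp$VNA <- if (vna == "main") comp$Va - comp$VA
                else comp$Va - comp$VA + comp$Vab + comp$Vae + comp$Vabe
    small <- comp$Vz < 1e-12
    comp$h2_z <- ifelse(small, 0, comp$VA / comp$Vz)
    comp$rho_z <- ifelse(small, 0, (comp$Va + comp$Vb + comp$Vab) / comp$Vz)
    for (q in comp_names) dr[[q]][, k] <- comp[[q]]
  }

  long <- do.call(rbind, lapply(comp_names, function(q) {
    sm <- t(apply(dr[[q]], 2, post_sum))
    data.frame(occasion = cells$occasion, cohort = cells$cohort,
               season = cells$season, component = q, sm,
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  structure(list(cells = long,
                 cell_index = cells[, c("occasion", "cohort", "season")],
                 draws = dr),
            class = "pheno_decomposition")
}

#' @export
print.pheno_decomposition <- function(x, ...) {
  cat(sprintf("<pheno_decomposition> %d cells x %d components\n",
              nrow(x$cell_index), length(x$draws)))
  invisible(x)
}

#' Seasonal grand means and autumn-winter contrasts
#'
#' For each posterior draw, averages a phenotypic-scale quantity over the
#' occasions of each season and over cohorts (equal weights by default),
#' then summarizes the seasonal grand means, their difference
#' (first season minus second) and the posterior probability that the
#' difference is positive.
#'
#' @param pd A `pheno_decomposition` from [posterior_decompose()].
#' @param quantities Components to summarize.
#' @param weights Optional per-cell weights (length = number of cells).
#' @return Data frame: quantity, season (or `"diff"`), mean, lo95, hi95 and
#'   `prob_greater` on the contrast rows.
#' @export
seasonal_grand_means <- function(pd, quantities = c("Va", "h2_z", "zbar",
                                                    "rho_z"),
                                 weights = NULL) {
  idx <- pd$cell_index
  seasons <- unique(idx$season)
  weights <- weights %||% rep(1, nrow(idx))
  out <- list()
  for (q in quantities) {
    mq <- pd$draws[[q]]
    gm <- lapply(seasons, function(s) {
      sel <- idx$season == s
      w <- weights[sel] / sum(weights[sel])
      as.numeric(mq[, sel, drop = FALSE] %*% w)
    })
    names(gm) <- seasons
    for (s in seasons) {
      out[[length(out) + 1L]] <- data.frame(
        quantity = q, season = s, t(post_sum(gm[[s]])),
        prob_greater = NA_real_, stringsAsFactors = FALSE)
    }
    if (length(seasons) == 2L) {
      dd <- gm[[1]] - gm[[2]]
      out[[length(out) + 1L]] <- data.frame(
        quantity = q, season = sprintf("%s - %s", seasons[1], seasons[2]),
        t(post_sum(dd)),
        prob_greater = prob_greater(gm[[1]], gm[[2]]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the phenotypic decomposition to CSV
#'
#' Long format: occasion, cohort, season, component, mean, lo95, hi95.
#'
#' @param pd A `pheno_decomposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pheno_decomposition <- function(pd, path) {
  utils::write.csv(pd$cells, path, row.names = FALSE)
  invisible(path)
}
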
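#' Liability-scale derived quantities for one draw (or vector of draws)
#'
#' On the standardized liability scale the residual variance is 1 by
#' construction, so the total liability variance is
#' \eqn{\sigma_L^{*2} = \sigma_a^{*2} + \sigma_b^{*2} + 1} and the derived
#' ratios are
#' \eqn{h_\ell^2 = \sigma_a^{*2}/\sigma_L^{*2}} (heritability),
#' \eqn{\chi_\ell = \sigma_b^{*2}/\sigma_L^{*2}} (individual-variance
#' proportion) and
#' \eqn{\rho_\ell = (\sigma_a^{*2}+\sigma_b^{*2})/\sigma_L^{*2}}
#' (repeatability).
#'
#' @param sa2,sb2 Additive genetic and individual variances (standardized
#'   scale); vectorized over draws.
#' @return Data frame with columns `sigma_L2`, `h2`, `chi`, `rho`.
#' @export
liability_ratios <- function(sa2, sb2) {
  if (any(sa2 < 0) || any(sb2 < 0)) stopf("variances must be non-negative")
  sL2 <- sa2 + sb2 + 1
  data.frame(sigma_L2 = sL2, h2 = sa2 / sL2, chi = sb2 / sL2,
             rho = (sa2 + sb2) / sL2)
}

#' Posterior probability that one quantity exceeds another
#'
#' Fraction of paired posterior draws with `x > y`; exact ties count 0.5,
#' which keeps the statistic well-defined for degenerate inputs and makes
#' `prob_greater(x, x) == 0.5`.
#'
#' @param x,y Equal-length vectors of paired draws.
#' @return Probability in `[0, 1]`.
#' @export
prob_greater <- function(x, y) {
  if (length(x) != length(y)) stopf("draw vectors differ in length")
  mean((x > y) + 0.5 * (x == y))
}

post_sum <- function(x) {
  c(mean = mean(x), lo95 = unname(stats::quantile(x, 0.025)),
    hi95 = unname(stats::quantile(x, 0.975)))
}

#' Posterior summaries of liability-scale derived parameters
#'
#' Computes, per posterior draw, the total standardized liability variance
#' and the heritability, individual-variance proportion and repeatability
#' for each season, then summarizes their posteriors (mean and equal-tailed
#' 95% credible interval). Reported quantities are posterior means of the
#' per-draw ratios, not ratios of posterior means. For a two-season fit the
#' cross-season block gives the heritability difference
#' (autumn - winter) and the posterior probability that autumn heritability
#' exceeds winter's.
#'
#' @param draws A `cram_draws` object, or a data frame / matrix containing
#'   columns `sigma_a[<season>]` and `sigma_b[<season>]` (SD scale).
#' @return List with `per_season` (long data frame: parameter, season, mean,
#'   lo95, hi95) and, when two seasons are present, `cross_season`.
#' @export
summarize_liability <- function(draws) {
  m <- if (inherits(draws, "cram_draws")) draws$draws else as.matrix(draws)
  sa_cols <- grep("^sigma_a\\[", colnames(m), value = TRUE)
  sb_cols <- grep("^sigma_b\\[", colnames(m), value = TRUE)
  if (!length(sa_cols) || !length(sb_cols)) {
    stopf("draws lack sigma_a[...] / sigma_b[...] columns")
  }
  seasons <- gsub("^sigma_a\\[|\\]$", "", sa_cols)

  per_draw <- lapply(seq_along(seasons), function(s) {
    liability_ratios(m[, sa_cols[s]]^2, m[, sb_cols[s]]^2)
  })
  per_season <- do.call(rbind, lapply(seq_along(seasons), function(s) {
    rr <- per_draw[[s]]
    do.call(rbind, lapply(c("sigma_L2", "h2", "chi", "rho"), function(q) {
      data.frame(parameter = q, season = seasons[s],
                 t(post_sum(rr[[q]])), stringsAsFactors = FALSE)
    }))
  }))
  extra <- do.call(rbind, lapply(seq_along(seasons), function(s) {
    data.frame(parameter = c("sigma_a2", "sigma_b2"), season = seasons[s],
               rbind(post_sum(m[, sa_cols[s]]^2), post_sum(m[, sb_cols[s]]^2)),
               stringsAsFactors = FALSE)
  }))
  per_season <- rbind(extra, per_season)
  rownames(per_season) <- NULL

  out <- list(per_season = per_season)
  if (length(seasons) == 2L) {
    dh <- per_draw[[1]]$h2 - per_draw[[2]]$h2
    out$cross_season <- data.frame(
      parameter = "d_h2", contrast = paste(seasons, collapse = " - "),
      t(post_sum(dh)),
      prob_greater = prob_greater(per_draw[[1]]$h2, per_draw[[2]]$h2),
      stringsAsFactors = FALSE)
  }
  out
}

#' Write a liability summary to CSV
#'
#' @param x Result of [summarize_liability()].
#' @param path Output path; the cross-season block, when present, is
#'   appended with parameter `d_h2`.
#' @return `path`, invisibly.
#' @export
write_liability_summary <- function(x, path) {
  df <- x$per_season
  if (!is.null(x$cross_season)) {
    cs <- data.frame(parameter = x$cross_season$parameter,
                     season = x$cross_season$contrast,
                     mean = x$cross_season$mean, lo95 = x$cross_season$lo95,
                     hi95 = x$cross_season$hi95, stringsAsFactors = FALSE)
    df <- rbind(df, cs)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
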
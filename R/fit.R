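#' Fit the capture-recapture animal model
#'
#' Samples the joint posterior of the CRAM — structural survival, movement
#' and detection probabilities, occasion-by-cohort liability intercepts, and
#' season-specific additive genetic and permanent individual variance
#' components — by an adaptive Metropolis-within-Gibbs sampler. Breeding
#' values for the full pedigree are updated single-site against their sparse
#' conditional prior (from the pedigree inverse-relationship matrix);
#' pedigree members without encounter data are Gibbs-sampled exactly. Each
#' SD parameter gets both a centred update and an
#' ancillarity-sufficiency-interweaving rescaling move, so mixing does not
#' collapse when the posterior concentrates near zero variance.
#'
#' @param histories An `encounter_histories` data frame.
#' @param pedigree A `cram_pedigree` (any order; sorted internally). Every
#'   history id must appear in it after pruning.
#' @param config A [cram_config()].
#' @param seed Integer seed; fits are reproducible given `seed` and config.
#' @param A Optional precomputed [make_A()] of the sorted pedigree (or a
#'   permuted version from [permute_A()] for the randomized-A null check).
#' @param prune Drop phenotyped individuals that are genetically
#'   uninformative before fitting (default `TRUE`; see
#'   [prune_informative()]).
#' @param init Optional named list of initial values (any of `mu`, `sa`,
#'   `sb`, `phiR`, `phiM`, `delta`, `gamma`, `p`, `p6`, `a`, `b`, shaped as
#'   the sampler's internal arrays); used for warm starts and diagnostics.
#'   Unset components keep their random overdispersed initialization.
#' @return A `cram_draws` object: matrix of posterior draws (one row per
#'   draw; columns are flattened parameters) with chain/iteration indices
#'   and convergence diagnostics (split-Rhat, effective sample size).
#' @export
cram_fit <- function(histories, pedigree, config = cram_config(), seed,
                     A = NULL, prune = TRUE, init = NULL) {
  stopifnot(inherits(config, "cram_config"))
  ped <- sort_pedigree(as_pedigree(pedigree))
  if (is.null(A)) A <- make_A(ped)
  if (!identical(A$ids, ped$id)) {
    stopf("relatedness matrix ids do not match the sorted pedigree")
  }
  Ainv <- make_Ainv(ped, if (is.null(A$permutation)) A else make_A(ped))

  keep <- histories$id
  missing_ids <- setdiff(keep, ped$id)
  if (length(missing_ids)) {
    if (!prune) {
      stopf("histories without pedigree rows: %s",
            paste(utils::head(missing_ids, 5L), collapse = ", "))
    }
    keep <- setdiff(keep, missing_ids)
  }
  if (prune) keep <- prune_informative(keep, A)
  dropped <- setdiff(histories$id, keep)
  if (length(dropped)) {
    message(sprintf("cram_fit: dropping %d uninformative individual(s)",
                    length(dropped)))
  }
  hh <- histories[match(keep, histories$id), , drop = FALSE]
  if (nrow(hh) < 2L) stopf("fewer than 2 informative histories")

  cohorts <- sort(unique(hh$cohort))
  C <- length(cohorts)
  events <- encode_events(hh)
  cohort_idx <- match(hh$cohort, cohorts) - 1L
  n_ped <- nrow(ped)
  hist_of_ped <- rep(-1L, n_ped)
  hist_of_ped[match(hh$id, ped$id)] <- seq_len(nrow(hh)) - 1L

  season_of_occ <- if (config$structure == "annual") rep(0L, 4L)
                   else c(0L, 0L, 1L, 1L)
  seasons <- if (config$structure == "annual") "annual"
             else c("autumn", "winter")

  # optional common-environment grouping for the A7-style robustness check
  group <- integer(0); G <- 0L
  if (config$extra_effect != "none") {
    prow <- ped[match(hh$id, ped$id), ]
    key <- switch(config$extra_effect,
                  brood = paste(prow$sire, prow$dam, prow$cohort),
                  maternal = prow$dam,
                  paternal = prow$sire)
    key[is.na(key)] <- paste0("solo_", hh$id[is.na(key)])
    group <- as.integer(factor(key)) - 1L
    G <- max(group) + 1L
  }

  # CSR of the symmetric sparse A-inverse (CSC of a symmetric matrix is its
  # own CSR)
  M <- as(as(Ainv, "generalMatrix"), "CsparseMatrix")
  ai_ptr <- M@p; ai_idx <- M@i; ai_val <- M@x

  # a permuted-A null: permute the phenotype-to-pedigree-row mapping, which
  # is equivalent to permuting A against the phenotypes
  if (!is.null(A$permutation)) {
    obs <- hist_of_ped
    hist_of_ped <- rep(-1L, n_ped)
    hist_of_ped[A$permutation] <- obs
  }

  par_names <- c(
    as.vector(vapply(cohorts, function(cc)
      sprintf("mu[%d,%s]", 2:5, cc), character(4))),
    sprintf("sigma_a[%s]", seasons),
    sprintf("sigma_b[%s]", seasons),
    if (G > 0L) sprintf("sigma_%s[%s]", config$extra_effect, seasons),
    as.vector(vapply(cohorts, function(cc)
      sprintf("phi[R,%d,%s]", 1:5, cc), character(5))),
    as.vector(vapply(cohorts, function(cc)
      sprintf("phi[M,%d,%s]", 2:5, cc), character(4))),
    as.vector(vapply(cohorts, function(cc)
      sprintf("delta[%d,%s]", 2:5, cc), character(4))),
    as.vector(vapply(cohorts, function(cc)
      sprintf("gamma[%d,%s]", 3:5, cc), character(3))),
    as.vector(vapply(cohorts, function(cc)
      sprintf("p[%s,%d,%s]", rep(c("R", "M1", "M2"), 4),
              rep(2:5, each = 3), cc), character(12))),
    sprintf("p6[%s]", cohorts),
    "loglik")

  res <- with_seed(seed, {
    lapply(seq_len(config$chains), function(ch) {
      out <- cram_mcmc_cpp(events, cohort_idx, C, hist_of_ped, season_of_occ,
                           ai_ptr, ai_idx, ai_val, group, G,
                           config$priors, config$warmup, config$iter,
                           config$thin, 1L, init %||% list())
      out$draws
    })
  })
  n_keep <- nrow(res[[1]])
  draws <- do.call(rbind, res)
  colnames(draws) <- par_names
  chain <- rep(seq_len(config$chains), each = n_keep)
  iteration <- rep(seq_len(n_keep), config$chains)

  diag_df <- fit_diagnostics(draws, chain, n_keep)
  fit <- structure(list(draws = draws, chain = chain, iteration = iteration,
                        pars = par_names, cohorts = cohorts,
                        seasons = seasons, config = config, seed = seed,
                        n_individuals = nrow(hh), dropped = dropped,
                        diagnostics = diag_df),
                   class = "cram_draws")

  key <- grepl("^(sigma_|mu\\[)", diag_df$parameter)
  bad <- diag_df[key & (diag_df$rhat > config$rhat_max |
                          diag_df$ess < config$ess_min), ]
  bad <- bad[stats::complete.cases(bad), ]
  if (nrow(bad)) {
    msg <- sprintf(
      "convergence tolerance exceeded for %d parameter(s), e.g. %s (Rhat %.3f, ESS %.0f)",
      nrow(bad), bad$parameter[1], bad$rhat[1], bad$ess[1])
    if (config$on_bad_convergence == "error") stopf("%s", msg) else warning(msg)
  }
  fit
}

fit_diagnostics <- function(draws, chain, n_keep) {
  chains <- length(unique(chain))
  data.frame(
    parameter = colnames(draws),
    rhat = vapply(seq_len(ncol(draws)), function(j)
      rhat(matrix(draws[, j], n_keep, chains)), numeric(1)),
    ess = vapply(seq_len(ncol(draws)), function(j)
      ess(matrix(draws[, j], n_keep, chains)), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Extract draws of selected parameters
#'
#' @param fit A `cram_draws` object.
#' @param pattern Regular expression matched against parameter names; `NULL`
#'   returns everything.
#' @return Matrix of draws (rows = draws across chains).
#' @export
draws_of <- function(fit, pattern = NULL) {
  stopifnot(inherits(fit, "cram_draws"))
  if (is.null(pattern)) return(fit$draws)
  sel <- grepl(pattern, colnames(fit$draws))
  if (!any(sel)) stopf("no parameters match '%s'", pattern)
  fit$draws[, sel, drop = FALSE]
}

#' @export
print.cram_draws <- function(x, ...) {
  cat(sprintf(
    "<cram_draws> %d draws (%d chains x %d), %d parameters, %d individuals\n",
    nrow(x$draws), length(unique(x$chain)),
    nrow(x$draws) / length(unique(x$chain)), ncol(x$draws),
    x$n_individuals))
  key <- grepl("^sigma_", x$diagnostics$parameter)
  print(x$diagnostics[key, ], row.names = FALSE)
  invisible(x)
}

#' Posterior summary of a fit
#'
#' @param object A `cram_draws` object.
#' @param pattern Optional regular expression restricting the parameters.
#' @param ... Unused.
#' @return Data frame with posterior mean, SD, equal-tailed 95% interval,
#'   split-Rhat and ESS per parameter.
#' @export
summary.cram_draws <- function(object, pattern = NULL, ...) {
  d <- draws_of(object, pattern)
  qs <- t(apply(d, 2, stats::quantile, probs = c(0.025, 0.975)))
  out <- data.frame(parameter = colnames(d), mean = colMeans(d),
                    sd = apply(d, 2, stats::sd),
                    lo95 = qs[, 1], hi95 = qs[, 2],
                    stringsAsFactors = FALSE)
  merge(out, object$diagnostics, by = "parameter", sort = FALSE)
}

#' Write posterior draws to a tabular file
#'
#' One row per draw; columns are the flattened parameters plus `chain` and
#' `iteration`.
#'
#' @param fit A `cram_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  df <- data.frame(chain = fit$chain, iteration = fit$iteration,
                   fit$draws, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param path Draws CSV path.
#' @return A `cram_draws` object (diagnostics recomputed; config absent).
#' @export
read_draws <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stopf("draws file is empty")
  if (!all(c("chain", "iteration") %in% names(df))) {
    stopf("draws file lacks chain/iteration columns")
  }
  m <- as.matrix(df[, setdiff(names(df), c("chain", "iteration")), drop = FALSE])
  sa <- grep("^sigma_a\\[", colnames(m), value = TRUE)
  seasons <- gsub("^sigma_a\\[|\\]$", "", sa)
  mu_cols <- grep("^mu\\[", colnames(m), value = TRUE)
  cohorts <- sort(unique(sub("^mu\\[\\d,(.*)\\]$", "\\1", mu_cols)))
  n_keep <- sum(df$chain == df$chain[1])
  structure(list(draws = m, chain = df$chain, iteration = df$iteration,
                 pars = colnames(m), cohorts = cohorts, seasons = seasons,
                 config = NULL, seed = NA,
                 n_individuals = NA,
                 diagnostics = fit_diagnostics(m, df$chain, n_keep)),
            class = "cram_draws")
}
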
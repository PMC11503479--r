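# End-to-end orchestration: config-file driven simulate / fit / decompose
# runs. Each run writes a resolved-config copy and a small log (seed,
# package version) into the output directory for reproducibility. A thin
# command-line wrapper over these functions ships in inst/cli/cram.R.

read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stopf("config must be a YAML file path or a list")
  if (is.null(cfg$seed)) stopf("config must set a `seed`")
  cfg
}

resolve_scenario <- function(cfg) {
  sc <- default_scenario(n_cohorts = cfg$scenario$n_cohorts %||% 2L,
                         base_year = cfg$scenario$base_year %||% 2010L)
  for (f in c("n_founders", "n_generations", "mean_brood")) {
    if (!is.null(cfg$scenario[[f]])) sc[[f]] <- cfg$scenario[[f]]
  }
  sc
}

resolve_sampler <- function(cfg) {
  s <- cfg$sampler %||% list()
  m <- cfg$model %||% list()
  cram_config(structure = m$structure %||% "seasonal",
              extra_effect = m$extra_effect %||% "none",
              chains = s$chains %||% 4L, warmup = s$warmup %||% 1000L,
              iter = s$iter %||% 2000L, thin = s$thin %||% 1L,
              priors = m$priors %||% list())
}

write_run_log <- function(cfg, out_dir, what) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out_dir, "resolved_config.yaml"))
  writeLines(c(sprintf("run: %s", what),
               sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               sprintf("seed: %s", cfg$seed),
               sprintf("cramr: %s",
                       as.character(utils::packageVersion("cramr")))),
             file.path(out_dir, "run_log.txt"))
}

#' Run the synthetic-data generator end to end
#'
#' @param config YAML path or list: must set `seed`; optional `scenario`
#'   block (`n_founders`, `n_generations`, `mean_brood`, `n_cohorts`,
#'   `base_year`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written: `pedigree.csv`, `histories.csv`,
#'   `truth_effects.csv`, `truth_states.csv`.
#' @export
run_simulate <- function(config, out_dir) {
  cfg <- read_run_config(config)
  sc <- resolve_scenario(cfg)
  dat <- simulate_cram_data(sc, seed = as.integer(cfg$seed))
  write_run_log(cfg, out_dir, "simulate")
  paths <- c(pedigree = file.path(out_dir, "pedigree.csv"),
             histories = file.path(out_dir, "histories.csv"),
             truth_effects = file.path(out_dir, "truth_effects.csv"),
             truth_states = file.path(out_dir, "truth_states.csv"))
  ped_out <- dat$pedigree[, c("id", "sire", "dam", "cohort")]
  utils::write.csv(ped_out, paths["pedigree"], row.names = FALSE, na = "")
  write_histories(dat$histories, paths["histories"])
  eff <- data.frame(id = rownames(dat$truth$a), dat$truth$a)
  names(eff)[-1] <- sprintf("a_%d", seq_len(ncol(dat$truth$a)))
  bm <- dat$truth$b[match(eff$id, rownames(dat$truth$b)), , drop = FALSE]
  for (s in seq_len(ncol(bm))) eff[[sprintf("b_%d", s)]] <- bm[, s]
  utils::write.csv(eff, paths["truth_effects"], row.names = FALSE, na = "")
  st <- data.frame(id = rownames(dat$truth$states), dat$truth$states)
  names(st)[-1] <- sprintf("occ%d", 1:6)
  utils::write.csv(st, paths["truth_states"], row.names = FALSE)
  invisible(paths)
}

#' Fit the CRAM from files
#'
#' Reads a pedigree plus either prebuilt encounter histories or raw
#' resightings with a ringing table (histories are then built first), fits
#' the model, and writes posterior draws, diagnostics and the liability
#' summary.
#'
#' @param config YAML path or list: `seed`, `paths` block (`pedigree`, and
#'   `histories` or `resightings` + `ringing`), optional `model` and
#'   `sampler` blocks, optional `null_permute: true` to also run the
#'   randomized-A null refit.
#' @param out_dir Output directory.
#' @return The fitted `cram_draws`, invisibly.
#' @export
run_fit <- function(config, out_dir) {
  cfg <- read_run_config(config)
  paths <- cfg$paths %||% stopf("config must set a `paths` block")
  ped <- read_pedigree(paths$pedigree)
  hh <- if (!is.null(paths$histories)) {
    read_histories(paths$histories)
  } else {
    rs <- utils::read.csv(paths$resightings, colClasses = c(id = "character"))
    rg <- utils::read.csv(paths$ringing, colClasses = c(id = "character"))
    build_histories(rs, rg)
  }
  config_fit <- resolve_sampler(cfg)
  fit <- cram_fit(hh, ped, config_fit, seed = as.integer(cfg$seed))
  write_run_log(cfg, out_dir, "fit")
  write_draws(fit, file.path(out_dir, "draws.csv"))
  utils::write.csv(fit$diagnostics, file.path(out_dir, "diagnostics.csv"),
                   row.names = FALSE)
  write_liability_summary(summarize_liability(fit),
                          file.path(out_dir, "liability_summary.csv"))
  if (isTRUE(cfg$null_permute)) {
    sped <- sort_pedigree(as_pedigree(ped))
    A_perm <- permute_A(make_A(sped), seed = as.integer(cfg$seed) + 1L)
    keep <- setdiff(hh$id, fit$dropped)
    nf <- cram_fit(hh[match(keep, hh$id), ], sped, config_fit,
                   seed = as.integer(cfg$seed) + 2L, A = A_perm,
                   prune = FALSE)
    write_draws(nf, file.path(out_dir, "draws_null_permuted.csv"))
    write_liability_summary(summarize_liability(nf),
                            file.path(out_dir, "liability_summary_null.csv"))
  }
  invisible(fit)
}

#' Derived summaries and phenotypic decomposition from a draws file
#'
#' @param draws_path A draws CSV written by [write_draws()].
#' @param out_dir Output directory.
#' @param vna See [decompose_phenotype()].
#' @return Invisibly, a list with the liability summary and the
#'   `pheno_decomposition`.
#' @export
run_decompose <- function(draws_path, out_dir, vna = "main") {
  fit <- read_draws(draws_path)
  ls <- summarize_liability(fit)
  pd <- posterior_decompose(fit, vna = vna)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_liability_summary(ls, file.path(out_dir, "liability_summary.csv"))
  write_pheno_decomposition(pd, file.path(out_dir, "pheno_decomposition.csv"))
  utils::write.csv(seasonal_grand_means(pd),
                   file.path(out_dir, "seasonal_grand_means.csv"),
                   row.names = FALSE)
  invisible(list(liability = ls, pheno = pd))
}
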
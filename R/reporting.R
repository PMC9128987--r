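## Pipeline entry points: generate / evaluate / sweep, each writing CSV
## outputs plus a JSON manifest (config + seed + package version) from which
## the run can be reproduced byte-for-byte.

.write_manifest <- function(dir, command, params) {
  manifest <- list(package = "scrrobust",
                   version = as.character(utils::packageVersion("scrrobust")),
                   command = command, params = params)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a synthetic null dataset and write it to disk
#'
#' Writes `dataset.csv` (long trial-level format) and `manifest.json` into
#' `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_participants,seed,sigma_subject,sigma_noise Passed to
#'   [generator_config()].
#' @return Invisibly, the path of the written CSV.
#' @export
cmd_generate <- function(out_dir, n_participants = 379L, seed = 1L,
                         sigma_subject = 0.2, sigma_noise = 0.25) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- generator_config(n_participants = n_participants, seed = seed,
                          sigma_subject = sigma_subject,
                          sigma_noise = sigma_noise)
  d <- generate_null_population(cfg)
  path <- file.path(out_dir, "dataset.csv")
  write_long_csv(d, path)
  .write_manifest(out_dir, "generate",
                  list(n_participants = cfg$n_participants, seed = cfg$seed,
                       sigma_subject = cfg$sigma_subject,
                       sigma_noise = cfg$sigma_noise,
                       mu = as.list(cfg$mu)))
  invisible(path)
}

#' Evaluate the strategy catalogue on a stored dataset
#'
#' Reads a labelled long CSV, runs all 15 strategies and writes a 15-row
#' results CSV (`id`, `category`, `eta_p2`, `n_subjects`, `degenerate`).
#'
#' @param dataset_path Path to a group-labelled long CSV.
#' @param out_file Output CSV path.
#' @return Invisibly, the results data frame.
#' @export
cmd_evaluate <- function(dataset_path, out_file) {
  d <- read_long_csv(dataset_path)
  if (is.null(d$group))
    stop("dataset must carry group labels for strategy evaluation")
  res <- evaluate_all(d)
  utils::write.csv(res, out_file, row.names = FALSE, quote = FALSE)
  invisible(res)
}

#' Run a robustness sweep and write its report files
#'
#' Orchestrates [size_sweep()], [trend_analysis()] and
#' [effect_size_trend()] (the trend files require >= 3 sizes), writing into
#' `out_dir`:
#' `pairwise_taub.csv` (per size and strategy pair: mean tau-b with CI),
#' `per_strategy_taub.csv` (per strategy: mean tau-b vs the others of its
#' category), `taub_trends.csv` (Pearson trend of mean tau-b vs size with
#' BH-FDR flags per category family), `effect_size_by_size.csv` (per-size
#' category-mean eta_p^2), `effect_size_trends.csv`, `degenerate_counts.csv`
#' and `manifest.json`.
#'
#' @param out_dir Output directory (created if needed).
#' @param source_path Optional path to a long CSV used as the bootstrap
#'   source; if `NULL`, a synthetic null population of
#'   `n_source` participants is generated from `config$seed`.
#' @param config A [resample_config()].
#' @param n_source Synthetic source size when `source_path` is `NULL`
#'   (default 379).
#' @return Invisibly, the `robustness_result`.
#' @export
cmd_sweep <- function(out_dir, source_path = NULL,
                      config = resample_config(), n_source = 379L) {
  stopifnot(inherits(config, "resample_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  source <- if (is.null(source_path)) {
    generate_null_population(generator_config(n_participants = n_source,
                                              seed = config$seed))
  } else read_long_csv(source_path)

  res <- size_sweep(source, config)
  wcsv <- function(x, f) utils::write.csv(
    x, file.path(out_dir, f), row.names = FALSE, quote = FALSE)
  wcsv(res$pairs, "pairwise_taub.csv")
  wcsv(res$per_strategy, "per_strategy_taub.csv")
  wcsv(res$degenerate, "degenerate_counts.csv")
  if (length(config$sizes) >= 3L) {
    est <- effect_size_trend(res)
    wcsv(attr(est, "by_size"), "effect_size_by_size.csv")
    wcsv(est, "effect_size_trends.csv")
    wcsv(trend_analysis(res), "taub_trends.csv")
  }
  .write_manifest(out_dir, "sweep",
                  list(source = if (is.null(source_path)) "synthetic"
                       else source_path,
                       n_source = if (is.null(source_path)) n_source else
                         n_participants(source),
                       sizes = config$sizes,
                       n_resamples = config$n_resamples,
                       n_ci_boot = config$n_ci_boot, mode = config$mode,
                       effect = config$effect, n_groups = config$n_groups,
                       ci_level = config$ci_level, seed = config$seed))
  invisible(res)
}
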
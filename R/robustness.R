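#' Configuration of a robustness sweep
#'
#' @param sizes Sample sizes (bootstrapped rows) to sweep. Default: the
#'   16-point grid 30, 60, 120, 180, 240, 360, 480, 600, 720, 840, 960,
#'   1080, 1200, 1500, 1750, 2000.
#' @param n_resamples Bootstrapped datasets per size over which the
#'   strategy effect-size matrix is built (default 100).
#' @param n_ci_boot Bootstrap replicates of the tau-b inputs used for the
#'   mean and 95 percent CI of each pairwise correlation (default 1000).
#' @param mode `"phase_wise"` (each phase x stimulus block of trials is
#'   resampled independently across participants, creating chimeric rows) or
#'   `"full_row"` (whole participants are resampled).
#' @param effect Simulated group-level effect applied to Group 3:
#'   `"none"`, `"base"`, `"a"` or `"b"` (see [builtin_schedule()]).
#' @param n_groups Number of equally allocated groups (default 3).
#' @param ci_level Confidence level for percentile intervals (default 0.95).
#' @param seed Master seed; one substream is derived per (size, resample)
#'   so partial sweeps agree with full serial runs.
#' @return A validated object of class `resample_config`.
#' @export
resample_config <- function(sizes = c(30, 60, 120, 180, 240, 360, 480, 600,
                                      720, 840, 960, 1080, 1200, 1500, 1750,
                                      2000),
                            n_resamples = 100L, n_ci_boot = 1000L,
                            mode = c("phase_wise", "full_row"),
                            effect = c("none", "base", "a", "b"),
                            n_groups = 3L, ci_level = 0.95, seed = 1L) {
  mode <- match.arg(mode)
  effect <- match.arg(effect)
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || anyNA(sizes) || any(sizes < 1L))
    stop("`sizes` must be positive integers")
  if (n_resamples < 2L) stop("`n_resamples` must be >= 2")
  if (n_ci_boot < 1L) stop("`n_ci_boot` must be >= 1")
  if (ci_level <= 0 || ci_level >= 1) stop("`ci_level` must be in (0, 1)")
  structure(list(sizes = sizes, n_resamples = as.integer(n_resamples),
                 n_ci_boot = as.integer(n_ci_boot), mode = mode,
                 effect = effect, n_groups = as.integer(n_groups),
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "resample_config")
}

#' Bootstrap a dataset by rows
#'
#' `"phase_wise"` mode draws, independently for each of the six
#' phase x stimulus trial blocks, `n_rows` source participants with
#' replacement and assembles chimeric rows from the drawn blocks — so a
#' synthetic participant's acquisition CS+ trials may come from a different
#' source participant than its late-extinction CS- trials. `"full_row"`
#' mode draws whole participants with replacement. Fresh row identifiers
#' are assigned either way; group labels are not carried over.
#'
#' @param source A non-empty `scr_dataset`.
#' @param n_rows Number of rows to draw.
#' @param mode `"phase_wise"` or `"full_row"`.
#' @return An unlabelled `scr_dataset` of `n_rows` rows. Uses the current
#'   RNG stream.
#' @export
bootstrap_dataset <- function(source, n_rows,
                              mode = c("phase_wise", "full_row")) {
  stopifnot(inherits(source, "scr_dataset"))
  mode <- match.arg(mode)
  n_src <- nrow(source$responses)
  if (n_src == 0L) stop("source dataset is empty")
  n_rows <- as.integer(n_rows)
  resp <- matrix(NA_real_, n_rows, 30L)
  if (mode == "full_row") {
    idx <- sample.int(n_src, n_rows, replace = TRUE)
    resp <- source$responses[idx, , drop = FALSE]
  } else {
    for (ph in PHASES) for (st in STIMULI) {
      cols <- .block_cols(ph, st)
      idx <- sample.int(n_src, n_rows, replace = TRUE)
      resp[, cols] <- source$responses[idx, cols, drop = FALSE]
    }
  }
  scr_dataset(resp, participant = sprintf("b%05d", seq_len(n_rows)))
}

#' Equal random group allocation
#'
#' Allocates `n` rows to `k` groups whose sizes differ by at most 1:
#' `floor(n/k)` per group, with the remainder spread over randomly chosen
#' groups, and the assignment order randomised.
#'
#' @param n Number of rows (>= k).
#' @param k Number of groups (default 3).
#' @return Integer vector of length `n` with labels in `1..k`. Uses the
#'   current RNG stream.
#' @export
allocate_groups <- function(n, k = 3L) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < k) stop("cannot allocate ", n, " rows to ", k, " groups")
  base <- rep(seq_len(k), floor(n / k))
  extra <- if (n %% k > 0L) sample.int(k, n %% k) else integer(0)
  sample(c(base, extra))
}

#' Kendall tau-b rank correlation
#'
#' `tau_b = (C - D) / sqrt((C + D + Tx)(C + D + Ty))` where C and D count
#' concordant and discordant pairs and Tx/Ty count pairs tied only in x /
#' only in y. Used to measure agreement in the ordering that two analytic
#' strategies impose on the same bootstrapped datasets.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return tau-b in `[-1, 1]`; errors if either vector is entirely tied.
#' @examples
#' kendall_tau_b(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 1/3
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 2L) stop("x and y must have equal length >= 2")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  dx <- dx[up]; dy <- dy[up]
  cd <- sum(dx * dy)               # C - D
  nx <- sum(dx != 0)               # pairs untied in x = C + D + Ty
  ny <- sum(dy != 0)               # pairs untied in y = C + D + Tx
  if (nx == 0L || ny == 0L)
    stop("tau-b is undefined when a vector is entirely tied")
  cd / sqrt(as.double(nx) * as.double(ny))
}

#' Percentile confidence interval
#'
#' Empirical percentile interval with linear interpolation between order
#' statistics (quantile type 7).
#'
#' @param samples Numeric vector of >= 2 bootstrap statistics.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
percentile_ci <- function(samples, level = 0.95) {
  if (length(samples) < 2L) stop("need >= 2 samples")
  a <- (1 - level) / 2
  stats::quantile(samples, c(a, 1 - a), type = 7, names = FALSE, na.rm = TRUE)
}

#' Strategy effect-size matrix at one sample size
#'
#' Runs `n_resamples` iterations of the bootstrap pipeline at a fixed
#' sample size: bootstrap the source, allocate equal random groups,
#' optionally inject the configured group-level effect into Group 3 (SD
#' reference computed from the bootstrapped sample before injection), and
#' evaluate all 15 strategies.
#'
#' @param source Source `scr_dataset`.
#' @param size Sample size (rows per bootstrapped dataset).
#' @param config A [resample_config()]; `config$seed` determines one
#'   substream per (size, resample) so results are reproducible and
#'   order-independent.
#' @return An `effect_matrix` object: `n_resamples x 15` matrix of partial
#'   eta squared (NA where an ANOVA stratum was degenerate) with attributes
#'   `size` and `degenerate` (per-strategy NA counts).
#' @export
strategy_effect_matrix <- function(source, size, config = resample_config()) {
  stopifnot(inherits(source, "scr_dataset"),
            inherits(config, "resample_config"))
  schedule <- if (config$effect != "none") builtin_schedule(config$effect)
  ids <- strategy_catalogue()$id
  mat <- matrix(NA_real_, config$n_resamples, length(ids),
                dimnames = list(NULL, ids))
  for (r in seq_len(config$n_resamples)) {
    res <- with_seed(derive_seed(config$seed, size, r), {
      d <- bootstrap_dataset(source, size, config$mode)
      d$group <- allocate_groups(size, config$n_groups)
      if (!is.null(schedule))
        d <- inject_effect(d, schedule, compute_sd_reference(d),
                           target_group = 3L)
      evaluate_all(d)
    })
    mat[r, ] <- res$eta_p2
  }
  structure(mat, size = size, degenerate = colSums(is.na(mat)),
            class = c("effect_matrix", class(mat)))
}

.category_pairs <- function() {
  cat <- strategy_catalogue()
  do.call(rbind, lapply(split(cat$id, cat$category), function(ids) {
    if (length(ids) < 2L) return(NULL)
    p <- utils::combn(ids, 2L)
    data.frame(strategy_a = p[1L, ], strategy_b = p[2L, ],
               stringsAsFactors = FALSE)
  }))
}

#' Pairwise Kendall tau-b robustness at one sample size
#'
#' For every within-category pair of strategies, correlates (tau-b) the two
#' strategies' partial eta squared values over the resampled datasets, then
#' bootstraps the `n_resamples` paired observations `n_ci_boot` times to
#' obtain the mean tau-b and its percentile confidence interval. Also
#' reports, per strategy, the average of its pairwise mean tau-b values
#' against the other strategies of its category.
#'
#' @param matrix An `effect_matrix` from [strategy_effect_matrix()].
#' @param config A [resample_config()].
#' @return A list with `pairs` (data frame: size, category, strategy_a,
#'   strategy_b, taub, mean_taub, ci_low, ci_high, n_used) and
#'   `per_strategy` (data frame: size, category, strategy, mean_vs_others).
#' @export
pairwise_robustness <- function(matrix, config = resample_config()) {
  stopifnot(inherits(config, "resample_config"))
  size <- attr(matrix, "size")
  pairs <- .category_pairs()
  cat_tab <- strategy_catalogue()
  pairs$category <- cat_tab$category[match(pairs$strategy_a, cat_tab$id)]
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- matrix[, pairs$strategy_a[i]]
    y <- matrix[, pairs$strategy_b[i]]
    ok <- !(is.na(x) | is.na(y))    # pairwise deletion of degenerate resamples
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L)
      stop("fewer than 2 non-degenerate paired values for ",
           pairs$strategy_a[i], " vs ", pairs$strategy_b[i])
    point <- kendall_tau_b(x, y)
    boots <- with_seed(derive_seed(config$seed, size, 1e7 + i), {
      vapply(seq_len(config$n_ci_boot), function(b) {
        idx <- sample.int(length(x), replace = TRUE)
        tryCatch(kendall_tau_b(x[idx], y[idx]), error = function(e) NA_real_)
      }, numeric(1))
    })
    ci <- percentile_ci(boots[!is.na(boots)], config$ci_level)
    out[[i]] <- data.frame(size = size, category = pairs$category[i],
                           strategy_a = pairs$strategy_a[i],
                           strategy_b = pairs$strategy_b[i],
                           taub = point,
                           mean_taub = mean(boots, na.rm = TRUE),
                           ci_low = ci[1L], ci_high = ci[2L],
                           n_used = length(x), stringsAsFactors = FALSE)
  }
  pairs_df <- do.call(rbind, out)
  rownames(pairs_df) <- NULL

  per <- do.call(rbind, lapply(split(pairs_df, pairs_df$category), function(p) {
    ids <- unique(c(p$strategy_a, p$strategy_b))
    data.frame(size = size, category = p$category[1L], strategy = ids,
               mean_vs_others = vapply(ids, function(s)
                 mean(p$mean_taub[p$strategy_a == s | p$strategy_b == s]),
                 numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(pairs = pairs_df, per_strategy = per)
}

#' Full robustness sweep across sample sizes
#'
#' The package's core experiment: for each configured sample size, build the
#' strategy effect-size matrix ([strategy_effect_matrix()]) and its pairwise
#' tau-b robustness summary ([pairwise_robustness()]).
#'
#' @param source Source `scr_dataset` (typically a synthetic null
#'   population from [generate_null_population()]).
#' @param config A [resample_config()].
#' @return A `robustness_result` list: `pairs` and `per_strategy` data
#'   frames stacked over sizes, `matrices` (one `effect_matrix` per size),
#'   `degenerate` (per-size, per-strategy NA counts) and `config`.
#' @export
size_sweep <- function(source, config = resample_config()) {
  stopifnot(inherits(source, "scr_dataset"),
            inherits(config, "resample_config"))
  mats <- lapply(config$sizes, function(s)
    strategy_effect_matrix(source, s, config))
  names(mats) <- as.character(config$sizes)
  rob <- lapply(mats, pairwise_robustness, config = config)
  deg <- do.call(rbind, lapply(mats, function(m)
    data.frame(size = attr(m, "size"), strategy = colnames(m),
               n_degenerate = as.integer(attr(m, "degenerate")),
               row.names = NULL, stringsAsFactors = FALSE)))
  rownames(deg) <- NULL
  structure(list(
    pairs = do.call(rbind, c(lapply(rob, `[[`, "pairs"),
                             list(make.row.names = FALSE))),
    per_strategy = do.call(rbind, c(lapply(rob, `[[`, "per_strategy"),
                                    list(make.row.names = FALSE))),
    matrices = mats, degenerate = deg, config = config),
    class = "robustness_result")
}

#' Sample-size trend of pairwise robustness
#'
#' For each within-category strategy pair, correlates the per-size mean
#' tau-b with sample size (Pearson, two-sided) and flags significance after
#' Benjamini-Hochberg false-discovery-rate control at Q = 0.1 within each
#' category's family of pairs.
#'
#' @param result A `robustness_result` from [size_sweep()] (needs >= 3
#'   sizes).
#' @param q FDR level (default 0.1).
#' @return Data frame: category, strategy_a, strategy_b, r, p, p_adj,
#'   fdr_significant. Pairs with a constant tau-b sequence get `NA` r/p and
#'   are excluded from the FDR family.
#' @export
trend_analysis <- function(result, q = 0.1) {
  pairs <- if (inherits(result, "robustness_result")) result$pairs else result
  if (length(unique(pairs$size)) < 3L)
    stop("trend analysis needs >= 3 sample sizes")
  key <- paste(pairs$category, pairs$strategy_a, pairs$strategy_b, sep = "|")
  out <- do.call(rbind, lapply(split(pairs, key), function(p) {
    r <- p_val <- NA_real_
    if (stats::sd(p$mean_taub) > 0 && nrow(p) >= 3L) {
      ct <- stats::cor.test(p$size, p$mean_taub, method = "pearson")
      r <- unname(ct$estimate); p_val <- ct$p.value
    }
    data.frame(category = p$category[1L], strategy_a = p$strategy_a[1L],
               strategy_b = p$strategy_b[1L], r = r, p = p_val,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$category, c("ACQ_EXT", "EXT", "EXT_EXT")),
                   out$strategy_a, out$strategy_b), ]
  rownames(out) <- NULL
  out$p_adj <- NA_real_
  for (cat in unique(out$category)) {
    sel <- out$category == cat & !is.na(out$p)
    out$p_adj[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  out$fdr_significant <- !is.na(out$p_adj) & out$p_adj <= q
  out
}

#' Sample-size trend of category-average effect sizes
#'
#' Averages the group-interaction partial eta squared across the strategies
#' of each category and correlates the average with sample size (Pearson,
#' two-sided). With `aggregate = "resample"` (default) each bootstrapped
#' dataset contributes one point per category (n = sizes x resamples),
#' which is the analysis under which the small-sample inflation of null
#' eta_p^2 is detectable; `aggregate = "size"` correlates the per-size
#' category means only (one point per size).
#'
#' @param result A `robustness_result` from [size_sweep()] (>= 3 sizes).
#' @param aggregate `"resample"` or `"size"`.
#' @return Data frame with one row per category: `category`, `r`, `p`,
#'   `n_points`; attribute `"by_size"` holds the per-size category means
#'   (category, size, mean_eta2).
#' @export
effect_size_trend <- function(result, aggregate = c("resample", "size")) {
  stopifnot(inherits(result, "robustness_result"))
  aggregate <- match.arg(aggregate)
  if (length(result$matrices) < 3L)
    stop("effect-size trend needs >= 3 sample sizes")
  cat_tab <- strategy_catalogue()
  cats <- unique(cat_tab$category)

  pts <- do.call(rbind, lapply(result$matrices, function(m) {
    do.call(rbind, lapply(cats, function(cc) {
      cols <- cat_tab$id[cat_tab$category == cc]
      data.frame(category = cc, size = attr(m, "size"),
                 mean_eta2 = rowMeans(m[, cols, drop = FALSE], na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(pts) <- NULL
  by_size <- stats::aggregate(mean_eta2 ~ category + size, data = pts, FUN = mean)
  by_size <- by_size[order(by_size$category, by_size$size), ]
  rownames(by_size) <- NULL

  dat <- if (aggregate == "resample") pts else by_size
  out <- do.call(rbind, lapply(cats, function(cc) {
    d <- dat[dat$category == cc, ]
    r <- p_val <- NA_real_
    if (stats::sd(d$mean_eta2) > 0) {
      ct <- stats::cor.test(d$size, d$mean_eta2, method = "pearson")
      r <- unname(ct$estimate); p_val <- ct$p.value
    }
    data.frame(category = cc, r = r, p = p_val, n_points = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "by_size") <- by_size
  out
}
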
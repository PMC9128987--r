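## The fifteen published analytic strategies, expressed declaratively and
## evaluated as the partial eta squared of each strategy's highest-order
## Group interaction. Trial-selection rules from the source studies'
## layouts are applied to this paradigm's 5 acquisition + 10 extinction
## trials; fractional selections round half up (last three-quarters of 10
## -> 8; quarters of 10 -> 3; halves of 10 -> 5; last half of 5 -> 3).

.STRATEGY_TABLE <- data.frame(
  id = c(paste0("ACQ_EXT.", 1:4), paste0("EXT.", 1:7), paste0("EXT_EXT.", 1:4)),
  category = c(rep("ACQ_EXT", 4), rep("EXT", 7), rep("EXT_EXT", 4)),
  index = c(1:4, 1:7, 1:4),
  trials_included = c(
    "all ACQ; last 2 EXT", "max differential ACQ; last 2 EXT",
    "all ACQ; last 3 EXT", "last half ACQ (3-5); first half EXT (1-5)",
    "last three-quarters EXT (3-10)", "early EXT (1-5), trial-by-trial",
    "last half EXT (6-10)", "last EXT trial (10)", "last 2 EXT (9-10)",
    "early EXT (1-5), running average", "first 2 EXT, trial-by-trial",
    "EXT halves (1-5 vs 6-10)", "EXT halves (1-5 vs 6-10)",
    "EXT quarters (1-3 vs 8-10)", "EXT halves (1-5 vs 6-10)"),
  aggregation = c("MEAN", "MEAN", "MEAN", "MEAN",
                  "MEAN", "TRIAL_BY_TRIAL", "MEAN", "SINGLE_TRIAL", "MEAN",
                  "RUNNING_AVERAGE", "TRIAL_BY_TRIAL",
                  "MEAN", "MEAN", "MEAN", "MEAN"),
  stimulus_handling = c("DIFFERENTIAL", "DIFFERENTIAL", "DIFFERENTIAL",
                        "DIFFERENTIAL", "BOTH", "BOTH", "BOTH",
                        "DIFFERENTIAL", "BOTH", "DIFFERENTIAL",
                        "DIFFERENTIAL", "BOTH", "DIFFERENTIAL",
                        "CSP_ONLY", "CSP_ONLY"),
  model_term = c("Group:Phase", "Group:Phase", "Group:Phase", "Group",
                 "Group:Stim", "Group:Trial:Stim", "Group:Stim", "Group",
                 "Group:Stim", "Group:Trial", "Group:Trial",
                 "Group:Phase:Stim", "Group:Phase", "Group:Phase",
                 "Group:Phase"),
  stringsAsFactors = FALSE
)

#' The built-in catalogue of fifteen analytic strategies
#'
#' Strategies fall into three categories according to the construct they
#' index: `ACQ_EXT` (change from acquisition to extinction, 4 strategies),
#' `EXT` (a static measure of extinction, 7 strategies) and `EXT_EXT`
#' (change across extinction, early vs late, 4 strategies). Each strategy
#' specifies a trial selection, an aggregation rule, a stimulus handling
#' (differential CS+ minus CS-, both stimuli as a factor, or CS+ only) and
#' the highest-order Group interaction whose partial eta squared is the
#' strategy's output.
#'
#' @return A list of 15 `strategy_spec` objects in catalogue order
#'   (`ACQ_EXT.1` ... `EXT_EXT.4`).
#' @seealso [strategy_catalogue()] for a tabular dump,
#'   [evaluate_strategy()] to run one.
#' @export
builtin_strategies <- function() {
  lapply(seq_len(nrow(.STRATEGY_TABLE)), function(i) {
    s <- as.list(.STRATEGY_TABLE[i, ])
    class(s) <- "strategy_spec"
    s
  })
}

#' Tabular description of the strategy catalogue
#'
#' @return A 15-row data frame (id, category, index, trials included,
#'   aggregation, stimulus handling, model term) suitable for export.
#' @export
strategy_catalogue <- function() .STRATEGY_TABLE

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("<strategy %s> %s | %s | %s | term %s\n", x$id,
              x$trials_included, x$aggregation, x$stimulus_handling,
              x$model_term))
  invisible(x)
}

## running-average rule: trials (1,2),(2,3),(3,4),(4,5) -> 4 pseudo-trials
.running_average <- function(mat) {
  (mat[, -ncol(mat), drop = FALSE] + mat[, -1L, drop = FALSE]) / 2
}

## Build the per-subject response matrix and within-factor layout for one
## strategy. Returns list(y = n x m matrix, within = data.frame or NULL).
.strategy_design <- function(dataset, spec) {
  dmat <- differential(dataset)  # n x 15, columns "<phase>.<trial>"
  acq_d <- dmat[, paste0("ACQ.", 1:5), drop = FALSE]
  ext_d <- dmat[, c(paste0("EXT_EARLY.", 1:5), paste0("EXT_LATE.", 1:5)),
                drop = FALSE]  # extinction trials 1..10, differential
  ext_p <- dataset$responses[, .ext_cols("CSP"), drop = FALSE]
  ext_m <- dataset$responses[, .ext_cols("CSM"), drop = FALSE]

  two_phase <- function(v1, v2)
    list(y = cbind(v1, v2),
         within = data.frame(Phase = c("1pre", "2post")))
  stim_pair <- function(p, m)
    list(y = cbind(p, m), within = data.frame(Stim = c("CSP", "CSM")))

  switch(spec$id,
    "ACQ_EXT.1" = two_phase(rowMeans(acq_d), rowMeans(ext_d[, 9:10])),
    "ACQ_EXT.2" = two_phase(apply(acq_d, 1L, max), rowMeans(ext_d[, 9:10])),
    "ACQ_EXT.3" = two_phase(rowMeans(acq_d), rowMeans(ext_d[, 8:10])),
    "ACQ_EXT.4" = list(y = matrix(rowMeans(acq_d[, 3:5]) - rowMeans(ext_d[, 1:5]),
                                  ncol = 1L),
                       within = NULL),
    "EXT.1" = stim_pair(rowMeans(ext_p[, 3:10]), rowMeans(ext_m[, 3:10])),
    "EXT.2" = list(y = cbind(ext_p[, 1:5], ext_m[, 1:5]),
                   within = data.frame(
                     Trial = as.character(rep(1:5, 2L)),
                     Stim = rep(c("CSP", "CSM"), each = 5L))),
    "EXT.3" = stim_pair(rowMeans(ext_p[, 6:10]), rowMeans(ext_m[, 6:10])),
    "EXT.4" = list(y = ext_d[, 10L, drop = FALSE], within = NULL),
    "EXT.5" = stim_pair(rowMeans(ext_p[, 9:10]), rowMeans(ext_m[, 9:10])),
    "EXT.6" = list(y = .running_average(ext_d[, 1:5]),
                   within = data.frame(Trial = as.character(1:4))),
    "EXT.7" = list(y = ext_d[, 1:2], within = data.frame(Trial = c("1", "2"))),
    "EXT_EXT.1" = list(y = cbind(rowMeans(ext_p[, 1:5]), rowMeans(ext_p[, 6:10]),
                                 rowMeans(ext_m[, 1:5]), rowMeans(ext_m[, 6:10])),
                       within = data.frame(
                         Phase = rep(c("1early", "2late"), 2L),
                         Stim = rep(c("CSP", "CSM"), each = 2L))),
    "EXT_EXT.2" = two_phase(rowMeans(ext_d[, 1:5]), rowMeans(ext_d[, 6:10])),
    "EXT_EXT.3" = two_phase(rowMeans(ext_p[, 1:3]), rowMeans(ext_p[, 8:10])),
    "EXT_EXT.4" = two_phase(rowMeans(ext_p[, 1:5]), rowMeans(ext_p[, 6:10])),
    stop("unknown strategy id: ", spec$id)
  )
}

#' Trial selection and aggregation for one strategy
#'
#' Applies a strategy's trial-selection, aggregation and stimulus-handling
#' rules to a dataset and returns the long analysis table that its ANOVA
#' consumes: one row per subject x design cell.
#'
#' @param dataset A labelled or unlabelled `scr_dataset`.
#' @param spec A `strategy_spec` from [builtin_strategies()].
#' @return Long data frame with columns `subject`, `group` (if labelled),
#'   any within-factor columns (`Phase`, `Trial`, `Stim`), and `value`.
#' @examples
#' d <- generate_null_population(generator_config(n_participants = 6, seed = 1))
#' head(select_trials(d, builtin_strategies()[[9]]))
#' @export
select_trials <- function(dataset, spec) {
  stopifnot(inherits(dataset, "scr_dataset"), inherits(spec, "strategy_spec"))
  des <- .strategy_design(dataset, spec)
  n <- nrow(des$y)
  m <- ncol(des$y)
  out <- data.frame(subject = rep(dataset$participant, times = m),
                    stringsAsFactors = FALSE)
  if (!is.null(dataset$group)) out$group <- rep(dataset$group, times = m)
  if (!is.null(des$within))
    for (f in names(des$within))
      out[[f]] <- rep(des$within[[f]], each = n)
  out$value <- as.vector(des$y)
  out
}

#' Evaluate one analytic strategy on a labelled dataset
#'
#' Runs the strategy's trial selection and its mixed-design ANOVA (or
#' one-way Group ANOVA on contrast/single-trial scores for the two
#' non-factorial strategies) and extracts the partial eta squared of the
#' strategy's highest-order Group interaction.
#'
#' @param dataset A group-labelled `scr_dataset` with >= 2 subjects per
#'   group.
#' @param spec A `strategy_spec`.
#' @return A one-row data frame (`strategy_result`): `id`, `category`,
#'   `eta_p2`, `n_subjects`, `degenerate`. Degenerate-variance resamples
#'   are flagged (with `eta_p2 = NA`) rather than raising.
#' @export
evaluate_strategy <- function(dataset, spec) {
  stopifnot(inherits(dataset, "scr_dataset"), inherits(spec, "strategy_spec"))
  if (is.null(dataset$group))
    stop("strategy evaluation requires a group-labelled dataset")
  des <- .strategy_design(dataset, spec)
  eta <- tryCatch({
    tab <- .anova_engine(des$y, dataset$group, des$within)
    tab$eta_p2[tab$term == spec$model_term]
  }, scrrobust_degenerate = function(e) NA_real_)
  if (length(eta) != 1L)
    stop("model term ", spec$model_term, " not found for ", spec$id)
  data.frame(id = spec$id, category = spec$category, eta_p2 = eta,
             n_subjects = nrow(des$y), degenerate = is.na(eta),
             stringsAsFactors = FALSE)
}

#' Evaluate the full strategy catalogue on one dataset
#'
#' @param dataset A group-labelled `scr_dataset`.
#' @return A 15-row data frame of strategy results in catalogue order.
#' @export
evaluate_all <- function(dataset) {
  out <- do.call(rbind, lapply(builtin_strategies(),
                               function(s) evaluate_strategy(dataset, s)))
  rownames(out) <- NULL
  out
}
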
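## Trial-wise CS+ offset schedules (SD units) emulating three conditioning/
## extinction phenotypes: "base" = high differential acquisition with rapid
## extinction, "a" = moderate acquisition with rapid extinction, "b" = no
## extinction of the CS+ response until late extinction.
.SCHEDULES <- list(
  base = c(ACQ = list(c(1, 0.8, 0.6, 0.4, 0)),
           EXT_EARLY = list(c(2, 1.5, 1, 0.8, 0.5)),
           EXT_LATE = list(c(1, 0.8, 0.5, 0.2, 0))),
  a = c(ACQ = list(c(0, 0.3, 0.3, 0.3, 0.3)),
        EXT_EARLY = list(c(1, 1, 1, 1, 1)),
        EXT_LATE = list(c(1.5, 1, 0.5, 0.1, 0))),
  b = c(ACQ = list(c(0, 0, 0.3, 0.3, 0.3)),
        EXT_EARLY = list(c(2, 1.5, 1, 0.5, 0.3)),
        EXT_LATE = list(c(1.5, 1, 0.5, 0.1, 0)))
)

.phase_trial_names <- function() {
  pc <- scr_cells()
  pc <- pc[pc$stimulus == "CSP", ]
  paste(pc$phase, pc$trial, sep = ".")
}

#' Construct an effect schedule
#'
#' An effect schedule is a set of 15 per-(phase, trial) offsets, expressed in
#' standard-deviation units, to be added to the CS+ responses of one target
#' group. Built-in variants come from [builtin_schedule()]; custom schedules
#' (including negated ones, e.g. to undo an injection) can be constructed
#' directly.
#'
#' @param offsets Named numeric vector of 15 offsets over the
#'   `"<phase>.<trial>"` cells (e.g. `"ACQ.1"`).
#' @param variant Label for the schedule (`"base"`, `"a"`, `"b"` or
#'   `"custom"`).
#' @return An object of class `effect_schedule`.
#' @export
effect_schedule <- function(offsets, variant = "custom") {
  nm <- .phase_trial_names()
  if (length(offsets) != 15L || is.null(names(offsets)) ||
      !setequal(names(offsets), nm))
    stop("`offsets` must be a named vector over the 15 (phase, trial) cells")
  offsets <- offsets[nm]
  if (anyNA(offsets)) stop("offsets must be non-missing")
  structure(list(variant = variant, offsets = offsets),
            class = "effect_schedule")
}

#' Built-in simulated group-level effect schedules
#'
#' Three trial-wise offset schedules define the simulated group-level
#' effects. Each adds the stated number of per-trial standard deviations to
#' the target group's CS+ scores:
#' * `"base"`: acquisition (1, 0.8, 0.6, 0.4, 0); early extinction
#'   (2, 1.5, 1, 0.8, 0.5); late extinction (1, 0.8, 0.5, 0.2, 0) —
#'   high differential acquisition, rapid extinction.
#' * `"a"`: acquisition (0, 0.3, 0.3, 0.3, 0.3); early extinction
#'   (1, 1, 1, 1, 1); late extinction (1.5, 1, 0.5, 0.1, 0) — moderate
#'   acquisition, rapid extinction.
#' * `"b"`: acquisition (0, 0, 0.3, 0.3, 0.3); early extinction
#'   (2, 1.5, 1, 0.5, 0.3); late extinction (1.5, 1, 0.5, 0.1, 0) — no
#'   early extinction of the CS+ response.
#'
#' @param variant One of `"base"`, `"a"`, `"b"`.
#' @return An [effect_schedule()] with all offsets non-negative.
#' @export
builtin_schedule <- function(variant = c("base", "a", "b")) {
  variant <- match.arg(variant)
  s <- .SCHEDULES[[variant]]
  off <- stats::setNames(
    c(s$ACQ, s$EXT_EARLY, s$EXT_LATE),
    c(paste0("ACQ.", 1:5), paste0("EXT_EARLY.", 1:5), paste0("EXT_LATE.", 1:5)))
  effect_schedule(off, variant = variant)
}

#' Write or read an effect schedule as YAML
#'
#' @param schedule An [effect_schedule()].
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns an `effect_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "effect_schedule"))
  yaml::write_yaml(list(variant = schedule$variant,
                        offsets = as.list(schedule$offsets)), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  x <- yaml::read_yaml(path)
  effect_schedule(unlist(x$offsets), variant = x$variant)
}

#' Per-trial SD reference for effect injection
#'
#' The SD-unit offsets of an [effect_schedule()] are converted to
#' micro-Siemens using the per-(phase, trial) standard deviation of CS+
#' responses across the dataset, computed before injection. By default the
#' whole sample (all groups) is used, which keeps the injected effect
#' independent of the random group allocation; restrict with `group` to use
#' a single group's SD instead.
#'
#' @param dataset An `scr_dataset` with at least 2 participants.
#' @param group Optional single group label; if given, only that group's
#'   rows enter the SD.
#' @return Named numeric vector of 15 SDs (n-1 denominator) over the
#'   `"<phase>.<trial>"` cells.
#' @export
compute_sd_reference <- function(dataset, group = NULL) {
  stopifnot(inherits(dataset, "scr_dataset"))
  cells <- scr_cells()
  csp <- dataset$responses[, cells$stimulus == "CSP", drop = FALSE]
  if (!is.null(group)) {
    if (is.null(dataset$group)) stop("dataset has no group labels")
    csp <- csp[dataset$group == group, , drop = FALSE]
  }
  if (nrow(csp) < 2L)
    stop("at least 2 participants are required to compute an SD reference")
  stats::setNames(apply(csp, 2L, stats::sd), .phase_trial_names())
}

#' Inject a trial-wise group-level effect into one group's CS+ responses
#'
#' For every participant in `target_group`, each CS+ response is shifted by
#' `offsets[phase, trial] * sd_ref[phase, trial]` micro-Siemens. The same
#' value is added to every individual score in the group; CS- responses and
#' the other groups are untouched, and row order and identifiers are
#' preserved.
#'
#' @param dataset A labelled `scr_dataset`.
#' @param schedule An [effect_schedule()] (SD-unit offsets).
#' @param sd_ref Named 15-vector from [compute_sd_reference()]; defaults to
#'   the whole-sample pre-injection SD of `dataset`.
#' @param target_group Group label receiving the effect (default 3).
#' @param stacked If `TRUE`, `schedule` is applied on top of a prior
#'   `"base"` injection (the two schedules' offsets are summed) rather than
#'   standing alone. Default `FALSE`: each variant is a standalone schedule
#'   applied to the raw bootstrapped values.
#' @return A new `scr_dataset` with the effect applied.
#' @export
inject_effect <- function(dataset, schedule, sd_ref = NULL, target_group = 3L,
                          stacked = FALSE) {
  stopifnot(inherits(dataset, "scr_dataset"),
            inherits(schedule, "effect_schedule"))
  if (is.null(dataset$group))
    stop("effect injection requires a group-labelled dataset")
  if (!any(dataset$group == target_group))
    stop("target group ", target_group, " is absent from the dataset")
  if (is.null(sd_ref)) sd_ref <- compute_sd_reference(dataset)
  nm <- .phase_trial_names()
  if (length(sd_ref) != 15L || !setequal(names(sd_ref), nm))
    stop("`sd_ref` must be a named vector over the 15 (phase, trial) cells")
  sd_ref <- sd_ref[nm]
  offsets <- schedule$offsets
  if (stacked) offsets <- offsets + builtin_schedule("base")$offsets

  cells <- scr_cells()
  csp_cols <- which(cells$stimulus == "CSP")
  shift <- offsets * sd_ref  # uS, aligned with CSP column order
  resp <- dataset$responses
  rows <- dataset$group == target_group
  resp[rows, csp_cols] <- resp[rows, csp_cols] +
    matrix(shift, nrow = sum(rows), ncol = 15L, byrow = TRUE)
  if (any(resp < 0))
    stop("injection produced negative responses (negative offsets larger than the data)")
  scr_dataset(resp, participant = dataset$participant, group = dataset$group)
}
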
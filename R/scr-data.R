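#' @keywords internal
"_PACKAGE"

## Trial-grid layout constants. The paradigm has 5 acquisition trials and 10
## extinction trials split into early/late blocks of 5, with a CS+ and a CS-
## response per trial: 3 phases x 5 trials x 2 stimuli = 30 cells per
## participant.
PHASES <- c("ACQ", "EXT_EARLY", "EXT_LATE")
STIMULI <- c("CSP", "CSM")
N_TRIALS <- 5L

#' Cell layout of the trial grid
#'
#' Every participant contributes exactly 30 responses: 3 phases (acquisition,
#' early extinction, late extinction) x 5 trials x 2 stimuli (CS+, CS-).
#' This function enumerates the cells in the canonical column order used by
#' the internal response matrix.
#'
#' @return A data frame with columns `phase`, `stimulus`, `trial` and `cell`
#'   (the canonical cell label, e.g. `"ACQ.CSP.1"`), one row per cell,
#'   30 rows in total.
#' @examples
#' head(scr_cells())
#' @export
scr_cells <- function() {
  g <- expand.grid(trial = seq_len(N_TRIALS), stimulus = STIMULI,
                   phase = PHASES, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, c("phase", "stimulus", "trial")]
  g$cell <- paste(g$phase, g$stimulus, g$trial, sep = ".")
  g
}

.cell_names <- function() scr_cells()$cell

## column indices of one (phase, stimulus) block of 5 trials
.block_cols <- function(phase, stimulus) {
  cells <- scr_cells()
  which(cells$phase == phase & cells$stimulus == stimulus)
}

## columns of the concatenated extinction trials 1..10 for one stimulus
.ext_cols <- function(stimulus, trials = 1:10) {
  stopifnot(all(trials >= 1L & trials <= 10L))
  early <- .block_cols("EXT_EARLY", stimulus)
  late <- .block_cols("EXT_LATE", stimulus)
  c(early, late)[trials]
}

#' Construct a trial-level SCR dataset
#'
#' The container couples a numeric response matrix (participants x 30 cells,
#' micro-Siemens) with participant identifiers and an optional 3-level group
#' allocation. It is the unit of resampling, effect injection and strategy
#' evaluation.
#'
#' @param responses Numeric matrix, one row per participant, 30 columns in
#'   the canonical order of [scr_cells()] (column names are enforced). All
#'   values must be finite and non-negative.
#' @param participant Character vector of unique participant identifiers;
#'   defaults to `"p1" ... "pn"`.
#' @param group Optional integer vector of group labels in `{1, 2, 3}`,
#'   one per participant, or `NULL` for an unlabelled dataset.
#' @return An object of class `scr_dataset`.
#' @seealso [read_long_csv()], [generate_null_population()]
#' @export
scr_dataset <- function(responses, participant = NULL, group = NULL) {
  responses <- as.matrix(responses)
  if (ncol(responses) != 30L)
    stop("`responses` must have 30 columns (3 phases x 5 trials x 2 stimuli), got ",
         ncol(responses))
  if (!is.numeric(responses) || anyNA(responses) || any(!is.finite(responses)))
    stop("`responses` must be finite and non-missing")
  if (any(responses < 0))
    stop("SCR responses must be non-negative; found negative value(s)")
  n <- nrow(responses)
  if (is.null(participant)) participant <- paste0("p", seq_len(n))
  participant <- as.character(participant)
  if (length(participant) != n) stop("`participant` length must match rows")
  if (anyDuplicated(participant))
    stop("participant identifiers must be unique; duplicated: ",
         paste(unique(participant[duplicated(participant)]), collapse = ", "))
  if (!is.null(group)) {
    group <- as.integer(group)
    if (length(group) != n) stop("`group` length must match rows")
    if (anyNA(group) || !all(group %in% 1:3))
      stop("group labels must be drawn from {1, 2, 3}")
  }
  dimnames(responses) <- list(participant, .cell_names())
  structure(list(responses = responses, participant = participant,
                 group = group),
            class = "scr_dataset")
}

#' @export
print.scr_dataset <- function(x, ...) {
  cat("<scr_dataset> ", nrow(x$responses), " participant(s), 30 cells each",
      if (is.null(x$group)) ", unlabelled" else
        paste0("; groups: ", paste(table(x$group), collapse = "/")),
      "\n", sep = "")
  invisible(x)
}

#' Number of participants in a dataset
#' @param dataset An `scr_dataset`.
#' @return Integer count of rows (participants).
#' @export
n_participants <- function(dataset) {
  stopifnot(inherits(dataset, "scr_dataset"))
  nrow(dataset$responses)
}

#' Convert a dataset to the long trial-level format
#'
#' @param x An `scr_dataset`.
#' @param row.names,optional Ignored; present for S3 compatibility.
#' @param ... Ignored.
#' @return Long data frame with columns `participant`, `group` (if
#'   labelled), `phase`, `trial`, `stimulus`, `response`; 30 rows per
#'   participant, participants in dataset order.
#' @export
as.data.frame.scr_dataset <- function(x, row.names = NULL, optional = FALSE, ...) {
  cells <- scr_cells()
  n <- nrow(x$responses)
  out <- data.frame(
    participant = rep(x$participant, each = 30L),
    phase = rep(cells$phase, times = n),
    trial = rep(cells$trial, times = n),
    stimulus = rep(cells$stimulus, times = n),
    response = as.vector(t(x$responses)),
    stringsAsFactors = FALSE
  )
  if (!is.null(x$group))
    out <- cbind(out[1], group = rep(x$group, each = 30L), out[-1])
  out
}

#' Read a long-format trial-level CSV into a dataset
#'
#' The long CSV is the package's single interchange format: one row per
#' (participant, phase, trial, stimulus) cell with the response in
#' micro-Siemens, plus an optional `group` column. Validation is strict:
#' every participant must contribute all 30 cells exactly once, responses
#' must be non-negative, and phase/stimulus labels must be among
#' `ACQ/EXT_EARLY/EXT_LATE` and `CSP/CSM`.
#'
#' @param path Path to a CSV file with header columns `participant`,
#'   `phase`, `trial`, `stimulus`, `response` and optionally `group`.
#' @return A validated [scr_dataset()]; participant order follows first
#'   appearance in the file.
#' @seealso [write_long_csv()]
#' @export
read_long_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant", "phase", "trial", "stimulus", "response")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("long CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    return(scr_dataset(matrix(numeric(0), 0, 30), character(0)))

  bad_phase <- !df$phase %in% PHASES
  if (any(bad_phase))
    stop("unknown phase label(s): ", paste(unique(df$phase[bad_phase]), collapse = ", "))
  bad_stim <- !df$stimulus %in% STIMULI
  if (any(bad_stim))
    stop("unknown stimulus label(s): ", paste(unique(df$stimulus[bad_stim]), collapse = ", "))
  if (anyNA(df$trial) || !all(df$trial %in% 1:5))
    stop("trial must be an integer in 1..5")
  if (anyNA(df$response))
    stop("missing response value(s)")
  if (any(df$response < 0)) {
    i <- which(df$response < 0)[1L]
    stop(sprintf("negative response at (%s, %s, trial %d, %s)",
                 df$participant[i], df$phase[i], df$trial[i], df$stimulus[i]))
  }

  key <- paste(df$participant, df$phase, df$trial, df$stimulus, sep = "|")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate cell key (participant|phase|trial|stimulus): ", d)
  }

  ids <- unique(df$participant)
  cell <- paste(df$phase, df$stimulus, df$trial, sep = ".")
  cn <- .cell_names()
  counts <- table(factor(df$participant, levels = ids))
  if (any(counts != 30L)) {
    p <- names(counts)[counts != 30L][1L]
    have <- cell[df$participant == p]
    miss <- setdiff(cn, have)
    stop(sprintf("participant %s has %d/30 cells; missing: %s", p,
                 sum(df$participant == p),
                 paste(utils::head(miss, 5L), collapse = ", ")))
  }

  resp <- matrix(NA_real_, length(ids), 30L,
                 dimnames = list(ids, cn))
  resp[cbind(match(df$participant, ids), match(cell, cn))] <- df$response

  group <- NULL
  if ("group" %in% names(df)) {
    per <- tapply(df$group, factor(df$participant, levels = ids),
                  function(g) unique(g))
    if (any(lengths(per) != 1L))
      stop("group label must be constant within participant: ",
           names(per)[lengths(per) != 1L][1L])
    group <- unlist(per, use.names = FALSE)
    if (anyNA(group)) group <- NULL else {
      if (!all(group %in% 1:3))
        stop("group labels must be drawn from {1, 2, 3}")
    }
  }
  scr_dataset(resp, participant = ids, group = group)
}

#' Write a dataset as a long-format trial-level CSV
#'
#' Responses are written with 17 significant digits so that
#' `read_long_csv(write_long_csv(d))` round-trips every cell exactly.
#'
#' @param dataset An `scr_dataset`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_long_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "scr_dataset"))
  df <- as.data.frame(dataset)
  df$response <- sprintf("%.17g", df$response)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Differential (CS+ minus CS-) responding
#'
#' Differential responding isolates stimulus-specific conditioned fear by
#' subtracting the safety-signal (CS-) response from the threat-cue (CS+)
#' response of the same trial. Several catalogued strategies analyse this
#' 15-cell differential grid rather than the raw 30-cell grid.
#'
#' @param dataset An `scr_dataset` (any number of participants).
#' @return Numeric matrix, participants x 15 columns named
#'   `"<phase>.<trial>"`, values in micro-Siemens (may be negative).
#' @export
differential <- function(dataset) {
  stopifnot(inherits(dataset, "scr_dataset"))
  cells <- scr_cells()
  csp <- dataset$responses[, cells$stimulus == "CSP", drop = FALSE]
  csm <- dataset$responses[, cells$stimulus == "CSM", drop = FALSE]
  d <- csp - csm
  pc <- cells[cells$stimulus == "CSP", ]
  colnames(d) <- paste(pc$phase, pc$trial, sep = ".")
  rownames(d) <- dataset$participant
  d
}

## run code with a temporary RNG state seeded from `seed`, restoring the
## caller's stream afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

## deterministic 31-bit substream seed derived from a master seed and one or
## two stream indices; exact in double precision (< 2^53 before the modulus)
derive_seed <- function(seed, i, j = 0) {
  s <- (as.double(seed) %% 2147483647)
  ((s * 48271 + as.double(i) * 104729 + as.double(j) * 7919) %% 2147483646) + 1
}
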
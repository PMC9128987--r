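#' Default mean-response profile of the synthetic generator
#'
#' The profile encodes the canonical shape of differential fear conditioning
#' at the group-mean level: CS- responding flat at 0.3 uS throughout; CS+
#' responding rising above the CS- during acquisition (differential
#' conditioning, peaking at 0.8 uS) and decaying monotonically across the ten
#' concatenated extinction trials back to the CS- level by late extinction.
#'
#' @return Named numeric vector of 30 cell means (micro-Siemens) in the
#'   canonical cell order of [scr_cells()].
#' @examples
#' mu <- default_mu_profile()
#' mu["ACQ.CSP.5"] > mu["ACQ.CSM.5"]
#' @export
default_mu_profile <- function() {
  mu <- stats::setNames(rep(0.3, 30), .cell_names())
  mu[paste0("ACQ.CSP.", 1:5)] <- c(0.50, 0.65, 0.75, 0.80, 0.80)
  mu[paste0("EXT_EARLY.CSP.", 1:5)] <- c(0.80, 0.70, 0.60, 0.52, 0.45)
  mu[paste0("EXT_LATE.CSP.", 1:5)] <- c(0.40, 0.37, 0.34, 0.32, 0.30)
  mu
}

#' Configuration of the synthetic null-population generator
#'
#' @param n_participants Number of participants to generate (default 379,
#'   the size of the pooled sample the generator stands in for).
#' @param mu Named 30-cell mean profile in micro-Siemens; defaults to
#'   [default_mu_profile()].
#' @param sigma_subject SD (uS) of the additive participant-level random
#'   intercept inducing within-subject correlation across cells. Default 0.2.
#' @param sigma_noise SD (uS) of i.i.d. cell-level noise. Default 0.25.
#' @param seed Master integer seed; per-participant substreams are derived
#'   from it so earlier participants are unchanged when `n_participants`
#'   grows.
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 379L,
                             mu = default_mu_profile(),
                             sigma_subject = 0.2,
                             sigma_noise = 0.25,
                             seed = 1L) {
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 1L)
    stop("`n_participants` must be a positive integer")
  if (length(mu) != 30L || is.null(names(mu)) ||
      !setequal(names(mu), .cell_names()))
    stop("`mu` must be a named vector over the 30 canonical cells")
  mu <- mu[.cell_names()]
  if (anyNA(mu) || any(mu < 0)) stop("`mu` values must be non-negative")
  if (sigma_subject < 0 || sigma_noise < 0) stop("sigma values must be >= 0")
  structure(list(n_participants = n_participants, mu = mu,
                 sigma_subject = sigma_subject, sigma_noise = sigma_noise,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic null population of SCR trial grids
#'
#' Each response is `max(0, a_i + mu[cell] + e)` where `a_i` is a
#' participant-level normal random intercept (SD `sigma_subject`) and `e` is
#' i.i.d. normal cell noise (SD `sigma_noise`). The floor at zero reproduces
#' the zero-inflation typical of scored SCRs. No group labels are assigned:
#' group structure enters only downstream, via random allocation and
#' optional effect injection.
#'
#' @param config A [generator_config()].
#' @return An unlabelled `scr_dataset` of `config$n_participants` rows;
#'   byte-identical across calls with the same config.
#' @examples
#' d <- generate_null_population(generator_config(n_participants = 10, seed = 7))
#' d
#' @export
generate_null_population <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_participants
  mu <- config$mu
  resp <- matrix(NA_real_, n, 30L)
  for (i in seq_len(n)) {
    resp[i, ] <- with_seed(derive_seed(config$seed, i), {
      a <- stats::rnorm(1L, 0, config$sigma_subject)
      e <- stats::rnorm(30L, 0, config$sigma_noise)
      pmax(0, a + mu + e)
    })
  }
  scr_dataset(resp, participant = sprintf("s%04d", seq_len(n)))
}

#' Per-cell mean and SD of a dataset
#'
#' Calibration surface for the generator and the SD reference used by effect
#' injection: one record per (phase, trial, stimulus) cell with the sample
#' mean and the n-1 denominator SD across participants.
#'
#' @param dataset An `scr_dataset` with at least 2 participants.
#' @return Data frame with columns `phase`, `trial`, `stimulus`, `mean`,
#'   `sd`; 30 rows in canonical cell order.
#' @export
summarize_population <- function(dataset) {
  stopifnot(inherits(dataset, "scr_dataset"))
  if (nrow(dataset$responses) < 2L)
    stop("at least 2 participants are required to summarize a population")
  cells <- scr_cells()
  data.frame(cells[, c("phase", "trial", "stimulus")],
             mean = unname(colMeans(dataset$responses)),
             sd = unname(apply(dataset$responses, 2L, stats::sd)),
             stringsAsFactors = FALSE)
}
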
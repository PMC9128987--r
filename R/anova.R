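## Balanced mixed-design (split-plot) ANOVA with one between-subjects factor
## (Group) and up to three fully-crossed within-subject factors. The
## decomposition is the classical univariate one: each within-effect and its
## Group interaction are tested against the corresponding
## within-factor x subject-within-group error stratum, and the Group main
## effect against the subject-within-group stratum. Group sizes may differ
## by the allocation remainder (+/-1); the sequential (hierarchical)
## weighted decomposition used here then agrees exactly with
## aov(y ~ group*W + Error(subject/W)) and preserves exact sums-of-squares
## conservation in every stratum.

.degenerate_error <- function(msg) {
  stop(structure(class = c("scrrobust_degenerate", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Partial eta squared from effect and error sums of squares
#'
#' `eta_p^2 = SS_effect / (SS_effect + SS_error)`, the per-term ANOVA effect
#' size used throughout the strategy catalogue.
#'
#' @param ss_effect Effect sum of squares (>= 0).
#' @param ss_error Error sum of squares from the term's stratum (>= 0).
#' @return A value in `[0, 1]`.
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (ss_effect < 0 || ss_error < 0) stop("sums of squares must be >= 0")
  if (ss_effect + ss_error <= 0)
    .degenerate_error("both effect and error sums of squares are zero")
  ss_effect / (ss_effect + ss_error)
}

## core engine on the wide representation:
##   y      n x m response matrix (one column per within-design cell)
##   group  length-n vector of between-subject labels
##   within data.frame with m rows; one column per within factor giving the
##          level of that factor in each column of y (NULL/0-col => one-way)
## returns the anova_table data.frame
.anova_engine <- function(y, group, within = NULL) {
  y <- as.matrix(y)
  n <- nrow(y); m <- ncol(y)
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2L) stop("at least 2 groups are required")
  ng <- as.vector(table(group))
  if (any(ng < 2L)) stop("at least 2 subjects per group are required")
  if (anyNA(y)) stop("design must be complete (no missing cells)")
  gidx <- as.integer(group)

  scale_tol <- 1e-12 * (sum((y - mean(y))^2) + 1)

  subj_mean <- rowMeans(y)
  gm <- as.vector(rowsum(subj_mean, gidx)) / ng
  grand <- mean(subj_mean)
  ss_G <- m * sum(ng * (gm - grand)^2)
  ss_subj <- m * sum((subj_mean - gm[gidx])^2)
  df_G <- k - 1L
  df_subj <- n - k

  terms <- data.frame(term = "Group", ss = ss_G, df = df_G,
                      error_ss = ss_subj, error_df = df_subj,
                      stringsAsFactors = FALSE)

  if (!is.null(within) && length(within) > 0L) {
    within <- as.data.frame(within, stringsAsFactors = FALSE)
    if (nrow(within) != m)
      stop("`within` must describe each of the ", m, " response columns")
    facs <- names(within)
    nf <- length(facs)
    lev <- lapply(within, function(f) sort(unique(as.character(f))))
    nlev <- lengths(lev)
    if (prod(nlev) != m)
      stop("within design must be fully crossed: ",
           paste(facs, collapse = " x "), " has ", prod(nlev),
           " cells but y has ", m, " columns")

    ## enumerate non-empty subsets of within factors by increasing size;
    ## per-subject effect arrays via recursive marginal-mean decomposition
    subsets <- unlist(lapply(seq_len(nf), function(s)
      utils::combn(nf, s, simplify = FALSE)), recursive = FALSE)
    eff <- list()     # per-subset n x m_T effect matrix
    cellidx <- list() # per-subset length-m mapping column -> T-cell index
    key <- function(ix) paste(ix, collapse = ",")

    for (T in subsets) {
      cid <- interaction(within[T], drop = FALSE, lex.order = TRUE)
      cells_T <- as.integer(cid)
      m_T <- nlevels(cid)
      cnt <- tabulate(cells_T, m_T)
      M_T <- t(rowsum(t(y), cells_T) / cnt)  # n x m_T marginal means
      e_T <- M_T - subj_mean
      if (length(T) > 1L) {
        rep_col <- match(seq_len(m_T), cells_T)  # a column in each T-cell
        for (S in subsets) {
          if (length(S) < length(T) && all(S %in% T)) {
            map <- cellidx[[key(S)]][rep_col]
            e_T <- e_T - eff[[key(S)]][, map, drop = FALSE]
          }
        }
      }
      eff[[key(T)]] <- e_T
      cellidx[[key(T)]] <- cells_T

      c_T <- m / m_T
      ebar <- colMeans(e_T)
      gme <- rowsum(e_T, gidx) / ng             # k x m_T group means
      dev_g <- sweep(gme, 2L, ebar)
      resid <- e_T - gme[gidx, , drop = FALSE]
      ss_T <- c_T * n * sum(ebar^2)
      ss_TG <- c_T * sum(ng * rowSums(dev_g^2))
      ss_err <- c_T * sum(resid^2)
      df_T <- prod(nlev[T] - 1L)
      tname <- paste(facs[T], collapse = ":")
      terms <- rbind(terms,
        data.frame(term = c(tname, paste("Group", tname, sep = ":")),
                   ss = c(ss_T, ss_TG),
                   df = c(df_T, (k - 1L) * df_T),
                   error_ss = ss_err,
                   error_df = (n - k) * df_T,
                   stringsAsFactors = FALSE))
    }
  }

  if (any(terms$error_ss <= scale_tol))
    .degenerate_error(paste0("zero error variance in stratum for term(s): ",
      paste(terms$term[terms$error_ss <= scale_tol], collapse = ", ")))

  terms$F <- (terms$ss / terms$df) / (terms$error_ss / terms$error_df)
  terms$eta_p2 <- terms$ss / (terms$ss + terms$error_ss)
  class(terms) <- c("anova_table", "data.frame")
  terms
}

#' Mixed-design ANOVA with partial eta squared per term
#'
#' Fits the classical univariate repeated-measures decomposition for a
#' design with one between-subjects factor (`group`) and any fully-crossed
#' subset of within-subject factors, returning sums of squares, F and
#' partial eta squared for every model term. Between-subject effects are
#' tested against the subject-within-group stratum; each within effect and
#' its Group interactions against the matching
#' within-factor x subject-within-group stratum. No sphericity correction is
#' applied (eta_p^2 depends only on sums of squares).
#'
#' @param data Long data frame with one row per subject x within-cell.
#' @param within Character vector naming the within-subject factor columns
#'   of `data` (possibly empty for a one-way between design).
#' @param response,subject,group Names of the response, subject-identifier
#'   and group columns. Defaults `"value"`, `"subject"`, `"group"`.
#' @return An `anova_table` data frame with columns `term`, `ss`, `df`,
#'   `error_ss`, `error_df`, `F`, `eta_p2`.
#' @section Degenerate inputs: a zero error sum of squares in any required
#'   stratum (e.g. all responses identical) raises an error of class
#'   `scrrobust_degenerate`, so simulation loops can count and skip such
#'   resamples explicitly.
#' @examples
#' d <- data.frame(subject = rep(1:4, each = 2),
#'                 group = rep(c("g1", "g2"), each = 4),
#'                 phase = rep(c("a", "b"), 4),
#'                 value = c(1, 2, 2, 3, 1, 4, 2, 5))
#' mixed_anova(d, within = "phase")
#' @export
mixed_anova <- function(data, within = character(),
                        response = "value", subject = "subject",
                        group = "group") {
  data <- as.data.frame(data)
  need <- c(response, subject, group, within)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  subj <- factor(data[[subject]], levels = unique(data[[subject]]))
  if (length(within) == 0L) {
    if (anyDuplicated(data[[subject]]))
      stop("one-way design expects one row per subject")
    y <- matrix(data[[response]], ncol = 1L)
    return(.anova_engine(y, data[[group]], NULL))
  }
  cid <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  m <- nlevels(cid)
  tab <- table(subj, cid)
  if (any(tab != 1L))
    stop("design must be balanced and complete: every subject needs exactly one value per within-cell")
  y <- matrix(NA_real_, nlevels(subj), m)
  y[cbind(as.integer(subj), as.integer(cid))] <- data[[response]]
  g_per <- tapply(as.character(data[[group]]), subj, function(x) unique(x)[1])
  cons <- tapply(as.character(data[[group]]), subj,
                 function(x) length(unique(x)) == 1L)
  if (!all(cons)) stop("group must be constant within subject")
  u <- !duplicated(as.integer(cid))
  within_df <- data[u, within, drop = FALSE]
  within_df <- within_df[order(as.integer(cid)[u]), , drop = FALSE]
  rownames(within_df) <- NULL
  .anova_engine(y, unname(g_per[levels(subj)]), within_df)
}

#' Group effect size for per-subject contrast scores
#'
#' One-way ANOVA partial eta squared of the Group effect computed on one
#' contrast score per subject (e.g. a phase-difference of differential
#' responding). This is the group-level interaction analogue of a
#' paired-contrast analysis: with two groups it reduces to the two-sample
#' t-test identity `eta_p^2 = t^2 / (t^2 + df)`.
#'
#' @param contrast_scores Numeric vector, one value per subject.
#' @param groups Group labels, one per subject (>= 2 per group).
#' @return Partial eta squared of the Group effect, in `[0, 1]`.
#' @export
group_contrast_eta <- function(contrast_scores, groups) {
  tab <- .anova_engine(matrix(contrast_scores, ncol = 1L), groups, NULL)
  tab$eta_p2[tab$term == "Group"]
}
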
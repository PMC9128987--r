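# Shared fixtures and independent oracles.

# small dataset with constant responses per participant offset
flat_dataset <- function(n = 4, value = 0.5, group = NULL) {
  scr_dataset(matrix(value, n, 30), group = group)
}

# dataset with arbitrary deterministic structure (no RNG)
patterned_dataset <- function(n = 6, group = NULL) {
  resp <- outer(seq_len(n) / 10, seq_len(30) / 7) + 0.1
  scr_dataset(resp, group = group)
}

# Independent ANOVA oracle: classical split-plot via stats::aov with
# Error(subject/(W1*W2*...)); returns term -> eta_p2.
aov_eta_oracle <- function(y, group, within = NULL) {
  n <- nrow(y)
  long <- data.frame(subject = factor(rep(seq_len(n), ncol(y))),
                     group = factor(rep(group, ncol(y))),
                     value = as.vector(y))
  if (is.null(within) || length(within) == 0L) {
    tab <- summary(stats::aov(value ~ group, data = long))[[1L]]
    ss <- tab[["Sum Sq"]]
    return(data.frame(term = "Group", eta_p2 = ss[1L] / (ss[1L] + ss[2L]),
                      stringsAsFactors = FALSE))
  }
  for (f in names(within)) long[[f]] <- factor(rep(within[[f]], each = n))
  wfs <- names(within)
  form <- stats::as.formula(paste(
    "value ~", paste(c("group", wfs), collapse = "*"),
    "+ Error(subject/(", paste(wfs, collapse = "*"), "))"))
  s <- summary(stats::aov(form, data = long))
  out <- NULL
  for (stratum in s) {
    tab <- stratum[[1L]]
    rn <- trimws(rownames(tab))
    resid_ss <- tab[rn == "Residuals", "Sum Sq"]
    keep <- which(rn != "Residuals")
    if (!length(keep)) next
    out <- rbind(out, data.frame(
      term = gsub("^group", "Group", rn[keep]),
      eta_p2 = tab[keep, "Sum Sq"] / (tab[keep, "Sum Sq"] + resid_ss),
      stringsAsFactors = FALSE))
  }
  out
}

# random balanced split-plot instance over the within layouts the strategy
# catalogue uses; subjects <= 12
random_anova_instance <- function() {
  layouts <- list(
    NULL,
    data.frame(Phase = c("a", "b")),
    data.frame(Stim = c("p", "m")),
    data.frame(Trial = as.character(1:4)),
    data.frame(Trial = as.character(1:5)),
    data.frame(Phase = rep(c("a", "b"), 2), Stim = rep(c("p", "m"), each = 2)),
    data.frame(Trial = as.character(rep(1:5, 2)),
               Stim = rep(c("p", "m"), each = 5))
  )
  within <- layouts[[sample.int(length(layouts), 1L)]]
  k <- sample(2:3, 1L)
  per <- sample(2:4, 1L)
  n <- k * per
  m <- if (is.null(within)) 1L else nrow(within)
  list(y = matrix(stats::rnorm(n * m), n, m), group = rep(seq_len(k), each = per),
       within = within)
}

# brute-force Kendall tau-b by explicit enumeration of all pairs
tau_b_enumerate <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) next
    else if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# Benjamini-Hochberg step-up by hand: returns logical rejection flags
bh_stepup <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= q * seq_len(m) / m)
  flags <- rep(FALSE, m)
  if (length(below)) flags[ord[seq_len(max(below))]] <- TRUE
  flags
}
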
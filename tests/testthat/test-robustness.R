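test_that("full-row bootstrap draws whole source participants", {
  src <- patterned_dataset(7)
  set.seed(4)
  b <- bootstrap_dataset(src, 25, mode = "full_row")
  expect_equal(n_participants(b), 25L)
  # membership: every output grid equals some source grid cell-exactly
  match_src <- apply(b$responses, 1L, function(r)
    any(apply(src$responses, 1L, function(s) all(s == r))))
  expect_true(all(match_src))
  expect_null(b$group)
})

test_that("phase-wise bootstrap assembles chimeric rows at the expected rate", {
  # two very different sources: blocks from different sources in ~half of rows
  src <- scr_dataset(rbind(rep(0.1, 30), rep(5, 30)))
  set.seed(8)
  b <- bootstrap_dataset(src, 4000, mode = "phase_wise")
  acq_src <- b$responses[, "ACQ.CSP.1"] > 1
  ext_src <- b$responses[, "EXT_EARLY.CSP.1"] > 1
  frac_mixed <- mean(acq_src != ext_src)
  # independent block draws: P(different sources) = 1/2; bound ~4 SE
  expect_lt(abs(frac_mixed - 0.5), 4 * sqrt(0.25 / 4000))

  # single-participant source: every row identical to it, either mode
  one <- patterned_dataset(1)
  for (mode in c("phase_wise", "full_row")) {
    b1 <- bootstrap_dataset(one, 5, mode = mode)
    expect_true(all(t(b1$responses) == as.vector(one$responses)))
  }
  expect_error(bootstrap_dataset(scr_dataset(matrix(numeric(0), 0, 30),
                                             character(0)), 5), "empty")
})

test_that("group allocation is equal up to the remainder and randomised", {
  set.seed(10)
  expect_equal(as.vector(table(allocate_groups(30))), c(10L, 10L, 10L))
  tab <- sort(as.vector(table(allocate_groups(2000))))
  expect_equal(tab, c(666L, 667L, 667L))
  expect_error(allocate_groups(2, 3), "cannot allocate")
  # per-position label frequencies uniform over many draws
  draws <- t(replicate(900, allocate_groups(9)))
  pos_counts <- apply(draws, 2L, function(col) table(factor(col, levels = 1:3)))
  chi <- sum((pos_counts - 300)^2 / 300)
  # 18 df; generous upper bound
  expect_lt(chi, qchisq(1 - 1e-6, df = 18))
})

test_that("kendall_tau_b matches enumeration, base R, and worked examples", {
  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(2, 1, 4, 3)), 1 / 3)
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(kendall_tau_b(x, x), 1)
  expect_equal(kendall_tau_b(x, -x), -1)
  expect_error(kendall_tau_b(rep(1, 4), 1:4), "tied")
  expect_error(kendall_tau_b(1:3, 1:4), "equal length")

  set.seed(14)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    # heavy ties via rounding
    a <- round(stats::runif(n, 0, 4))
    b <- round(stats::runif(n, 0, 4))
    if (length(unique(a)) < 2L || length(unique(b)) < 2L) next
    expect_equal(kendall_tau_b(a, b), tau_b_enumerate(a, b), tolerance = 1e-12)
    expect_equal(kendall_tau_b(a, b),
                 suppressWarnings(stats::cor(a, b, method = "kendall")),
                 tolerance = 1e-12)
  }
})

test_that("percentile CI uses interpolated order statistics", {
  expect_equal(percentile_ci(1:1000), c(25.975, 975.025))
  expect_equal(percentile_ci(rep(3.2, 10)), c(3.2, 3.2))
  set.seed(2)
  s <- stats::rnorm(50)
  ci <- percentile_ci(s)
  expect_lte(ci[1], ci[2])
})

test_that("effect matrix has the right shape, determinism and seed independence", {
  src <- generate_null_population(generator_config(n_participants = 60, seed = 2))
  cfg <- resample_config(sizes = c(24, 48), n_resamples = 8, n_ci_boot = 20,
                         seed = 5)
  m1 <- strategy_effect_matrix(src, 24, cfg)
  expect_equal(dim(m1), c(8L, 15L))
  expect_true(all(m1 >= 0 & m1 <= 1, na.rm = TRUE))
  m2 <- strategy_effect_matrix(src, 24, cfg)
  expect_identical(unclass(m1), unclass(m2))
  # per-(size, resample) substreams: global RNG state does not leak in
  set.seed(999)
  m3 <- strategy_effect_matrix(src, 24, cfg)
  expect_identical(unclass(m1), unclass(m3))
})

test_that("pairwise robustness covers the within-category pair families", {
  pairs <- scrrobust:::.category_pairs()
  expect_equal(nrow(pairs), 6L + 21L + 6L)

  src <- generate_null_population(generator_config(n_participants = 60, seed = 2))
  cfg <- resample_config(sizes = 24, n_resamples = 10, n_ci_boot = 40, seed = 5)
  m <- strategy_effect_matrix(src, 24, cfg)
  rob <- pairwise_robustness(m, cfg)
  expect_equal(nrow(rob$pairs), 33L)
  expect_equal(as.vector(table(rob$pairs$category)[c("ACQ_EXT", "EXT", "EXT_EXT")]),
               c(6L, 21L, 6L))
  expect_true(all(rob$pairs$ci_low <= rob$pairs$ci_high))
  expect_true(all(abs(rob$pairs$mean_taub) <= 1))
  expect_equal(nrow(rob$per_strategy), 15L)

  # identical strategy columns give tau = 1 with a degenerate CI
  m2 <- m
  m2[, "ACQ_EXT.2"] <- m2[, "ACQ_EXT.1"]
  rob2 <- pairwise_robustness(m2, cfg)
  row <- rob2$pairs[rob2$pairs$strategy_a == "ACQ_EXT.1" &
                    rob2$pairs$strategy_b == "ACQ_EXT.2", ]
  expect_equal(row$mean_taub, 1)
  expect_equal(c(row$ci_low, row$ci_high), c(1, 1))
})

test_that("independent random columns yield tau near zero", {
  set.seed(33)
  cfg <- resample_config(sizes = 24, n_resamples = 100, n_ci_boot = 100, seed = 1)
  m <- matrix(stats::runif(100 * 15), 100, 15,
              dimnames = list(NULL, strategy_catalogue()$id))
  attr(m, "size") <- 24
  rob <- pairwise_robustness(m, cfg)
  # null tau SE for n = 100 is about sqrt(2(2n+5)/(9n(n-1))) ~ 0.068
  expect_true(all(abs(rob$pairs$taub) < 4 * 0.068))
  expect_gt(mean(rob$pairs$ci_low <= 0 & rob$pairs$ci_high >= 0), 0.8)
})

test_that("trend analysis computes Pearson trends with BH flags per family", {
  sizes <- c(30, 60, 120, 240)
  base <- expand.grid(size = sizes, pair = 1:33)
  pairs <- scrrobust:::.category_pairs()
  cat_tab <- strategy_catalogue()
  df <- do.call(rbind, lapply(seq_len(33), function(i) {
    data.frame(size = sizes,
               category = cat_tab$category[match(pairs$strategy_a[i], cat_tab$id)],
               strategy_a = pairs$strategy_a[i], strategy_b = pairs$strategy_b[i],
               mean_taub = if (i == 1) sizes / 1000               # r = 1
                           else if (i == 2) rep(0.5, 4)          # constant
                           else sin(i * sizes),                  # arbitrary
               stringsAsFactors = FALSE)
  }))
  tr <- trend_analysis(df)
  r1 <- tr[tr$strategy_a == "ACQ_EXT.1" & tr$strategy_b == "ACQ_EXT.2", ]
  expect_equal(r1$r, 1, tolerance = 1e-12)
  r2 <- tr[tr$strategy_a == "ACQ_EXT.1" & tr$strategy_b == "ACQ_EXT.3", ]
  expect_true(is.na(r2$r))
  expect_false(r2$fdr_significant)
  # flags equal the hand step-up rule within each category family
  for (cc in unique(tr$category)) {
    sel <- tr$category == cc & !is.na(tr$p)
    expect_equal(tr$fdr_significant[sel], bh_stepup(tr$p[sel], 0.1))
  }
  expect_error(trend_analysis(df[df$size < 100, ]), ">= 3")
})

test_that("reduced sweep is seed-reproducible end to end", {
  src <- generate_null_population(generator_config(n_participants = 50, seed = 6))
  cfg <- resample_config(sizes = c(24, 45), n_resamples = 6, n_ci_boot = 25,
                         seed = 12)
  r1 <- size_sweep(src, cfg)
  r2 <- size_sweep(src, cfg)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$matrices, r2$matrices)
  expect_equal(nrow(r1$pairs), 2L * 33L)
  expect_equal(nrow(r1$degenerate), 2L * 15L)
  # size 45: groups 15/15/15split by remainder rule
  expect_true(all(r1$degenerate$n_degenerate >= 0))
})

test_that("effect size trend reports per-category correlations and size means", {
  src <- generate_null_population(generator_config(n_participants = 50, seed = 6))
  cfg <- resample_config(sizes = c(24, 48, 96), n_resamples = 10,
                         n_ci_boot = 10, seed = 12)
  res <- size_sweep(src, cfg)
  tr <- effect_size_trend(res)
  expect_equal(sort(tr$category), c("ACQ_EXT", "EXT", "EXT_EXT"))
  expect_equal(tr$n_points, rep(30L, 3))
  by_size <- attr(tr, "by_size")
  expect_equal(nrow(by_size), 9L)
  tr2 <- effect_size_trend(res, aggregate = "size")
  expect_equal(tr2$n_points, rep(3L, 3))
})
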
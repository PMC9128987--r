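# deterministic labelled dataset with heterogeneous values
strategy_fixture <- function(n = 12, seed = 3) {
  set.seed(seed)
  scr_dataset(matrix(stats::rexp(n * 30, 2), n, 30),
              group = rep(1:3, length.out = n))
}

test_that("catalogue has 15 strategies with the published category structure", {
  specs <- builtin_strategies()
  expect_length(specs, 15L)
  cat <- strategy_catalogue()
  expect_equal(as.vector(table(cat$category)[c("ACQ_EXT", "EXT", "EXT_EXT")]),
               c(4L, 7L, 4L))
  expect_equal(cat$id[1:4], paste0("ACQ_EXT.", 1:4))
  expect_true(all(grepl("Group", cat$model_term)))

  ext4 <- specs[[which(cat$id == "EXT.4")]]
  expect_equal(ext4$aggregation, "SINGLE_TRIAL")
  expect_equal(ext4$stimulus_handling, "DIFFERENTIAL")
  expect_equal(ext4$model_term, "Group")

  ext6 <- specs[[which(cat$id == "EXT.6")]]
  expect_equal(ext6$aggregation, "RUNNING_AVERAGE")
})

test_that("trial selection implements the per-strategy aggregation rules", {
  d <- strategy_fixture(3)
  specs <- builtin_strategies()
  ids <- strategy_catalogue()$id
  dm <- differential(d)
  ext_d <- dm[, c(paste0("EXT_EARLY.", 1:5), paste0("EXT_LATE.", 1:5))]

  # EXT.5: per stimulus, mean of extinction trials 9-10
  t5 <- select_trials(d, specs[[which(ids == "EXT.5")]])
  expect_equal(nrow(t5), 3L * 2L)
  p1 <- t5$value[t5$subject == d$participant[1] & t5$Stim == "CSP"]
  expect_equal(p1, mean(d$responses[1, c("EXT_LATE.CSP.4", "EXT_LATE.CSP.5")]))

  # EXT.6: running average of the 5 early-extinction differentials
  t6 <- select_trials(d, specs[[which(ids == "EXT.6")]])
  expect_equal(sort(unique(t6$Trial)), as.character(1:4))
  v <- t6$value[t6$subject == d$participant[2]]
  ee <- dm[2, paste0("EXT_EARLY.", 1:5)]
  expect_equal(v, unname((ee[-5] + ee[-1]) / 2))

  # ACQ_EXT.2: acquisition value is the per-subject max differential
  t2 <- select_trials(d, specs[[which(ids == "ACQ_EXT.2")]])
  acq_val <- t2$value[t2$subject == d$participant[3] & t2$Phase == "1pre"]
  expect_equal(acq_val, max(dm[3, paste0("ACQ.", 1:5)]))

  # EXT.4: single last extinction trial, differential
  t4 <- select_trials(d, specs[[which(ids == "EXT.4")]])
  expect_equal(t4$value, unname(ext_d[, 10]))
})

test_that("running average maps (1,2,3,4,5) to (1.5,2.5,3.5,4.5)", {
  expect_equal(as.vector(scrrobust:::.running_average(matrix(1:5, 1))),
               c(1.5, 2.5, 3.5, 4.5))
})

test_that("evaluate_all returns 15 in-range results in catalogue order", {
  d <- strategy_fixture(12)
  res <- evaluate_all(d)
  expect_equal(res$id, strategy_catalogue()$id)
  expect_true(all(res$eta_p2 >= 0 & res$eta_p2 <= 1, na.rm = TRUE))
  expect_true(all(!res$degenerate))
  # deterministic and invariant to subject reordering
  expect_equal(evaluate_all(d), res)
  perm <- sample(n_participants(d))
  dp <- scr_dataset(d$responses[perm, ], participant = d$participant[perm],
                    group = d$group[perm])
  expect_equal(evaluate_all(dp)$eta_p2, res$eta_p2, tolerance = 1e-12)
})

test_that("EXT-category strategies ignore acquisition responses", {
  d <- strategy_fixture(12)
  res <- evaluate_all(d)
  resp <- d$responses
  acq_cols <- scr_cells()$phase == "ACQ"
  resp[, acq_cols] <- resp[, acq_cols] * 2 + 0.3
  d2 <- scr_dataset(resp, participant = d$participant, group = d$group)
  res2 <- evaluate_all(d2)
  unaffected <- res$category != "ACQ_EXT"
  expect_equal(res2$eta_p2[unaffected], res$eta_p2[unaffected], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(res2$eta_p2[!unaffected], res$eta_p2[!unaffected])))
})

test_that("differential strategies cancel shifts common to both stimuli", {
  d <- strategy_fixture(12)
  res <- evaluate_all(d)
  # add a constant to CSP and CSM of every cell (same shift both stimuli)
  d2 <- scr_dataset(d$responses + 0.7, participant = d$participant,
                    group = d$group)
  res2 <- evaluate_all(d2)
  diff_ids <- strategy_catalogue()$id[
    strategy_catalogue()$stimulus_handling == "DIFFERENTIAL"]
  sel <- res$id %in% diff_ids
  expect_equal(res2$eta_p2[sel], res$eta_p2[sel], tolerance = 1e-9)
})

test_that("a large CSP-only group shift is detected by Group x Stim strategies", {
  set.seed(21)
  n <- 120  # 40 per group
  d <- scr_dataset(matrix(stats::rexp(n * 30, 2), n, 30),
                   group = rep(1:3, length.out = n))
  resp <- d$responses
  csp <- scr_cells()$stimulus == "CSP"
  resp[d$group == 3, csp] <- resp[d$group == 3, csp] + 2
  d2 <- scr_dataset(resp, participant = d$participant, group = d$group)
  r <- evaluate_strategy(d2, builtin_strategies()[[5]])  # EXT.1, Group:Stim
  expect_gt(r$eta_p2, 0.5)
})

test_that("degenerate datasets are flagged, not fatal", {
  d <- flat_dataset(6, 1, group = rep(1:3, 2))
  res <- evaluate_all(d)
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$eta_p2)))
})

test_that("strategy evaluation requires group labels", {
  expect_error(evaluate_all(patterned_dataset(6)), "group-labelled")
})
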
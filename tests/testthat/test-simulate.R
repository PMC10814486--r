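test_that("selection configs validate their invariants", {
  expect_s3_class(selection_config(), "selection_config")
  expect_error(selection_config(n_clones = 1), ">= 2")
  expect_error(selection_config(selection_fraction = 0), "\\(0, 1\\]")
  expect_error(selection_config(response = 1.2), "\\[0, 1\\]")
  expect_error(selection_config(apoptosis_threshold = 0), "> 0")
})

test_that("the initial population is a zero-floored draw around the equilibrium mean", {
  degenerate <- selection_config(init_sd = 0, seed = 1)
  pop <- sample_initial_population(degenerate)
  expect_identical(nrow(pop), 48L)
  expect_true(all(pop$fcm_percent == 0.6))

  cfg <- selection_config(seed = 4)
  expect_identical(sample_initial_population(cfg),
                   sample_initial_population(cfg))

  # calibration: stage-0 sample mean near the 0.6% equilibrium
  means <- vapply(1:100, function(s) {
    mean(sample_initial_population(selection_config(seed = s))$fcm_percent)
  }, numeric(1))
  expect_gte(mean(means >= 0.4 & means <= 0.8), 0.9)
  expect_true(all(vapply(1:20, function(s) {
    min(sample_initial_population(selection_config(seed = s))$fcm_percent)
  }, numeric(1)) >= 0))
})

test_that("selection_step blends population and parent means as configured", {
  clones <- clones_tbl(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))

  # response 0: offspring centred on the population mean
  cfg0 <- selection_config(response = 0, init_sd = 0)
  off0 <- selection_step(clones, cfg0, stage = 1)
  expect_true(all(off0$fcm_percent == mean(clones$fcm_percent)))

  # response 1 with top-10% selection: offspring centred on the parent mean
  cfg1 <- selection_config(response = 1, init_sd = 0,
                           selection_fraction = 0.1)
  off1 <- selection_step(clones, cfg1, stage = 1)
  expect_true(all(off1$fcm_percent == 10))  # single top parent

  # selection_fraction 1: no selection differential, any response
  cfgall <- selection_config(selection_fraction = 1, response = 0.7,
                             init_sd = 0)
  offall <- selection_step(clones, cfgall, stage = 1)
  expect_equal(unique(offall$fcm_percent), mean(clones$fcm_percent))
  expect_equal(attr(offall, "parent_mean"), attr(offall, "pop_mean"))

  expect_error(selection_step(clones_tbl(1), cfg0), "at least 2")
})

test_that("expected mean FCM is non-decreasing under positive response", {
  # one-sided sign test over 100 seeded experiments
  incs <- unlist(lapply(1:100, function(s) {
    diff(run_selection_experiment(selection_config(seed = s))$summaries$avg_fcm)
  }))
  bt <- binom.test(sum(incs > 0), length(incs), p = 0.5,
                   alternative = "greater")
  expect_lt(bt$p.value, 1e-6)
})

test_that("the apoptosis filter partitions inclusively and conserves counts", {
  clones <- clones_tbl(c(5, 12))
  part <- apoptosis_filter(clones, threshold = 10)
  expect_identical(nrow(part$survivors), 1L)
  expect_identical(nrow(part$apoptotic), 1L)

  all_low <- apoptosis_filter(clones_tbl(c(1, 2, 3)), 10)
  expect_identical(nrow(all_low$apoptotic), 0L)
  at <- apoptosis_filter(clones_tbl(c(10, 10)), 10)
  expect_identical(nrow(at$survivors), 0L)  # inclusive boundary

  set.seed(12)
  for (i in 1:10) {
    cl <- clones_tbl(runif(40, 0, 20))
    p <- apoptosis_filter(cl, 10)
    expect_identical(nrow(p$survivors) + nrow(p$apoptotic), nrow(cl))
    expect_true(all(p$apoptotic$fcm_percent >= 10))
    expect_true(all(p$survivors$fcm_percent < 10))
  }
})

test_that("stage summaries report exact min/mean/max", {
  s <- stage_summary(0, clones_tbl(c(0.0, 0.6, 2.0)))
  expect_identical(s$min_fcm, 0)
  expect_identical(s$max_fcm, 2)
  expect_equal(s$avg_fcm, 0.8666667, tolerance = 1e-6)
  one <- stage_summary(3, clones_tbl(4.2))
  expect_true(one$min_fcm == one$avg_fcm && one$avg_fcm == one$max_fcm)
  expect_error(stage_summary(0, clones_tbl(numeric(0))), "empty")
})

test_that("a no-selection control run stays stationary and completes", {
  res <- run_selection_experiment(
    selection_config(response = 0, dispersal = 1, apoptosis_threshold = 100,
                     seed = 2)
  )
  expect_identical(res$cause, "selection-complete")
  expect_identical(nrow(res$summaries), 5L)
  expect_lt(diff(range(res$summaries$avg_fcm)), 0.5)
  expect_identical(tidy(res), res$summaries)
  expect_identical(glance(res)$cause, "selection-complete")
})

test_that("experiments are bit-reproducible from the config seed", {
  cfg <- selection_config(seed = 77)
  a <- run_selection_experiment(cfg)
  b <- run_selection_experiment(cfg)
  expect_identical(a$summaries, b$summaries)
  expect_identical(a$stages, b$stages)
})

test_that("aggressive selection from an elevated population ends in apoptosis", {
  agg <- function(s) {
    selection_config(init_mean = 4, init_sd = 1, dispersal = 1.1,
                     response = 1, selection_fraction = 0.1,
                     apoptosis_threshold = 10, n_stages = 10, seed = s)
  }
  runs <- lapply(1:40, function(s) run_selection_experiment(agg(s)))
  causes <- vapply(runs, `[[`, character(1), "cause")
  tstage <- vapply(runs, `[[`, numeric(1), "termination_stage")
  expect_gte(mean(causes == "apoptosis"), 0.9)
  expect_gte(mean(causes == "apoptosis" & tstage <= 5), 0.5)
  # apoptotic flags in the terminal stage are consistent with the threshold
  done <- runs[causes == "apoptosis"][[1]]
  last <- done$stages[[length(done$stages)]]
  expect_true(all(last$fcm_percent[last$apoptotic] >= 10))
})

test_that("the configured selection response is recovered by regression", {
  cfg <- function(s) selection_config(response = 0.6,
                                      apoptosis_threshold = 100, seed = s)
  runs <- lapply(1:200, function(s) run_selection_experiment(cfg(s)))
  est <- estimate_selection_response(runs)
  expect_lt(abs(est - 0.6), 0.15)
})
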
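test_that("cumulative_distribution matches a brute-force count", {
  cdf <- cumulative_distribution(c(1, 2, 3))
  expect_equal(cdf$value, c(1, 2, 3))
  expect_equal(cdf$fraction, c(1 / 3, 2 / 3, 1))

  cdf1 <- cumulative_distribution(rep(4.2, 10))
  expect_equal(nrow(cdf1), 1L)
  expect_equal(cdf1$fraction, 1)

  set.seed(100)
  v <- rnorm(200)
  cdf <- cumulative_distribution(v)
  for (i in sample(nrow(cdf), 20)) {
    expect_equal(cdf$fraction[i], sum(v <= cdf$value[i]) / 200)
  }
  expect_error(cumulative_distribution(numeric()), "nonempty")
})

test_that("the failure rule excludes rows strictly beyond 60 deg / 60 mm", {
  rows <- rbind(
    data.frame(pair_id = 1:5, stage = "coarse",
               e_r = c(5, 90, 10, 15, 20), e_t = c(5, 5, 5, 5, 5),
               runtime_s = 1, failed = c(FALSE, TRUE, FALSE, FALSE, FALSE)),
    data.frame(pair_id = 1:5, stage = "fine",
               e_r = c(0.5, 80, 1, 1.5, 2), e_t = c(0.2, 70, 0.3, 0.4, 0.1),
               runtime_s = 1, failed = c(FALSE, TRUE, FALSE, FALSE, FALSE)))
  rep <- spinereg:::.summarize_report(rows)
  expect_equal(rep$summary$coarse$mean_e_r, mean(c(5, 10, 15, 20)))
  expect_equal(rep$summary$fine$mean_e_r, mean(c(0.5, 1, 1.5, 2)))
  expect_equal(rep$summary$coarse$n, 4L)
  expect_equal(rep$n_failed, 1L)

  # rule boundary is strict: exactly 60 is not a failure
  expect_false(60 > rep$failure_rule$e_r_max)
})

test_that("reports round-trip through CSV + JSON", {
  rows <- data.frame(pair_id = c(1L, 1L, 2L, 2L),
                     stage = c("coarse", "fine", "coarse", "fine"),
                     e_r = c(4.5, 0.3, 70, 80), e_t = c(3.2, 0.1, 65, 61),
                     runtime_s = c(1.5, 1.5, 2.5, 2.5),
                     failed = c(FALSE, FALSE, TRUE, TRUE))
  rep <- spinereg:::.summarize_report(rows)
  prefix <- file.path(withr::local_tempdir(), "exp")
  write_report(rep, prefix)
  back <- read_report(prefix)
  expect_equal(back$rows, rep$rows)
  expect_equal(back$summary, rep$summary)
  expect_equal(back$n_failed, rep$n_failed)
})

test_that("run_experiment produces one row per stage and pair with sane errors", {
  fix <- tiny_trained_fixture()
  rep <- run_experiment(fix$pairs[1:3], fix$model, pipeline_config(),
                        mode = "oracle")
  expect_equal(sort(unique(rep$rows$pair_id)), 1:3)
  expect_true(all(rep$rows$stage %in% c("coarse", "fine")))
  expect_equal(nrow(rep$rows), 6L)
  expect_true(all(rep$rows$e_r >= 0 | is.na(rep$rows$e_r)))
  expect_true(all(c("coarse", "fine") %in% names(rep$summary) |
                    rep$n_failed == 3L))
})

test_that("noise_sweep re-registers at each sigma with a common schema", {
  fix <- tiny_trained_fixture()
  reports <- suppressMessages(
    noise_sweep(fix$pairs[1:2], c(0, 0.5), fix$model, pipeline_config(),
                mode = "oracle"))
  expect_equal(names(reports), c("sigma_0", "sigma_0.5"))
  for (r in reports) {
    expect_s3_class(r, "experiment_report")
    expect_equal(sort(unique(r$rows$pair_id)), 1:2)
    expect_identical(names(r$rows), names(reports[[1]]$rows))
  }
  # sigma = 0 reproduces the noise-free registration of the same pairs
  base <- run_experiment(fix$pairs[1:2], fix$model, pipeline_config(),
                         mode = "oracle")
  expect_equal(reports$sigma_0$rows$e_r, base$rows$e_r, tolerance = 1e-9)
})
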
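fake_result <- function(percent, time_min = 30, cell_id = "c1",
                        null_percent = 0.1) {
  vesicoloc:::new_coloc_result(
    label_A = "cargo", label_B = "marker", direction = "B_with_A",
    numerator_px = 1L, denominator_px = 4L,
    percent = percent, defined = !is.na(percent),
    null_percent = null_percent, per_slab = NULL,
    time_min = time_min, cell_id = cell_id)
}

test_that("time-course summary reports mean, SEM and n per group", {
  res <- list(fake_result(10, cell_id = "c1"),
              fake_result(20, cell_id = "c2"),
              fake_result(30, cell_id = "c3"))
  s <- summarize_timecourse(res)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_cells, 3)
  expect_equal(s$mean_percent, 20)
  expect_equal(s$sem_percent, 10 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$sem_percent, 5.7735, tolerance = 1e-4)
  # identical percents: SEM exactly 0; single cell: SEM absent
  s2 <- summarize_timecourse(list(fake_result(12), fake_result(12)))
  expect_equal(s2$sem_percent, 0)
  s3 <- summarize_timecourse(list(fake_result(12)))
  expect_equal(s3$n_cells, 1)
  expect_true(is.na(s3$sem_percent))
  expect_error(summarize_timecourse(list()), class = "vc_degenerate_error")
})

test_that("undefined results are excluded from aggregation", {
  res <- list(fake_result(10), fake_result(NA), fake_result(20))
  expect_message(s <- summarize_timecourse(res), "excluding 1")
  expect_equal(s$n_cells, 2)
  expect_equal(s$mean_percent, 15)
})

test_that("aggregation is invariant to cell order", {
  res <- list(fake_result(10, cell_id = "a"), fake_result(25, cell_id = "b"),
              fake_result(31, cell_id = "c"))
  expect_equal(summarize_timecourse(res)$mean_percent,
               summarize_timecourse(rev(res))$mean_percent)
  expect_equal(summarize_timecourse(res)$sem_percent,
               summarize_timecourse(rev(res))$sem_percent)
})

test_that("pooled-variance t-test reproduces the hand computation", {
  cp <- compare_pairs(c(10, 12, 14), c(20, 22, 24), "student")
  expect_equal(cp$t, -6.123724, tolerance = 1e-6)
  expect_equal(cp$df, 4)
  expect_equal(cp$p, 0.003602233, tolerance = 1e-6)
  # identical groups: t = 0, p = 1
  cp0 <- compare_pairs(1:3, 1:3)
  expect_equal(cp0$t, 0)
  expect_equal(cp0$p, 1)
  # swapping the groups flips t, preserves p
  sw <- compare_pairs(c(20, 22, 24), c(10, 12, 14), "student")
  expect_equal(sw$t, -cp$t)
  expect_equal(sw$p, cp$p)
  expect_error(compare_pairs(1, 1:3), class = "vc_degenerate_error")
})

test_that("student and welch agree on balanced equal-variance groups", {
  cp_s <- compare_pairs(c(1, 2, 3, 4), c(11, 12, 13, 14), "student")
  cp_w <- compare_pairs(c(1, 2, 3, 4), c(11, 12, 13, 14), "welch")
  expect_lt(abs(cp_s$t - cp_w$t), 1e-9)
})

test_that("significance stars follow the 0.05/0.01/0.001 convention", {
  expect_identical(signif_stars(c(0.2, 0.04, 0.009, 0.0009)),
                   c("", "*", "**", "***"))
})

test_that("end-to-end pipeline on full co-location scenes reports > 90%", {
  out <- run_fixture_pipeline(file.path(tempdir(), "pipe_out1"))
  per_cell <- read.csv(file.path(out, "per_cell.csv"))
  expect_equal(nrow(per_cell), 3)
  smry <- read.csv(file.path(out, "summary.csv"))
  expect_equal(nrow(smry), 1)
  expect_gt(smry$mean_percent, 90)
  expect_equal(smry$n_cells, 3)
  expect_true(file.exists(file.path(out, "run.log")))
  expect_true(file.exists(file.path(out, "config_snapshot.yaml")))
  # every summary number re-derivable from the per-cell table
  expect_equal(smry$mean_percent, mean(per_cell$percent))
  expect_equal(smry$sem_percent, sd(per_cell$percent) / sqrt(3))
})

test_that("an empty manifest is rejected with no outputs", {
  out <- file.path(tempdir(), "pipe_out_empty")
  man <- file.path(tempdir(), "empty_manifest.csv")
  write.csv(data.frame(file = character(0)), man, row.names = FALSE)
  expect_error(run_pipeline(list(), man, out), class = "vc_validation_error")
  expect_false(file.exists(file.path(out, "per_cell.csv")))
})
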
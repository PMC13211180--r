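test_that("control reference and threshold use interpolated order statistics", {
  r <- control_reference(c(4, 4, 4))
  expect_equal(r$reference, 4)
  expect_equal(r$threshold, 4)

  r <- control_reference(1:20)
  expect_equal(r$reference, 10.5)
  expect_equal(r$threshold, 19.05)

  r <- control_reference(c(1, 100))
  expect_equal(r$reference, 50.5)
  expect_equal(r$threshold, 95.05)

  expect_error(control_reference(3), "at least 2")
  expect_error(control_reference(c(-1, 2)), "positive")
})

test_that("standardized log-ratios match the closed form for geometric means", {
  R <- 2.5
  means <- c(CTRL = R, C1 = R * exp(1), C2 = R * exp(2), C3 = R * exp(3))
  out <- standardized_log_ratios(means, reference = R, threshold = R * 1.1)
  expect_equal(out$log_ratio, c(0, 1, 2, 3))
  sdL <- sqrt(sum((0:3 - 1.5)^2) / 3) # 1.29099...
  expect_equal(out$z, (0:3) / sdL, tolerance = 1e-12)
  expect_equal(out$z[4], 2.32379, tolerance = 1e-5)
  expect_equal(out$included, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("degenerate cases follow the stated conventions", {
  means <- c(CTRL = 3, C1 = 3, C2 = 3)
  out <- standardized_log_ratios(means, reference = 3, threshold = 3)
  expect_equal(out$z, rep(0, 3))
  expect_false(any(out$included))

  # all equal but different from the reference: sd of L is 0 -> z = 0
  out <- standardized_log_ratios(c(a = 6, b = 6), reference = 3, threshold = 5)
  expect_equal(out$z, c(0, 0))
  expect_true(all(out$included))

  expect_error(standardized_log_ratios(c(a = 1, b = -2), 1, 1), "nonpositive.*b")
})

test_that("the score is the mean absolute z over included biomarkers", {
  expect_equal(ibrt_score(c(1, 2), c(FALSE, FALSE)), 0)
  expect_equal(ibrt_score(c(1.54919, -2.32379), c(TRUE, TRUE)), 1.93649)
  expect_equal(ibrt_score(0.5, TRUE), 0.5)
  expect_error(ibrt_score(c(1, 2), TRUE), "same length")
})

test_that("compute_ibrt matches an independent re-derivation on random tables", {
  set.seed(42)
  for (rep in 1:5) {
    df <- make_records(function(ti, tr, dy, bm, i) exp(rnorm(1, 0, 0.6)),
                       days = c(10L, 20L), n = 5L)
    fit <- compute_ibrt(df)
    orc <- oracle_ibrt(df)
    got <- merge(fit$scores, orc, by = c("tissue", "day", "treatment"))
    expect_equal(nrow(got), nrow(fit$scores))
    expect_lt(max(abs(got$score.x - got$score.y)), 1e-12)
  }
})

test_that("the index is invariant to rescaling any single biomarker", {
  set.seed(7)
  df <- make_records(function(ti, tr, dy, bm, i) exp(rnorm(1, 0, 0.5)), n = 6L)
  base <- compute_ibrt(df)
  df2 <- df
  k <- 137.5
  sel <- df2$biomarker == "MDA"
  df2$value[sel] <- df2$value[sel] * k
  scaled <- compute_ibrt(df2)
  expect_equal(scaled$scores$score, base$scores$score, tolerance = 1e-12)
  expect_equal(scaled$details$z, base$details$z, tolerance = 1e-12)
  expect_equal(scaled$details$included, base$details$included)
})

test_that("null data scores zero everywhere, including the control", {
  df <- make_records(function(ti, tr, dy, bm, i) 5, n = 4L)
  fit <- compute_ibrt(df)
  expect_true(all(fit$scores$score == 0))
  expect_false(any(fit$details$included))
})

test_that("noise-free dose-monotone effects order the scores by dose", {
  x <- generate_study(effect_config(seed = 1, n_per_cell = 3), noise = FALSE)
  fit <- compute_ibrt(x)
  sc <- fit$scores
  for (ti in unique(sc$tissue)) for (dy in unique(sc$day)) {
    s <- sc[sc$tissue == ti & sc$day == dy, ]
    expect_gte(s$score[s$treatment == "C3"], s$score[s$treatment == "C1"])
    expect_equal(s$score[s$treatment == "CTRL"], 0)
  }
})

test_that("stronger dose slopes never weaken the C3 score (fixed seed)", {
  scores <- vapply(c(0.1, 0.2, 0.4), function(sl) {
    x <- generate_study(effect_config(dose_slope = sl, seed = 9), noise = FALSE)
    f <- compute_ibrt(x)
    f$scores$score[f$scores$tissue == "gills" & f$scores$day == 10 &
                   f$scores$treatment == "C3"]
  }, 0)
  expect_equal(scores, sort(scores))
})

test_that("structural requirements are enforced", {
  df <- make_records(function(...) 2, treatments = c("C1", "C2"), n = 3L)
  expect_error(compute_ibrt(df), "no control group")
  one_ctrl <- make_records(function(...) 2, treatments = c("CTRL", "C1"), n = 1L)
  expect_error(compute_ibrt(one_ctrl), "fewer than 2 control values")
})

test_that("day pooling draws the reference from both days' controls", {
  df <- make_records(function(ti, tr, dy, bm, i) ifelse(dy == 10, i, i * 10),
                     tissues = "gills", biomarkers = "SOD",
                     days = c(10L, 20L), n = 4L)
  per_day <- compute_ibrt(df)
  pooled <- compute_ibrt(df, pool_days = TRUE)
  # pooled reference is shared across days; per-day references differ
  ref_pd <- unique(per_day$details$reference)
  ref_pool <- unique(pooled$details$reference)
  expect_equal(length(ref_pd), 2L)
  expect_equal(length(ref_pool), 1L)
})

test_that("two-sided mode can include suppressed biomarkers", {
  df <- make_records(function(ti, tr, dy, bm, i) {
    base <- c(1.0, 1.2, 1.4, 1.1, 1.3)[i]
    if (tr == "C3") base * 0.2 else base
  }, tissues = "gills", biomarkers = "SOD", treatments = c("CTRL", "C3"),
     n = 5L)
  up_only <- compute_ibrt(df)
  both <- compute_ibrt(df, two_sided = TRUE)
  expect_false(any(up_only$details$included[up_only$details$treatment == "C3"]))
  expect_true(any(both$details$included[both$details$treatment == "C3"]))
})
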
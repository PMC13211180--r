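test_that("sum coding yields the right column counts and balanced-sum property", {
  d <- balanced_data()
  bd <- build_design(d, value ~ Treatment)
  expect_equal(sum(bd$assign == 1), 3L) # 4 levels -> 3 columns
  expect_equal(unname(colSums(bd$X[, bd$assign == 1])), rep(0, 3))

  bd2 <- build_design(d, value ~ Treatment + Day + Treatment:Day)
  expect_equal(sum(bd2$assign == 3), 3L) # (4-1)(2-1)

  full <- assemble_model_data(
    generate_study(effect_config(seed = 2, n_per_cell = 2)),
    generate_viability(viability_config(n_per_cell = 2), seed = 2))
  bdf <- build_design(full)
  dfs <- vapply(seq_along(bdf$term_labels),
                function(t) sum(bdf$assign == t), 1L)
  B <- nlevels(full$Biomarker)
  expect_equal(dfs, c(3L, 1L, 3L, B - 1L, 3L, 3L * (B - 1L), 3L * (B - 1L)))
})

test_that("dummy coding and broken designs are refused", {
  d <- balanced_data()
  expect_error(build_design(d, value ~ Treatment, contrasts = "contr.treatment"),
               "sum-to-zero")
  d2 <- d[d$Treatment != "C3", ]
  expect_error(build_design(d2, value ~ Treatment), "unobserved level.*C3")
})

test_that("least squares reproduces exact structure", {
  d <- balanced_data(seed = 4)
  bd <- build_design(d, value ~ Treatment + Day)
  beta <- c(2, 0.5, -0.25, 0.1, 1.5)
  y <- as.vector(bd$X %*% beta)
  fit <- fit_least_squares(bd$X, y)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)
  # intercept-only model returns the mean
  fit0 <- fit_least_squares(matrix(1, nrow(d), 1), d$value)
  expect_equal(unname(fit0$coefficients), mean(d$value))
  # residual orthogonality to the design
  fit1 <- fit_least_squares(bd$X, d$value)
  expect_lt(max(abs(crossprod(bd$X, fit1$residuals))), 1e-8)
})

test_that("a balanced 2x2 fit recovers half the classical contrasts", {
  g <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"))
  g$A <- factor(g$A); g$B <- factor(g$B)
  cellmeans <- c(10, 14, 12, 20) # a1b1, a2b1, a1b2, a2b2
  g$value <- cellmeans
  bd <- build_design(g, value ~ A + B)
  fit <- fit_least_squares(bd$X, g$value)
  # classical main effect of A = mean(a2) - mean(a1) = 6; sum coding
  # estimates the a1 deviation = -3
  expect_equal(unname(fit$coefficients[2]), -3)
  expect_equal(unname(fit$coefficients[3]), -2)
})

test_that("Type III equals sequential SS on balanced designs", {
  d <- balanced_data(n = 4, seed = 8, trt_eff = c(0, 0.3, 0.5, 1),
                     day_eff = c(0, 0.4))
  f <- value ~ Treatment * Day * Biomarker
  mine <- type3_anova(d, formula = f)
  seq_tab <- anova(lm(f, data = d))
  seq_ss <- seq_tab[mine$term, "Sum Sq"]
  expect_lt(max(abs(mine$sum_sq - seq_ss) / seq_ss), 1e-9)
  expect_equal(attr(mine, "df_residual"),
               seq_tab["Residuals", "Df"])
})

test_that("Type III matches car::Anova under identical coding", {
  skip_if_not_installed("car")
  bio <- generate_study(effect_config(seed = 5, n_per_cell = 3))
  viab <- generate_viability(viability_config(n_per_cell = 3), seed = 5)
  d <- assemble_model_data(bio, viab)
  f <- value ~ Matrix + Treatment * Day * Biomarker # unbalanced across Matrix
  mine <- type3_anova(d, formula = f)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  ca <- car::Anova(lm(f, data = d), type = 3)
  ca <- ca[mine$term, ]
  expect_equal(mine$sum_sq, ca$`Sum Sq`, tolerance = 1e-10)
  expect_equal(mine$statistic, ca$`F value`, tolerance = 1e-10)
  expect_equal(mine$p_value, ca$`Pr(>F)`, tolerance = 1e-10)
})

test_that("results are invariant to row order, shifts, and term order", {
  d <- balanced_data(n = 3, seed = 9, trt_eff = c(0, 0.2, 0.4, 0.8))
  f <- value ~ Treatment + Day + Biomarker + Treatment:Day
  a <- type3_anova(d, formula = f)
  set.seed(1)
  b <- type3_anova(d[sample(nrow(d)), ], formula = f)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)

  d2 <- d; d2$value <- d2$value + 100
  c2 <- type3_anova(d2, formula = f)
  expect_equal(a$statistic, c2$statistic, tolerance = 1e-8)
  expect_equal(a$sum_sq, c2$sum_sq, tolerance = 1e-8)

  f_rev <- value ~ Biomarker + Day + Treatment + Treatment:Day
  r <- type3_anova(d, formula = f_rev)
  canon <- function(t) vapply(strsplit(t, ":"),
                              function(p) paste(sort(p), collapse = ":"), "")
  r <- r[match(canon(a$term), canon(r$term)), ]
  expect_equal(a$statistic, r$statistic, tolerance = 1e-10)
})

test_that("the assembled model dataset has the reported factor structure", {
  bio <- generate_study(effect_config(seed = 1, n_per_cell = 2))
  viab <- generate_viability(viability_config(n_per_cell = 2), seed = 1)
  d <- assemble_model_data(bio, viab)
  expect_equal(nlevels(d$Biomarker), 5L) # four enzymes/markers + viability
  expect_equal(nlevels(d$Matrix), 4L)    # three tissues + hemolymph
  expect_equal(nrow(d), nrow(bio) + nrow(viab))
  # z-scored within biomarker level
  for (b in levels(d$Biomarker)) {
    expect_equal(mean(d$value[d$Biomarker == b]), 0, tolerance = 1e-12)
    expect_equal(sd(d$value[d$Biomarker == b]), 1, tolerance = 1e-12)
  }
  # without viability: 4 biomarker levels, 3 matrices
  d0 <- assemble_model_data(bio)
  expect_equal(nlevels(d0$Biomarker), 4L)
  expect_equal(nlevels(d0$Matrix), 3L)
})
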
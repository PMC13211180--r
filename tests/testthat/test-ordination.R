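test_that("z-scoring centres and scales each column", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- zscore(m)
  expect_equal(z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1))
  expect_warning(zc <- zscore(cbind(k = c(5, 5, 5))), "constant")
  expect_equal(unname(zc[, 1]), c(0, 0, 0))
  expect_error(zscore(cbind(c(1, NA, NA))), "fewer than 2")
})

test_that("imputation is the identity on complete matrices", {
  m <- matrix(rnorm(20), 5, 4)
  out <- impute_missing(m)
  expect_equal(unclass(out)[, ], m[, ])
})

test_that("a masked cell of a rank-1 matrix is recovered exactly", {
  u <- c(1, 2, 3, 4, 5)
  v <- c(2, -1, 0.5, 3)
  m <- outer(u, v)
  truth <- m[2, 3]
  m[2, 3] <- NA
  out <- impute_missing(m, n_components = 1, tol = 1e-12, max_iter = 2000)
  expect_lt(abs(out[2, 3] - truth), 1e-8)
  # observed cells untouched
  obs <- !is.na(m)
  expect_identical(out[obs], m[obs])
})

test_that("MCAR imputation error stays below the noise level", {
  set.seed(21)
  n <- 40; p <- 8
  signal <- matrix(rnorm(n * 2), n, 2) %*% matrix(rnorm(2 * p, sd = 2), 2, p)
  noise_sd <- 0.3
  m <- signal + rnorm(n * p, sd = noise_sd)
  mask <- matrix(runif(n * p) < 0.1, n, p)
  # keep every row/column partly observed
  mask[1, ] <- FALSE; mask[, 1] <- FALSE
  mm <- m; mm[mask] <- NA
  out <- impute_missing(mm, n_components = 2)
  # the imputed cells should recover the underlying signal more
  # accurately than a raw noisy observation would
  rmse <- sqrt(mean((out[mask] - signal[mask])^2))
  expect_lt(rmse, noise_sd)
})

test_that("imputation rejects hopeless structures", {
  m <- matrix(rnorm(12), 4, 3)
  m[2, ] <- NA
  expect_error(impute_missing(m), "row is entirely missing")
  m2 <- matrix(rnorm(12), 4, 3)
  m2[, 3] <- NA
  expect_error(impute_missing(m2), "column is entirely missing")
  expect_error(impute_missing(matrix(c(1, NA, 2, 4), 2, 2), n_components = 2),
               "smaller than")
})

test_that("Euclidean distances are the plain Pythagorean metric", {
  m <- rbind(c(0, 0), c(3, 4), c(0, 0))
  d <- as.matrix(euclidean_distances(m))
  expect_equal(d[1, 2], 5)
  expect_equal(d[1, 3], 0)
  expect_error(euclidean_distances(rbind(c(1, NA))), "impute_missing")
  # triangle inequality on random data
  set.seed(2)
  dm <- as.matrix(euclidean_distances(matrix(rnorm(30), 10, 3)))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
  }
})

test_that("NMDS reproduces planar and collinear configurations", {
  set.seed(4)
  x <- matrix(rnorm(20), 10, 2)
  fit <- nmds(dist(x), n_starts = 5, seed = 1)
  expect_lt(fit$stress, 1e-3)
  expect_equal(classify_stress(fit$stress), "acceptable")

  line <- cbind(c(0, 1, 2, 3.5), 0)
  fit_line <- nmds(dist(line), n_starts = 5, seed = 1)
  expect_lt(fit_line$stress, 1e-3)
})

test_that("the returned stress never exceeds the PCoA start's stress", {
  set.seed(10)
  x <- matrix(rnorm(60), 20, 3) # 3-D data in a 2-D map: nonzero stress
  fit <- nmds(dist(x), n_starts = 8, seed = 2)
  expect_lte(fit$stress, fit$start_stress)
  expect_gt(fit$stress, 0)
})

test_that("NMDS is deterministic and its start sequence is nested", {
  set.seed(30)
  d <- dist(matrix(rnorm(45), 15, 3))
  a <- nmds(d, n_starts = 6, seed = 11)
  b <- nmds(d, n_starts = 6, seed = 11)
  expect_identical(a$points, b$points)
  expect_identical(a$stress, b$stress)
  few <- nmds(d, n_starts = 3, seed = 11)
  many <- nmds(d, n_starts = 12, seed = 11)
  expect_lte(many$stress, few$stress + 1e-15)
})

test_that("stress is invariant under rigid motions of the configuration", {
  set.seed(12)
  d <- dist(matrix(rnorm(36), 12, 3))
  fit <- nmds(d, n_starts = 4, seed = 3)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  moved <- fit$points %*% R
  moved[, 1] <- -moved[, 1] # reflection
  moved <- sweep(moved, 2, c(3, -8), `+`) # translation
  s0 <- vegan::monoMDS(d, y = fit$points, k = 2, model = "global",
                       maxit = 0)$stress
  s1 <- vegan::monoMDS(d, y = moved, k = 2, model = "global",
                       maxit = 0)$stress
  expect_equal(s1, s0, tolerance = 1e-10)
})

test_that("stress classification applies the 0.2 rule strictly", {
  expect_equal(classify_stress(0.1488), "acceptable")
  expect_equal(classify_stress(0.25), "poor")
  expect_equal(classify_stress(0.2), "poor")
  expect_equal(classify_stress(0), "acceptable")
  expect_error(classify_stress(-0.1), "nonnegative")
})

test_that("degenerate distance inputs are refused", {
  expect_error(nmds(dist(matrix(0, 5, 2))), "degenerate")
  expect_error(nmds(dist(matrix(rnorm(6), 3, 2))), "at least 4")
})

test_that("the feature matrix pivots tissues and viability correctly", {
  bio <- generate_study(effect_config(seed = 3, n_per_cell = 3))
  viab <- generate_viability(viability_config(n_per_cell = 3), seed = 3)
  fm <- build_feature_matrix(bio, viab)
  expect_equal(colnames(fm$values), c("SOD", "GPx", "GST", "MDA", "NR", "TB"))
  # hemolymph rows have only viability, gills/muscle rows only enzymes
  he <- fm$meta$matrix == "hemolymph"
  expect_true(all(is.na(fm$values[he, 1:4])))
  expect_true(all(!is.na(fm$values[he, 5:6])))
  gi <- fm$meta$matrix == "gills"
  expect_true(all(!is.na(fm$values[gi, 1:4])))
  expect_true(all(is.na(fm$values[gi, 5:6])))
  # hepatopancreas rows join enzymes and viability for the same animal
  hp <- fm$meta$matrix == "hepatopancreas"
  expect_true(all(!is.na(fm$values[hp, ])))
})

test_that("strong effects separate treatments in the ordination", {
  bio <- generate_study(effect_config(dose_slope = 0.6, seed = 5,
                                      n_per_cell = 4))
  sub <- bio[bio$tissue == "gills" & bio$day == 20, ]
  fm <- build_feature_matrix(sub)
  z <- zscore(fm$values)
  fit <- nmds(euclidean_distances(z), n_starts = 10, seed = 6)
  dm <- as.matrix(dist(fit$points))
  same <- outer(fm$meta$treatment, fm$meta$treatment, "==")
  diag(same) <- NA
  within <- mean(dm[same & !is.na(same)])
  between <- mean(dm[!same & !is.na(same)])
  expect_gt(between, within)
})
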
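# Ordination stage: z-scoring, iterative low-rank (EM-PCA) imputation
# of missing cells, Euclidean distances, and non-metric MDS with
# Kruskal stress-1. The NMDS optimizer is vegan::monoMDS (global
# nonmetric model, primary tie treatment); this package manages the
# starts (one deterministic principal-coordinates start plus seeded
# random starts), selects the best, and normalizes the configuration.

#' Column-wise z-scoring
#'
#' Centers and scales every column by the mean and sample SD of its
#' non-missing entries. A zero-SD column becomes all zeros with a
#' warning; a column with fewer than 2 observed values is an error.
#'
#' @param x Numeric matrix or data frame; may contain `NA`.
#' @return A numeric matrix of the same shape; missing cells stay
#'   missing.
#' @export
zscore <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  for (j in seq_len(ncol(x))) {
    obs <- x[, j][!is.na(x[, j])]
    if (length(obs) < 2L) {
      stop(sprintf("column %s has fewer than 2 observed values",
                   colnames(x)[j] %||% j), call. = FALSE)
    }
    s <- stats::sd(obs)
    if (s == 0) {
      warning(sprintf("column %s is constant; z-scores set to 0",
                      colnames(x)[j] %||% j))
      x[, j] <- ifelse(is.na(x[, j]), NA_real_, 0)
    } else {
      x[, j] <- (x[, j] - mean(obs)) / s
    }
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Iterative low-rank imputation of missing cells
#'
#' EM-style principal-component imputation: missing cells are
#' initialized with column means, then the matrix is repeatedly
#' approximated by a rank-`n_components` SVD (of the column-centered
#' matrix) whose reconstruction refills the missing cells while
#' observed cells are reimposed unchanged. Iteration stops when the
#' largest absolute change in an imputed cell falls below `tol`.
#'
#' @param x Numeric matrix with `NA` marking missing cells. Every row
#'   and column must have at least one observed value.
#' @param n_components Rank of the reconstruction; must be smaller
#'   than both dimensions.
#' @param tol Convergence tolerance on imputed cells.
#' @param max_iter Iteration cap.
#' @return The completed matrix; attributes `iterations` and
#'   `converged` record the stopping state. Observed cells are
#'   returned bit-identically.
#' @export
impute_missing <- function(x, n_components = 2, tol = 1e-6, max_iter = 500) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  miss <- is.na(x)
  if (!any(miss)) {
    attr(x, "iterations") <- 0L
    attr(x, "converged") <- TRUE
    return(x)
  }
  if (any(rowSums(!miss) == 0L)) stop("a row is entirely missing", call. = FALSE)
  if (any(colSums(!miss) == 0L)) stop("a column is entirely missing", call. = FALSE)
  if (n_components >= min(dim(x))) {
    stop("n_components must be smaller than both matrix dimensions",
         call. = FALSE)
  }
  colm <- colMeans(x, na.rm = TRUE)
  xf <- x
  xf[miss] <- colm[col(x)[miss]]
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- colMeans(xf)
    xc <- sweep(xf, 2L, mu)
    s <- svd(xc, nu = n_components, nv = n_components)
    d <- s$d[seq_len(n_components)]
    rec <- s$u %*% (d * t(s$v))
    rec <- sweep(rec, 2L, mu, `+`)
    delta <- max(abs(rec[miss] - xf[miss]))
    xf[miss] <- rec[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  attr(xf, "iterations") <- it
  attr(xf, "converged") <- converged
  xf
}

#' Euclidean distance matrix
#'
#' Plain Euclidean distances between rows. Missing cells are refused:
#' impute first (see [impute_missing()]).
#'
#' @param x Complete numeric matrix or data frame.
#' @return A `stats::dist` object.
#' @export
euclidean_distances <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) {
    stop("x contains missing values; run impute_missing() first",
         call. = FALSE)
  }
  stats::dist(x, method = "euclidean")
}

# Principal-coordinates start padded to k columns (degenerate
# configurations can yield fewer informative axes).
.pcoa_start <- function(d, k) {
  y <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(y) < k) y <- cbind(y, matrix(0, nrow(y), k - ncol(y)))
  # monoMDS rejects exactly-degenerate starts in rare cases; a tiny
  # deterministic perturbation on a zero column keeps it usable.
  for (j in seq_len(ncol(y))) {
    if (all(y[, j] == 0)) y[, j] <- 1e-8 * seq_len(nrow(y))
  }
  y
}

#' Non-metric multidimensional scaling with Kruskal stress-1
#'
#' Multi-start NMDS on a dissimilarity matrix: one deterministic
#' principal-coordinates start plus `n_starts - 1` seeded random
#' starts, each optimized by `vegan::monoMDS` (global nonmetric model,
#' monotone regression with primary tie treatment, stress-1
#' `sqrt(sum((dhat - d)^2) / sum(d^2))`). The lowest-stress solution
#' is returned, centered and rotated to its principal axes. Identical
#' seeds give identical results, and the seeded start sequence is
#' nested: raising `n_starts` can only add candidate starts.
#'
#' @param d A `dist` object or symmetric distance matrix (at least 4
#'   points, not all zero).
#' @param k Target dimension (default 2).
#' @param n_starts Total number of starts including the
#'   principal-coordinates start (default 100).
#' @param seed Integer seed for the random starts.
#' @param tol Relative stress-improvement tolerance terminating the
#'   inner optimization.
#' @param max_iter Inner iteration cap per start.
#' @return An object of class `nmds_fit`: `points` (n x k), `stress`,
#'   `start_stress` (stress of the principal-coordinates start before
#'   optimization), `best_start_index`, `n_starts`, `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 100, seed = 1, tol = 1e-7,
                 max_iter = 300) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (anyNA(d)) stop("distances contain missing values", call. = FALSE)
  if (n < 4L) stop("need at least 4 points for NMDS", call. = FALSE)
  if (all(d == 0)) stop("all distances are zero; configuration is degenerate",
                        call. = FALSE)
  if (n_starts < 1L) stop("n_starts must be at least 1", call. = FALSE)

  init <- .pcoa_start(d, k)
  start_stress <- vegan::monoMDS(d, y = init, k = k, model = "global",
                                 maxit = 0)$stress
  best <- NULL
  best_i <- NA_integer_
  for (i in seq_len(n_starts)) {
    y0 <- if (i == 1L) {
      init
    } else {
      .with_seed(.substream_seed(seed, paste0("nmds_start:", i)),
                 matrix(stats::runif(n * k, -1, 1), n, k))
    }
    fit <- vegan::monoMDS(d, y = y0, k = k, model = "global",
                          maxit = max_iter, sratmax = 1 - tol)
    if (is.null(best) || fit$stress < best$stress) {
      best <- fit
      best_i <- i
    }
  }
  pts <- scale(best$points, scale = FALSE)
  sv <- svd(pts)
  pts <- pts %*% sv$v
  dimnames(pts) <- list(labels(d) %||% seq_len(n),
                        paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = best$stress,
                 start_stress = start_stress,
                 best_start_index = best_i, n_starts = n_starts,
                 converged = best$iters < max_iter,
                 k = k, seed = seed),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("Non-metric MDS (k = %d): stress-1 = %.4f (%s)\n",
              x$k, x$stress, classify_stress(x$stress)))
  cat(sprintf("  best of %d starts (start %d); PCoA start stress %.4f\n",
              x$n_starts, x$best_start_index, x$start_stress))
  invisible(x)
}

#' @export
plot.nmds_fit <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$points[, 1], x$points[, 2], col = col,
                 xlab = "NMDS1", ylab = "NMDS2", asp = 1, ...)
  if (!is.null(groups)) {
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 1)
  }
  invisible(x)
}

#' Classify an NMDS stress value
#'
#' The conventional rule: stress below 0.2 is an acceptable
#' representation, at or above 0.2 it is poor.
#'
#' @param stress Nonnegative stress-1 value.
#' @return `"acceptable"` or `"poor"`.
#' @export
#' @examples
#' classify_stress(0.1488)
classify_stress <- function(stress) {
  if (any(!is.finite(stress)) || any(stress < 0)) {
    stop("stress must be nonnegative", call. = FALSE)
  }
  ifelse(stress < 0.2, "acceptable", "poor")
}

#' Wide feature matrix for ordination
#'
#' Pivots long biomarker records (and optionally viability records)
#' into one row per (subject, biological matrix) observation with one
#' column per measured variable: the four enzymes/damage markers plus
#' the NR and TB viability percentages. Variables not measured in a
#' compartment are `NA` (e.g. enzymes in hemolymph), which is what
#' the imputation stage consumes.
#'
#' @param records A biomarker table.
#' @param viability Optional viability table.
#' @return A list with `values` (numeric matrix) and `meta` (data
#'   frame with `subject_id`, `matrix`, `treatment`, `day` per row).
#' @export
build_feature_matrix <- function(records, viability = NULL) {
  records <- as_biomarker_records(records)
  keys <- data.frame(subject_id = records$subject_id,
                     matrix = as.character(records$tissue),
                     treatment = as.character(records$treatment),
                     day = records$day, stringsAsFactors = FALSE)
  vals <- data.frame(variable = as.character(records$biomarker),
                     value = records$value, stringsAsFactors = FALSE)
  if (!is.null(viability)) {
    viability <- as_viability_records(viability)
    keys <- rbind(keys, data.frame(
      subject_id = viability$subject_id,
      matrix = as.character(viability$compartment),
      treatment = as.character(viability$treatment),
      day = viability$day, stringsAsFactors = FALSE))
    vals <- rbind(vals, data.frame(variable = as.character(viability$assay),
                                   value = viability$percent_viable,
                                   stringsAsFactors = FALSE))
  }
  rowkey <- paste(keys$subject_id, keys$matrix, keys$treatment, keys$day,
                  sep = "\r")
  meta <- keys[!duplicated(rowkey), , drop = FALSE]
  urow <- rowkey[!duplicated(rowkey)]
  variables <- c(.BIOMARKERS, if (!is.null(viability)) .ASSAYS)
  m <- matrix(NA_real_, nrow = length(urow), ncol = length(variables),
              dimnames = list(NULL, variables))
  ridx <- match(rowkey, urow)
  cidx <- match(vals$variable, variables)
  m[cbind(ridx, cidx)] <- vals$value
  rownames(meta) <- NULL
  list(values = m, meta = meta)
}
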
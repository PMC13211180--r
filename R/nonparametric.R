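# Kruskal-Wallis omnibus test (tie-corrected, chi-square reference
# distribution with an exact enumeration option for tiny samples) and
# Dunn's post hoc z tests on mean ranks, with the conventional
# significance-star bands.

.as_group_list <- function(x, g = NULL) {
  if (is.list(x) && is.null(g)) {
    groups <- lapply(x, as.numeric)
  } else {
    if (is.null(g)) stop("supply either a list of samples or x plus g", call. = FALSE)
    groups <- split(as.numeric(x), g, drop = TRUE)
  }
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop("every group must be nonempty", call. = FALSE)
  }
  if (any(!is.finite(unlist(groups)))) stop("values must be finite", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups
}

# Tie-corrected H for pooled ranks `r` split by sizes; returns 0 when
# every value is tied (correction denominator vanishes).
.kw_H <- function(r, sizes) {
  N <- length(r)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  rbar <- vapply(seq_along(sizes),
                 function(i) mean(r[starts[i]:ends[i]]), 0)
  H <- 12 / (N * (N + 1)) * sum(sizes * (rbar - (N + 1) / 2)^2)
  tie <- table(r)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C <= 0) return(0)
  H / C
}

# All distinct assignments of the pooled ranks to groups of the given
# sizes; returns the vector of H statistics over the exact
# permutation distribution.
.kw_perm_H <- function(r, sizes) {
  out <- numeric(0)
  rec <- function(avail, gi, acc) {
    if (gi == length(sizes)) {
      out[[length(out) + 1L]] <<- .kw_H(c(acc, avail), sizes)
      return(invisible())
    }
    picks <- utils::combn(length(avail), sizes[gi], simplify = FALSE)
    for (p in picks) rec(avail[-p], gi + 1L, c(acc, avail[p]))
  }
  rec(r, 1L, numeric(0))
  out
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Pooled midranks; `H = 12 / (N (N + 1)) * sum n_i (Rbar_i - (N+1)/2)^2`,
#' divided by the tie correction `1 - sum(t^3 - t) / (N^3 - N)`. The
#' p-value comes from the chi-square distribution with k - 1 degrees
#' of freedom, or, for `p_method = "exact"`, from exhaustive
#' enumeration of the permutation distribution (small samples only).
#' When every value is tied, H = 0 and p = 1.
#'
#' @param x A list of numeric samples, or a numeric vector.
#' @param g Grouping factor aligned with `x` when `x` is a vector.
#' @param p_method `"chisq"` (default) or `"exact"`.
#' @param exact_limit Maximum number of enumerated assignments allowed
#'   for the exact method.
#' @return An object of class `kw_test` with fields `statistic`, `df`,
#'   `p.value`, `n`, `sizes`, `tie_correction`, `p_method`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))) # H = 7.2
kruskal_wallis <- function(x, g = NULL, p_method = c("chisq", "exact"),
                           exact_limit = 2e5) {
  p_method <- match.arg(p_method)
  groups <- .as_group_list(x, g)
  sizes <- vapply(groups, length, 1L)
  N <- sum(sizes)
  if (N < 3L) stop("need at least 3 observations in total", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  r <- rank(pooled) # midranks
  H <- .kw_H(r, sizes)
  df <- length(groups) - 1L
  tie <- table(r)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)

  if (p_method == "exact") {
    n_assign <- exp(lfactorial(N) - sum(lfactorial(sizes)))
    if (n_assign > exact_limit) {
      stop(sprintf("exact enumeration would need %.0f assignments (limit %g)",
                   n_assign, exact_limit), call. = FALSE)
    }
    perm <- .kw_perm_H(r, sizes)
    p <- mean(perm >= H - 1e-9)
  } else {
    p <- if (C <= 0) 1 else stats::pchisq(H, df, lower.tail = FALSE)
  }
  structure(list(statistic = H, df = df, p.value = p, n = N,
                 sizes = sizes, tie_correction = C, p_method = p_method),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat("Kruskal-Wallis rank test (tie-corrected)\n")
  cat(sprintf("  H = %.5g, df = %d, p = %.5g (%s)\n",
              x$statistic, x$df, x$p.value, x$p_method))
  cat(sprintf("  N = %d, group sizes: %s\n", x$n,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' Strict bands: `***` for p < 0.001, `**` for p < 0.01, `*` for
#' p < 0.05, empty otherwise (so p = 0.05 earns no star).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of star strings.
#' @export
#' @examples
#' stars(c(0.03, 0.0005, 0.05))
stars <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Dunn's post hoc pairwise comparisons
#'
#' For every pair of groups, the standardized mean-rank difference
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 -
#' sum(t^3 - t) / (12 (N - 1))) (1/n_i + 1/n_j))` with two-sided
#' normal p-values, optional multiplicity adjustment over all
#' k (k - 1) / 2 pairs, and significance stars on the adjusted
#' p-values. The default is no adjustment; the choice is recorded in
#' the output.
#'
#' @inheritParams kruskal_wallis
#' @param adjustment `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return A data frame of class `dunn_test` with columns `group_i`,
#'   `group_j`, `z`, `p_raw`, `p_adj`, `stars`; the adjustment used is
#'   attached as attribute `adjustment`.
#' @export
dunn_posthoc <- function(x, g = NULL,
                         adjustment = c("none", "bonferroni", "holm")) {
  adjustment <- match.arg(adjustment)
  groups <- .as_group_list(x, g)
  sizes <- vapply(groups, length, 1L)
  N <- sum(sizes)
  if (N < 3L) stop("need at least 3 observations in total", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  r <- rank(pooled)
  ends <- cumsum(sizes); starts <- ends - sizes + 1L
  rbar <- vapply(seq_along(sizes), function(i) mean(r[starts[i]:ends[i]]), 0)
  tie <- table(r)
  sigma2 <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))

  pairs <- utils::combn(seq_along(groups), 2L)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt(sigma2 * (1 / sizes[i] + 1 / sizes[j]))
    z[k] <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p_raw[k] <- if (se == 0) 1 else 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- stats::p.adjust(p_raw, method = adjustment,
                           n = length(p_raw))
  out <- data.frame(group_i = names(groups)[pairs[1L, ]],
                    group_j = names(groups)[pairs[2L, ]],
                    z = z, p_raw = p_raw, p_adj = p_adj,
                    stars = stars(p_adj), stringsAsFactors = FALSE)
  attr(out, "adjustment") <- adjustment
  class(out) <- c("dunn_test", "data.frame")
  out
}

#' @export
print.dunn_test <- function(x, digits = 4, ...) {
  cat(sprintf("Dunn's post hoc comparisons (adjustment: %s)\n",
              attr(x, "adjustment")))
  y <- as.data.frame(x)
  y$z <- round(y$z, digits); y$p_raw <- signif(y$p_raw, digits)
  y$p_adj <- signif(y$p_adj, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
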
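# Factorial linear model on z-scored responses with Treatment, Day,
# Matrix and Biomarker as fixed factors and the Treatment x Day,
# Treatment x Biomarker and Treatment x Day x Biomarker interactions,
# tested by Type III (marginal) ANOVA under sum-to-zero contrasts.

#' Default factorial model formula
#'
#' Main effects for Treatment, Day, Matrix and Biomarker plus the
#' Treatment:Day, Treatment:Biomarker and Treatment:Day:Biomarker
#' interactions — the terms capturing biomarker-specific temporal
#' dose responses. Pass `full_factorial = TRUE` for all interactions
#' among Treatment, Day and Biomarker.
#'
#' @param full_factorial Include every interaction of Treatment, Day
#'   and Biomarker (default `FALSE`).
#' @return A formula with response `value`.
#' @export
ibrt_model_formula <- function(full_factorial = FALSE) {
  if (full_factorial) {
    value ~ Matrix + Treatment * Day * Biomarker
  } else {
    value ~ Treatment + Day + Matrix + Biomarker +
      Treatment:Day + Treatment:Biomarker + Treatment:Day:Biomarker
  }
}

#' Assemble the model dataset from biomarker and viability records
#'
#' Stacks enzyme/damage measurements (Matrix = tissue, Biomarker =
#' measured variable) and, when supplied, viability percentages
#' (Matrix = compartment, Biomarker = "viability", NR and TB pooled)
#' into one long response table, then z-scores the response within
#' each Biomarker level so all variables enter on a comparable scale.
#'
#' @param records A biomarker table.
#' @param viability Optional viability table; adds hemolymph (and
#'   hepatopancreas) rows under the extra Biomarker level
#'   `"viability"`.
#' @return A data frame with factors `Treatment`, `Day`, `Matrix`,
#'   `Biomarker`, the z-scored `value`, and `raw` (original scale).
#' @export
assemble_model_data <- function(records, viability = NULL) {
  records <- as_biomarker_records(records)
  dat <- data.frame(Treatment = as.character(records$treatment),
                    Day = as.character(records$day),
                    Matrix = as.character(records$tissue),
                    Biomarker = as.character(records$biomarker),
                    raw = records$value, stringsAsFactors = FALSE)
  biom_levels <- .BIOMARKERS
  matrix_levels <- .TISSUES
  if (!is.null(viability)) {
    viability <- as_viability_records(viability)
    dat <- rbind(dat, data.frame(
      Treatment = as.character(viability$treatment),
      Day = as.character(viability$day),
      Matrix = as.character(viability$compartment),
      Biomarker = "viability",
      raw = viability$percent_viable, stringsAsFactors = FALSE))
    biom_levels <- c(biom_levels, "viability")
    matrix_levels <- unique(c(matrix_levels, "hemolymph"))
  }
  dat$Treatment <- factor(dat$Treatment, levels = .TREATMENTS)
  dat$Day <- factor(dat$Day, levels = as.character(.DAYS))
  dat$Matrix <- factor(dat$Matrix, levels = sort(matrix_levels))
  dat$Biomarker <- factor(dat$Biomarker, levels = biom_levels)
  dat$value <- NA_real_
  for (b in levels(dat$Biomarker)) {
    i <- dat$Biomarker == b
    if (!any(i)) next
    v <- dat$raw[i]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) stop(sprintf(
      "biomarker level %s has zero variance; cannot z-score", b), call. = FALSE)
    dat$value[i] <- (v - mean(v)) / s
  }
  droplevels(dat)
}

#' Build a sum-to-zero design matrix
#'
#' Encodes every factor with deviation (sum-to-zero) contrasts and
#' assembles interaction columns as elementwise products of the
#' constituent contrast columns, so a term for factors with
#' `l_1, ..., l_m` levels always spans `prod(l_j - 1)` columns —
#' including when a lower-order margin (such as Day:Biomarker in the
#' default model) is deliberately excluded. Treatment (dummy) coding
#' is refused: Type III marginal sums of squares are only meaningful
#' under contrasts orthogonal to the intercept, and silently
#' accepting another coding would produce wrong answers.
#'
#' @param data Model dataset (see [assemble_model_data()]).
#' @param formula Model formula (default [ibrt_model_formula()]);
#'   every right-hand-side variable must be a factor.
#' @param contrasts Must be `"contr.sum"`.
#' @return A list with `X` (design matrix), `assign` (term index per
#'   column, 0 = intercept), `term_labels`, `terms`, and `response`.
#' @export
build_design <- function(data, formula = ibrt_model_formula(),
                         contrasts = "contr.sum") {
  if (!identical(contrasts, "contr.sum")) {
    stop("Type III tests require sum-to-zero contrasts; refusing '",
         contrasts, "' (see ?type3_anova)", call. = FALSE)
  }
  mf <- stats::model.frame(formula, data)
  tt <- attr(mf, "terms")
  labels <- attr(tt, "term.labels")
  vars <- attr(tt, "factors")
  rhs_vars <- rownames(vars)[rowSums(vars != 0) > 0]
  for (v in rhs_vars) {
    if (!is.factor(mf[[v]])) {
      stop(sprintf("model variable %s must be a factor", v), call. = FALSE)
    }
    counts <- table(mf[[v]])
    if (any(counts == 0L)) {
      stop(sprintf("factor %s has unobserved level(s): %s", v,
                   paste(names(counts)[counts == 0L], collapse = ", ")),
           call. = FALSE)
    }
  }
  # per-factor sum-coded columns, expanded to observations
  coded <- lapply(stats::setNames(nm = rhs_vars), function(v) {
    f <- mf[[v]]
    C <- stats::contr.sum(nlevels(f))
    colnames(C) <- paste0(v, seq_len(ncol(C)))
    C[as.integer(f), , drop = FALSE]
  })
  n <- nrow(mf)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  assign <- 0L
  for (t in seq_along(labels)) {
    parts <- rhs_vars[vars[rhs_vars, t] != 0]
    block <- coded[[parts[1L]]]
    if (length(parts) > 1L) {
      for (p in parts[-1L]) {
        B <- coded[[p]]
        block <- do.call(cbind, lapply(seq_len(ncol(B)), function(j) {
          out <- block * B[, j]
          colnames(out) <- paste(colnames(block), colnames(B)[j], sep = ":")
          out
        }))
      }
    }
    X <- cbind(X, block)
    assign <- c(assign, rep(t, ncol(block)))
  }
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient for this formula and dataset",
         call. = FALSE)
  }
  list(X = X, assign = assign, term_labels = labels, terms = tt,
       response = stats::model.response(mf))
}

#' Ordinary least squares on an explicit design matrix
#'
#' Thin wrapper over `stats::lm.fit` returning the pieces the ANOVA
#' routines need; rejects rank-deficient designs.
#'
#' @param X Full-column-rank design matrix.
#' @param y Response vector.
#' @return A list with `coefficients`, `fitted`, `residuals`, `rss`,
#'   `rank`, `df_residual`.
#' @export
fit_least_squares <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y dimensions differ", call. = FALSE)
  z <- stats::lm.fit(X, y)
  if (z$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  list(coefficients = z$coefficients, fitted = z$fitted.values,
       residuals = z$residuals, rss = sum(z$residuals^2),
       rank = z$rank, df_residual = length(y) - z$rank)
}

#' Type III (marginal) ANOVA under sum-to-zero contrasts
#'
#' For every term, the model is refit with that term's columns
#' removed while all other terms (including any interactions
#' containing it) are retained; the term's sum of squares is the
#' resulting increase in residual sum of squares, and
#' `F = (SS / df_term) / (RSS_full / df_residual)` is referred to the
#' F distribution. Under sum-to-zero coding this is the classical
#' Type III test, invariant to the order in which terms are listed.
#'
#' @inheritParams build_design
#' @return An object of class `anova_type3`: a data frame with one
#'   row per term (`term`, `df`, `sum_sq`, `statistic`, `p_value`)
#'   and attributes `df_residual`, `rss`, `contrasts`.
#' @export
type3_anova <- function(data, formula = ibrt_model_formula(),
                        contrasts = "contr.sum") {
  bd <- build_design(data, formula, contrasts)
  full <- fit_least_squares(bd$X, bd$response)
  dfres <- full$df_residual
  if (dfres <= 0) stop("no residual degrees of freedom", call. = FALSE)
  ms_res <- full$rss / dfres

  nterm <- length(bd$term_labels)
  out <- data.frame(term = bd$term_labels, df = NA_integer_,
                    sum_sq = NA_real_, statistic = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  for (t in seq_len(nterm)) {
    keep <- bd$assign != t
    red <- stats::lm.fit(bd$X[, keep, drop = FALSE], bd$response)
    ss <- sum(red$residuals^2) - full$rss
    df_t <- sum(bd$assign == t)
    f <- (ss / df_t) / ms_res
    out$df[t] <- df_t
    out$sum_sq[t] <- ss
    out$statistic[t] <- f
    out$p_value[t] <- stats::pf(f, df_t, dfres, lower.tail = FALSE)
  }
  attr(out, "df_residual") <- dfres
  attr(out, "rss") <- full$rss
  attr(out, "contrasts") <- "contr.sum"
  class(out) <- c("anova_type3", "data.frame")
  out
}

#' @export
print.anova_type3 <- function(x, digits = 4, ...) {
  cat("Type III ANOVA (sum-to-zero contrasts)\n")
  y <- as.data.frame(x)
  y$sum_sq <- signif(y$sum_sq, digits)
  y$statistic <- signif(y$statistic, digits)
  y$p_value <- signif(y$p_value, digits)
  names(y) <- c("term", "df", "Sum Sq", "F", "Pr(>F)")
  print(y, row.names = FALSE)
  cat(sprintf("Residual df: %d, RSS: %.6g\n",
              attr(x, "df_residual"), attr(x, "rss")))
  invisible(x)
}
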
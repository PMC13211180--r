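# Threshold-based Integrative Biomarker Response (IBR-T). Within each
# (tissue, day) stratum: the control group defines, per biomarker, a
# reference (median) and a threshold (95th percentile); each
# treatment's log-ratio of its mean to the reference is standardized
# by the SD of the log-ratios across treatments; the IBR-T score of a
# treatment is the mean absolute standardized log-ratio over the
# biomarkers whose mean exceeds the threshold (induced biomarkers),
# or 0 when none does.

#' Control reference and threshold for one biomarker sample
#'
#' Reference = median, threshold = 95th percentile, both via linear
#' interpolation on order statistics (position `h = (n - 1) p + 1`,
#' i.e. `stats::quantile` type 7).
#'
#' @param control_values Numeric vector of at least 2 positive control
#'   measurements.
#' @param threshold_prob Upper percentile defining the induction
#'   threshold (default 0.95).
#' @return A list with elements `reference` and `threshold`.
#' @export
#' @examples
#' control_reference(1:20) # reference 10.5, threshold 19.05
control_reference <- function(control_values, threshold_prob = 0.95) {
  x <- as.numeric(control_values)
  if (length(x) < 2L || any(!is.finite(x))) {
    stop("need at least 2 finite control values", call. = FALSE)
  }
  if (any(x <= 0)) stop("control values must be strictly positive", call. = FALSE)
  list(reference = unname(stats::median(x)),
       threshold = unname(stats::quantile(x, threshold_prob, type = 7)))
}

#' Standardized log-ratios of treatment means against a control reference
#'
#' For each treatment mean `m_t`, computes `L_t = ln(m_t / reference)`,
#' standardizes by the sample SD of `L` across all treatments
#' (including the control), and flags inclusion where the mean
#' strictly exceeds the threshold. If the SD is zero (all log-ratios
#' equal), every `z` is set to 0 by convention.
#'
#' @param group_means Named numeric vector of per-treatment means
#'   (length at least 2, all positive).
#' @param reference Control reference value (median).
#' @param threshold Control threshold value (95th percentile).
#' @param two_sided If `TRUE`, means falling below the symmetric lower
#'   control percentile also count as responding. Off by default:
#'   only upward exceedance is "induced".
#' @param lower_threshold Lower-tail threshold used when
#'   `two_sided = TRUE`.
#' @return A data frame with columns `treatment`, `mean`, `log_ratio`,
#'   `z`, `included`.
#' @export
standardized_log_ratios <- function(group_means, reference, threshold,
                                    two_sided = FALSE, lower_threshold = NULL) {
  m <- as.numeric(group_means)
  if (length(m) < 2L) stop("need means for at least 2 treatments", call. = FALSE)
  if (any(!is.finite(m)) || any(m <= 0)) {
    bad <- names(group_means)[!is.finite(m) | m <= 0]
    stop("nonpositive treatment mean(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.finite(reference) || reference <= 0) {
    stop("reference must be positive", call. = FALSE)
  }
  L <- log(m / reference)
  sd_L <- stats::sd(L)
  z <- if (sd_L == 0) rep(0, length(L)) else L / sd_L
  included <- m > threshold
  if (isTRUE(two_sided)) {
    if (is.null(lower_threshold)) {
      stop("two_sided = TRUE requires lower_threshold", call. = FALSE)
    }
    included <- included | m < lower_threshold
  }
  data.frame(treatment = if (is.null(names(group_means)))
               as.character(seq_along(m)) else names(group_means),
             mean = m, log_ratio = L, z = z, included = included,
             stringsAsFactors = FALSE)
}

#' IBR-T score from standardized log-ratios and inclusion flags
#'
#' Mean of `|z|` over included biomarkers; 0 when none is included.
#'
#' @param z Numeric vector of standardized log-ratios, one per
#'   biomarker.
#' @param included Logical vector aligned with `z`.
#' @return The nonnegative IBR-T score.
#' @export
ibrt_score <- function(z, included) {
  if (length(z) != length(included)) {
    stop("z and included must have the same length", call. = FALSE)
  }
  if (!any(included)) return(0)
  mean(abs(z[included]))
}

#' Compute the IBR-T index for a biomarker table
#'
#' Runs the full construction per (tissue, day) stratum: group means,
#' control reference/threshold per biomarker, standardized log-ratios
#' across treatments, and per-treatment scores. The control's own
#' score is reported too (expected near 0: its mean rarely exceeds
#' its own 95th percentile).
#'
#' @param records A biomarker table accepted by
#'   [as_biomarker_records()]. Every (tissue, day) stratum must
#'   contain the control, with at least 2 control values per
#'   biomarker.
#' @param threshold_prob Control percentile defining induction
#'   (default 0.95).
#' @param pool_days If `TRUE`, reference and threshold are computed
#'   from controls pooled over both sampling days; by default each
#'   day's stratum uses its own-day control, matching per-day
#'   reporting.
#' @param two_sided Also count suppression below the symmetric lower
#'   control percentile (default `FALSE`).
#' @return An object of class `ibrt`: a list with `scores` (one row
#'   per tissue, day, treatment), `details` (one row per tissue, day,
#'   treatment, biomarker) and `settings`.
#' @export
compute_ibrt <- function(records, threshold_prob = 0.95, pool_days = FALSE,
                         two_sided = FALSE) {
  records <- as_biomarker_records(records)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)

  strata <- unique(records[c("tissue", "day")])
  strata <- strata[order(strata$tissue, strata$day), ]
  details <- list()
  for (s in seq_len(nrow(strata))) {
    ti <- strata$tissue[s]; dy <- strata$day[s]
    sub <- records[records$tissue == ti & records$day == dy, ]
    ctrl_pool <- if (pool_days) {
      records[records$tissue == ti & records$treatment == "CTRL", ]
    } else {
      sub[sub$treatment == "CTRL", ]
    }
    if (nrow(ctrl_pool) == 0L) {
      stop(sprintf("no control group in stratum (%s, day %d)", ti, dy),
           call. = FALSE)
    }
    for (bm in levels(droplevels(sub$biomarker))) {
      cv <- ctrl_pool$value[ctrl_pool$biomarker == bm]
      if (length(cv) < 2L) {
        stop(sprintf("fewer than 2 control values for %s in stratum (%s, day %d)",
                     bm, ti, dy), call. = FALSE)
      }
      ref <- control_reference(cv, threshold_prob)
      lower <- if (two_sided) {
        unname(stats::quantile(cv, 1 - threshold_prob, type = 7))
      } else NULL
      grp <- sub[sub$biomarker == bm, ]
      means <- tapply(grp$value, droplevels(grp$treatment), mean)
      slr <- standardized_log_ratios(means, ref$reference, ref$threshold,
                                     two_sided = two_sided,
                                     lower_threshold = lower)
      slr$tissue <- ti; slr$day <- dy; slr$biomarker <- bm
      slr$reference <- ref$reference; slr$threshold <- ref$threshold
      details[[length(details) + 1L]] <- slr
    }
  }
  details <- do.call(rbind, details)
  details <- details[c("tissue", "day", "treatment", "biomarker", "mean",
                       "reference", "threshold", "log_ratio", "z", "included")]

  key <- list(tissue = details$tissue, day = details$day,
              treatment = details$treatment)
  idx <- split(seq_len(nrow(details)), key, drop = TRUE)
  scores <- do.call(rbind, lapply(idx, function(i) {
    data.frame(tissue = details$tissue[i[1L]], day = details$day[i[1L]],
               treatment = details$treatment[i[1L]],
               n_included = sum(details$included[i]),
               score = ibrt_score(details$z[i], details$included[i]),
               stringsAsFactors = FALSE)
  }))
  tr_order <- match(scores$treatment, .TREATMENTS)
  scores <- scores[order(scores$tissue, scores$day, tr_order), ]
  rownames(scores) <- NULL
  rownames(details) <- NULL

  structure(list(scores = scores, details = details,
                 settings = list(threshold_prob = threshold_prob,
                                 pool_days = pool_days,
                                 two_sided = two_sided,
                                 log_base = "natural",
                                 sd_across = "treatment log-ratios (n-1)")),
            class = "ibrt")
}

#' @export
print.ibrt <- function(x, digits = 3, ...) {
  cat("Threshold-based Integrative Biomarker Response (IBR-T)\n")
  cat(sprintf("  induction threshold: control %.0fth percentile%s\n",
              100 * x$settings$threshold_prob,
              if (x$settings$two_sided) " (two-sided)" else ""))
  sc <- x$scores
  sc$score <- round(sc$score, digits)
  print(sc, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ibrt <- function(x, ...) {
  sc <- x$scores
  strata <- unique(sc[c("tissue", "day")])
  lab <- sprintf("%s d%d", substr(strata$tissue, 1, 4), strata$day)
  mat <- sapply(seq_len(nrow(strata)), function(i) {
    s <- sc[sc$tissue == strata$tissue[i] & sc$day == strata$day[i], ]
    s$score[match(.TREATMENTS, s$treatment)]
  })
  graphics::barplot(mat, beside = TRUE, names.arg = lab,
                    legend.text = .TREATMENTS, ylab = "IBR-T score",
                    las = 2, ...)
  invisible(x)
}
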
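# Independent oracles and fixture builders. These re-derive results
# by straight-line code paths separate from the package internals.

# Order-statistic quantile by direct interpolation (h = (n-1)p + 1),
# written without stats::quantile.
q_interp <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Build a long biomarker table from a value function of
# (tissue, treatment, day, biomarker, subject index).
make_records <- function(value_fun,
                         tissues = c("gills", "hepatopancreas", "muscle"),
                         treatments = c("CTRL", "C1", "C2", "C3"),
                         days = 10L,
                         biomarkers = c("SOD", "GPx", "GST", "MDA"),
                         n = 5L) {
  units <- c(SOD = "U mg-1 protein", GPx = "nmol (mg.min)-1",
             GST = "nmol (ug.min)-1", MDA = "umol mg-1 protein")
  rows <- list()
  for (ti in tissues) for (tr in treatments) for (dy in days)
    for (bm in biomarkers) for (i in seq_len(n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("%s_d%02d_%02d", tr, dy, i),
        tissue = ti, treatment = tr, day = dy, biomarker = bm,
        value = value_fun(ti, tr, dy, bm, i), unit = units[[bm]],
        stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}

# Straight-line IBR-T re-derivation: explicit loops, manual
# median/percentile, manual sample SD. Per (tissue, day) stratum.
oracle_ibrt <- function(df) {
  out <- list()
  trt_order <- c("CTRL", "C1", "C2", "C3")
  for (ti in unique(as.character(df$tissue))) {
    for (dy in unique(df$day)) {
      sub <- df[as.character(df$tissue) == ti & df$day == dy, ]
      trs <- intersect(trt_order, unique(as.character(sub$treatment)))
      bms <- unique(as.character(sub$biomarker))
      zs <- matrix(NA_real_, length(trs), length(bms),
                   dimnames = list(trs, bms))
      inc <- zs == 0
      for (bm in bms) {
        ctrl <- sub$value[as.character(sub$treatment) == "CTRL" &
                          as.character(sub$biomarker) == bm]
        ref <- q_interp(ctrl, 0.5)
        thr <- q_interp(ctrl, 0.95)
        means <- vapply(trs, function(tr) {
          mean(sub$value[as.character(sub$treatment) == tr &
                         as.character(sub$biomarker) == bm])
        }, 0)
        L <- log(means / ref)
        s <- sqrt(sum((L - mean(L))^2) / (length(L) - 1))
        zs[, bm] <- if (s == 0) 0 else L / s
        inc[, bm] <- means > thr
      }
      for (tr in trs) {
        sc <- if (any(inc[tr, ])) mean(abs(zs[tr, inc[tr, ]])) else 0
        out[[length(out) + 1L]] <- data.frame(
          tissue = ti, day = dy, treatment = tr, score = sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# Tie-corrected Kruskal-Wallis H computed independently (formula
# transcription, no shared helpers).
oracle_kw_H <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  sizes <- vapply(groups, length, 1L)
  ends <- cumsum(sizes)
  H <- 0
  for (i in seq_along(groups)) {
    ri <- r[(ends[i] - sizes[i] + 1):ends[i]]
    H <- H + sizes[i] * (mean(ri) - (N + 1) / 2)^2
  }
  H <- H * 12 / (N * (N + 1))
  tie <- table(r)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# Monte-Carlo permutation p for the KW statistic.
mc_perm_p <- function(groups, B = 20000) {
  sizes <- vapply(groups, length, 1L)
  pooled <- unlist(groups)
  H_obs <- oracle_kw_H(groups)
  hits <- 0L
  for (b in seq_len(B)) {
    shuf <- sample(pooled)
    gs <- split(shuf, rep(seq_along(sizes), sizes))
    if (oracle_kw_H(gs) >= H_obs - 1e-9) hits <- hits + 1L
  }
  hits / B
}

# Small balanced dataset builder: full factorial grid with n
# replicates and a response assembled from known effects plus noise.
balanced_data <- function(n = 3, seed = 1, trt_eff = c(0, 0, 0, 0),
                          day_eff = c(0, 0), noise = 1) {
  g <- expand.grid(Treatment = c("CTRL", "C1", "C2", "C3"),
                   Day = c("10", "20"),
                   Biomarker = c("SOD", "GPx", "MDA"),
                   rep = seq_len(n), stringsAsFactors = FALSE)
  g$Treatment <- factor(g$Treatment, levels = c("CTRL", "C1", "C2", "C3"))
  g$Day <- factor(g$Day, levels = c("10", "20"))
  g$Biomarker <- factor(g$Biomarker)
  set.seed(seed)
  g$value <- trt_eff[as.integer(g$Treatment)] +
    day_eff[as.integer(g$Day)] + rnorm(nrow(g), sd = noise)
  g
}
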
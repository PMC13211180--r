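# End-to-end orchestration: generate (or read) -> summarize -> rank
# tests -> IBR-T -> NMDS -> Type III ANOVA, seeded throughout,
# writing plain-text artifacts plus a manifest with per-artifact
# checksums so identical config + seed gives bit-identical output.

#' Pipeline configuration
#'
#' Bundles the inputs and settings of one full analysis run. Either
#' generator configs (the default) or paths to existing CSV tables
#' drive the input stage; the single `seed` governs every source of
#' randomness downstream.
#'
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory for artifacts.
#' @param effects [effect_config()] for the synthetic biomarker study
#'   (its own seed is overridden by `seed`).
#' @param viability [viability_config()] for synthetic viability.
#' @param biomarker_file,viability_file Optional CSV paths; when set,
#'   the generator is skipped and these are read instead.
#' @param adjustment Multiplicity adjustment for Dunn's test.
#' @param nmds_starts,nmds_k NMDS start count and dimension.
#' @param impute_rank Rank of the missing-value imputation.
#' @param stages Named logical vector switching stages on/off; the
#'   names are `tests`, `ibrt`, `nmds`, `anova`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = file.path(tempdir(), "ibrtox_run"),
                            effects = effect_config(),
                            viability = viability_config(),
                            biomarker_file = NULL, viability_file = NULL,
                            adjustment = "none",
                            nmds_starts = 100L, nmds_k = 2L,
                            impute_rank = 2L,
                            stages = c(tests = TRUE, ibrt = TRUE,
                                       nmds = TRUE, anova = TRUE)) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 effects = effects, viability = viability,
                 biomarker_file = biomarker_file,
                 viability_file = viability_file,
                 adjustment = adjustment,
                 nmds_starts = as.integer(nmds_starts),
                 nmds_k = as.integer(nmds_k),
                 impute_rank = as.integer(impute_rank),
                 stages = stages),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  message(sprintf("[%s] start", name))
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done", name))
  res
}

.write_csv <- function(x, path) {
  utils::write.table(x, path, sep = ",", row.names = FALSE, quote = TRUE)
  path
}

# Rank tests over every stratum: biomarkers grouped by treatment
# within (tissue, day, biomarker), viability within
# (compartment, assay, day).
.run_rank_tests <- function(bio, viab, adjustment) {
  kw_rows <- list(); dunn_rows <- list()
  add <- function(scope, where, assay, day, biomarker, values, groups) {
    groups <- droplevels(groups)
    if (nlevels(groups) < 2L) return(invisible())
    kw <- kruskal_wallis(values, groups)
    kw_rows[[length(kw_rows) + 1L]] <<- data.frame(
      scope = scope, where = where, assay = assay, day = day,
      biomarker = biomarker, H = kw$statistic, df = kw$df,
      p = kw$p.value, n = kw$n, stringsAsFactors = FALSE)
    dn <- dunn_posthoc(values, groups, adjustment = adjustment)
    dn <- cbind(data.frame(scope = scope, where = where, assay = assay,
                           day = day, biomarker = biomarker,
                           stringsAsFactors = FALSE),
                as.data.frame(dn))
    dunn_rows[[length(dunn_rows) + 1L]] <<- dn
  }
  for (ti in levels(droplevels(bio$tissue))) {
    for (dy in unique(bio$day)) {
      for (bm in levels(droplevels(bio$biomarker))) {
        i <- bio$tissue == ti & bio$day == dy & bio$biomarker == bm
        if (!any(i)) next
        add("biomarker", ti, NA_character_, dy, bm,
            bio$value[i], bio$treatment[i])
      }
    }
  }
  if (!is.null(viab)) {
    for (cp in levels(droplevels(viab$compartment))) {
      for (a in levels(droplevels(viab$assay))) {
        for (dy in unique(viab$day)) {
          i <- viab$compartment == cp & viab$assay == a & viab$day == dy
          if (!any(i)) next
          add("viability", cp, a, dy, NA_character_,
              viab$percent_viable[i], viab$treatment[i])
        }
      }
    }
  }
  list(kw = do.call(rbind, kw_rows), dunn = do.call(rbind, dunn_rows))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writes one plain-text
#' artifact per stage under `config$out_dir`, and finishes with
#' `manifest.json` recording the package version, seed, settings and
#' an MD5 checksum per artifact. Reruns with the same config and seed
#' reproduce every artifact bit-identically.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `manifest` (the parsed manifest) and
#'   `results` (in-memory stage results).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config object", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  results <- list()

  inputs <- .stage("input", {
    if (!is.null(config$biomarker_file)) {
      bio <- read_biomarker_table(config$biomarker_file)
      viab <- if (!is.null(config$viability_file)) {
        read_viability_table(config$viability_file)
      }
    } else {
      eff <- config$effects
      eff$seed <- config$seed
      bio <- generate_study(eff)
      viab <- generate_viability(config$viability, seed = config$seed)
    }
    list(bio = bio, viab = viab)
  })
  paths["biomarkers"] <- write_biomarker_table(
    inputs$bio, file.path(config$out_dir, "biomarkers.csv"))
  if (!is.null(inputs$viab)) {
    paths["viability"] <- write_viability_table(
      inputs$viab, file.path(config$out_dir, "viability.csv"))
  }

  results$summaries <- .stage("summarize", summarize_groups(inputs$bio))
  paths["group_summaries"] <- .write_csv(
    local({x <- results$summaries
           for (nm in c("tissue", "treatment", "biomarker"))
             x[[nm]] <- as.character(x[[nm]]); x}),
    file.path(config$out_dir, "group_summaries.csv"))

  if (isTRUE(config$stages[["tests"]])) {
    results$tests <- .stage("tests",
      .run_rank_tests(inputs$bio, inputs$viab, config$adjustment))
    paths["kw_tests"] <- .write_csv(results$tests$kw,
      file.path(config$out_dir, "kw_tests.csv"))
    paths["dunn_pairs"] <- .write_csv(results$tests$dunn,
      file.path(config$out_dir, "dunn_pairs.csv"))
  }

  if (isTRUE(config$stages[["ibrt"]])) {
    results$ibrt <- .stage("ibrt", compute_ibrt(inputs$bio))
    paths["ibrt_scores"] <- .write_csv(results$ibrt$scores,
      file.path(config$out_dir, "ibrt_scores.csv"))
    paths["ibrt_details"] <- .write_csv(results$ibrt$details,
      file.path(config$out_dir, "ibrt_details.csv"))
  }

  if (isTRUE(config$stages[["nmds"]])) {
    results$nmds <- .stage("nmds", {
      fm <- build_feature_matrix(inputs$bio, inputs$viab)
      filled <- impute_missing(fm$values, n_components = config$impute_rank)
      z <- zscore(filled)
      fit <- nmds(euclidean_distances(z), k = config$nmds_k,
                  n_starts = config$nmds_starts,
                  seed = .substream_seed(config$seed, "pipeline:nmds"))
      list(fit = fit, meta = fm$meta)
    })
    coords <- cbind(results$nmds$meta,
                    as.data.frame(results$nmds$fit$points))
    paths["nmds_coords"] <- .write_csv(coords,
      file.path(config$out_dir, "nmds_coords.csv"))
    nm <- results$nmds$fit
    jsonlite::write_json(
      list(stress = nm$stress, classification = classify_stress(nm$stress),
           k = nm$k, n_starts = nm$n_starts,
           best_start_index = nm$best_start_index,
           converged = nm$converged, impute_rank = config$impute_rank),
      file.path(config$out_dir, "nmds_report.json"),
      auto_unbox = TRUE, digits = NA)
    paths["nmds_report"] <- file.path(config$out_dir, "nmds_report.json")
  }

  if (isTRUE(config$stages[["anova"]])) {
    results$anova <- .stage("anova", {
      md <- assemble_model_data(inputs$bio, inputs$viab)
      type3_anova(md)
    })
    paths["anova"] <- .write_csv(as.data.frame(results$anova),
      file.path(config$out_dir, "anova.csv"))
  }

  manifest <- list(
    package = "ibrtox",
    version = as.character(utils::packageVersion("ibrtox")),
    seed = config$seed,
    settings = list(adjustment = config$adjustment,
                    nmds_starts = config$nmds_starts,
                    nmds_k = config$nmds_k,
                    impute_rank = config$impute_rank,
                    stages = as.list(config$stages),
                    effects = list(n_per_cell = config$effects$n_per_cell,
                                   baseline = config$effects$baseline,
                                   cv = config$effects$cv,
                                   dose_slope = config$effects$dose_slope,
                                   day_gain = config$effects$day_gain),
                    viability = config$viability$table),
    artifacts = lapply(stats::setNames(nm = names(paths)), function(k) {
      list(file = basename(paths[[k]]),
           md5 = unname(tools::md5sum(paths[[k]])))
    }))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("[manifest] written")
  invisible(list(manifest = manifest, paths = paths, results = results))
}
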
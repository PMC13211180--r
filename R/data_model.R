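# Canonical enumerations for the exposure design: 4 nominal PVA levels,
# two sampling days, three solid tissues (hemolymph appears only in the
# viability records) and the four oxidative-stress biomarkers.

.TISSUES      <- c("gills", "hepatopancreas", "muscle")
.TREATMENTS   <- c("CTRL", "C1", "C2", "C3")
.DOSES        <- c(CTRL = 0, C1 = 0.5, C2 = 5, C3 = 25) # mg L^-1
.DAYS         <- c(10L, 20L)
.BIOMARKERS   <- c("SOD", "GPx", "GST", "MDA")
.UNITS        <- c(SOD = "U mg-1 protein",
                   GPx = "nmol (mg.min)-1",
                   GST = "nmol (ug.min)-1",
                   MDA = "umol mg-1 protein")
.COMPARTMENTS <- c("hemolymph", "hepatopancreas")
.ASSAYS       <- c("NR", "TB")

#' Nominal exposure dose for a treatment label
#'
#' Maps the treatment codes `CTRL`, `C1`, `C2`, `C3` to their nominal
#' polyvinyl alcohol concentrations (0, 0.5, 5 and 25 mg per litre).
#'
#' @param treatment Character vector of treatment codes.
#' @return Numeric vector of doses in mg per litre.
#' @export
#' @examples
#' treatment_dose(c("CTRL", "C3"))
treatment_dose <- function(treatment) {
  bad <- !treatment %in% .TREATMENTS
  if (any(bad)) {
    stop("unknown treatment level(s): ",
         paste(unique(treatment[bad]), collapse = ", "), call. = FALSE)
  }
  unname(.DOSES[treatment])
}

#' Declared measurement unit for each biomarker
#'
#' @param biomarker Character vector of biomarker codes (`SOD`, `GPx`,
#'   `GST`, `MDA`). If missing, the full named unit map is returned.
#' @return Character vector of unit strings.
#' @export
biomarker_unit <- function(biomarker) {
  if (missing(biomarker)) return(.UNITS)
  bad <- !biomarker %in% .BIOMARKERS
  if (any(bad)) {
    stop("unknown biomarker(s): ",
         paste(unique(biomarker[bad]), collapse = ", "), call. = FALSE)
  }
  unname(.UNITS[biomarker])
}

# Shared row-indexed error helper: `bad` is a logical vector over rows.
.stop_rows <- function(bad, what) {
  idx <- which(bad)
  shown <- paste(utils::head(idx, 5L), collapse = ", ")
  if (length(idx) > 5L) shown <- paste0(shown, ", ...")
  stop(sprintf("row(s) %s: %s", shown, what), call. = FALSE)
}

.require_columns <- function(x, required) {
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

.parse_numeric <- function(x, dec = ".") {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  if (!identical(dec, ".")) x <- gsub(dec, ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Validate a long-format biomarker table
#'
#' Checks the schema and invariants of a long-format biomarker table
#' (one measurement per row) and returns it in canonical form: factor
#' columns with the fixed design levels, integer `day`, and a derived
#' `dose` column in mg per litre. The key
#' (tissue, treatment, day, biomarker, subject_id) must be unique,
#' values must be nonnegative, and the `unit` string must match the
#' declared unit of its biomarker.
#'
#' @param x A data frame with columns `subject_id`, `tissue`,
#'   `treatment`, `day`, `biomarker`, `value`, `unit`.
#' @param dec Decimal mark used if `value` arrives as character.
#' @return A validated data frame with an added `dose` column.
#' @export
as_biomarker_records <- function(x, dec = ".") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  .require_columns(x, c("subject_id", "tissue", "treatment", "day",
                        "biomarker", "value", "unit"))
  if (nrow(x) == 0L) {
    out <- data.frame(subject_id = character(), tissue = factor(levels = .TISSUES),
                      treatment = factor(levels = .TREATMENTS), day = integer(),
                      biomarker = factor(levels = .BIOMARKERS),
                      value = numeric(), unit = character(), dose = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }

  tissue <- as.character(x$tissue)
  treatment <- as.character(x$treatment)
  biomarker <- as.character(x$biomarker)
  unit <- as.character(x$unit)

  if (any(bad <- !tissue %in% .TISSUES)) .stop_rows(bad, "unknown tissue level")
  if (any(bad <- !treatment %in% .TREATMENTS)) .stop_rows(bad, "unknown treatment level")
  if (any(bad <- !biomarker %in% .BIOMARKERS)) .stop_rows(bad, "unknown biomarker level")

  day <- .parse_numeric(x$day, dec)
  if (any(bad <- is.na(day) | !(day %in% .DAYS))) {
    .stop_rows(bad, "day must be 10 or 20")
  }
  value <- .parse_numeric(x$value, dec)
  if (any(bad <- is.na(value) | !is.finite(value))) {
    .stop_rows(bad, "value is not a finite number")
  }
  if (any(bad <- value < 0)) .stop_rows(bad, "negative biomarker value")
  if (any(bad <- unit != .UNITS[biomarker])) {
    .stop_rows(bad, "unit does not match the declared unit of its biomarker")
  }

  out <- data.frame(
    subject_id = as.character(x$subject_id),
    tissue     = factor(tissue, levels = .TISSUES),
    treatment  = factor(treatment, levels = .TREATMENTS),
    day        = as.integer(day),
    biomarker  = factor(biomarker, levels = .BIOMARKERS),
    value      = value,
    unit       = unit,
    dose       = unname(.DOSES[treatment]),
    stringsAsFactors = FALSE
  )
  key <- paste(out$tissue, out$treatment, out$day, out$biomarker,
               out$subject_id, sep = "\r")
  if (any(bad <- duplicated(key))) {
    .stop_rows(bad, "duplicate (tissue, treatment, day, biomarker, subject_id) key")
  }
  rownames(out) <- NULL
  out
}

#' Validate a viability table
#'
#' Schema and range validation for cell-viability records (percent of
#' viable cells per subject, compartment and assay).
#'
#' @param x A data frame with columns `subject_id`, `compartment`,
#'   `assay`, `treatment`, `day`, `percent_viable`.
#' @param dec Decimal mark used if `percent_viable` arrives as character.
#' @return A validated data frame with canonical factor levels.
#' @export
as_viability_records <- function(x, dec = ".") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  .require_columns(x, c("subject_id", "compartment", "assay", "treatment",
                        "day", "percent_viable"))
  if (nrow(x) == 0L) {
    return(data.frame(subject_id = character(),
                      compartment = factor(levels = .COMPARTMENTS),
                      assay = factor(levels = .ASSAYS),
                      treatment = factor(levels = .TREATMENTS),
                      day = integer(), percent_viable = numeric(),
                      stringsAsFactors = FALSE))
  }
  compartment <- as.character(x$compartment)
  assay <- as.character(x$assay)
  treatment <- as.character(x$treatment)
  if (any(bad <- !compartment %in% .COMPARTMENTS)) .stop_rows(bad, "unknown compartment")
  if (any(bad <- !assay %in% .ASSAYS)) .stop_rows(bad, "unknown assay")
  if (any(bad <- !treatment %in% .TREATMENTS)) .stop_rows(bad, "unknown treatment level")
  day <- .parse_numeric(x$day, dec)
  if (any(bad <- is.na(day) | !(day %in% .DAYS))) .stop_rows(bad, "day must be 10 or 20")
  pv <- .parse_numeric(x$percent_viable, dec)
  if (any(bad <- is.na(pv) | !is.finite(pv))) .stop_rows(bad, "percent_viable is not a finite number")
  if (any(bad <- pv < 0 | pv > 100)) .stop_rows(bad, "percent_viable outside [0, 100]")
  out <- data.frame(subject_id = as.character(x$subject_id),
                    compartment = factor(compartment, levels = .COMPARTMENTS),
                    assay = factor(assay, levels = .ASSAYS),
                    treatment = factor(treatment, levels = .TREATMENTS),
                    day = as.integer(day), percent_viable = pv,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a long-format biomarker table from delimited text
#'
#' @param file Path or connection to a delimited text file with header
#'   columns `subject_id`, `tissue`, `treatment`, `day`, `biomarker`,
#'   `value`, `unit`.
#' @param sep Field separator (default comma).
#' @param dec Decimal mark (default `.`).
#' @return A validated data frame (see [as_biomarker_records()]); rows
#'   in file order.
#' @export
read_biomarker_table <- function(file, sep = ",", dec = ".") {
  raw <- utils::read.table(file, header = TRUE, sep = sep, dec = dec,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, comment.char = "")
  as_biomarker_records(raw, dec = dec)
}

#' Write a biomarker table as delimited text
#'
#' Writes the canonical seven columns (the derived `dose` column is
#' dropped; it is reconstructed on read).
#'
#' @param x A biomarker table accepted by [as_biomarker_records()].
#' @param file Output path or connection.
#' @param sep Field separator.
#' @return `file`, invisibly.
#' @export
write_biomarker_table <- function(x, file, sep = ",") {
  x <- as_biomarker_records(x)
  cols <- c("subject_id", "tissue", "treatment", "day", "biomarker",
            "value", "unit")
  out <- x[cols]
  for (nm in c("tissue", "treatment", "biomarker")) out[[nm]] <- as.character(out[[nm]])
  out$value <- sprintf("%.17g", out$value) # full precision round-trips doubles
  utils::write.table(out, file, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Read a viability table from delimited text
#'
#' @inheritParams read_biomarker_table
#' @return A validated data frame (see [as_viability_records()]).
#' @export
read_viability_table <- function(file, sep = ",", dec = ".") {
  raw <- utils::read.table(file, header = TRUE, sep = sep, dec = dec,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, comment.char = "")
  as_viability_records(raw, dec = dec)
}

#' Write a viability table as delimited text
#'
#' @inheritParams write_biomarker_table
#' @export
write_viability_table <- function(x, file, sep = ",") {
  x <- as_viability_records(x)
  for (nm in c("compartment", "assay", "treatment")) x[[nm]] <- as.character(x[[nm]])
  x$percent_viable <- sprintf("%.17g", x$percent_viable)
  utils::write.table(x, file, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Per-cell summaries of a biomarker table
#'
#' Computes n, mean and sample standard deviation (n - 1 denominator)
#' for every occupied (tissue, treatment, day, biomarker) cell. Cells
#' with a single observation carry `sd = NA`: a one-point SD is treated
#' as undefined rather than zero, and downstream stages must handle it
#' explicitly.
#'
#' @param records A biomarker table accepted by [as_biomarker_records()].
#' @return A data frame with columns `tissue`, `treatment`, `day`,
#'   `biomarker`, `n`, `mean`, `sd`, sorted by tissue, day, treatment,
#'   biomarker.
#' @export
summarize_groups <- function(records) {
  records <- as_biomarker_records(records)
  if (nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  key <- list(tissue = records$tissue, treatment = records$treatment,
              day = records$day, biomarker = records$biomarker)
  idx <- split(seq_len(nrow(records)), key, drop = TRUE)
  rows <- lapply(idx, function(i) {
    v <- records$value[i]
    data.frame(tissue = records$tissue[i[1L]],
               treatment = records$treatment[i[1L]],
               day = records$day[i[1L]],
               biomarker = records$biomarker[i[1L]],
               n = length(v),
               mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tissue, out$day, out$treatment, out$biomarker), ]
  rownames(out) <- NULL
  out
}
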
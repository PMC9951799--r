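#' @keywords internal
"_PACKAGE"

# Columns every study table must carry. Dispersions arrive as SD or SE
# (per-row kind column) and are normalized to SD on read.
.required_columns <- function(dispersion_kind_column = "dispersion_kind") {
  c(
    "study_id", "substudy_id", "trait", "growth_compartment",
    "method_category", "duration_days", "grass_species", "recipient_species",
    "grass_origin", "recipient_origin", "dose_value", "dose_unit",
    "material_condition", "material_part", "solvent_polarity",
    "year_published",
    "mean_control", "dispersion_control", "n_control",
    "mean_treatment", "dispersion_treatment", "n_treatment",
    dispersion_kind_column
  )
}

#' Convert a reported dispersion to a standard deviation
#'
#' Source studies report group dispersion either as a standard deviation or a
#' standard error of the mean; both are accepted and normalized to the SD
#' scale, `sd = se * sqrt(n)`.
#'
#' @param raw_value Non-negative dispersion value(s).
#' @param kind `"sd"` or `"se"` (recycled against `raw_value`).
#' @param n Group sample size(s), `>= 2`.
#' @return Standard deviation(s), same length as `raw_value`.
#' @examples
#' normalize_dispersion(1, "se", 16) # 4
#' @export
normalize_dispersion <- function(raw_value, kind, n) {
  kind <- match.arg(as.character(kind), c("sd", "se"), several.ok = TRUE)
  if (any(raw_value < 0, na.rm = TRUE)) {
    stop("dispersion values must be non-negative")
  }
  if (any(n < 2, na.rm = TRUE)) {
    stop("group sample sizes must be >= 2")
  }
  ifelse(kind == "se", raw_value * sqrt(n), raw_value)
}

#' Pick the growth compartment to analyse
#'
#' When a study reports growth for several compartments, a single one is kept
#' per comparison with the preference order aboveground, then belowground,
#' then total.
#'
#' @param available Character vector of compartments present
#'   (`"aboveground"`, `"belowground"`, `"total"`).
#' @return The selected compartment.
#' @export
select_growth_measure <- function(available) {
  if (length(available) == 0) stop("no growth compartments available")
  preference <- c("aboveground", "belowground", "total")
  available <- match.arg(available, preference, several.ok = TRUE)
  preference[min(match(available, preference))]
}

.valid_traits <- c("germination", "growth")
.valid_compartments <- c("aboveground", "belowground", "total", "n/a")
.valid_origins <- c("native", "nonnative")

# Per-row validation; returns character(0) when the row is clean.
.validate_row <- function(row, dispersion_kind_column) {
  reasons <- character(0)
  num <- function(x) suppressWarnings(as.numeric(x))
  for (grp in c("control", "treatment")) {
    m <- num(row[[paste0("mean_", grp)]])
    s <- num(row[[paste0("dispersion_", grp)]])
    n <- num(row[[paste0("n_", grp)]])
    if (is.na(m) || !is.finite(m)) {
      reasons <- c(reasons, paste0("non-numeric or non-finite mean_", grp))
    }
    if (is.na(s) || s < 0) {
      reasons <- c(reasons, paste0("missing or negative dispersion_", grp))
    }
    if (is.na(n) || n < 2 || n != round(n)) {
      reasons <- c(reasons, paste0("n_", grp, " must be an integer >= 2"))
    }
  }
  kind <- tolower(as.character(row[[dispersion_kind_column]]))
  if (!kind %in% c("sd", "se")) {
    reasons <- c(reasons, "dispersion kind must be 'sd' or 'se'")
  }
  trait <- as.character(row[["trait"]])
  if (!trait %in% .valid_traits) {
    reasons <- c(reasons, "trait must be 'germination' or 'growth'")
  }
  comp <- as.character(row[["growth_compartment"]])
  if (!comp %in% .valid_compartments) {
    reasons <- c(reasons, "unknown growth_compartment")
  } else if (identical(trait, "growth") && identical(comp, "n/a")) {
    reasons <- c(reasons, "growth rows need a growth_compartment")
  }
  for (o in c("grass_origin", "recipient_origin")) {
    if (!as.character(row[[o]]) %in% .valid_origins) {
      reasons <- c(reasons, paste0(o, " must be 'native' or 'nonnative'"))
    }
  }
  dur <- num(row[["duration_days"]])
  if (is.na(dur) || dur <= 0) {
    reasons <- c(reasons, "duration_days must be > 0")
  }
  dose <- row[["dose_value"]]
  if (!is.na(dose) && num(dose) <= 0) {
    reasons <- c(reasons, "dose_value must be > 0 when present")
  }
  yr <- num(row[["year_published"]])
  if (is.na(yr) || yr != round(yr)) {
    reasons <- c(reasons, "year_published must be an integer")
  }
  reasons
}

#' Read and validate a study-level table
#'
#' Reads a delimited table of control/treatment comparisons (one row per
#' comparison), validates every row, normalizes dispersions to standard
#' deviations, and returns clean records together with a rejects table.
#' Rows failing validation are reported with reasons, never silently dropped:
#' filtering decisions feed directly into the analysed-effect count.
#'
#' @param path Path to a CSV (or TSV, see `sep`) file with a header.
#' @param dispersion_kind_column Name of the per-row column saying whether the
#'   dispersion columns hold an SD or an SE. Default `"dispersion_kind"`.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @return A list with components `records` (validated rows with
#'   `sd_control`/`sd_treatment` added) and `rejects` (offending rows with a
#'   `reject_reason` column).
#' @seealso [write_study_table()], [compute_effect_sizes()]
#' @export
read_study_table <- function(path, dispersion_kind_column = "dispersion_kind",
                             sep = ",") {
  if (!file.exists(path)) stop("study table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           na.strings = c("NA", ""), check.names = FALSE,
                           colClasses = "character")
  required <- .required_columns(dispersion_kind_column)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("study table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_study_table(raw, dispersion_kind_column = dispersion_kind_column)
}

#' Validate an in-memory study table
#'
#' Workhorse behind [read_study_table()]; useful when records are constructed
#' programmatically (e.g. by [simulate_dataset()]).
#'
#' @inheritParams read_study_table
#' @param table A data frame with the full study-table column set.
#' @return A list with `records` and `rejects` data frames.
#' @export
validate_study_table <- function(table, dispersion_kind_column = "dispersion_kind") {
  stopifnot(is.data.frame(table))
  reasons <- vapply(seq_len(nrow(table)), function(i) {
    paste(.validate_row(table[i, , drop = FALSE], dispersion_kind_column),
          collapse = "; ")
  }, character(1))
  ok <- !nzchar(reasons)
  records <- table[ok, , drop = FALSE]
  numeric_cols <- c("duration_days", "dose_value", "year_published",
                    "mean_control", "dispersion_control", "n_control",
                    "mean_treatment", "dispersion_treatment", "n_treatment")
  for (col in numeric_cols) {
    records[[col]] <- as.numeric(records[[col]])
  }
  kind <- tolower(as.character(records[[dispersion_kind_column]]))
  if (nrow(records) > 0) {
    records$sd_control <- normalize_dispersion(
      records$dispersion_control, kind, records$n_control)
    records$sd_treatment <- normalize_dispersion(
      records$dispersion_treatment, kind, records$n_treatment)
  } else {
    records$sd_control <- numeric(0)
    records$sd_treatment <- numeric(0)
  }
  rejects <- table[!ok, , drop = FALSE]
  if (nrow(rejects) > 0) rejects$reject_reason <- reasons[!ok]
  rownames(records) <- NULL
  rownames(rejects) <- NULL
  list(records = records, rejects = rejects)
}

#' Write a study table (or rejects table) back to disk
#'
#' @param records Data frame as returned in `read_study_table()$records`.
#' @param path Output file path.
#' @param sep Field separator, `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(records, path, sep = ",") {
  out <- records
  # drop derived columns so a write -> read round trip is exact
  out$sd_control <- NULL
  out$sd_treatment <- NULL
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
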
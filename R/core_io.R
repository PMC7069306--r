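# Individual-level records and study configuration.
#
# Units are fixed by convention and are part of the column names: lengths and
# distances in cm, dry weights in mg. The configuration cannot override them.

#' Canonical column order of the individuals table
#'
#' @return Character vector of the ten column names of the individuals CSV
#'   dialect, in canonical order.
#' @export
individual_columns <- function() {
  c(
    "id", "shell_id", "x_cm", "y_cm", "operculum_radius_cm",
    "penis_length_cm", "operculum_weight_mg", "testis_sv_weight_mg",
    "penis_weight_mg", "ovary_weight_mg"
  )
}

# columns that must be present and non-missing in every record
.required_columns <- c(
  "id", "shell_id", "x_cm", "y_cm", "penis_length_cm", "operculum_weight_mg"
)
# organ weights that may be missing (empty cell); missingness triggers
# exclusion downstream, never imputation
.organ_columns <- c("testis_sv_weight_mg", "penis_weight_mg", "ovary_weight_mg")

#' Study configuration
#'
#' Holds the tunable choices of the mating-group analysis: the penis
#' elongation factor that converts resting penis length to reach, the
#' isolation rule used to exclude individuals without potential partners, and
#' how inter-individual distance is measured.
#'
#' @param elongation_factor Multiplier converting resting penis length (cm) to
#'   functional reach (cm). Default 1.82, the elongation rate measured for
#'   *Balanus glandula* on a wave-protected shore and applied here to its
#'   congener.
#' @param inclusion_rule How "no potential mating partner" is interpreted when
#'   excluding isolated individuals: `"both_roles_isolated"` (default; excluded
#'   only if MGSm = 1 AND MGSf = 1) or `"either_role_isolated"` (excluded if
#'   isolated in either role).
#' @param distance_mode `"center"` (default): Euclidean distance between
#'   operculum centers; `"operculum_edge"`: center distance minus both
#'   operculum radii, floored at 0 for touching or overlapping opercula.
#' @param seed Integer seed echoed into reports; `NA` leaves the RNG untouched.
#' @return An object of class `study_config`.
#' @export
study_config <- function(elongation_factor = 1.82,
                         inclusion_rule = c("both_roles_isolated",
                                            "either_role_isolated"),
                         distance_mode = c("center", "operculum_edge"),
                         seed = NA_integer_) {
  inclusion_rule <- match.arg(inclusion_rule)
  distance_mode <- match.arg(distance_mode)
  stopifnot(is.numeric(elongation_factor), length(elongation_factor) == 1L,
            is.finite(elongation_factor), elongation_factor > 0)
  structure(
    list(
      elongation_factor = as.numeric(elongation_factor),
      inclusion_rule = inclusion_rule,
      distance_mode = distance_mode,
      seed = seed
    ),
    class = "study_config"
  )
}

#' Read a study configuration from a flat YAML file
#'
#' @param path Path to a flat key-value YAML file with any subset of the
#'   `study_config()` fields.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- c("elongation_factor", "inclusion_rule", "distance_mode", "seed")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  }
  vals <- vals[intersect(names(vals), known)]
  do.call(study_config, vals)
}

#' Write a study configuration to a flat YAML file
#'
#' @param config A `study_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat(sprintf("  elongation factor: %g (reach = factor x penis length)\n",
              x$elongation_factor))
  cat(sprintf("  inclusion rule:    %s\n", x$inclusion_rule))
  cat(sprintf("  distance mode:     %s\n", x$distance_mode))
  cat(sprintf("  seed:              %s\n", format(x$seed)))
  invisible(x)
}

#' Read an individuals table from CSV
#'
#' Reads the standard individuals dialect (one row per barnacle: identifier,
#' shell, planar position in cm, penis length in cm, organ dry weights in mg)
#' and validates it. Empty cells in the organ-weight columns are preserved as
#' `NA`, never replaced with zero; an absent `operculum_radius_cm` column is
#' filled with 0 (point opercula).
#'
#' @param path Path to a CSV file with a header row.
#' @param config A `study_config` (currently unused by reading itself; kept so
#'   every pipeline stage shares one signature).
#' @return A validated `data.frame` with the columns of
#'   [individual_columns()].
#' @export
read_individuals <- function(path, config = study_config()) {
  if (!file.exists(path)) stop("individuals file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  cols <- individual_columns()
  unknown <- setdiff(names(raw), cols)
  if (length(unknown) > 0) {
    warning("unknown column(s) ignored: ", paste(unknown, collapse = ", "))
  }
  if (!"operculum_radius_cm" %in% names(raw)) raw$operculum_radius_cm <- "0"
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- data.frame(
    id = trimws(raw$id),
    shell_id = trimws(raw$shell_id),
    stringsAsFactors = FALSE
  )
  for (col in setdiff(cols, c("id", "shell_id"))) {
    cell <- trimws(raw[[col]])
    cell[cell == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                   col, bad[1], cell[bad[1]]))
    }
    records[[col]] <- num
  }
  records$operculum_radius_cm[is.na(records$operculum_radius_cm)] <- 0
  assert_valid_records(records)
  records[, cols]
}

#' Write an individuals table to CSV
#'
#' Numeric cells are written with enough significant digits that reading the
#' file back reproduces the records exactly; missing organ weights become
#' empty cells, not `"0"`.
#'
#' @param records Validated individuals `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_individuals <- function(records, path) {
  assert_valid_records(records)
  cols <- individual_columns()
  records <- records[, cols]
  out <- records
  for (col in setdiff(cols, c("id", "shell_id"))) {
    cell <- vapply(records[[col]], function(v) {
      if (is.na(v)) "" else sprintf("%.17g", v)
    }, character(1))
    out[[col]] <- cell
  }
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to: ", path))
  on.exit(close(con))
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Validate an individuals table
#'
#' Reporting operation: checks every record against the data-model invariants
#' (unique non-empty ids, non-empty shell ids, finite coordinates, positive
#' penis length and operculum weight, non-negative weights and radii where
#' present) and lists every violation found. A valid table yields a zero-row
#' report.
#'
#' @param records Individuals `data.frame`.
#' @return A `data.frame` with columns `row`, `id`, `field`, `problem`, one
#'   row per violation.
#' @export
validate_records <- function(records) {
  empty_report <- data.frame(row = integer(), id = character(),
                             field = character(), problem = character(),
                             stringsAsFactors = FALSE)
  viol <- list()
  note <- function(row, id, field, problem) {
    viol[[length(viol) + 1L]] <<- data.frame(
      row = row, id = id, field = field, problem = problem,
      stringsAsFactors = FALSE
    )
  }
  cols <- individual_columns()
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0) {
    for (col in missing_cols) note(NA_integer_, NA_character_, col,
                                   "column missing")
    return(do.call(rbind, viol))
  }
  n <- nrow(records)
  if (n == 0) return(empty_report)
  ids <- as.character(records$id)
  blank_id <- is.na(ids) | ids == ""
  for (i in which(blank_id)) note(i, "", "id", "empty id")
  dup_ids <- unique(ids[!blank_id][duplicated(ids[!blank_id])])
  for (d in dup_ids) {
    note(which(ids == d)[2], d, "id", "duplicate id")
  }
  shells <- as.character(records$shell_id)
  for (i in which(is.na(shells) | shells == "")) {
    note(i, ids[i], "shell_id", "empty shell_id")
  }
  check_num <- function(col, lower, strict, required) {
    v <- records[[col]]
    for (i in seq_len(n)) {
      if (is.nan(v[i])) {          # NaN is a sentinel, not a missing cell
        note(i, ids[i], col, "non-finite value")
        next
      }
      if (is.na(v[i])) {
        if (required) note(i, ids[i], col, "missing required value")
        next
      }
      if (!is.finite(v[i])) {
        note(i, ids[i], col, "non-finite value")
      } else if (strict && v[i] <= lower) {
        note(i, ids[i], col, sprintf("must be > %g", lower))
      } else if (!strict && v[i] < lower) {
        note(i, ids[i], col, sprintf("must be >= %g", lower))
      }
    }
  }
  check_num("x_cm", -Inf, FALSE, TRUE)
  check_num("y_cm", -Inf, FALSE, TRUE)
  check_num("operculum_radius_cm", 0, FALSE, TRUE)
  check_num("penis_length_cm", 0, TRUE, TRUE)
  check_num("operculum_weight_mg", 0, TRUE, TRUE)
  for (col in .organ_columns) check_num(col, 0, FALSE, FALSE)
  if (length(viol) == 0) empty_report else do.call(rbind, viol)
}

# hard-error wrapper naming the first offending rows
assert_valid_records <- function(records) {
  report <- validate_records(records)
  if (nrow(report) > 0) {
    shown <- utils::head(report, 5)
    stop("invalid individual records (", nrow(report), " violation(s)):\n",
         paste(sprintf("  row %s (id %s), %s: %s", format(shown$row),
                       shown$id, shown$field, shown$problem),
               collapse = "\n"),
         if (nrow(report) > 5) "\n  ..." else "")
  }
  invisible(records)
}
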
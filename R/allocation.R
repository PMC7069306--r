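# Reproductive-cost aggregates and the sex-allocation index.
#
# Cost partition (dry weights, mg): ovary = female variable cost; testis +
# seminal vesicles = male variable cost; penis = male fixed cost. Sex
# allocation is male variable investment over total variable investment --
# the penis is deliberately in neither numerator nor denominator; it enters
# only its own model and the penis-fraction statistic.

#' Sex-allocation index
#'
#' Male variable investment divided by total variable investment:
#' `male_variable / (male_variable + female_variable)`. Ranges over \[0, 1\]
#' with 0 a pure female and 1 a pure male; scale-invariant in its arguments.
#'
#' @param male_variable Testis + seminal vesicle dry weight, mg (vectorized).
#' @param female_variable Ovary dry weight, mg.
#' @return Sex allocation in \[0, 1\].
#' @export
sex_allocation <- function(male_variable, female_variable) {
  stopifnot(length(male_variable) == length(female_variable))
  if (any(male_variable < 0 | female_variable < 0, na.rm = TRUE)) {
    stop("investments must be non-negative")
  }
  total <- male_variable + female_variable
  if (any(total == 0, na.rm = TRUE)) {
    stop("sex allocation undefined when total variable investment is 0")
  }
  male_variable / total
}

#' Penis share of total male output
#'
#' Percentage of the total male output (male variable + male fixed cost)
#' accounted for by the penis: `100 * penis / (penis + male_variable)`.
#'
#' @param penis_weight Penis dry weight, mg (vectorized).
#' @param male_variable Testis + seminal vesicle dry weight, mg.
#' @return Percent of total male output.
#' @export
penis_fraction_of_male_output <- function(penis_weight, male_variable) {
  stopifnot(length(penis_weight) == length(male_variable))
  if (any(penis_weight < 0 | male_variable < 0, na.rm = TRUE)) {
    stop("weights must be non-negative")
  }
  total <- penis_weight + male_variable
  if (any(total == 0, na.rm = TRUE)) {
    stop("penis fraction undefined when total male output is 0")
  }
  100 * penis_weight / total
}

#' Assemble the per-individual analysis table
#'
#' Merges MGS values with the cost aggregates for every individual passing
#' the inclusion filter, in deterministic order (shell_id, then id). This is
#' the table all mixed models are fitted on.
#'
#' @param records Validated individuals `data.frame`.
#' @param mgs_records Output of [compute_mgs()] (inclusion flags are
#'   recomputed here via [apply_inclusion_filter()] if absent).
#' @param config A [study_config()].
#' @return Data frame of class `analysis_table`: `id`, `shell_id`, `mgs_m`,
#'   `mgs_f`, `body_weight_mg`, `male_variable_mg`, `male_fixed_mg`,
#'   `female_variable_mg`, `sex_allocation`, one row per included individual.
#' @export
build_analysis_table <- function(records, mgs_records,
                                 config = study_config()) {
  assert_valid_records(records)
  if (!"included" %in% names(mgs_records)) {
    mgs_records <- apply_inclusion_filter(records, mgs_records, config)
  }
  merged <- merge(records, mgs_records[, c("id", "mgs_m", "mgs_f", "included",
                                           "exclusion_reason")],
                  by = "id", sort = FALSE)
  kept <- merged[merged$included, , drop = FALSE]
  if (nrow(kept) == 0) {
    reasons <- table(merged$exclusion_reason[!merged$included])
    stop("no individuals left after inclusion filtering (input ",
         nrow(merged), ", included 0; exclusions: ",
         paste(sprintf("%s=%d", names(reasons), as.integer(reasons)),
               collapse = ", "), ")")
  }
  tab <- data.frame(
    id = kept$id,
    shell_id = kept$shell_id,
    mgs_m = kept$mgs_m,
    mgs_f = kept$mgs_f,
    body_weight_mg = kept$operculum_weight_mg,
    male_variable_mg = kept$testis_sv_weight_mg,
    male_fixed_mg = kept$penis_weight_mg,
    female_variable_mg = kept$ovary_weight_mg,
    stringsAsFactors = FALSE
  )
  tab$sex_allocation <- sex_allocation(tab$male_variable_mg,
                                       tab$female_variable_mg)
  tab <- tab[order(tab$shell_id, tab$id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("analysis_table", "data.frame")
  tab
}

#' Write an analysis table to CSV
#'
#' @param table An `analysis_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_analysis_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
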
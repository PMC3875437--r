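#' Read a variant activity table
#'
#' Reads a delimited table of per-variant repression measurements (one row
#' per variant, effector condition and clone) and validates it against the
#' measurement schema. Duplicate clones of the same
#' (homolog, position, substitution, condition) are merged with
#' [merge_clone_duplicates()]. Homolog contexts (parent activity, DEL
#' control, active condition, growth threshold) are supplied as a companion
#' table or file; parent rows in the variant table (where `sub_aa == wt_aa`)
#' are retained as measurements but contexts are authoritative for
#' normalization.
#'
#' Required columns (renamable through `schema`): `homolog`, `position`,
#' `wt_aa`, `sub_aa`, `condition` (`"minus_effector"`/`"plus_effector"`),
#' `mean_miller`, `sd_miller`, `n_reps`. An optional logical `excluded`
#' column flags variants (e.g. no activity in either DNA pull-down assay)
#' that stay in the files but are dropped from classification.
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from the
#'   extension; `.tsv`/`.txt` are tab-delimited).
#' @param contexts A data frame, or path to a CSV/TSV, with columns
#'   `homolog`, `parent_mean`, `parent_sd`, `del_mean`, `del_sd`,
#'   `active_condition`, `growth_threshold` and optionally
#'   `parent_inactive_mean`, `parent_inactive_sd` (the parent's activity in
#'   the non-readout condition; defaults to the DEL control, i.e. full
#'   induction).
#' @param schema Optional named character vector mapping required column
#'   names to the names used in the file, e.g. `c(mean_miller = "activity")`.
#' @return A list with elements `measurements` (tibble, one row per merged
#'   variant measurement, with `excluded` and `merge_flagged` columns) and
#'   `contexts` (tibble).
#' @export
read_variant_table <- function(path, contexts = NULL, schema = NULL) {
  raw <- read_delim_auto(path)
  required <- c("homolog", "position", "wt_aa", "sub_aa", "condition",
                "mean_miller", "sd_miller", "n_reps")
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(raw)) {
        abort(sprintf("Schema maps '%s' to missing column '%s'",
                      std, schema[[std]]))
      }
      names(raw)[names(raw) == schema[[std]]] <- std
    }
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Variant table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  meas <- as_tibble(raw) %>%
    dplyr::mutate(
      homolog = as.character(.data$homolog),
      position = as.character(.data$position),
      wt_aa = toupper(as.character(.data$wt_aa)),
      sub_aa = toupper(as.character(.data$sub_aa)),
      condition = as.character(.data$condition),
      mean_miller = as.numeric(.data$mean_miller),
      sd_miller = as.numeric(.data$sd_miller),
      n_reps = as.integer(.data$n_reps)
    )
  if (!"excluded" %in% names(meas)) meas$excluded <- FALSE
  meas$excluded <- isTRUE_vec(meas$excluded)
  validate_measurements(meas)
  meas <- merge_clone_duplicates(meas)

  ctx <- NULL
  if (!is.null(contexts)) {
    ctx <- if (is.character(contexts)) read_delim_auto(contexts) else contexts
    ctx <- validate_contexts(ctx)
  }
  list(measurements = meas, contexts = ctx)
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(as.character(x))
  x %in% c("true", "t", "1", "yes")
}

read_delim_auto <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
}

validate_measurements <- function(meas) {
  bad <- which(!is.na(meas$mean_miller) & meas$mean_miller < 0)
  if (length(bad) > 0) {
    abort(sprintf("Negative mean activity at row(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(!is.na(meas$sd_miller) & meas$sd_miller < 0)
  if (length(bad) > 0) {
    abort(sprintf("Negative activity sd at row(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(!is.na(meas$n_reps) & meas$n_reps < 1)
  if (length(bad) > 0) {
    abort(sprintf("n_reps < 1 at row(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  check_amino_acids(meas$wt_aa, "wild-type amino acid")
  check_amino_acids(meas$sub_aa, "substituted amino acid")
  bad_cond <- setdiff(unique(meas$condition), assay_conditions())
  if (length(bad_cond) > 0) {
    abort(sprintf("Unknown condition value(s): %s",
                  paste(bad_cond, collapse = ", ")))
  }
  invisible(meas)
}

#' Validate and complete a homolog context table
#'
#' @param ctx A data frame of homolog contexts (see [read_variant_table()]).
#' @return The contexts as a tibble with defaults filled in.
#' @export
validate_contexts <- function(ctx) {
  required <- c("homolog", "parent_mean", "parent_sd", "del_mean", "del_sd",
                "active_condition")
  missing_cols <- setdiff(required, names(ctx))
  if (length(missing_cols) > 0) {
    abort(sprintf("Context table is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  ctx <- as_tibble(ctx)
  if (!"growth_threshold" %in% names(ctx)) ctx$growth_threshold <- 13
  # with no stated induced-state value the parent is taken to induce fully
  if (!"parent_inactive_mean" %in% names(ctx)) {
    ctx$parent_inactive_mean <- ctx$del_mean
    ctx$parent_inactive_sd <- ctx$del_sd
  }
  if (any(ctx$growth_threshold <= 0)) {
    abort("growth_threshold must be positive")
  }
  weak <- ctx$del_mean <= ctx$parent_mean
  if (any(weak)) {
    warn(sprintf(
      "Homolog(s) with parent activity at or above the DEL control (no measurable repression): %s",
      paste(ctx$homolog[weak], collapse = ", ")
    ))
  }
  ctx
}

#' Merge duplicate clone measurements
#'
#' Repeated clones of the same (homolog, position, substitution, condition)
#' are merged into one measurement: geometric mean of the means, pooled
#' standard deviation (root mean square), summed replicate counts. Clone
#' pairs whose means differ by more than 2-fold are merged anyway but
#' flagged for review in the `merge_flagged` column, mirroring the
#' observation that repeat clones usually agree within 2-fold.
#'
#' @param measurements A measurement tibble (see [read_variant_table()]).
#' @return The tibble with duplicates merged and a `merge_flagged` column.
#' @export
merge_clone_duplicates <- function(measurements) {
  key <- c("homolog", "position", "wt_aa", "sub_aa", "condition")
  merged <- measurements %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) %>%
    dplyr::summarise(
      merge_flagged = dplyr::n() > 1 &&
        max(.data$mean_miller) > 2 * max(min(.data$mean_miller),
                                         .Machine$double.xmin),
      mean_miller = exp(mean(log(pmax(.data$mean_miller,
                                      .Machine$double.xmin)))),
      sd_miller = sqrt(mean(.data$sd_miller^2)),
      n_reps = sum(.data$n_reps),
      excluded = any(.data$excluded),
      .groups = "drop"
    ) %>%
    dplyr::relocate(dplyr::all_of(key))
  n_flag <- sum(merged$merge_flagged)
  if (n_flag > 0) {
    warn(sprintf(
      "%d merged clone group(s) differed by more than 2-fold; see merge_flagged",
      n_flag
    ))
  }
  merged
}

#' Write and read report tables
#'
#' `write_report()` writes any result tibble as TSV (the layout used for
#' behavior, entropy, enhancement, outcome-code and screen reports);
#' `read_report()` reads one back. With `digits = NULL` a write/read round
#' trip recovers the values exactly; `digits` can be set (e.g. 2, matching
#' published entropy tables) for display copies.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param digits Optional number of decimal places for numeric columns.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns a tibble.
#' @export
write_report <- function(x, path, digits = NULL) {
  if (!is.null(digits)) {
    x <- dplyr::mutate(x, dplyr::across(
      dplyr::where(is.double), ~ round(.x, digits)
    ))
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
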
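#' Cohort table: subject-by-variable data plus a data dictionary
#'
#' The single currency passed between pipeline stages: a rectangular
#' subject-by-variable table, a dictionary assigning each column a role
#' from the closed set `vrf_binary`, `vrf_continuous`, `cognitive`,
#' `heart_feature`, `brain_volume`, `brain_fa`, `brain_md`, `brain_wmh`,
#' `covariate`, `confounder`, and an append-only provenance log of applied
#' transforms.
#'
#' @param data A data.frame with a unique `subject_id` column.
#' @param dictionary A data.frame with columns `column`, `role`, and
#'   optionally `type` and `transform` (`"ln"`, `"ln1p"`, or `"none"`).
#' @param provenance Character vector of applied-transform records.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(data, dictionary, provenance = character()) {
  stopifnot(is.data.frame(data), is.data.frame(dictionary))
  assert_cols(data, "subject_id", "cohort data")
  assert_cols(dictionary, c("column", "role"), "dictionary")
  if (anyDuplicated(data$subject_id)) {
    stop("subject_id values must be unique", call. = FALSE)
  }
  if (is.null(dictionary$type)) dictionary$type <- "continuous"
  if (is.null(dictionary$transform)) dictionary$transform <- "none"
  valid_roles <- c("vrf_binary", "vrf_continuous", "cognitive",
                   "heart_feature", "brain_volume", "brain_fa", "brain_md",
                   "brain_wmh", "covariate", "confounder")
  bad <- setdiff(dictionary$role, valid_roles)
  if (length(bad)) {
    stop("unknown dictionary roles: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  undeclared <- setdiff(setdiff(names(data), "subject_id"),
                        dictionary$column)
  if (length(undeclared)) {
    stop("columns missing from dictionary: ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(dictionary$column, names(data))
  if (length(absent)) {
    stop("dictionary lists absent columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  structure(list(data = data, dictionary = dictionary,
                 provenance = as.character(provenance)),
            class = "cohort_table")
}

#' @rdname cohort_table
#' @param x A `cohort_table`.
#' @export
cohort_data <- function(x) {
  stopifnot(inherits(x, "cohort_table"))
  x$data
}

#' @rdname cohort_table
#' @export
dictionary <- function(x) {
  stopifnot(inherits(x, "cohort_table"))
  x$dictionary
}

#' @rdname cohort_table
#' @export
provenance <- function(x) {
  stopifnot(inherits(x, "cohort_table"))
  x$provenance
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x$data), "subjects x",
      nrow(x$dictionary), "variables\n")
  print(table(x$dictionary$role))
  if (length(x$provenance)) {
    cat("Provenance:\n")
    cat(paste0("  ", x$provenance, collapse = "\n"), "\n")
  }
  invisible(x)
}

# columns of a cohort with any of the given roles
role_columns <- function(cohort, roles) {
  dict <- dictionary(cohort)
  dict$column[dict$role %in% roles]
}

#' Apply the skew-correcting cognitive transforms
#'
#' Replaces the reaction-time score by its natural log (reaction times are
#' positively skewed) and the visual-memory error count by `log(x + 1)`
#' (zero-inflated and positively skewed). Columns are located through the
#' dictionary's `transform` field (`"ln"` and `"ln1p"`), so the operation
#' is generic over column names. The transforms are recorded in the
#' provenance log and marked applied in the dictionary.
#'
#' @param cohort A [cohort_table].
#' @return The transformed cohort.
#' @export
transform_cognitive <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  dict <- dictionary(cohort)
  data <- cohort_data(cohort)
  prov <- provenance(cohort)
  for (i in which(dict$transform == "ln")) {
    cl <- dict$column[i]
    bad <- which(!is.na(data[[cl]]) & data[[cl]] <= 0)
    if (length(bad)) {
      stop("non-positive values in '", cl, "' for subjects: ",
           paste(utils::head(data$subject_id[bad], 5), collapse = ", "),
           call. = FALSE)
    }
    data[[cl]] <- log(data[[cl]])
    dict$transform[i] <- "ln:applied"
    prov <- c(prov, paste0("transform_cognitive: ln(", cl, ")"))
  }
  for (i in which(dict$transform == "ln1p")) {
    cl <- dict$column[i]
    bad <- which(!is.na(data[[cl]]) & data[[cl]] < 0)
    if (length(bad)) {
      stop("negative values in '", cl, "' for subjects: ",
           paste(utils::head(data$subject_id[bad], 5), collapse = ", "),
           call. = FALSE)
    }
    data[[cl]] <- log1p(data[[cl]])
    dict$transform[i] <- "ln1p:applied"
    prov <- c(prov, paste0("transform_cognitive: ln1p(", cl, ")"))
  }
  cohort_table(data, dict, prov)
}

#' Aggregate vascular-risk-factor count
#'
#' Counts, per subject, how many of six binary criteria hold: diagnosis of
#' hypertension, diabetes, or hypercholesterolaemia; having ever smoked
#' (pack-years strictly greater than 0); BMI strictly greater than 25; and
#' high waist-to-hip ratio (strictly greater than 0.85 for females, 0.90
#' for males). Subjects missing any ingredient get a missing count.
#'
#' @param cohort A [cohort_table].
#' @param diagnoses Names of the three binary diagnosis columns.
#' @param pack_years,bmi,whr,sex Column names of the continuous
#'   ingredients and of sex.
#' @param female_code Value of `sex` coding female.
#' @return The cohort with an integer `vrf_count` column (role
#'   `covariate`) appended.
#' @export
aggregate_vrf_count <- function(cohort,
                                diagnoses = c("vrf_htn", "vrf_diab",
                                              "vrf_chol"),
                                pack_years = "vrf_pack_years",
                                bmi = "vrf_bmi", whr = "vrf_whr",
                                sex = "sex", female_code = 1) {
  stopifnot(inherits(cohort, "cohort_table"))
  data <- cohort_data(cohort)
  assert_cols(data, c(diagnoses, pack_years, bmi, whr, sex), "cohort data")
  female <- data[[sex]] == female_code
  crit <- do.call(cbind, c(
    lapply(diagnoses, function(d) data[[d]] > 0),
    list(ever_smoked = data[[pack_years]] > 0,
         high_bmi = data[[bmi]] > 25,
         high_whr = data[[whr]] > ifelse(female, 0.85, 0.90))))
  count <- as.integer(rowSums(crit))
  count[rowSums(is.na(crit)) > 0] <- NA_integer_
  data$vrf_count <- count
  dict <- dictionary(cohort)
  dict <- dict[dict$column != "vrf_count", ]
  dict <- rbind(dict, data.frame(column = "vrf_count", role = "covariate",
                                 type = "count", transform = "none",
                                 stringsAsFactors = FALSE))
  cohort_table(data, dict,
               c(provenance(cohort), "aggregate_vrf_count"))
}

#' Complete-case filtering with an attrition report
#'
#' Drops every subject with a missing value in any column whose role is in
#' `required_roles`, one role at a time, recording the attrition at each
#' step.
#'
#' @param cohort A [cohort_table].
#' @param required_roles Roles whose columns must be complete; defaults
#'   to every role present in the dictionary.
#' @return A list with the filtered `cohort` and a `report` (class
#'   `prep_report`) with per-step retained counts and drop reasons.
#' @export
complete_case_filter <- function(cohort, required_roles = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  dict <- dictionary(cohort)
  required_roles <- required_roles %||% unique(dict$role)
  unknown <- setdiff(required_roles, dict$role)
  if (length(unknown)) {
    stop("required_roles not present in dictionary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  data <- cohort_data(cohort)
  n_input <- nrow(data)
  n_after <- integer(0)
  dropped <- integer(0)
  for (role in required_roles) {
    cols <- dict$column[dict$role == role]
    keep <- rowSums(is.na(data[, cols, drop = FALSE])) == 0
    dropped[role] <- sum(!keep)
    data <- data[keep, , drop = FALSE]
    n_after[role] <- nrow(data)
  }
  if (nrow(data) == 0) stop("no complete cases remain", call. = FALSE)
  report <- structure(list(n_input = n_input, n_after_each_step = n_after,
                           dropped_reasons = dropped,
                           n_final = nrow(data)),
                      class = "prep_report")
  out <- cohort_table(data, dict,
                      c(provenance(cohort),
                        sprintf("complete_case_filter: %d -> %d subjects",
                                n_input, nrow(data))))
  list(cohort = out, report = report)
}

#' @export
print.prep_report <- function(x, ...) {
  cat("Complete-case filter:", x$n_input, "->", x$n_final, "subjects\n")
  steps <- data.frame(step = names(x$n_after_each_step),
                      dropped = unname(x$dropped_reasons),
                      retained = unname(x$n_after_each_step))
  print(steps, row.names = FALSE)
  invisible(x)
}

#' Z-score columns with a reusable train/apply contract
#'
#' Standardizes the named columns to mean 0 and SD 1 (denominator n - 1).
#' If `stats` from a previous call is supplied, those means and SDs are
#' reused, so statistics learned on a training table can be applied to new
#' data (on which the resulting means are generally not 0).
#'
#' @param cohort A [cohort_table] or plain data.frame.
#' @param columns Columns to standardize.
#' @param stats Optional data.frame returned by a previous call (`column`,
#'   `mean`, `sd`).
#' @return A list with the transformed `cohort` (same class as the input)
#'   and the `stats` used.
#' @export
zscore_columns <- function(cohort, columns, stats = NULL) {
  is_ct <- inherits(cohort, "cohort_table")
  data <- if (is_ct) cohort_data(cohort) else cohort
  assert_cols(data, columns)
  if (is.null(stats)) {
    mu <- vapply(columns, function(cl) mean(data[[cl]], na.rm = TRUE), 0)
    sd_ <- vapply(columns, function(cl) stats::sd(data[[cl]], na.rm = TRUE), 0)
    zero <- columns[!is.finite(sd_) | sd_ < .Machine$double.eps^0.5]
    if (length(zero)) {
      stop("zero-variance column(s): ", paste(zero, collapse = ", "),
           call. = FALSE)
    }
    stats <- data.frame(column = columns, mean = unname(mu),
                        sd = unname(sd_), stringsAsFactors = FALSE)
  } else {
    assert_cols(stats, c("column", "mean", "sd"), "stats")
    miss <- setdiff(columns, stats$column)
    if (length(miss)) {
      stop("stats missing for column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  for (cl in columns) {
    s <- stats[stats$column == cl, ]
    data[[cl]] <- (data[[cl]] - s$mean) / s$sd
  }
  out <- if (is_ct) {
    cohort_table(data, dictionary(cohort),
                 c(provenance(cohort),
                   paste0("zscore: ", paste(columns, collapse = ","))))
  } else data
  list(cohort = out, stats = stats)
}

#' Replay a provenance log sanity check
#'
#' Re-applies [transform_cognitive()] to a raw cohort and verifies that it
#' reproduces the prepared cohort's data exactly; used to check that the
#' provenance log is replayable.
#'
#' @param raw,prepared Cohorts before and after preparation.
#' @return `TRUE` invisibly if identical; errors otherwise.
#' @keywords internal
#' @export
replay_transforms <- function(raw, prepared) {
  redo <- transform_cognitive(raw)
  if (!isTRUE(all.equal(cohort_data(redo), cohort_data(prepared)))) {
    stop("provenance replay failed to reproduce the prepared table",
         call. = FALSE)
  }
  invisible(TRUE)
}
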
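#' Coerce a data frame to a cohort table
#'
#' A cohort table is a tibble with one row per subject-visit: a `subject_id`
#' column, an integer `visit` column (0 = baseline), a two-level `label`
#' factor (`control`, `patient`), and one numeric column per biomarker or
#' test score. Missing scores are allowed and are carried as `NA`.
#'
#' @param data A data frame.
#' @param label_col Name of the diagnostic label column.
#' @param control_value Value in `label_col` marking control subjects; every
#'   other value present must equal `patient_value` (when given) or be a
#'   single common value, which is taken to mean "patient".
#' @param id_col Name of the subject identifier column.
#' @param visit_col Name of the integer visit-index column. If absent, all
#'   rows are treated as baseline (visit 0).
#' @param patient_value Optional explicit patient label value.
#' @param biomarkers Optional character vector naming the score columns;
#'   defaults to every column other than id, visit and label.
#' @return A tibble of class `ebm_cohort` with canonical columns
#'   `subject_id`, `visit`, `label`, followed by the biomarker columns.
#' @export
as_ebm_cohort <- function(data,
                          label_col = "label",
                          control_value = "control",
                          id_col = "subject_id",
                          visit_col = "visit",
                          patient_value = NULL,
                          biomarkers = NULL) {
  stopifnot(is.data.frame(data))
  for (col in c(label_col, id_col)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in cohort data", call. = FALSE)
    }
  }

  labels_raw <- as.character(data[[label_col]])
  other <- setdiff(unique(labels_raw), control_value)
  if (is.null(patient_value)) {
    if (length(other) > 1) {
      bad <- setdiff(other, other[1])
      stop("label column '", label_col, "' contains more than two values; ",
           "unexpected: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    patient_value <- other
  } else {
    bad <- setdiff(other, patient_value)
    if (length(bad) > 0) {
      rows <- which(labels_raw %in% bad)
      stop("unknown label value(s) ", paste(unique(bad), collapse = ", "),
           " in row(s) ", paste(utils::head(rows, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  label <- factor(ifelse(labels_raw == control_value, "control", "patient"),
                  levels = c("control", "patient"))

  visit <- if (visit_col %in% names(data)) {
    v <- data[[visit_col]]
    if (any(is.na(v)) || any(v %% 1 != 0) || any(v < 0)) {
      stop("visit column must hold non-negative integers", call. = FALSE)
    }
    as.integer(v)
  } else {
    rep(0L, nrow(data))
  }

  if (is.null(biomarkers)) {
    biomarkers <- setdiff(names(data), c(label_col, id_col, visit_col))
  }
  if (length(biomarkers) < 2) {
    stop("a cohort needs at least 2 biomarker columns, found ",
         length(biomarkers), call. = FALSE)
  }
  scores <- data[biomarkers]
  scores[] <- lapply(scores, function(x) suppressWarnings(as.numeric(x)))

  out <- tibble::tibble(
    subject_id = as.character(data[[id_col]]),
    visit = visit,
    label = label
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(scores))

  if (anyDuplicated(out[c("subject_id", "visit")]) > 0) {
    stop("(subject_id, visit) pairs must be unique", call. = FALSE)
  }
  new_ebm_cohort(out, biomarkers)
}

new_ebm_cohort <- function(tbl, biomarkers) {
  attr(tbl, "biomarkers") <- biomarkers
  class(tbl) <- unique(c("ebm_cohort", class(tbl)))
  tbl
}

#' Biomarker column names of a cohort table
#'
#' @param cohort A cohort tibble (see [as_ebm_cohort()]).
#' @return Character vector of score column names.
#' @export
cohort_biomarkers <- function(cohort) {
  bm <- attr(cohort, "biomarkers")
  if (is.null(bm)) {
    bm <- setdiff(names(cohort), c("subject_id", "visit", "label"))
  }
  bm
}

#' Baseline rows of a cohort
#'
#' Baseline is each subject's minimum visit index. Model fitting uses
#' baseline rows only; staging uses every row.
#'
#' @inheritParams cohort_biomarkers
#' @return Cohort tibble restricted to one baseline row per subject.
#' @export
baseline_rows <- function(cohort) {
  out <- cohort |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::filter(.data$visit == min(.data$visit)) |>
    dplyr::ungroup()
  new_ebm_cohort(out, cohort_biomarkers(cohort))
}

# tokens treated as missing when reading CSV (case-insensitive)
missing_tokens <- function() {
  base <- c("", "NA", "NaN", "nan")
  unique(c(base, toupper(base), tolower(base)))
}

#' Read a cohort table from CSV
#'
#' Expects a header row; empty cells and the tokens `NA`, `NaN`, `nan`
#' (case-insensitive) become missing values. All columns other than the id,
#' visit and label columns are parsed as numeric scores.
#'
#' @param path Path to a CSV file.
#' @inheritParams as_ebm_cohort
#' @return A cohort tibble (see [as_ebm_cohort()]).
#' @examples
#' csv <- system.file("extdata", "example_cohort.csv", package = "kdeebm")
#' read_cohort(csv, label_col = "DX", control_value = "HC", id_col = "id")
#' @export
read_cohort <- function(path,
                        label_col = "label",
                        control_value = "control",
                        id_col = "subject_id",
                        visit_col = "visit",
                        patient_value = NULL) {
  raw <- readr::read_csv(path, na = missing_tokens(),
                         show_col_types = FALSE, progress = FALSE)
  as_ebm_cohort(raw, label_col = label_col, control_value = control_value,
                id_col = id_col, visit_col = visit_col,
                patient_value = patient_value)
}

#' Write a cohort table to CSV
#'
#' Missing scores are written as empty cells, so a read/write/read round
#' trip preserves scores, labels and the missing mask exactly.
#'
#' @inheritParams cohort_biomarkers
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

# N x M numeric score matrix (rows = cohort rows, cols = biomarkers)
score_matrix <- function(cohort, biomarkers = cohort_biomarkers(cohort)) {
  miss <- setdiff(biomarkers, names(cohort))
  if (length(miss) > 0) {
    stop("cohort is missing biomarker column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(cohort[biomarkers])
  storage.mode(m) <- "double"
  m
}
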
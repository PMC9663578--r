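#' Packaged cohort tables
#'
#' The package ships two per-specimen cohort tables transcribed verbatim from
#' the published clinical evaluation of the probe-based FACS assay, plus the
#' accompanying cohort summary:
#'
#' * the surgical cohort -- 23 untreated NSCLC resection specimens with
#'   Sanger mutation status and the three background-corrected labeling
#'   percentages;
#' * the biopsy cohort -- 31 patients with mutation status, first-line
#'   treatment, best RECIST response, and the three labeling percentages
#'   (negative corrected values occur and are preserved);
#' * the cohort summary -- marginal counts by genotype.
#'
#' Values are stored exactly as printed, including mixed significant figures;
#' loaders validate structure and marginal counts on every load and also
#' accept user-supplied CSVs with the same schema.
#'
#' @name cohort_tables
NULL

cohort_file <- function(name) {
  path <- system.file("extdata", name, package = "activeEGFR")
  if (path == "") stop("packaged file '", name, "' not found", call. = FALSE)
  path
}

#' Load the surgical cohort table
#'
#' @param path Optional path to a CSV with the same schema; defaults to the
#'   packaged table.
#' @return A data frame of 23 records: `sample_code`, `sex`, `ajcc_stage`,
#'   `sanger_status` (`L858R`, `19del` or `none`), `ddpcr_status` (non-empty
#'   only for the one sample that is Sanger-negative but ddPCR-positive),
#'   and the three labeling percentages `double_pos_pct`, `egfr_pos_pct`,
#'   `hx103_pos_pct`.
#' @rdname cohort_tables
#' @export
load_surgical <- function(path = NULL) {
  if (is.null(path)) path <- cohort_file("surgical_cohort.csv")
  df <- utils::read.csv(path, colClasses = c(ddpcr_status = "character"))
  need <- c("sample_code", "sex", "ajcc_stage", "sanger_status", "ddpcr_status",
            "double_pos_pct", "egfr_pos_pct", "hx103_pos_pct")
  if (!all(need %in% names(df)))
    stop("surgical cohort schema failure: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (nrow(df) != 23)
    stop("surgical cohort must contain exactly 23 records", call. = FALSE)
  if (!all(df$sanger_status %in% c("L858R", "19del", "none")))
    stop("invalid sanger_status values", call. = FALSE)
  if (sum(df$sanger_status != "none") != 12)
    stop("surgical cohort must contain 12 Sanger-positive records", call. = FALSE)
  pct <- as.matrix(df[, c("double_pos_pct", "egfr_pos_pct", "hx103_pos_pct")])
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100))
    stop("surgical percentages must lie in [0, 100]", call. = FALSE)
  df
}

#' Load the biopsy cohort table
#'
#' @rdname cohort_tables
#' @export
load_biopsy <- function(path = NULL) {
  if (is.null(path)) path <- cohort_file("biopsy_cohort.csv")
  df <- utils::read.csv(path)
  need <- c("patient_no", "mutation", "first_line_treatment", "response",
            "double_pos_pct", "egfr_pos_pct", "hx103_pos_pct")
  if (!all(need %in% names(df)))
    stop("biopsy cohort schema failure: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (nrow(df) != 31)
    stop("biopsy cohort must contain exactly 31 records", call. = FALSE)
  if (!all(df$mutation %in% c("L858R", "19del", "none")))
    stop("invalid mutation values", call. = FALSE)
  if (!all(df$response %in% c("CR", "PR", "SD", "PD", "NE")))
    stop("invalid response values", call. = FALSE)
  if (sum(df$mutation != "none") != 15)
    stop("biopsy cohort must contain 15 mutation-positive records", call. = FALSE)
  pct <- as.matrix(df[, c("double_pos_pct", "egfr_pos_pct", "hx103_pos_pct")])
  if (any(!is.finite(pct)) || any(pct < -100) || any(pct > 100))
    stop("biopsy percentages must lie in [-100, 100]", call. = FALSE)
  ev <- tki_evaluable(df)
  if (sum(ev) != 13)
    stop("expected 13 response-evaluable TKI-treated patients", call. = FALSE)
  if (sum(df$response[ev] %in% c("CR", "PR")) != 9)
    stop("expected 9 TKI responders (CR/PR)", call. = FALSE)
  df
}

#' Load the printed cohort summary
#'
#' @rdname cohort_tables
#' @export
load_cohort_summary <- function(path = NULL) {
  if (is.null(path)) path <- cohort_file("biopsy_cohort_summary.csv")
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("characteristic", "category", "total", "l858r", "del19", "wt")
  if (!all(need %in% names(df)))
    stop("cohort summary schema failure", call. = FALSE)
  df
}

# TKI-treated with an evaluable RECIST response
tki_evaluable <- function(biopsy) {
  biopsy$mutation != "none" & biopsy$response %in% c("CR", "PR", "SD", "PD")
}

pct_column <- function(parameter) {
  cols <- c(double_pos = "double_pos_pct", egfr_pos = "egfr_pos_pct",
            hx103_pos = "hx103_pos_pct")
  if (!parameter %in% names(cols))
    stop("'parameter' must be one of: ", paste(names(cols), collapse = ", "),
         call. = FALSE)
  cols[[parameter]]
}

#' Labeled scores from the cohort tables
#'
#' Convenience extractors turning a cohort data frame into a
#' [labeled_scores()] object for one labeling parameter.
#' `mutation_scores()` labels specimens by activating-mutation status
#' (Sanger for the surgical table, genotype for the biopsy table);
#' `tki_response_scores()` restricts the biopsy table to response-evaluable
#' TKI-treated patients and labels objective responders (CR/PR) positive.
#'
#' @param records A cohort data frame from [load_surgical()] or
#'   [load_biopsy()].
#' @param parameter One of `"double_pos"`, `"egfr_pos"`, `"hx103_pos"`.
#' @return A [labeled_scores()] object.
#' @export
mutation_scores <- function(records, parameter = "double_pos") {
  col <- pct_column(parameter)
  status_col <- if ("sanger_status" %in% names(records)) "sanger_status" else "mutation"
  labeled_scores(records[[col]], records[[status_col]] != "none",
                 parameter_name = parameter)
}

#' @rdname mutation_scores
#' @export
tki_response_scores <- function(records, parameter = "double_pos") {
  col <- pct_column(parameter)
  ev <- tki_evaluable(records)
  labeled_scores(records[[col]][ev], records$response[ev] %in% c("CR", "PR"),
                 parameter_name = parameter)
}

#' Validate the printed cohort summary against the per-patient table
#'
#' Recomputes every cell of the cohort summary that is derivable from the
#' per-patient biopsy table -- genotype counts, the double-positive
#' threshold buckets at 30.1%, TKI-therapy counts and the response
#' categories -- and reports printed versus recomputed values side by side.
#' Known discrepancies (the printed threshold buckets disagree by one
#' patient with a direct count at the 30.1% threshold) are reported, not
#' raised.
#'
#' @param biopsy Biopsy cohort data frame, defaults to [load_biopsy()].
#' @param summary Printed summary, defaults to [load_cohort_summary()].
#' @return A data frame: `characteristic`, `category`, `column`, `printed`,
#'   `recomputed`, `agree`. Cells not derivable from the per-patient table
#'   (age, sex, stage) are omitted.
#' @export
validate_summary <- function(biopsy = load_biopsy(),
                             summary = load_cohort_summary()) {
  groups <- list(total = rep(TRUE, nrow(biopsy)),
                 l858r = biopsy$mutation == "L858R",
                 del19 = biopsy$mutation == "19del",
                 wt = biopsy$mutation == "none")
  ev <- tki_evaluable(biopsy)
  recompute <- function(characteristic, category, g) {
    switch(paste(characteristic, category),
           "patients n" = sum(g),
           "double_pos_bucket ge_30.1" = sum(g & biopsy$double_pos_pct >= 30.1),
           "double_pos_bucket lt_30.1" = sum(g & biopsy$double_pos_pct < 30.1),
           "tki_therapy n" = sum(g & biopsy$mutation != "none"),
           "tki_response CR_PR" = sum(g & ev & biopsy$response %in% c("CR", "PR")),
           "tki_response SD" = sum(g & ev & biopsy$response == "SD"),
           "tki_response PD" = sum(g & ev & biopsy$response == "PD"),
           "tki_response NE" = sum(g & biopsy$mutation != "none" &
                                     biopsy$response == "NE"),
           NA_integer_)
  }
  rows <- list()
  for (i in seq_len(nrow(summary))) {
    for (col in names(groups)) {
      printed <- suppressWarnings(as.integer(summary[[col]][i]))
      if (is.na(printed) && !nzchar(summary[[col]][i])) next  # blank cell
      rec <- recompute(summary$characteristic[i], summary$category[i],
                       groups[[col]])
      if (is.na(rec)) next  # not derivable from the per-patient table

      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = summary$characteristic[i],
        category = summary$category[i], column = col,
        printed = printed, recomputed = rec,
        agree = !is.na(printed) & !is.na(rec) & printed == rec)
    }
  }
  do.call(rbind, rows)
}
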
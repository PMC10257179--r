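# Reading, validating and quality-gating animal-level trial data.

#' Brain area loss percentage from hemisphere section areas
#'
#' Computes the percent tissue loss of the injured (ipsilateral) hemisphere
#' relative to the uninjured (contralateral) hemisphere from one animal's
#' stained sections. Section areas are summed before the ratio is taken, so
#' larger sections carry proportionally more weight:
#' \deqn{100 \times (1 - \sum A_{ipsi} / \sum A_{contra})}
#' Negative values (ipsilateral larger than contralateral, e.g. oedema) are
#' clipped to 0, keeping the outcome in [0, 100].
#'
#' @param ipsilateral numeric vector of ipsilateral section areas (> 0),
#'   one entry per section, arbitrary but consistent units.
#' @param contralateral numeric vector of contralateral section areas (> 0),
#'   same length and units as `ipsilateral`.
#' @return a single percentage in [0, 100].
#' @examples
#' area_loss_percent(c(20, 30), c(40, 40))  # 37.5
#' @export
area_loss_percent <- function(ipsilateral, contralateral) {
  if (length(ipsilateral) < 1L || length(contralateral) < 1L) {
    stopf("area_loss_percent: at least one section measurement is required")
  }
  if (length(ipsilateral) != length(contralateral)) {
    stopf("area_loss_percent: ipsilateral and contralateral must have one area per section")
  }
  areas <- c(ipsilateral, contralateral)
  if (anyNA(areas) || any(!is.finite(areas)) || any(areas <= 0)) {
    stopf("area_loss_percent: all section areas must be finite and strictly positive")
  }
  loss <- 100 * (1 - sum(ipsilateral) / sum(contralateral))
  max(loss, 0)
}

#' Construct a validated trial dataset
#'
#' A `trial_dataset` is a data frame of animal-level records with one row per
#' animal and columns `animal_id`, `experiment_id`, `litter_id`, `treatment`,
#' `sex`, `area_loss_pct`. The control condition carries the reserved
#' treatment label `"control"`. Validation enforces: outcomes in [0, 100],
#' non-empty labels, unique (experiment_id, animal_id) pairs, and at least one
#' control animal in every experiment.
#'
#' @param records data frame with the columns above.
#' @param provenance character vector of free-text provenance notes.
#' @return an object of class `trial_dataset` (a data frame).
#' @export
trial_dataset <- function(records, provenance = character()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  problems <- validate_trial_records(records)
  if (length(problems) > 0L) {
    stopf("invalid trial dataset:\n%s", paste("  -", problems, collapse = "\n"))
  }
  rownames(records) <- NULL
  structure(records,
            provenance = as.character(provenance),
            class = c("trial_dataset", "data.frame"))
}

required_columns <- c("animal_id", "experiment_id", "litter_id",
                      "treatment", "sex", "area_loss_pct")

# Returns a character vector of row-numbered problems; empty if valid.
validate_trial_records <- function(records) {
  problems <- character()
  missing_cols <- setdiff(required_columns, names(records))
  if (length(missing_cols) > 0L) {
    return(sprintf("missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  }
  bad_rows <- function(idx, fmt) {
    if (any(idx)) sprintf(fmt, paste(which(idx), collapse = ", ")) else character()
  }
  y <- records$area_loss_pct
  problems <- c(problems,
    bad_rows(is.na(y) | !is.finite(y), "area_loss_pct missing or non-numeric in row(s): %s"),
    bad_rows(!is.na(y) & is.finite(y) & (y < 0 | y > 100),
             "area_loss_pct outside [0, 100] in row(s): %s"),
    bad_rows(is.na(records$treatment) | !nzchar(records$treatment),
             "empty treatment label in row(s): %s"),
    bad_rows(is.na(records$experiment_id) | !nzchar(records$experiment_id),
             "empty experiment_id in row(s): %s"),
    bad_rows(!records$sex %in% c("male", "female", "unknown"),
             "sex not one of male/female/unknown in row(s): %s"))
  key <- paste(records$experiment_id, records$animal_id, sep = "\r")
  problems <- c(problems,
    bad_rows(duplicated(key), "duplicate (experiment_id, animal_id) in row(s): %s"))
  has_ctrl <- tapply(records$treatment == "control", records$experiment_id, any)
  no_ctrl <- names(has_ctrl)[!has_ctrl]
  if (length(no_ctrl) > 0L) {
    problems <- c(problems, sprintf("experiment(s) without a control group: %s",
                                    paste(no_ctrl, collapse = ", ")))
  }
  problems
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("trial_dataset: %d animals, %d experiments, %d treatments (+control)\n",
              nrow(x), length(unique(x$experiment_id)),
              length(setdiff(unique(x$treatment), "control"))))
  prov <- attr(x, "provenance")
  if (length(prov) > 0L) cat(paste0("  ", prov, collapse = "\n"), "\n")
  invisible(x)
}

#' Read a trial dataset from CSV
#'
#' Reads animal-level records from a comma-separated file (UTF-8, dot decimal
#' separator, mandatory header). If `area_loss_pct` is absent but paired
#' hemisphere-area columns are present (`ipsi_area_s1`, `contra_area_s1`,
#' optionally `_s2`, `_s3`, ...), the loss percentage is derived per animal
#' with [area_loss_percent()]. Treatment labels matching `control_aliases`
#' (case-insensitively) are renamed to the internal label `"control"`.
#'
#' @param path path to the CSV file.
#' @param column_map optional named character vector mapping the internal
#'   column names to the names used in the file, e.g.
#'   `c(animal_id = "rat", treatment = "group")`.
#' @param control_aliases treatment labels to be treated as control.
#' @return a validated [trial_dataset()].
#' @export
read_trial_csv <- function(path,
                           column_map = NULL,
                           control_aliases = c("control", "HI/saline", "saline")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (internal in names(column_map)) {
      ext <- column_map[[internal]]
      if (!ext %in% names(raw)) stopf("mapped column '%s' not found in %s", ext, path)
      names(raw)[names(raw) == ext] <- internal
    }
  }
  if (!"area_loss_pct" %in% names(raw)) {
    ipsi_cols <- grep("^ipsi_area_s[0-9]+$", names(raw), value = TRUE)
    contra_cols <- grep("^contra_area_s[0-9]+$", names(raw), value = TRUE)
    if (length(ipsi_cols) == 0L || length(ipsi_cols) != length(contra_cols)) {
      stopf("%s: need either an area_loss_pct column or matched ipsi_area_s*/contra_area_s* columns", path)
    }
    ipsi_cols <- sort(ipsi_cols); contra_cols <- sort(contra_cols)
    raw$area_loss_pct <- vapply(seq_len(nrow(raw)), function(r) {
      tryCatch(area_loss_percent(as.numeric(raw[r, ipsi_cols]),
                                 as.numeric(raw[r, contra_cols])),
               error = function(e) stopf("row %d: %s", r, conditionMessage(e)))
    }, numeric(1))
  }
  missing_cols <- setdiff(required_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stopf("%s: missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  raw <- raw[required_columns]
  for (col in c("animal_id", "experiment_id", "litter_id", "treatment", "sex")) {
    raw[[col]] <- as.character(raw[[col]])
  }
  raw$area_loss_pct <- as.numeric(raw$area_loss_pct)
  is_ctrl <- tolower(raw$treatment) %in% tolower(control_aliases)
  raw$treatment[is_ctrl] <- "control"
  trial_dataset(raw, provenance = sprintf("loaded from %s (%d rows)", path, nrow(raw)))
}

#' Quality-control gate on control-group injury severity
#'
#' Retains only experiments whose control-group median area loss lies in the
#' moderate-injury window (closed interval `[lower, upper]`, default
#' [35, 50] percent); experiments below or above the window are removed in
#' their entirety (all arms). The median uses the standard convention (mean of
#' the two central order statistics for even n).
#'
#' @param dataset a [trial_dataset()].
#' @param lower,upper bounds of the retained window, percent.
#' @return a list with elements `dataset` (the filtered [trial_dataset()]) and
#'   `report` (a `qc_report` data frame: one row per input experiment with its
#'   control median, control n and verdict `retained` / `excluded_low` /
#'   `excluded_high`).
#' @export
qc_filter <- function(dataset, lower = 35, upper = 50) {
  stopifnot(inherits(dataset, "trial_dataset"))
  ctrl <- dataset[dataset$treatment == "control", , drop = FALSE]
  exps <- unique(dataset$experiment_id)
  med <- vapply(exps, function(e)
    stats::median(ctrl$area_loss_pct[ctrl$experiment_id == e]), numeric(1))
  n_ctrl <- vapply(exps, function(e)
    sum(ctrl$experiment_id == e), integer(1))
  verdict <- ifelse(med < lower, "excluded_low",
                    ifelse(med > upper, "excluded_high", "retained"))
  report <- data.frame(experiment_id = exps,
                       control_median = med,
                       control_n = n_ctrl,
                       verdict = verdict,
                       row.names = NULL,
                       stringsAsFactors = FALSE)
  class(report) <- c("qc_report", "data.frame")
  keep <- exps[verdict == "retained"]
  if (length(keep) == 0L) {
    stopf("qc_filter: no experiment has a control median within [%g, %g]", lower, upper)
  }
  filtered <- dataset[dataset$experiment_id %in% keep, , drop = FALSE]
  out <- trial_dataset(
    filtered,
    provenance = c(attr(dataset, "provenance"),
                   sprintf("qc_filter: retained %d of %d experiments (control median in [%g, %g])",
                           length(keep), length(exps), lower, upper)))
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  n_excl <- sum(x$verdict != "retained")
  cat(sprintf("qc_report: %d experiments, %d excluded\n", nrow(x), n_excl))
  print.data.frame(x, ...)
  invisible(x)
}
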
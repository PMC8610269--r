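# Clinical definitions: analysis-set exclusions, response classification,
# overall survival, and long/short survivor grouping.

DAYS_PER_MONTH <- 30.4375

#' Restrict clinical records to the analysis set
#'
#' Tumor cases are retained when serous, chemo-naive (no neoadjuvant
#' chemotherapy before surgery) and sampled from primary (not recurrent)
#' tissue. Benign (non-tumor) records pass through untouched. Exclusion
#' counts per reason are attached as the `"exclusions"` attribute and
#' reported via `message()`. The three filters commute, so application
#' order is irrelevant.
#'
#' @param records Clinical data frame with columns `histology`,
#'   `neoadjuvant`, `recurrent_tissue` and (optionally) logical `tumor`.
#' @param quiet Suppress the exclusion-count message.
#' @return The retained records, with an `"exclusions"` attribute.
#' @export
filter_analysis_set <- function(records, quiet = FALSE) {
  col <- function(nm, default) {
    if (nm %in% names(records)) records[[nm]] else rep(default, nrow(records))
  }
  is_tumor <- col("tumor", TRUE) %in% TRUE
  # a record can only be excluded on evidence; absent columns exclude nobody
  hist_col <- col("histology", "serous")
  non_serous <- is_tumor & !is.na(hist_col) & !(hist_col %in% "serous")
  neoadj <- is_tumor & col("neoadjuvant", FALSE) %in% TRUE
  recurrent <- is_tumor & col("recurrent_tissue", FALSE) %in% TRUE
  drop <- non_serous | neoadj | recurrent
  excl <- c(non_serous = sum(non_serous), neoadjuvant = sum(neoadj),
            recurrent_tissue = sum(recurrent), total_excluded = sum(drop))
  if (!quiet)
    message(sprintf(
      "excluded %d of %d tumor cases (non-serous %d, neoadjuvant %d, recurrent tissue %d)",
      sum(drop), sum(is_tumor), excl[1], excl[2], excl[3]))
  out <- records[!drop, , drop = FALSE]
  attr(out, "exclusions") <- excl
  out
}

#' Classify response to first-line platinum chemotherapy
#'
#' Complete responders (CR) had complete disappearance of all measurable
#' disease sustained at least 4 weeks after first-line platinum therapy, or
#' — in the absence of measurable lesions — normalization of CA-125 for at
#' least 4 weeks. Incomplete responders (IR) had a partial response (>= 50%
#' reduction in tumor burden, or a CA-125 drop > 50% without
#' normalization), stable disease, or progression during adjuvant therapy.
#' Returns `NA` when the determining fields are missing.
#'
#' @param records Clinical data frame with columns `measurable_disease`,
#'   `lesion_response` (`complete`/`partial`/`stable`/`progression`/`NA`),
#'   `ca125_normalized_4wk`, `ca125_drop_gt50_4wk`.
#' @return Character vector `"CR"`/`"IR"`/`NA`, one per record.
#' @export
classify_response <- function(records) {
  contradiction <- records$ca125_normalized_4wk %in% TRUE &
    records$lesion_response %in% "progression"
  if (any(contradiction))
    stop("contradictory response fields (CA-125 normalized with ",
         "progressive disease) for subject(s) ",
         paste(records$subject_id[contradiction], collapse = ", "),
         call. = FALSE)
  n <- nrow(records)
  out <- rep(NA_character_, n)
  measurable <- records$measurable_disease %in% TRUE
  lr <- records$lesion_response
  out[measurable & lr %in% "complete"] <- "CR"
  out[measurable & lr %in% c("partial", "stable", "progression")] <- "IR"
  # no measurable lesion: CA-125 rules
  nm <- records$measurable_disease %in% FALSE
  out[nm & records$ca125_normalized_4wk %in% TRUE] <- "CR"
  out[nm & is.na(out) & records$ca125_normalized_4wk %in% FALSE &
        records$ca125_drop_gt50_4wk %in% TRUE] <- "IR"
  # progression recorded without measurable-disease info still counts as IR
  out[is.na(out) & lr %in% "progression"] <- "IR"
  out
}

#' Compute overall survival from diagnosis and follow-up dates
#'
#' Overall survival is the time from the date of diagnosis to death or last
#' contact, in months (30.4375 days per month); the event flag is 1 for
#' death, 0 for censoring at last contact.
#'
#' @param records Clinical data frame with `dx_date`,
#'   `last_contact_or_death_date` (Dates or parseable strings) and
#'   `vital_status` (`"dead"`/`"alive"`).
#' @return Data frame with columns `os_months` and `os_event`.
#' @export
compute_os <- function(records) {
  dx <- as.Date(records$dx_date)
  last <- as.Date(records$last_contact_or_death_date)
  if (any(!is.na(dx) & !is.na(last) & last < dx))
    stop("death/last-contact date precedes diagnosis date", call. = FALSE)
  months <- as.numeric(difftime(last, dx, units = "days")) / DAYS_PER_MONTH
  data.frame(os_months = months,
             os_event = as.integer(records$vital_status %in% "dead"))
}

#' Assign long-term / short-term survivor groups
#'
#' Long-term survivors lived more than 60 months after diagnosis (dead or
#' alive); short-term survivors died within 36 months. Cases with follow-up
#' under 36 months while alive, or death between 36 and 60 months, belong
#' to neither group and are `"excluded"`. Vectorized.
#'
#' @param os_months Overall survival in months.
#' @param os_event 1 = dead, 0 = censored alive.
#' @return Character vector `"long"`/`"short"`/`"excluded"`.
#' @export
assign_survival_group <- function(os_months, os_event) {
  if (any(os_months < 0, na.rm = TRUE))
    stop("os_months must be >= 0", call. = FALSE)
  out <- rep("excluded", length(os_months))
  out[os_months > 60] <- "long"
  out[os_event == 1 & os_months <= 36] <- "short"
  out[is.na(os_months)] <- NA_character_
  out
}

#' Derive all clinical annotations in one pass
#'
#' Applies the analysis-set filter, response classification, overall
#' survival and survivor grouping, plus the age dichotomy (<= 65 vs > 65
#' years), the stage dichotomy (early I/II vs advanced III/IV) and tumor
#' vs benign tissue classes.
#'
#' @param records Raw clinical data frame (see [generate_cohort()] for the
#'   column contract).
#' @param quiet Passed to [filter_analysis_set()].
#' @return Annotated, filtered clinical data frame with added columns
#'   `response`, `os_months`, `os_event`, `survival_group`, `age_group`,
#'   `stage_group`.
#' @export
annotate_clinical <- function(records, quiet = FALSE) {
  records <- filter_analysis_set(records, quiet = quiet)
  # degrade gracefully: derive only what the available columns support
  if (!"response" %in% names(records) &&
      all(c("measurable_disease", "lesion_response", "ca125_normalized_4wk",
            "ca125_drop_gt50_4wk") %in% names(records)))
    records$response <- classify_response(records)
  if (!all(c("os_months", "os_event") %in% names(records)) &&
      all(c("dx_date", "last_contact_or_death_date", "vital_status") %in%
            names(records))) {
    os <- compute_os(records)
    records$os_months <- os$os_months
    records$os_event <- os$os_event
  }
  if (all(c("os_months", "os_event") %in% names(records)))
    records$survival_group <- assign_survival_group(records$os_months,
                                                    records$os_event)
  if ("age_dx" %in% names(records))
    records$age_group <- ifelse(records$age_dx <= 65, "<=65", ">65")
  if ("stage" %in% names(records))
    records$stage_group <- ifelse(is.na(records$stage), NA_character_,
                                  ifelse(records$stage %in% c("I", "II"),
                                         "early", "advanced"))
  records
}

#' Read a clinical table from delimited text or spreadsheet
#'
#' Reads CSV/TSV natively and XLS/XLSX via the readxl package when
#' installed. An optional column mapping renames file columns to the
#' package's canonical clinical column names.
#'
#' @param path File path (`.csv`, `.tsv`/`.txt`, `.xls`, `.xlsx`).
#' @param mapping Named character vector: `canonical_name = "file column"`.
#'   Columns not mentioned are kept under their original names.
#' @param sheet Sheet index/name for spreadsheets.
#' @return Data frame.
#' @export
read_clinical_table <- function(path, mapping = NULL, sheet = 1) {
  if (!file.exists(path))
    stop("clinical table not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    tsv = ,
    txt = utils::read.delim(path, stringsAsFactors = FALSE),
    xls = ,
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading ", ext, " files requires the readxl package",
             call. = FALSE)
      as.data.frame(readxl::read_excel(path, sheet = sheet))
    },
    stop("unsupported clinical table format: .", ext, call. = FALSE))
  if (!is.null(mapping)) {
    missing_cols <- setdiff(unname(mapping), names(tab))
    if (length(missing_cols))
      stop("mapped column(s) absent from ", basename(path), ": ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    for (canonical in names(mapping))
      names(tab)[names(tab) == mapping[[canonical]]] <- canonical
  }
  tab
}
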
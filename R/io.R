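## Delimited-text persistence for cohort tables and configs.
## One header row, tab-separated, ISO-8601 dates, empty string = missing.

COHORT_TABLE_NAMES <- c("participants", "visits", "ehr_events",
                        "healthcare_counts")

write_table_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (inherits(out[[j]], "Date")) out[[j]] <- format(out[[j]], "%Y-%m-%d")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_table_tsv <- function(path, date_cols = character()) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "", colClasses = NA)
  for (cl in intersect(date_cols, names(df))) df[[cl]] <- as.Date(df[[cl]])
  ## delimited text drops the distinction between "" and NA for answers;
  ## restore "" = missing convention for character columns read as NA
  df
}

#' Write cohort tables as delimited text
#'
#' Writes the four observable tables (and, optionally, the latent-truth
#' sidecar) as tab-separated text with one header row, ISO-8601 dates and
#' empty strings for missing values, plus the generator configuration as a
#' YAML file.
#'
#' @param tables a `cohort_tables` object.
#' @param dir output directory (created if absent).
#' @param include_truth also write the latent-truth sidecar (off by default:
#'   analyses must never see it).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(tables, dir, include_truth = FALSE) {
  stopifnot(inherits(tables, "cohort_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in COHORT_TABLE_NAMES) {
    write_table_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  if (include_truth) {
    write_table_tsv(tables$truth, file.path(dir, "truth.tsv"))
  }
  cfg <- tables$config
  cfg_out <- lapply(unclass(cfg), function(v) {
    if (inherits(v, "Date")) format(v) else v
  })
  ## write effect vectors as maps so their names survive the YAML round trip
  cfg_out$covariate_effect_vector <-
    lapply(cfg_out$covariate_effect_vector, as.list)
  yaml::write_yaml(cfg_out, file.path(dir, "generator_config.yaml"))
  invisible(dir)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir directory containing the `.tsv` tables.
#' @return A `cohort_tables` object (with an empty truth sidecar unless
#'   `truth.tsv` is present).
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, paste0(COHORT_TABLE_NAMES, ".tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stopf("missing cohort table file(s): %s", paste(missing, collapse = ", "))
  }
  out <- list(
    participants = read_table_tsv(need[1], c("birth_ym", "death_date")),
    visits = read_table_tsv(need[2], "visit_date"),
    ehr_events = read_table_tsv(need[3], "event_date"),
    healthcare_counts = read_table_tsv(need[4])
  )
  for (cl in c("sr_hearing_difficulty", "sr_background_noise", "sr_ha_use",
               "sr_cochlear_implant")) {
    if (cl %in% names(out$visits)) {
      out$visits[[cl]][is.na(out$visits[[cl]])] <- ""
    }
  }
  tpath <- file.path(dir, "truth.tsv")
  out$truth <- if (file.exists(tpath)) {
    read_table_tsv(tpath, c("true_onset", "recordable_onset", "recorded_hl",
                            "ha_date", "dementia_date_control",
                            "dementia_date_treated", "dementia_date_actual"))
  } else {
    empty_cohort_tables(generator_config(n_participants = 0))$truth
  }
  cpath <- file.path(dir, "generator_config.yaml")
  out$config <- if (file.exists(cpath)) {
    raw <- yaml::read_yaml(cpath)
    raw$pattern <- NULL
    if (!is.null(raw$covariate_effect_vector)) {
      raw$covariate_effect_vector <-
        lapply(raw$covariate_effect_vector, function(v) unlist(v))
    }
    do.call(generator_config, raw[names(raw) %in% names(formals(generator_config))])
  } else {
    generator_config(n_participants = nrow(out$participants))
  }
  class(out) <- "cohort_tables"
  out
}
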
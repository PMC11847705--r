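#' @title Cohort containers and OMOP-like event I/O
#' @name cohort_io
#' @description Readers for delimited OMOP-like event tables, the two
#'   observation-window rules (pregnancy-anchored and diagnosis/sampling
#'   anchored), and assembly of pretraining/omics cohorts. All dates are
#'   handled as integer day offsets from an arbitrary epoch; observation
#'   windows are closed intervals on whole days.
NULL

OMOP_TABLES <- c("measurement", "observation", "drug_exposure",
                 "condition_occurrence", "procedure_occurrence")

new_comet_cohort <- function(records, task, analytes = NULL, manifest = list()) {
  names(records) <- vapply(records, `[[`, "", "record_id")
  structure(list(records = records, task = task, analytes = analytes,
                 manifest = manifest),
            class = "comet_cohort")
}

#' @export
print.comet_cohort <- function(x, ...) {
  ct <- cohort_table(x)
  cat(sprintf("comet_cohort: %d records, %d patients (%s outcome)\n",
              length(x$records), length(unique(ct$patient_id)), x$task))
  for (g in unique(ct$cohort)) {
    cat(sprintf("  %-12s %5d records, %5d patients\n", g,
                sum(ct$cohort == g), length(unique(ct$patient_id[ct$cohort == g]))))
  }
  if (!is.null(x$analytes)) {
    cat(sprintf("  %d analytes: %s ...\n", length(x$analytes),
                paste(head(x$analytes, 3), collapse = ", ")))
  }
  invisible(x)
}

# flat record-level summary used by print/split/subset helpers
cohort_table <- function(cohort) {
  data.frame(
    record_id = vapply(cohort$records, `[[`, "", "record_id"),
    patient_id = vapply(cohort$records, `[[`, "", "patient_id"),
    cohort = vapply(cohort$records, `[[`, "", "cohort"),
    outcome = vapply(cohort$records, function(r) as.numeric(r$outcome), 0),
    n_events = vapply(cohort$records, function(r) nrow(r$events), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Subset a cohort by cohort flag or record ids
#'
#' @param cohort A `comet_cohort`.
#' @param which `"pretraining"`, `"omics"`, or a character vector of record ids.
#' @return A `comet_cohort` with the selected records.
#' @export
cohort_subset <- function(cohort, which) {
  recs <- cohort$records
  keep <- if (length(which) == 1 && which %in% c("pretraining", "omics")) {
    vapply(recs, function(r) r$cohort == which, TRUE)
  } else {
    names(recs) %in% which
  }
  new_comet_cohort(recs[keep], task = cohort$task, analytes = cohort$analytes,
                   manifest = cohort$manifest)
}

#' Read an OMOP-like event table
#'
#' Expects columns `patient_id`, `concept_id`, `date`, `source_table`
#' (comma- or tab-delimited, chosen by file extension). Rows with
#' `concept_id == 0` are removed; rows whose `source_table` is not one of the
#' five supported OMOP tables (measurement, observation, drug_exposure,
#' condition_occurrence, procedure_occurrence) are dropped with a warning.
#' Dates may be ISO dates or plain integer day offsets.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A data.frame of events with `date` as integer days.
#' @export
load_events <- function(path) {
  df <- read_delim_auto(path)
  required <- c("patient_id", "concept_id", "date", "source_table")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("load_events: missing column(s): %s", paste(missing, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  df$concept_id <- as.character(df$concept_id)
  df$date <- parse_day(df$date, path)
  drop0 <- df$concept_id == "0"
  df <- df[!drop0, , drop = FALSE]
  bad_table <- !(df$source_table %in% OMOP_TABLES)
  if (any(bad_table)) {
    warnf("load_events: dropped %d row(s) from unsupported source table(s): %s",
          sum(bad_table),
          paste(unique(df$source_table[bad_table]), collapse = ", "))
    df <- df[!bad_table, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

read_delim_auto <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") read.csv(path, stringsAsFactors = FALSE)
  else read.delim(path, stringsAsFactors = FALSE)
}

parse_day <- function(x, path = "<input>") {
  if (is.numeric(x)) return(as.integer(x))
  suppress <- suppressWarnings
  num <- suppress(as.numeric(x))
  if (!anyNA(num)) return(as.integer(num))
  d <- suppress(as.Date(as.character(x), format = "%Y-%m-%d"))
  bad <- which(is.na(d) & !is.na(x))
  if (length(bad)) {
    stopf("%s: unparseable date(s) at data row(s) %s (e.g. '%s')",
          path, paste(head(bad, 5), collapse = ", "), x[bad[1]])
  }
  as.integer(d)
}

#' Observation window for the pregnancy task
#'
#' The window starts at the beginning of pregnancy, defined as 280 days
#' before childbirth. For omics-cohort patients it ends at the omics
#' sampling date; for pretraining-cohort patients (who have no sampling
#' date) it ends at a random date drawn uniformly on whole days between
#' childbirth and up to 100 days prior, mimicking the sampling design.
#'
#' @param delivery_date Integer day of childbirth (vectorised).
#' @param cohort `"omics"` or `"pretraining"`.
#' @param sampling_date Integer day of omics sampling (omics cohort).
#' @param seed Seed for the pretraining-cohort random cut-off.
#' @return A matrix with columns `start`, `end`, one row per patient.
#' @export
pregnancy_window <- function(delivery_date, cohort = c("omics", "pretraining"),
                             sampling_date = NULL, seed = NULL) {
  cohort <- match.arg(cohort)
  start <- delivery_date - 280L
  if (cohort == "omics") {
    if (is.null(sampling_date)) {
      stopf("pregnancy_window: omics cohort requires a sampling_date")
    }
    if (any(sampling_date < start)) {
      stopf("pregnancy_window: sampling_date precedes the start of pregnancy")
    }
    end <- sampling_date
  } else {
    end <- with_seed(seed, {
      delivery_date - (sample.int(101L, length(delivery_date),
                                  replace = TRUE) - 1L)
    })
  }
  cbind(start = as.integer(start), end = as.integer(end))
}

#' Observation window for the cancer task
#'
#' All history is retained (unbounded past); the window ends at the omics
#' sampling date for omics-cohort patients and at the date of first cancer
#' diagnosis for pretraining-cohort patients. Identifying the diagnosis
#' date (first ICD10 code starting with "C") is the caller's concern when
#' preparing anchors.
#'
#' @param cohort `"omics"` or `"pretraining"`.
#' @param sampling_date Integer sampling day (omics cohort).
#' @param diagnosis_date Integer diagnosis day (pretraining cohort).
#' @return A matrix with columns `start` (`-Inf`) and `end`.
#' @export
cancer_window <- function(cohort = c("omics", "pretraining"),
                          sampling_date = NULL, diagnosis_date = NULL) {
  cohort <- match.arg(cohort)
  end <- if (cohort == "omics") sampling_date else diagnosis_date
  if (is.null(end)) {
    stopf("cancer_window: no anchor date available for the %s cohort", cohort)
  }
  cbind(start = rep(-Inf, length(end)), end = as.numeric(end))
}

#' Assemble pretraining and omics cohorts from event and anchor tables
#'
#' Splits patients into the omics cohort (those with at least one omics
#' sample) and the pretraining cohort, computes per-record observation
#' windows with the task's rule, restricts events to the window, and
#' attaches outcomes: days from the window end to delivery for the
#' pregnancy task, or a supplied binary label (e.g. 3-year mortality) for
#' the cancer task. A patient with multiple omics samples contributes one
#' record per sample, all sharing the patient id. Patients whose window
#' contains no events are retained with an empty event set (a warning
#' reports the count): dropping them would silently change cohort
#' composition.
#'
#' @param events Event data.frame as returned by [load_events()].
#' @param anchors Data.frame with `patient_id` plus `delivery_date`
#'   (pregnancy) or `diagnosis_date` (cancer), integer days.
#' @param omics Data.frame with `sample_id`, `patient_id`, `sampling_date`,
#'   then one column per analyte; `NULL` for an EHR-only assembly.
#' @param outcomes For the cancer task, a data.frame with `patient_id` and
#'   a binary `outcome` column; ignored for the pregnancy task.
#' @param task `"pregnancy"` or `"cancer"`.
#' @param seed Seed for the pregnancy pretraining-window draw.
#' @return A `comet_cohort`.
#' @export
assemble_cohort <- function(events, anchors, omics = NULL, outcomes = NULL,
                            task = c("pregnancy", "cancer"), seed = 1) {
  task <- match.arg(task)
  anchors$patient_id <- as.character(anchors$patient_id)
  events$patient_id <- as.character(events$patient_id)
  code_col <- if ("concept_id" %in% names(events)) "concept_id" else "code"
  day_col <- if ("date" %in% names(events)) "date" else "day"

  omics_pat <- character(0)
  analytes <- NULL
  if (!is.null(omics)) {
    omics$patient_id <- as.character(omics$patient_id)
    unknown <- setdiff(omics$patient_id, anchors$patient_id)
    if (length(unknown)) {
      stopf("assemble_cohort: omics sample(s) with no matching patient: %s",
            paste(unique(unknown), collapse = ", "))
    }
    omics_pat <- unique(omics$patient_id)
    analytes <- setdiff(names(omics), c("sample_id", "patient_id", "sampling_date"))
  }

  ev_split <- split(events[, c(day_col, code_col)], events$patient_id)
  outcome_map <- NULL
  if (task == "cancer") {
    if (is.null(outcomes)) stopf("assemble_cohort: cancer task needs outcomes")
    outcome_map <- stats::setNames(outcomes$outcome,
                                   as.character(outcomes$patient_id))
  }

  records <- list()
  n_empty <- 0L
  pretrain_ids <- setdiff(anchors$patient_id, omics_pat)
  # pretraining-cohort windows are drawn in one seeded batch for determinism
  if (length(pretrain_ids)) {
    arow <- anchors[match(pretrain_ids, anchors$patient_id), , drop = FALSE]
    win <- if (task == "pregnancy") {
      pregnancy_window(arow$delivery_date, "pretraining", seed = seed)
    } else {
      cancer_window("pretraining", diagnosis_date = arow$diagnosis_date)
    }
    for (j in seq_along(pretrain_ids)) {
      pid <- pretrain_ids[j]
      ev <- windowed_events(ev_split[[pid]], day_col, code_col,
                            win[j, "start"], win[j, "end"])
      if (nrow(ev) == 0L) n_empty <- n_empty + 1L
      y <- if (task == "pregnancy") unname(arow$delivery_date[j] - win[j, "end"])
           else unname(outcome_map[pid])
      records[[length(records) + 1L]] <- list(
        record_id = pid, patient_id = pid, cohort = "pretraining",
        window = unname(win[j, ]), events = ev, omics = NULL, outcome = y)
    }
  }
  if (!is.null(omics)) {
    for (j in seq_len(nrow(omics))) {
      pid <- omics$patient_id[j]
      arow <- anchors[match(pid, anchors$patient_id), , drop = FALSE]
      win <- if (task == "pregnancy") {
        pregnancy_window(arow$delivery_date, "omics",
                         sampling_date = omics$sampling_date[j])
      } else {
        cancer_window("omics", sampling_date = omics$sampling_date[j])
      }
      ev <- windowed_events(ev_split[[pid]], day_col, code_col,
                            win[1, "start"], win[1, "end"])
      if (nrow(ev) == 0L) n_empty <- n_empty + 1L
      y <- if (task == "pregnancy") unname(arow$delivery_date[1] - win[1, "end"])
           else unname(outcome_map[pid])
      x <- as.numeric(omics[j, analytes])
      names(x) <- analytes
      records[[length(records) + 1L]] <- list(
        record_id = as.character(omics$sample_id[j]), patient_id = pid,
        cohort = "omics", window = unname(win[1, ]), events = ev,
        omics = x, outcome = y)
    }
  }
  if (n_empty > 0L) {
    warnf("assemble_cohort: %d record(s) have no events inside their window",
          n_empty)
  }
  new_comet_cohort(records,
                   task = if (task == "pregnancy") "continuous" else "binary",
                   analytes = analytes,
                   manifest = list(task = task, seed = seed,
                                   n_patients = nrow(anchors)))
}

windowed_events <- function(ev, day_col, code_col, start, end) {
  if (is.null(ev) || nrow(ev) == 0L) {
    return(data.frame(day = integer(0), code = character(0),
                      stringsAsFactors = FALSE))
  }
  keep <- ev[[day_col]] >= start & ev[[day_col]] <= end
  out <- data.frame(day = as.integer(ev[[day_col]][keep]),
                    code = as.character(ev[[code_col]][keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$day, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a cohort bundle
#'
#' A bundle is a directory of plain-text tables (`records.tsv`,
#' `events.tsv`, optionally `omics.tsv`) plus a JSON `manifest.json`
#' carrying record counts and the windowing seed.
#'
#' @param cohort A `comet_cohort`.
#' @param dir Directory to write to (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a
#'   `comet_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ct <- cohort_table(cohort)
  ct$window_start <- vapply(cohort$records, function(r) r$window[1], 0)
  ct$window_end <- vapply(cohort$records, function(r) r$window[2], 0)
  write.table(ct, file.path(dir, "records.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  ev <- do.call(rbind, lapply(cohort$records, function(r) {
    if (nrow(r$events) == 0L) return(NULL)
    cbind(record_id = r$record_id, r$events)
  }))
  write.table(ev %||% data.frame(record_id = character(0), day = integer(0),
                                 code = character(0)),
              file.path(dir, "events.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  om <- Filter(function(r) !is.null(r$omics), cohort$records)
  if (length(om)) {
    mat <- do.call(rbind, lapply(om, `[[`, "omics"))
    df <- data.frame(record_id = vapply(om, `[[`, "", "record_id"), mat,
                     check.names = FALSE)
    write.table(df, file.path(dir, "omics.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  manifest <- c(cohort$manifest,
                list(task = cohort$task, n_records = length(cohort$records)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ct <- read.delim(file.path(dir, "records.tsv"), stringsAsFactors = FALSE)
  ct$record_id <- as.character(ct$record_id)
  ct$patient_id <- as.character(ct$patient_id)
  ev <- read.delim(file.path(dir, "events.tsv"), stringsAsFactors = FALSE)
  ev$record_id <- as.character(ev$record_id)
  ev$code <- as.character(ev$code)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  om_path <- file.path(dir, "omics.tsv")
  om <- NULL
  if (file.exists(om_path)) {
    om <- read.delim(om_path, stringsAsFactors = FALSE, check.names = FALSE)
    rownames(om) <- as.character(om$record_id)
  }
  ev_split <- split(ev[, c("day", "code")], ev$record_id)
  analytes <- if (!is.null(om)) setdiff(names(om), "record_id") else NULL
  records <- lapply(seq_len(nrow(ct)), function(i) {
    rid <- ct$record_id[i]
    e <- ev_split[[rid]]
    if (is.null(e)) e <- data.frame(day = integer(0), code = character(0))
    rownames(e) <- NULL
    x <- NULL
    if (!is.null(om) && rid %in% rownames(om)) {
      x <- as.numeric(om[rid, analytes])
      names(x) <- analytes
    }
    list(record_id = rid, patient_id = ct$patient_id[i],
         cohort = ct$cohort[i],
         window = c(ct$window_start[i], ct$window_end[i]),
         events = e, omics = x, outcome = ct$outcome[i])
  })
  new_comet_cohort(records, task = manifest$task, analytes = analytes,
                   manifest = manifest[setdiff(names(manifest),
                                               c("task", "n_records"))])
}
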
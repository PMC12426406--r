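#' Event-record datasets
#'
#' Estimation input follows a NONMEM-like event-record dialect: one row per
#' dose or observation with columns
#' `ID`, `TIME` (h), `AMT` (mg, dose rows), `DUR` (h, infusion duration),
#' `DV` (mg/L, observation rows), `EVID` (1 dose / 0 observation), `MDV`
#' (1 if `DV` missing), `OCC` (occasion index) and the covariate columns
#' `SEX`, `AGE` (years), `GAGE` (weeks), `WT` (kg), `HT` (cm), `FFM` (kg),
#' `GST` (nmol/min/mL). Missing numeric fields are `NA` (serialised as
#' empty fields in CSV). Concentrations are always mg/L.
#'
#' @param df data.frame with the columns above.
#' @return object of class `pk_dataset` (a validated data.frame).
#' @export
as_dataset <- function(df) {
  req <- c("ID", "TIME", "AMT", "DUR", "DV", "EVID", "MDV", "OCC",
           "SEX", "AGE", "GAGE", "WT", "HT", "FFM", "GST")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing dataset columns: ", paste(miss, collapse = ", "))
  if (any(df$TIME < 0)) stop("times must be non-negative")
  dose <- df$EVID == 1
  if (any(dose & (is.na(df$AMT) | df$AMT <= 0)))
    stop("dose rows must have AMT > 0")
  if (any(dose & !is.na(df$DV))) stop("dose rows must not carry DV")
  obs <- df$EVID == 0 & df$MDV == 0
  if (any(obs & (is.na(df$DV) | df$DV < 0)))
    stop("observation rows must have DV >= 0")
  for (id in unique(df$ID)) {
    tt <- df$TIME[df$ID == id]
    if (is.unsorted(tt)) stop("times must be non-decreasing within subject ", id)
  }
  class(df) <- c("pk_dataset", "data.frame")
  df
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("<pk_dataset> %d subjects, %d dose rows, %d observations\n",
              length(unique(x$ID)), sum(x$EVID == 1),
              sum(x$EVID == 0 & x$MDV == 0)))
  NextMethod()
}

#' Write an event-record dataset to delimited text
#'
#' Comma-separated, dot decimal; concentrations in mg/L.
#'
#' @param dataset a `pk_dataset`.
#' @param path output file.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an event-record dataset from delimited text
#'
#' @param path CSV file written by [write_dataset()] (or hand-built with the
#'   same columns).
#' @return a `pk_dataset`.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(names(df), c("ID", "SEX"))
  for (nm in num) df[[nm]] <- as.numeric(df[[nm]])
  df$ID <- as.character(df$ID)
  as_dataset(df)
}

# rebuild subject_covariates from the covariate columns of one subject
subject_from_rows <- function(rows) {
  r <- rows[1, ]
  subject_covariates(id = r$ID, sex = r$SEX, postnatal_age = r$AGE,
                     wt = r$WT, ht = r$HT, gestational_age = r$GAGE,
                     ffm = r$FFM, gst = r$GST)
}

# split a dataset into the per-subject pieces the estimator consumes
split_subjects <- function(dataset, occ_breaks) {
  ids <- unique(dataset$ID)
  lapply(ids, function(id) {
    rows <- dataset[dataset$ID == id, , drop = FALSE]
    dose <- rows[rows$EVID == 1, , drop = FALSE]
    obs <- rows[rows$EVID == 0 & rows$MDV == 0, , drop = FALSE]
    list(id = id,
         cov = subject_from_rows(rows),
         d_start = dose$TIME, d_dur = dose$DUR, d_amt = dose$AMT,
         obs_times = obs$TIME, dv = obs$DV,
         occ = findInterval(obs$TIME, occ_breaks, left.open = TRUE) + 1)
  })
}

#' Assemble event records for one subject
#'
#' @param cov [subject_covariates()].
#' @param regimen data.frame from [dosing_regimen()].
#' @param obs_times observation times (h).
#' @param dv observed concentrations (mg/L), same length as `obs_times`;
#'   `NA` marks below-quantification rows (`MDV = 1`).
#' @param occ_breaks occasion window boundaries (h).
#' @return data.frame of event rows sorted by time (observations before a
#'   dose that starts at the same time).
#' @export
make_event_records <- function(cov, regimen, obs_times, dv,
                               occ_breaks = c(6, 36, 66)) {
  ht <- if (is.null(cov$ht)) NA_real_ else cov$ht
  base <- data.frame(ID = cov$id, SEX = cov$sex, AGE = cov$postnatal_age,
                     GAGE = cov$gestational_age, WT = cov$wt, HT = ht,
                     FFM = cov$ffm, GST = cov$gst, stringsAsFactors = FALSE)
  dose <- cbind(data.frame(TIME = regimen$start_time, AMT = regimen$amount,
                           DUR = regimen$duration, DV = NA_real_, EVID = 1L,
                           MDV = 1L, ord = 1L), base)
  ev <- dose
  if (length(obs_times)) {
    obs <- cbind(data.frame(TIME = obs_times, AMT = NA_real_,
                            DUR = NA_real_, DV = dv, EVID = 0L,
                            MDV = ifelse(is.na(dv), 1L, 0L), ord = 0L),
                 base)
    ev <- rbind(dose, obs)
  }
  ev <- ev[order(ev$TIME, ev$ord), ]
  ev$ord <- NULL
  ev$OCC <- findInterval(ev$TIME, occ_breaks, left.open = TRUE) + 1L
  rownames(ev) <- NULL
  ev[, c("ID", "TIME", "AMT", "DUR", "DV", "EVID", "MDV", "OCC",
         "SEX", "AGE", "GAGE", "WT", "HT", "FFM", "GST")]
}
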
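#' Sparse pharmacokinetic dataset container
#'
#' Holds a cohort of subjects: dosing events, timed concentration
#' observations (with below-limit-of-quantification flags), and covariates.
#' Times are hours from each subject's first dose; concentrations are total
#' plasma concentrations in mg/L.
#'
#' @param obs data frame with columns `id`, `time` (h), `dv` (mg/L) and
#'   optionally `blq` (logical). Missing `blq` is derived from `dv < lloq`.
#' @param doses data frame with columns `id`, `time`, `amt` (mg),
#'   `dur` (h).
#' @param covariates data frame with column `id` plus one column per
#'   covariate, one row per subject; may be `NULL`.
#' @param lloq lower limit of quantification (mg/L) used to flag BLQ
#'   observations; flagged observations are retained in the container but
#'   excluded from estimation likelihoods.
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(obs, doses, covariates = NULL, lloq = 1.0) {
  stopifnot(all(c("id", "time", "dv") %in% names(obs)),
            all(c("id", "time", "amt", "dur") %in% names(doses)))
  ids <- unique(doses$id)
  if (length(ids) == 0L) {
    obs <- obs[0, , drop = FALSE]
  }
  bad <- setdiff(unique(obs$id), ids)
  if (length(bad)) {
    stop("subject(s) without any dose record: ", paste(bad, collapse = ", "))
  }
  if (any(doses$amt < 0) || any(doses$dur <= 0) || any(doses$time < 0)) {
    stop("invalid dose rows: need amt >= 0, dur > 0, time >= 0")
  }
  first_dose <- tapply(doses$time, doses$id, min)
  if (nrow(obs)) {
    fd <- first_dose[as.character(obs$id)]
    early <- obs$time < fd
    if (any(early)) {
      stop("observation before first dose for subject(s): ",
           paste(unique(obs$id[early]), collapse = ", "))
    }
    if (is.null(obs$blq)) obs$blq <- !is.na(obs$dv) & obs$dv < lloq
    if (any(!obs$blq & obs$dv < 0, na.rm = TRUE)) {
      stop("negative concentration on a non-BLQ row")
    }
  } else if (is.null(obs$blq)) {
    obs$blq <- logical(0)
  }
  obs <- obs[order(match(obs$id, ids), obs$time), , drop = FALSE]
  doses <- doses[order(match(doses$id, ids), doses$time), , drop = FALSE]
  rownames(obs) <- rownames(doses) <- NULL
  if (!is.null(covariates)) {
    stopifnot("id" %in% names(covariates))
    covariates <- covariates[match(ids, covariates$id), , drop = FALSE]
    rownames(covariates) <- NULL
  }
  structure(list(obs = obs, doses = doses, covariates = covariates,
                 ids = ids, lloq = lloq),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat("PK dataset:", length(x$ids), "subjects,", nrow(x$obs),
      "observations (", sum(x$obs$blq), "BLQ ),", nrow(x$doses), "doses\n")
  if (!is.null(x$covariates)) {
    cat("Covariates:", paste(setdiff(names(x$covariates), "id"),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.pk_dataset <- function(object, ...) {
  ns <- table(factor(object$obs$id, levels = object$ids))
  cat("Subjects:            ", length(object$ids), "\n")
  cat("Observations/subject:", paste(range(ns), collapse = "-"), "\n")
  if (nrow(object$obs)) {
    cat("Sampling times (d):  ",
        paste(round(range(object$obs$time) / 24, 1), collapse = "-"), "\n")
    cat("Concentrations:      ",
        paste(round(range(object$obs$dv, na.rm = TRUE), 1), collapse = "-"),
        "mg/L\n")
  }
  invisible(object)
}

#' @export
as.data.frame.pk_dataset <- function(x, ...) {
  dr <- data.frame(ID = x$doses$id, TIME = x$doses$time, DV = NA_real_,
                   AMT = x$doses$amt, DUR = x$doses$dur, EVID = 1L,
                   BLQ = 0L)
  or <- data.frame(ID = x$obs$id, TIME = x$obs$time, DV = x$obs$dv,
                   AMT = NA_real_, DUR = NA_real_, EVID = 0L,
                   BLQ = as.integer(x$obs$blq))
  long <- rbind(dr, or)
  long <- long[order(match(long$ID, x$ids), long$TIME, -long$EVID), ,
               drop = FALSE]
  rownames(long) <- NULL
  if (!is.null(x$covariates)) {
    long <- cbind(long,
                  x$covariates[match(long$ID, x$covariates$id),
                               setdiff(names(x$covariates), "id"),
                               drop = FALSE])
    rownames(long) <- NULL
  }
  long
}

#' Read / write the long-format PK dataset
#'
#' The on-disk format is a comma-separated long table with header columns
#' `ID, TIME, DV, AMT, DUR, EVID, BLQ` plus optional covariate columns:
#' one row per dose (`EVID = 1`, empty `DV`) or observation (`EVID = 0`,
#' empty `AMT`/`DUR`). Times are hours from each subject's first dose.
#' Reading validates the dataset invariants and reports offending line
#' numbers.
#'
#' @param path CSV file path.
#' @param lloq lower limit of quantification used to flag BLQ rows.
#' @return [read_pk_dataset()] returns a [pk_dataset()];
#'   [write_pk_dataset()] invisibly returns `path`.
#' @export
read_pk_dataset <- function(path, lloq = 1.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ID", "TIME", "DV", "AMT", "DUR", "EVID")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cc in c("TIME", "DV", "AMT", "DUR", "EVID")) {
    raw[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
  }
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad <- which(!raw$EVID %in% c(0L, 1L) | is.na(raw$TIME))
  if (length(bad)) {
    stop("malformed row at line ", bad[1] + 1L,
         ": EVID must be 0/1 and TIME non-missing")
  }
  isd <- raw$EVID == 1L
  bad <- which(isd & (is.na(raw$AMT) | is.na(raw$DUR)))
  if (length(bad)) stop("dose row without AMT/DUR at line ", line[bad[1]])
  bad <- which(!isd & is.na(raw$DV))
  if (length(bad)) stop("observation row without DV at line ", line[bad[1]])
  covcols <- setdiff(names(raw), c(need, "BLQ"))
  covariates <- NULL
  if (length(covcols)) {
    covariates <- unique(raw[, c("ID", covcols), drop = FALSE])
    names(covariates)[1] <- "id"
    if (anyDuplicated(covariates$id)) {
      stop("covariates vary within subject: ",
           covariates$id[duplicated(covariates$id)][1])
    }
  }
  obs <- data.frame(id = raw$ID[!isd], time = raw$TIME[!isd],
                    dv = raw$DV[!isd])
  if ("BLQ" %in% names(raw)) obs$blq <- raw$BLQ[!isd] == 1L
  doses <- data.frame(id = raw$ID[isd], time = raw$TIME[isd],
                      amt = raw$AMT[isd], dur = raw$DUR[isd])
  pk_dataset(obs, doses, covariates, lloq = lloq)
}

#' @rdname read_pk_dataset
#' @param x a `pk_dataset`.
#' @export
write_pk_dataset <- function(x, path) {
  stopifnot(inherits(x, "pk_dataset"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

# doses of one subject as a plain data.frame(time, amt, dur)
.subject_doses <- function(data, id) {
  d <- data$doses[data$doses$id == id, c("time", "amt", "dur"), drop = FALSE]
  rownames(d) <- NULL
  d
}
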
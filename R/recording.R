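#' Construct an fNIRS recording
#'
#' A recording is a channels-by-samples matrix of oxygenated-hemoglobin
#' concentration changes (micromolar) -- or raw light intensities before
#' Beer-Lambert conversion -- together with its sampling rate, montage and
#' session labels.
#'
#' @param data Numeric matrix, channels x samples (`kind = "hbo"`), or a
#'   3-d array channels x samples x wavelengths (`kind = "intensity"`).
#' @param fs Sampling rate in Hz (default 10, the instrument rate).
#' @param montage An `fnirs_montage`; defaults to [default_montage()].
#' @param kind `"hbo"` for concentration changes, `"intensity"` for raw
#'   light intensities.
#' @param state Session state label, `"resting"` or `"movement"`.
#' @param subject_id,group Free-form labels.
#' @return An object of class `fnirs_recording`.
#' @export
recording <- function(data, fs = 10, montage = default_montage(),
                      kind = c("hbo", "intensity"),
                      state = "resting", subject_id = "S01",
                      group = "control") {
  kind <- match.arg(kind)
  if (kind == "hbo") {
    data <- as.matrix(data)
    if (is.null(rownames(data)) &&
        nrow(data) == length(montage$channels)) {
      rownames(data) <- montage$channels
    }
  }
  rec <- structure(
    list(data = data, fs = as.numeric(fs), montage = montage, kind = kind,
         state = state, subject_id = subject_id, group = group),
    class = "fnirs_recording"
  )
  validate_recording(rec)
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (rec$fs <= 0) stop("sampling rate must be > 0", call. = FALSE)
  nch <- if (rec$kind == "hbo") nrow(rec$data) else dim(rec$data)[1]
  if (nch != length(rec$montage$channels)) {
    stop(sprintf("data has %d channel rows but montage lists %d channels",
                 nch, length(rec$montage$channels)), call. = FALSE)
  }
  rec
}

#' Number of samples in a recording
#' @param rec An `fnirs_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) {
  if (rec$kind == "hbo") ncol(rec$data) else dim(rec$data)[2]
}

#' Read a recording from delimited text plus montage JSON
#'
#' The file holds one header row of channel ids and one column per channel,
#' samples as rows.  Sampling rate and session labels come from a JSON
#' sidecar (`<path>.json`, written by [write_recording()]) with fields
#' `fs`, `state`, `subject_id`, `group`; if the sidecar is absent `fs`
#' must be supplied.
#'
#' @param path Path to the CSV file.
#' @param montage_path Path to the montage JSON.
#' @param fs Sampling rate override (Hz); required when no sidecar exists.
#' @return An `fnirs_recording` with channels in montage order.
#' @export
read_recording <- function(path, montage_path, fs = NULL) {
  montage <- read_montage(montage_path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  got <- colnames(df)
  if (!setequal(got, montage$channels)) {
    missing <- setdiff(montage$channels, got)
    extra <- setdiff(got, montage$channels)
    stop("channel header does not match montage",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  x <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) x <- matrix(x, nrow = 1, dimnames = list(NULL, got))
  bad <- which(is.na(x) & df != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value in column '%s', data row %d",
                 got[bad[1, 2]], bad[1, 1]), call. = FALSE)
  }
  side <- paste0(path, ".json")
  meta <- list(fs = fs, state = "resting", subject_id = "S01",
               group = "control")
  if (file.exists(side)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(side,
                                                        simplifyVector = TRUE))
  }
  if (!is.null(fs)) meta$fs <- fs
  if (is.null(meta$fs)) {
    stop("no sampling rate: supply fs= or a '", side, "' sidecar",
         call. = FALSE)
  }
  recording(t(x[, montage$channels, drop = FALSE]), fs = meta$fs,
            montage = montage, state = meta$state,
            subject_id = meta$subject_id, group = meta$group)
}

#' Write a recording as delimited text plus JSON sidecar
#'
#' Values are written with 17 significant digits so that a
#' read/write round trip is lossless for finite doubles.
#'
#' @param rec An `fnirs_recording` of kind `"hbo"`.
#' @param path Output CSV path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  if (rec$kind != "hbo") {
    stop("only concentration ('hbo') recordings are written as CSV",
         call. = FALSE)
  }
  x <- t(rec$data)
  txt <- apply(x, 2, function(col) formatC(col, digits = 17, format = "g"))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1)
  colnames(txt) <- rec$montage$channels
  utils::write.table(txt, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(fs = rec$fs, state = rec$state, subject_id = rec$subject_id,
         group = rec$group),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
print.fnirs_recording <- function(x, ...) {
  cat(sprintf("fNIRS recording [%s]: %d channels x %d samples @ %g Hz\n",
              x$kind, length(x$montage$channels), n_samples(x), x$fs))
  cat(sprintf("  subject %s, group %s, state %s\n",
              x$subject_id, x$group, x$state))
  invisible(x)
}
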
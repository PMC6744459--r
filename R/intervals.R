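#' Physiological frequency intervals of cerebral hemodynamic oscillations
#'
#' Spontaneous oxygenation signals carry oscillations from distinct
#' physiological sources that occupy characteristic frequency intervals:
#' I cardiac (0.6--2 Hz), II respiratory (0.145--0.6 Hz), III myogenic
#' (0.052--0.145 Hz), IV neurogenic (0.021--0.052 Hz) and V endothelial /
#' metabolic (0.0095--0.021 Hz).
#'
#' @return A data frame with columns `id`, `f_low`, `f_high` (Hz) and a
#'   human-readable `source` label, one row per interval I--V.
#' @examples
#' frequency_intervals()
#' @export
frequency_intervals <- function() {
  data.frame(
    id     = c("I", "II", "III", "IV", "V"),
    f_low  = c(0.6, 0.145, 0.052, 0.021, 0.0095),
    f_high = c(2.0, 0.6, 0.145, 0.052, 0.021),
    source = c("cardiac", "respiratory", "myogenic", "neurogenic",
               "endothelial"),
    stringsAsFactors = FALSE
  )
}

#' Look up one frequency interval by id
#'
#' @param id Interval id, one of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`,
#'   or an object already carrying `f_low`/`f_high` (returned unchanged).
#' @return A one-row data frame with `id`, `f_low`, `f_high`, `source`.
#' @export
get_interval <- function(id) {
  if (is.list(id) && !is.null(id$f_low) && !is.null(id$f_high)) {
    return(as.data.frame(id[intersect(names(id),
                                      c("id", "f_low", "f_high", "source"))]))
  }
  tab <- frequency_intervals()
  hit <- match(as.character(id), tab$id)
  if (is.na(hit)) {
    stop("unknown frequency interval id: ", id, call. = FALSE)
  }
  tab[hit, , drop = FALSE]
}

#' Geometric center frequency of an interval
#' @param id Interval id or interval row (see [get_interval()]).
#' @return Center frequency in Hz (geometric mean of the interval bounds).
#' @export
interval_center <- function(id) {
  iv <- get_interval(id)
  sqrt(iv$f_low * iv$f_high)
}
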
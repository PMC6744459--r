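#' @title Optode montage
#' @description A montage maps measurement channels to source/detector
#'   optodes and to one of six cortical regions: left/right prefrontal
#'   (LPFC/RPFC), motor (LMC/RMC) and occipital (LOC/ROC) cortex.  It also
#'   carries the optical constants needed by the modified Beer-Lambert law:
#'   inter-optode distance, differential path-length factor (DPF) and the
#'   instrument wavelengths.
#' @name fnirs_montage
NULL

REGIONS <- c("LPFC", "RPFC", "LMC", "RMC", "LOC", "ROC")

new_montage <- function(channels, source, detector, region,
                        inter_optode_distance_mm, dpf, wavelengths_nm) {
  m <- structure(
    list(
      channels = as.character(channels),
      source = as.character(source),
      detector = as.character(detector),
      region = as.character(region),
      inter_optode_distance_mm = as.numeric(inter_optode_distance_mm),
      dpf = as.numeric(dpf),
      wavelengths_nm = as.numeric(wavelengths_nm)
    ),
    class = "fnirs_montage"
  )
  validate_montage(m)
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "fnirs_montage"))
  n <- length(m$channels)
  if (anyDuplicated(m$channels)) {
    stop("duplicate channel ids in montage", call. = FALSE)
  }
  if (length(m$source) != n || length(m$detector) != n ||
      length(m$region) != n) {
    stop("montage fields must have one entry per channel", call. = FALSE)
  }
  bad <- setdiff(unique(m$region), REGIONS)
  if (length(bad)) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (m$inter_optode_distance_mm <= 0) {
    stop("inter_optode_distance_mm must be > 0", call. = FALSE)
  }
  if (any(m$dpf <= 0)) stop("dpf must be > 0", call. = FALSE)
  if (length(m$wavelengths_nm) > 1 && any(diff(m$wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  m
}

#' Default 14-channel, six-region montage
#'
#' Two channels per prefrontal and occipital hemisphere and three per motor
#' hemisphere, 30 mm inter-optode distance, DPF 7.0 at every wavelength and
#' wavelengths 740/808/850 nm.  The channel-to-region assignment lives in a
#' versioned JSON fixture (`inst/extdata/default_montage.json`) so it can be
#' replaced without a code change.
#'
#' @return An object of class `fnirs_montage`.
#' @examples
#' m <- default_montage()
#' table(m$region)
#' @export
default_montage <- function() {
  path <- system.file("extdata", "default_montage.json",
                      package = "nirscoupling", mustWork = TRUE)
  read_montage(path)
}

#' Read a montage from JSON
#'
#' @param path Path to a montage JSON file with fields
#'   `inter_optode_distance_mm`, `dpf` (scalar, applied to all wavelengths),
#'   `wavelengths_nm` and a `channels` array of
#'   `{id, source, detector, region}` records.
#' @return An `fnirs_montage` object.
#' @export
read_montage <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ch <- j$channels
  dpf <- rep_len(as.numeric(j$dpf), length(j$wavelengths_nm))
  new_montage(ch$id, ch$source, ch$detector, ch$region,
              j$inter_optode_distance_mm, dpf, j$wavelengths_nm)
}

#' Write a montage to JSON
#'
#' Serialization is canonical (fixed key order, no whitespace variation), so
#' the same montage always produces byte-identical output.
#'
#' @param montage An `fnirs_montage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  validate_montage(montage)
  j <- list(
    version = 1L,
    inter_optode_distance_mm = montage$inter_optode_distance_mm,
    dpf = montage$dpf[1],
    wavelengths_nm = montage$wavelengths_nm,
    channels = data.frame(
      id = montage$channels, source = montage$source,
      detector = montage$detector, region = montage$region,
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' All unordered region pairs of a montage
#'
#' @param montage An `fnirs_montage`.
#' @return A data frame with columns `region_i`, `region_j`, one row per
#'   unordered pair of distinct regions present in the montage, in a
#'   deterministic order (the canonical region order LPFC, RPFC, LMC, RMC,
#'   LOC, ROC).
#' @examples
#' nrow(region_pairs(default_montage()))  # choose(6, 2) = 15
#' @export
region_pairs <- function(montage) {
  validate_montage(montage)
  regs <- REGIONS[REGIONS %in% unique(montage$region)]
  if (length(regs) < 2) stop("montage has fewer than two regions",
                             call. = FALSE)
  idx <- utils::combn(seq_along(regs), 2)
  data.frame(region_i = regs[idx[1, ]], region_j = regs[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Channels belonging to a region
#' @param montage An `fnirs_montage`.
#' @param region Region label.
#' @return Character vector of channel ids.
#' @export
region_channels <- function(montage, region) {
  montage$channels[montage$region == region]
}

#' @export
print.fnirs_montage <- function(x, ...) {
  cat("fNIRS montage:", length(x$channels), "channels,",
      length(unique(x$region)), "regions\n")
  cat("  distance:", x$inter_optode_distance_mm, "mm; DPF:",
      paste(x$dpf, collapse = "/"), "; wavelengths:",
      paste(x$wavelengths_nm, collapse = "/"), "nm\n")
  print(table(region = x$region))
  invisible(x)
}
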
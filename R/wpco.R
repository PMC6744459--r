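#' Wavelet phase coherence between two decompositions in one interval
#'
#' Per grid frequency, the phase difference
#' \eqn{\Delta\phi(f,t) = \arg W_x - \arg W_y} is averaged over time as
#' \deqn{WPCO(f) = \sqrt{\langle\cos\Delta\phi\rangle_t^2 +
#'       \langle\sin\Delta\phi\rangle_t^2},}
#' and the interval value is the mean of \eqn{WPCO(f)} over the grid
#' frequencies inside the interval (cone-of-influence policy as for the
#' wavelet amplitude).  The value lies in \[0, 1\]: 1 means the phase
#' difference is constant throughout.
#'
#' @param dec_x,dec_y `band_decomposition`s on the same frequency grid and
#'   time axis.
#' @param interval Frequency-interval id (I--V) or interval row.
#' @param exclude_coi Mask the cone of influence?  Defaults to the shared
#'   policy (yes for IV--V).
#' @param coi_mult Edge-trim multiplier: how many e-folding times of the
#'   wavelet envelope to discard per edge when `exclude_coi` is set.  The
#'   default 1 is the conventional cone of influence; 3 suppresses edge
#'   transients to below 1e-6 in the coherence.
#' @return Coherence scalar in \[0, 1\].
#' @export
wpco_pair <- function(dec_x, dec_y, interval,
                      exclude_coi = default_coi_policy(interval),
                      coi_mult = 1) {
  if (!isTRUE(all.equal(dec_x$freqs, dec_y$freqs)) ||
      ncol(dec_x$coeffs) != ncol(dec_y$coeffs)) {
    stop("decompositions are not on a shared grid", call. = FALSE)
  }
  rows <- interval_rows(dec_x, interval)
  if (!length(rows)) stop("interval outside the frequency grid",
                          call. = FALSE)
  vals <- vapply(rows, function(r) {
    m <- if (exclude_coi) coi_mask(dec_x, r, coi_mult) else
      rep(TRUE, ncol(dec_x$coeffs))
    if (!any(m)) return(NA_real_)
    dphi <- Arg(dec_x$coeffs[r, m]) - Arg(dec_y$coeffs[r, m])
    sqrt(mean(cos(dphi))^2 + mean(sin(dphi))^2)
  }, numeric(1))
  if (all(is.na(vals))) {
    stop("interval entirely inside the cone of influence (series too short)",
         call. = FALSE)
  }
  mean(vals, na.rm = TRUE)
}

#' Wavelet phase coherence between two raw series in one interval
#'
#' Convenience wrapper that decomposes both series on a grid restricted to
#' the interval and returns their coherence; the natural `stat_fn` for
#' [significance_threshold()].
#'
#' @param x,y Numeric series.
#' @param fs Sampling rate, Hz.
#' @param interval Frequency-interval id.
#' @param freqs Optional explicit frequency grid.
#' @param f0 Morlet parameter.
#' @return Coherence scalar in \[0, 1\].
#' @export
wpco_series <- function(x, y, fs, interval, freqs = NULL, f0 = 1) {
  if (is.null(freqs)) {
    iv <- get_interval(interval)
    freqs <- wavelet_freqs(f_min = iv$f_low, f_max = iv$f_high)
  }
  wpco_pair(cwt_morlet(x, fs, f0 = f0, freqs = freqs),
            cwt_morlet(y, fs, f0 = f0, freqs = freqs), interval)
}

#' Channel-pair wavelet phase coherence with surrogate significance
#'
#' Computes WPCO for every unordered channel pair and every frequency
#' interval, and gates each value against the AAFT mean + 2 SD threshold.
#' For efficiency the surrogate ensemble (and its decompositions) is built
#' once per channel and reused across the pairs that channel participates
#' in; the second channel of each pair is the surrogated one.
#'
#' @param rec A preprocessed `fnirs_recording`.
#' @param n_surr Surrogates per channel (default 50).
#' @param seed Integer seed.
#' @param freqs Analysis frequency grid.
#' @param f0 Morlet parameter.
#' @return List of class `wpco_result`: `pairs` (data frame `channel_i`,
#'   `channel_j`), `wpco`, `threshold`, `significant` (pair x interval
#'   matrices), `montage`, `n_surr`, `seed`.
#' @export
wpco_matrix <- function(rec, n_surr = 50, seed = 1,
                        freqs = wavelet_freqs(), f0 = 1) {
  validate_recording(rec)
  nch <- nrow(rec$data)
  ids <- frequency_intervals()$id
  unitize <- function(dec) {
    m <- Mod(dec$coeffs)
    m[m == 0] <- 1
    list(re = Re(dec$coeffs) / m, im = Im(dec$coeffs) / m)
  }
  dec0 <- cwt_morlet(rec$data[1, ], rec$fs, f0 = f0, freqs = freqs)
  nt <- ncol(dec0$coeffs)
  row_sets <- lapply(ids, function(iv) interval_rows(dec0, iv))
  names(row_sets) <- ids
  # rows whose interval excludes the cone of influence use a trimmed slice
  coi_rows <- sort(unique(unlist(
    row_sets[ids[vapply(ids, default_coi_policy, logical(1))]])))
  slices <- lapply(seq_along(freqs), function(r) {
    if (!(r %in% coi_rows)) return(c(1L, nt))
    m <- which(coi_mask(dec0, r))
    if (!length(m)) c(NA_integer_, NA_integer_) else range(m)
  })
  agg <- function(rho_rows) {
    vapply(ids, function(iv) mean(rho_rows[row_sets[[iv]]], na.rm = TRUE),
           numeric(1))
  }
  row_wpco <- function(Ux, Uy) {
    pr <- Ux$re * Uy$re + Ux$im * Uy$im
    pi_ <- Ux$im * Uy$re - Ux$re * Uy$im
    sr <- rowSums(pr); si <- rowSums(pi_)
    vapply(seq_along(slices), function(r) {
      ab <- slices[[r]]
      if (is.na(ab[1])) return(NA_real_)
      a <- ab[1]; b <- ab[2]
      zr <- sr[r]; zi <- si[r]
      if (a > 1) {
        zr <- zr - sum(pr[r, 1:(a - 1)]); zi <- zi - sum(pi_[r, 1:(a - 1)])
      }
      if (b < nt) {
        zr <- zr - sum(pr[r, (b + 1):nt]); zi <- zi - sum(pi_[r, (b + 1):nt])
      }
      len <- b - a + 1
      sqrt(zr^2 + zi^2) / len
    }, numeric(1))
  }
  Us <- vector("list", nch)
  Us[[1]] <- unitize(dec0)
  for (ch in 2:nch) {
    Us[[ch]] <- unitize(cwt_morlet(rec$data[ch, ], rec$fs, f0 = f0,
                                   freqs = freqs))
  }
  surr_Us <- lapply(seq_len(nch), function(ch) {
    if (n_surr == 0) return(list())
    ens <- aaft(rec$data[ch, ], n = n_surr, seed = seed + ch)
    lapply(seq_len(n_surr),
           function(s) unitize(cwt_morlet(ens$series[s, ], rec$fs,
                                          f0 = f0, freqs = freqs)))
  })
  idx <- utils::combn(nch, 2)
  npair <- ncol(idx)
  pairs <- data.frame(channel_i = rec$montage$channels[idx[1, ]],
                      channel_j = rec$montage$channels[idx[2, ]],
                      stringsAsFactors = FALSE)
  wpco <- thr <- matrix(NA_real_, npair, length(ids),
                        dimnames = list(NULL, ids))
  for (p in seq_len(npair)) {
    i <- idx[1, p]; j <- idx[2, p]
    wpco[p, ] <- agg(row_wpco(Us[[i]], Us[[j]]))
    if (n_surr > 0) {
      sv <- vapply(surr_Us[[j]], function(U) agg(row_wpco(Us[[i]], U)),
                   numeric(length(ids)))
      thr[p, ] <- apply(sv, 1, mean) + 2 * apply(sv, 1, stats::sd)
    }
  }
  structure(list(pairs = pairs, wpco = wpco, threshold = thr,
                 significant = !is.na(thr) & wpco > thr,
                 montage = rec$montage, n_surr = n_surr, seed = seed),
            class = "wpco_result")
}

#' Aggregate channel-pair coherence to region pairs
#'
#' @param res A `wpco_result` from [wpco_matrix()].
#' @param montage Montage (defaults to the one stored in `res`).
#' @return Data frame with one row per unordered region pair and interval:
#'   mean WPCO over all cross-region channel pairs and the fraction of
#'   member pairs whose coherence passed the surrogate gate.
#' @export
region_wpco <- function(res, montage = res$montage) {
  rp <- region_pairs(montage)
  ids <- colnames(res$wpco)
  ch_region <- stats::setNames(montage$region, montage$channels)
  ri <- ch_region[res$pairs$channel_i]
  rj <- ch_region[res$pairs$channel_j]
  out <- list()
  for (k in seq_len(nrow(rp))) {
    a <- rp$region_i[k]; b <- rp$region_j[k]
    member <- (ri == a & rj == b) | (ri == b & rj == a)
    for (iv in ids) {
      out[[length(out) + 1]] <- data.frame(
        region_i = a, region_j = b, interval = iv,
        wpco = mean(res$wpco[member, iv]),
        sig_fraction = if (all(is.na(res$threshold[member, iv]))) NA_real_
        else mean(res$significant[member, iv]),
        n_pairs = sum(member),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
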
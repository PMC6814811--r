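# Cross-sectional fluorescence line-profile analysis: normalization, peak
# localization and the peak-betweenness verdict.

#' Fluorescence line profile
#'
#' Intensities of one or more channels sampled along a cross-sectional
#' line, e.g. Tom20 (MOM), Sec61b (ER) and a reconstituted GFP signal.
#'
#' @param positions strictly increasing numeric vector of positions along
#'   the line (nm or px, any consistent unit).
#' @param channels named list or data.frame of per-channel intensities,
#'   each the same length as `positions`.
#' @return object of class `line_profile` with fields `positions`,
#'   `channels` and (after [normalize_profile()]) `normalized`.
#' @export
line_profile <- function(positions, channels) {
  positions <- as.numeric(positions)
  if (length(positions) < 3L || any(diff(positions) <= 0) ||
      any(!is.finite(positions)))
    stop("positions must be >= 3 strictly increasing finite values")
  channels <- lapply(as.list(channels), as.numeric)
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be named")
  bad <- vapply(channels, function(v) {
    length(v) != length(positions) || any(!is.finite(v))
  }, logical(1))
  if (any(bad))
    stop("channel(s) ", paste(names(channels)[bad], collapse = ", "),
         ": length mismatch or non-finite intensities")
  structure(list(positions = positions, channels = channels,
                 normalized = NULL),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples, channels: %s%s\n",
              length(x$positions), paste(names(x$channels), collapse = ", "),
              if (is.null(x$normalized)) "" else " (normalized)"))
  invisible(x)
}

#' Read a line profile from CSV
#'
#' Expects a `position` column followed by one column per channel.
#'
#' @param path CSV path.
#' @return a [line_profile()].
#' @export
read_line_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"position" %in% names(df))
    stop("line profile CSV needs a 'position' column")
  line_profile(df$position, df[setdiff(names(df), "position")])
}

#' Min-max normalize each channel to [0, 1]
#'
#' Affine per-channel rescaling so the minimum maps to 0 and the maximum to
#' 1 — the "normalized fluorescence distribution" read off cross-sectional
#' plots.  Idempotent; a constant channel has no distribution and is an
#' error.
#'
#' @param profile a [line_profile()].
#' @return the profile with the `normalized` field filled.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "line_profile"))
  profile$normalized <- lapply(seq_along(profile$channels), function(i) {
    v <- profile$channels[[i]]
    rng <- range(v)
    if (diff(rng) <= 0)
      stop("channel '", names(profile$channels)[i],
           "' is constant and cannot be normalized")
    (v - rng[1L]) / diff(rng)
  })
  names(profile$normalized) <- names(profile$channels)
  profile
}

#' Locate per-channel peak positions
#'
#' Position of each channel's global maximum after centred moving-average
#' smoothing of the normalized intensities.  Ties (multiple samples at the
#' maximum) are broken by first occurrence and flagged.
#'
#' @param profile a [line_profile()]; normalized automatically if needed.
#' @param smooth_window odd integer window for the moving average
#'   (default 3; 1 disables smoothing).
#' @return `data.frame` with columns `channel`, `position`, `tied`.
#' @export
locate_peaks <- function(profile, smooth_window = 3L) {
  stopifnot(inherits(profile, "line_profile"))
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("smooth_window must be a positive odd integer")
  if (is.null(profile$normalized)) profile <- normalize_profile(profile)
  k <- (smooth_window - 1L) %/% 2L
  res <- lapply(names(profile$normalized), function(ch) {
    v <- profile$normalized[[ch]]
    if (k > 0L) {
      vp <- c(rep(v[1L], k), v, rep(v[length(v)], k))
      v <- as.numeric(stats::filter(vp, rep(1 / smooth_window, smooth_window)))
      v <- v[(k + 1L):(k + length(profile$positions))]
    }
    mx <- max(v)
    hits <- which(abs(v - mx) < 1e-12)
    data.frame(channel = ch, position = profile$positions[hits[1L]],
               tied = length(hits) > 1L)
  })
  do.call(rbind, res)
}

#' Is a query channel's peak between two flanking marker peaks?
#'
#' The readout placing a split-GFP contact signal between the ER and MOM
#' marker peaks along a cross-sectional line.  Order-agnostic in the
#' flanks; boundary equality counts as between.
#'
#' @param peaks result of [locate_peaks()], or a named numeric vector of
#'   peak positions.
#' @param query,flank_a,flank_b channel names.
#' @return list with `between` (logical), `offset_a` and `offset_b`
#'   (signed `query - flank` position offsets).
#' @export
betweenness_test <- function(peaks, query, flank_a, flank_b) {
  if (is.data.frame(peaks)) {
    pos <- stats::setNames(peaks$position, peaks$channel)
  } else {
    pos <- peaks
  }
  need <- c(query, flank_a, flank_b)
  missing_ch <- setdiff(need, names(pos))
  if (length(missing_ch))
    stop("missing channel(s): ", paste(missing_ch, collapse = ", "))
  pq <- pos[[query]]; pa <- pos[[flank_a]]; pb <- pos[[flank_b]]
  list(between = min(pa, pb) <= pq && pq <= max(pa, pb),
       offset_a = pq - pa, offset_b = pq - pb)
}
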
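# Brute-force raster cross-check for the polyline band computation.

#' Raster distance-transform band profile (brute-force cross-check)
#'
#' Independent route to the band profile: the MOM curve is rasterized onto
#' a fine grid (default 0.25 nm/px), the exact Euclidean distance transform
#' of the rasterized curve is computed with `EBImage::distmap`, and each ER
#' trace is walked in fine arc-length steps whose distances are looked up
#' in the transform.  Used to validate [compute_band_profile()], never as
#' the production path.
#'
#' @inheritParams compute_band_profile
#' @param pixel_nm raster pitch of the oracle grid.
#' @param sample_step_nm ER arc-length step for the band accumulation.
#' @return a `band_profile`.
#' @export
band_profile_raster <- function(mom, er_traces = list(),
                                config = band_config(), pixel_nm = 0.25,
                                sample_step_nm = 0.1) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("band_profile_raster needs the EBImage package")
  stopifnot(is_membrane_trace(mom), pixel_nm > 0)
  if (is_membrane_trace(er_traces)) er_traces <- list(er_traces)

  l <- numeric(config$n_bands)
  if (length(er_traces)) {
    # The EDT window is the ER bounding box expanded by the contact range
    # plus a safety margin: any MOM pixel that could be nearest to an
    # in-range ER point lies inside, so in-range band assignment is exact;
    # ER farther than the window margin from every windowed MOM pixel is
    # beyond the contact range by construction.
    range_nm <- config$n_bands * config$step_nm
    er_v <- do.call(rbind, lapply(er_traces, `[[`, "vertices"))
    margin <- range_nm + 15 + 10 * pixel_nm
    x0 <- min(er_v[, 1L]) - margin; x1 <- max(er_v[, 1L]) + margin
    y0 <- min(er_v[, 2L]) - margin; y1 <- max(er_v[, 2L]) + margin
    ncx <- ceiling((x1 - x0) / pixel_nm) + 1L
    ncy <- ceiling((y1 - y0) / pixel_nm) + 1L

    # rasterize the MOM curve as background (0) pixels in a field of 1s,
    # dropping curve samples outside the window
    rs <- polyline_midpoints(mom, 0.3 * pixel_nm)
    ix <- round((rs$mid[, 1L] - x0) / pixel_nm)
    iy <- round((rs$mid[, 2L] - y0) / pixel_nm)
    ok <- ix >= 0L & ix < ncx & iy >= 0L & iy < ncy
    if (any(ok)) {
      field <- matrix(1, nrow = ncy, ncol = ncx)
      field[cbind(iy[ok] + 1L, ix[ok] + 1L)] <- 0
      dt <- EBImage::distmap(field) * pixel_nm
      for (er in er_traces) {
        es <- polyline_midpoints(er, sample_step_nm)
        jx <- pmin(pmax(round((es$mid[, 1L] - x0) / pixel_nm), 0L), ncx - 1L)
        jy <- pmin(pmax(round((es$mid[, 2L] - y0) / pixel_nm), 0L), ncy - 1L)
        d <- dt[cbind(jy + 1L, jx + 1L)]
        band <- pmax(ceiling(d / config$step_nm - 1e-9), 1)
        keep <- band <= config$n_bands
        if (any(keep))
          l <- l + tabulate(band[keep], config$n_bands) * es$len[1L]
      }
    }
  }
  structure(list(config = config, incremental_nm = l,
                 cumulative_nm = cumsum(l)),
            class = "band_profile")
}
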
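# Stimulus geometry: correlated/anticorrelated gratings, generalized-Gaussian
# windows, retinal-phase arithmetic and the postsaccadic noise mask.

#' Display geometry of the experimental monitor
#'
#' Describes the screen used to render stimuli: physical size, pixel
#' resolution, viewing distance and the luminance of black, white and grey
#' pixels. Angular positions are expressed in degrees of visual angle with
#' the origin at screen centre, rightward/upward positive; the deg-to-pixel
#' mapping uses the exact tangent relation (no small-angle approximation),
#' so it is invertible.
#'
#' @param width_cm,height_cm physical display size in cm.
#' @param width_px,height_px resolution in pixels.
#' @param viewing_distance_cm eye-to-screen distance in cm.
#' @param luminance_black,luminance_white,luminance_grey luminances in cd/m2.
#'
#' @return An object of class `display_geometry`.
#' @export
display_geometry <- function(width_cm = 51.5, height_cm = 29,
                             width_px = 1920, height_px = 1080,
                             viewing_distance_cm = 60,
                             luminance_black = 0.21,
                             luminance_white = 105.70,
                             luminance_grey = 58.33) {
  stopifnot(width_cm > 0, height_cm > 0, width_px > 0, height_px > 0,
            viewing_distance_cm > 0)
  if (!(luminance_black < luminance_grey && luminance_grey < luminance_white))
    stop("luminances must satisfy black < grey < white")
  structure(
    list(width_cm = width_cm, height_cm = height_cm,
         width_px = width_px, height_px = height_px,
         viewing_distance_cm = viewing_distance_cm,
         luminance_black = luminance_black,
         luminance_white = luminance_white,
         luminance_grey = luminance_grey),
    class = "display_geometry")
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf("<display_geometry> %.1f x %.1f cm (%d x %d px) at %.0f cm\n",
              x$width_cm, x$height_cm, x$width_px, x$height_px,
              x$viewing_distance_cm))
  cat(sprintf("  luminance black/grey/white: %.2f / %.2f / %.2f cd/m2\n",
              x$luminance_black, x$luminance_grey, x$luminance_white))
  invisible(x)
}

#' Convert between degrees of visual angle and pixels
#'
#' Exact tangent mapping along the horizontal axis: a position at `deg`
#' degrees from straight ahead lies `d * tan(deg)` cm from screen centre.
#'
#' @param deg,px positions (degrees of visual angle / pixel coordinate with
#'   0 at the left edge).
#' @param geometry a [display_geometry()].
#' @return Numeric vector of converted positions.
#' @export
deg_to_px <- function(deg, geometry) {
  cm <- geometry$viewing_distance_cm * tan(deg * pi / 180)
  geometry$width_px / 2 + cm * geometry$width_px / geometry$width_cm
}

#' @rdname deg_to_px
#' @export
px_to_deg <- function(px, geometry) {
  cm <- (px - geometry$width_px / 2) * geometry$width_cm / geometry$width_px
  atan2(cm, geometry$viewing_distance_cm) * 180 / pi
}

#' Wavelength of the anticorrelated grating
#'
#' The saccade target sits at twice the wavelength of the correlated grating,
#' so a saccade of that amplitude shifts the correlated grating by an integer
#' number of cycles. The anticorrelated grating's wavelength is chosen so the
#' same displacement equals 1.5 or 2.5 of its cycles:
#' `lambda_anti = 2 * lambda_corr / f_anti`.
#'
#' @param lambda_corr wavelength of the correlated grating (deg).
#' @param f_anti cycle factor, 1.5 or 2.5 (2 would reproduce the correlated
#'   grating and is accepted only when `strict = FALSE`).
#' @param strict if `TRUE` (default) only the factors used in the designs
#'   (1.5, 2.5) are accepted.
#' @return Wavelength of the anticorrelated grating in degrees.
#' @export
anticorrelated_wavelength <- function(lambda_corr, f_anti, strict = TRUE) {
  if (any(lambda_corr <= 0)) stop("lambda_corr must be positive")
  ok <- if (strict) f_anti %in% c(1.5, 2.5) else f_anti > 0
  if (!all(ok)) stop("unsupported f_anti factor")
  2 * lambda_corr / f_anti
}

#' Split a mean test contrast into the two grating contrasts
#'
#' The test stimulus holds mean contrast constant while varying the contrast
#' difference `delta_c = c_anti - c_corr`. The split is symmetric about the
#' mean, the only split compatible with a constant mean:
#' `c_corr = mean - delta_c / 2`, `c_anti = mean + delta_c / 2`.
#'
#' @param mean_contrast mean Michelson contrast of the two test gratings.
#' @param delta_c contrast difference `c_anti - c_corr`.
#' @return Named numeric vector `c(c_corr = , c_anti = )`.
#' @export
split_contrast <- function(mean_contrast, delta_c) {
  c_corr <- mean_contrast - delta_c / 2
  c_anti <- mean_contrast + delta_c / 2
  eps <- 1e-12
  if (any(c_corr < -eps | c_corr > 1 + eps | c_anti < -eps | c_anti > 1 + eps))
    stop("resulting contrasts outside [0, 1]")
  c(c_corr = min(max(c_corr, 0), 1), c_anti = min(max(c_anti, 0), 1))
}

#' Specification of one luminance grating
#'
#' @param wavelength_deg spatial wavelength (deg of visual angle).
#' @param phase_rad common phase in radians (jittered per trial in
#'   `[-pi/2, pi/2]` by the scheduler).
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param half which half of the display the grating fills.
#' @param role correlated or anticorrelated with the presaccadic input.
#' @param waveform `"sinusoid"` (default) or `"square"`.
#' @return An object of class `grating_spec`.
#' @export
grating_spec <- function(wavelength_deg, phase_rad = 0, contrast = 0.5,
                         half = c("upper", "lower"),
                         role = c("correlated", "anticorrelated"),
                         waveform = c("sinusoid", "square")) {
  stopifnot(wavelength_deg > 0, contrast >= 0, contrast <= 1)
  structure(
    list(wavelength_deg = wavelength_deg, phase_rad = phase_rad,
         contrast = contrast, half = match.arg(half), role = match.arg(role),
         waveform = match.arg(waveform)),
    class = "grating_spec")
}

#' Luminance profile of a grating along the horizontal axis
#'
#' `L(x) = L_grey * (1 + c * w(2 * pi * x / lambda + phi))` where `w` is the
#' waveform bounded in `[-1, 1]`. Output is clipped to the displayable range
#' `[black, white]`; for the contrasts used in the designs (<= 0.7) no
#' clipping occurs because `grey * 1.7 < white`.
#'
#' @param spec a [grating_spec()].
#' @param x horizontal positions in degrees of visual angle.
#' @param geometry a [display_geometry()].
#' @return Luminance values in cd/m2, same length as `x`.
#' @export
grating_profile <- function(spec, x, geometry = display_geometry()) {
  arg <- 2 * pi * x / spec$wavelength_deg + spec$phase_rad
  w <- switch(spec$waveform,
              sinusoid = sin(arg),
              square = {
                s <- sign(sin(arg))
                s[s == 0] <- 1
                s
              })
  L <- geometry$luminance_grey * (1 + spec$contrast * w)
  pmin(pmax(L, geometry$luminance_black), geometry$luminance_white)
}

#' Generalized-Gaussian window specification
#'
#' A one-dimensional window `exp(-(|y - y0| / alpha)^beta)`. In its inverted
#' form it carves the grey separation bar out of the gratings: at the window
#' centre the contrast is fully attenuated to grey, and the edges blend
#' smoothly into the gratings. The non-inverted form is used to uncover a
#' vertical slice of the test gratings through the noise mask.
#'
#' @param scale_deg scale alpha (> 0, deg).
#' @param shape shape beta (>= 1; larger values give flatter tops and
#'   steeper flanks).
#' @param center window centre along the windowed axis (deg).
#' @param orientation axis along which the window varies.
#' @param inverted if `TRUE`, attenuation is maximal at the centre.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(scale_deg = 2.1, shape = 3, center = 0,
                        orientation = c("horizontal", "vertical"),
                        inverted = TRUE) {
  stopifnot(scale_deg > 0, shape >= 1)
  structure(
    list(scale_deg = scale_deg, shape = shape, center = center,
         orientation = match.arg(orientation), inverted = inverted),
    class = "window_spec")
}

#' Contrast-retention factor of a window at given positions
#'
#' @param window a [window_spec()].
#' @param pos positions along the windowed axis (deg).
#' @return Retention factor in `[0, 1]`: 0 means attenuated fully to grey.
#' @export
window_attenuation <- function(window, pos) {
  g <- exp(-(abs(pos - window$center) / window$scale_deg)^window$shape)
  if (window$inverted) 1 - g else g
}

#' Apply a window to a luminance profile
#'
#' Attenuates deviations from grey by the window's contrast-retention
#' factor, so an inverted window yields pure grey at its centre.
#'
#' @param profile luminance values (cd/m2).
#' @param pos positions of the profile samples along the windowed axis (deg).
#' @param window a [window_spec()].
#' @param geometry a [display_geometry()] supplying the grey level.
#' @return Windowed luminance profile.
#' @export
apply_window <- function(profile, pos, window, geometry = display_geometry()) {
  a <- window_attenuation(window, pos)
  geometry$luminance_grey + (profile - geometry$luminance_grey) * a
}

#' Retinal phase shift caused by a gaze displacement
#'
#' A horizontal gaze shift of `displacement` degrees slides the retinal image
#' of a grating by `displacement / wavelength` cycles. The phase shift modulo
#' a full cycle determines whether the postsaccadic grating is correlated
#' (shift 0) or anticorrelated (shift pi) with the presaccadic input.
#'
#' @param displacement gaze displacement (deg).
#' @param wavelength grating wavelength (deg, > 0).
#' @return Phase shift in radians within `[0, 2*pi)`.
#' @export
retinal_phase_shift <- function(displacement, wavelength) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  r <- (2 * pi * displacement / wavelength) %% (2 * pi)
  # snap floating-point residue at the wrap point back to 0
  r[r >= 2 * pi - 1e-9] <- 0
  r
}

#' Gaussian-filtered noise mask
#'
#' The postsaccadic mask is white noise filtered so its amplitude spectrum is
#' a Gaussian centred on `mean_sf` with spread `sf_sd`, then scaled to the
#' requested Michelson contrast about grey. Rendered as a one-dimensional
#' horizontal luminance profile (the canonical representation; the full
#' frame repeats it vertically).
#'
#' @param mean_sf centre spatial frequency (cyc/deg).
#' @param sf_sd spectral spread (cyc/deg).
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param geometry a [display_geometry()].
#' @param seed integer seed; identical seeds give identical masks.
#' @return List with `x_deg` (sample positions), `luminance` (cd/m2) and the
#'   realized `spectral_centroid` (cyc/deg, amplitude-weighted over the
#'   positive frequencies).
#' @export
make_noise_mask <- function(mean_sf = 0.18, sf_sd = 0.02, contrast = 0.7,
                            geometry = display_geometry(), seed = 1L) {
  stopifnot(contrast >= 0, contrast <= 1, mean_sf > 0, sf_sd > 0)
  # sample on a uniform angular grid spanning the display width
  half_w <- px_to_deg(geometry$width_px, geometry)
  n <- 2048L
  x <- seq(-half_w, half_w, length.out = n)
  dx <- x[2] - x[1]
  if (contrast == 0) {
    return(list(x_deg = x,
                luminance = rep(geometry$luminance_grey, n),
                spectral_centroid = NA_real_))
  }
  rng <- local_rng(seed)
  noise <- rng$normal(n)
  f <- c(seq(0, n / 2), seq(-n / 2 + 1, -1)) / (n * dx)  # cyc/deg
  gain <- exp(-((abs(f) - mean_sf)^2) / (2 * sf_sd^2))
  gain[1] <- 0  # remove DC so the mask is zero-mean about grey
  filtered <- Re(stats::fft(stats::fft(noise) * gain, inverse = TRUE)) / n
  filtered <- filtered / max(abs(filtered))
  amp <- Mod(stats::fft(filtered))
  pos <- seq(2, n / 2)  # positive, non-DC frequencies
  centroid <- sum(f[pos] * amp[pos]) / sum(amp[pos])
  lum <- geometry$luminance_grey * (1 + contrast * filtered)
  lum <- pmin(pmax(lum, geometry$luminance_black), geometry$luminance_white)
  list(x_deg = x, luminance = lum, spectral_centroid = centroid)
}

#' Render a full display frame as a luminance matrix
#'
#' Derived 2-D view built from the canonical 1-D profiles: the upper and
#' lower gratings windowed by the inverted generalized-Gaussian bar at the
#' vertical midline.
#'
#' @param upper,lower [grating_spec()]s for the two halves.
#' @param geometry a [display_geometry()].
#' @param bar_window a [window_spec()] for the horizontal grey bar.
#' @param n_x,n_y output resolution (columns sample the horizontal axis).
#' @return List with `x_deg`, `y_deg` and a `luminance` matrix
#'   (rows = vertical positions, top row = upper edge).
#' @export
render_frame <- function(upper, lower, geometry = display_geometry(),
                         bar_window = window_spec(), n_x = 480L, n_y = 270L) {
  half_w <- px_to_deg(geometry$width_px, geometry)
  cm_h <- geometry$height_cm / 2
  half_h <- atan2(cm_h, geometry$viewing_distance_cm) * 180 / pi
  x <- seq(-half_w, half_w, length.out = n_x)
  y <- seq(half_h, -half_h, length.out = n_y)
  up <- grating_profile(upper, x, geometry)
  lo <- grating_profile(lower, x, geometry)
  frame <- matrix(0, n_y, n_x)
  for (i in seq_len(n_y)) frame[i, ] <- if (y[i] >= 0) up else lo
  att <- window_attenuation(bar_window, y)
  frame <- geometry$luminance_grey +
    (frame - geometry$luminance_grey) * att
  list(x_deg = x, y_deg = y, luminance = frame)
}
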
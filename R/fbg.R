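# FBG strain transduction: sensor specs, calibration, hysteresis

#' Specification of a single fiber Bragg grating
#'
#' An FBG reflects a narrow band centered at its Bragg wavelength
#' \eqn{\lambda_B}; axial strain shifts \eqn{\lambda_B} linearly. The spec
#' stores the nominal wavelength and the strain sensitivity measured during
#' calibration. A temperature sensitivity slot is kept for completeness but
#' defaults to zero: the intended recordings are short constant-temperature
#' breath-holds where thermal drift is negligible.
#'
#' @param label Channel label, e.g. `"FBG1"`.
#' @param lambda_B0 Nominal Bragg wavelength in nm (> 0).
#' @param S_eps Strain sensitivity in nm per m\eqn{\epsilon} (> 0).
#' @param S_T Temperature sensitivity in nm per degree C (default 0, inactive).
#' @param grating_length Length of the sensing element in mm (> 0).
#' @param center_position Center of the grating along the array axis, mm.
#'
#' @return An object of class `fbg_spec`.
#' @export
#' @examples
#' fbg_spec("FBG1", lambda_B0 = 1525, S_eps = 0.044)
fbg_spec <- function(label, lambda_B0, S_eps, S_T = 0,
                     grating_length = 10, center_position = NA_real_) {
  if (!is.character(label) || length(label) != 1L)
    stopf("`label` must be a single string")
  if (!is_number(lambda_B0) || lambda_B0 <= 0)
    stopf("`lambda_B0` must be a positive number (nm)")
  if (!is_number(S_eps) || S_eps <= 0)
    stopf("`S_eps` must be a positive number (nm per me)")
  if (!is_number(S_T)) stopf("`S_T` must be a number (nm per degree C)")
  if (!is_number(grating_length) || grating_length <= 0)
    stopf("`grating_length` must be a positive number (mm)")
  structure(
    list(label = label, lambda_B0 = lambda_B0, S_eps = S_eps, S_T = S_T,
         grating_length = grating_length,
         center_position = as.numeric(center_position)),
    class = "fbg_spec")
}

#' @export
print.fbg_spec <- function(x, ...) {
  cat(sprintf("<fbg_spec> %s: lambda_B0 = %g nm, S_eps = %g nm/me, length = %g mm\n",
              x$label, x$lambda_B0, x$S_eps, x$grating_length))
  invisible(x)
}

#' Specification of a four-grating sensing array
#'
#' The wearable patch embeds exactly four gratings in a soft polymer matrix.
#' Consecutive grating centers must be `grating_length + edge_to_edge_spacing`
#' apart (for equal-length gratings), which is checked at construction.
#'
#' @param gratings List of exactly 4 [fbg_spec()] objects, ordered along the
#'   array axis.
#' @param edge_to_edge_spacing Gap between consecutive grating edges, mm.
#' @param matrix_dims Length-3 numeric, overall matrix (length, width,
#'   thickness) in mm.
#'
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(gratings, edge_to_edge_spacing, matrix_dims) {
  if (!is.list(gratings) || length(gratings) != 4L ||
      !all(vapply(gratings, inherits, logical(1), "fbg_spec")))
    stopf("`gratings` must be a list of exactly 4 fbg_spec objects")
  if (!is_number(edge_to_edge_spacing) || edge_to_edge_spacing < 0)
    stopf("`edge_to_edge_spacing` must be a non-negative number (mm)")
  if (!is.numeric(matrix_dims) || length(matrix_dims) != 3L || any(matrix_dims <= 0))
    stopf("`matrix_dims` must be 3 positive numbers (length, width, thickness) in mm")
  centers <- vapply(gratings, `[[`, numeric(1), "center_position")
  lens <- vapply(gratings, `[[`, numeric(1), "grating_length")
  if (!anyNA(centers)) {
    expected <- (lens[-4] + lens[-1]) / 2 + edge_to_edge_spacing
    if (any(abs(diff(centers) - expected) > 1e-9))
      stopf("grating center positions inconsistent with grating_length + spacing")
  }
  structure(
    list(gratings = gratings,
         edge_to_edge_spacing = edge_to_edge_spacing,
         matrix_dims = as.numeric(matrix_dims)),
    class = "array_spec")
}

#' @export
print.array_spec <- function(x, ...) {
  cat(sprintf("<array_spec> 4 FBGs, spacing %g mm, matrix %s mm\n",
              x$edge_to_edge_spacing, paste(x$matrix_dims, collapse = " x ")))
  for (g in x$gratings) print(g)
  invisible(x)
}

#' Packaged default sensing array
#'
#' Reads the array specification shipped with the package
#' (`extdata/default_array.yaml`): four 10 mm gratings edge-to-edge spaced by
#' 20 mm with nominal wavelengths 1525/1533/1541/1549 nm, strain sensitivities
#' 0.044/0.045/0.045/0.046 nm per m\eqn{\epsilon}, in a 230 x 36 x 1 mm soft
#' matrix. Note: sensitivities are uniformly in nm per millistrain; published
#' sensor characterizations occasionally mix the m\eqn{\epsilon} and
#' \eqn{\mu\epsilon} unit symbols for values of this magnitude.
#'
#' @param path Optional path to an alternative YAML array file.
#' @return An `array_spec`.
#' @export
#' @examples
#' default_array()
default_array <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_array.yaml", package = "scghr",
                        mustWork = TRUE)
  read_array_spec(path)
}

#' Read an array specification from YAML
#'
#' @param path YAML file with an `array:` block (see the packaged
#'   `default_array.yaml` for the schema).
#' @return An `array_spec`.
#' @export
read_array_spec <- function(path) {
  y <- yaml::read_yaml(path)
  a <- y$array
  if (is.null(a)) stopf("array YAML must contain a top-level `array:` block")
  gratings <- lapply(a$gratings, function(g)
    fbg_spec(label = g$label, lambda_B0 = g$lambda_B0_nm,
             S_eps = g$S_eps_nm_per_me,
             S_T = if (is.null(g$S_T_nm_per_C)) 0 else g$S_T_nm_per_C,
             grating_length = g$grating_length_mm,
             center_position = g$center_position_mm))
  array_spec(gratings,
             edge_to_edge_spacing = a$edge_to_edge_spacing_mm,
             matrix_dims = unlist(a$matrix_dims_mm))
}

#' Strain to Bragg-wavelength shift
#'
#' Linear transduction model: \eqn{\Delta\lambda_B = S_\epsilon \epsilon +
#' S_T \Delta T}. The temperature term is inactive unless both `S_T` and `dT`
#' are nonzero.
#'
#' @param spec An [fbg_spec()].
#' @param strain Strain in m\eqn{\epsilon} (vectorized).
#' @param dT Temperature change in degrees C (default 0).
#' @return Wavelength shift(s) in nm.
#' @export
#' @examples
#' strain_to_shift(fbg_spec("FBG1", 1525, 0.044), 1)  # 0.044 nm
strain_to_shift <- function(spec, strain, dT = 0) {
  stopifnot(inherits(spec, "fbg_spec"))
  spec$S_eps * strain + spec$S_T * dT
}

#' Bragg-wavelength shift to strain
#'
#' Exact inverse of [strain_to_shift()] (temperature term at its default).
#'
#' @param spec An [fbg_spec()].
#' @param shift Wavelength shift(s) in nm.
#' @return Strain in m\eqn{\epsilon}.
#' @export
shift_to_strain <- function(spec, shift) {
  if (is.null(spec$S_eps) || !is_number(spec$S_eps) || spec$S_eps == 0)
    stopf("cannot invert transduction: zero or missing strain sensitivity")
  shift / spec$S_eps
}

#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit of wavelength shift against applied strain,
#' with a free intercept (calibration rigs rarely guarantee a true zero).
#'
#' @param strains Applied strains, m\eqn{\epsilon} (at least 2 distinct).
#' @param shifts Measured wavelength shifts, nm (same length).
#' @return A `calibration_fit` with fields `S_eps_hat` (nm/m\eqn{\epsilon}),
#'   `intercept` (nm), `residual_rms` (nm) and `n_points`.
#' @export
#' @examples
#' fit_calibration(c(0, 1, 2), c(0, 0.045, 0.090))
fit_calibration <- function(strains, shifts) {
  if (length(strains) != length(shifts))
    stopf("`strains` and `shifts` must have equal length")
  if (length(unique(strains)) < 2L)
    stopf("calibration requires at least 2 distinct strain values")
  fit <- stats::lm(shifts ~ strains)
  structure(
    list(S_eps_hat = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         residual_rms = sqrt(mean(stats::residuals(fit)^2)),
         n_points = length(strains)),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> S_eps = %.4g nm/me, intercept = %.3g nm, RMS = %.3g nm (n = %d)\n",
              x$S_eps_hat, x$intercept, x$residual_rms, x$n_points))
  invisible(x)
}

#' Hysteresis error of a loading/unloading cycle
#'
#' Maximum discrepancy between the loading and unloading branches, expressed
#' as a percentage of the full-scale output span of the loading branch -- the
#' usual sensor-metrology convention. Branches on different strain grids are
#' linearly interpolated onto the loading grid (restricted to the overlap).
#'
#' @param loading Two-column matrix or data frame `(strain, shift)`.
#' @param unloading Two-column matrix or data frame `(strain, shift)`.
#' @return Hysteresis error in percent.
#' @export
#' @examples
#' load <- cbind(0:2, c(0, 0.05, 0.10))
#' unload <- cbind(2:0, c(0.10, 0.07, 0))
#' hysteresis_error(load, unload)  # 20
hysteresis_error <- function(loading, unloading) {
  as_branch <- function(b, nm) {
    b <- as.matrix(b)
    if (ncol(b) != 2L || nrow(b) < 2L)
      stopf("`%s` must have 2 columns (strain, shift) and >= 2 rows", nm)
    b[order(b[, 1L]), , drop = FALSE]
  }
  ld <- as_branch(loading, "loading")
  ul <- as_branch(unloading, "unloading")
  span <- diff(range(ld[, 2L]))
  if (span == 0) stopf("zero full-scale output span on the loading branch")
  grid <- ld[, 1L]
  keep <- grid >= min(ul[, 1L]) & grid <= max(ul[, 1L])
  if (!any(keep)) stopf("loading and unloading branches do not overlap in strain")
  ul_on_grid <- stats::approx(ul[, 1L], ul[, 2L], xout = grid[keep])$y
  100 * max(abs(ld[keep, 2L] - ul_on_grid)) / abs(span)
}
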
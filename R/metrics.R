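# The cushioning and stress observables: landmark-to-surface minimum
# distances, baseline-normalized separation series, and stress scalars.

#' Minimum distance from points to a discretized surface
#'
#' Exact point-to-segment minimum over all segments of a closed 2-D polyline,
#' or exact point-to-triangle minimum over all faces of a 3-D surface mesh
#' (`surface = list(V = vertices, F = faces)`).
#'
#' @param points Query positions (n x 2 or n x 3 matrix, or a single point).
#' @param surface Polyline node matrix (m x 2) or `list(V, F)` triangle mesh.
#' @param closed Treat the polyline as a closed loop (default `TRUE`).
#' @return Minimum distances (m).
#' @export
min_distance <- function(points, surface, closed = TRUE) {
  if (!is.matrix(points)) points <- matrix(points, nrow = 1)
  if (is.list(surface) && !is.null(surface$V)) {
    stopifnot(ncol(points) == 3)
    return(cpp_min_dist_trimesh(points, surface$V, surface$F))
  }
  surface <- surface_matrix(surface)
  if (nrow(surface) < 2) abort("empty surface")
  cpp_min_dist_polyline(points, surface, closed)
}

#' Normalize a separation series by its baseline
#'
#' Divides each raw distance by its value at the first time point, so the
#' series starts at exactly 1; values below 1 indicate compression of the
#' fluid gap, above 1 increased separation.
#'
#' @param raw Either a numeric distance series, or a tidy tibble with
#'   columns `time`, `raw_m` and optionally `landmark` (normalized per
#'   landmark).
#' @return Same shape as the input with the normalized series (column
#'   `normalized` for tibbles).
#' @export
normalized_series <- function(raw) {
  norm1 <- function(x) {
    if (x[1] == 0) abort("zero baseline distance: cannot normalize")
    x / x[1]
  }
  if (is.numeric(raw)) return(norm1(raw))
  stopifnot(is.data.frame(raw), all(c("time", "raw_m") %in% names(raw)))
  if ("landmark" %in% names(raw)) {
    dplyr::mutate(dplyr::group_by(raw, .data$landmark),
                  normalized = norm1(.data$raw_m)) |> dplyr::ungroup()
  } else {
    dplyr::mutate(raw, normalized = norm1(.data$raw_m))
  }
}

#' Von Mises equivalent stress from principal stresses
#'
#' `sqrt(0.5 * ((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2))`; invariant under
#' permutation of the inputs and under a common hydrostatic offset.
#' `truncate = TRUE` truncates towards zero to an integer in the input units
#' (the convention used when such values are reported as whole kilopascals).
#'
#' @param s1,s2,s3 Principal stresses (any common unit).
#' @param truncate Truncate the result to an integer (default `FALSE`).
#' @return Equivalent stress, same unit as the inputs.
#' @export
von_mises <- function(s1, s2, s3, truncate = FALSE) {
  v <- sqrt(0.5 * ((s1 - s2)^2 + (s2 - s3)^2 + (s3 - s1)^2))
  if (truncate) trunc(v) else v
}

#' Mean stress and stress triaxiality
#'
#' `sigma_m = (s1 + s2 + s3) / 3` and `T = sigma_m / sigma_VM`. The
#' triaxiality is undefined for a hydrostatic state (zero von Mises stress)
#' and is returned as `NA` there.
#'
#' @inheritParams von_mises
#' @return A tibble with columns `mean_stress`, `von_mises`, `triaxiality`.
#' @export
triaxiality <- function(s1, s2, s3) {
  vm <- von_mises(s1, s2, s3)
  sm <- (s1 + s2 + s3) / 3
  tibble::tibble(mean_stress = sm, von_mises = vm,
                 triaxiality = ifelse(vm > 0, sm / vm, NA_real_))
}

#' First deviatoric principal stress
#'
#' Largest eigenvalue of the stress deviator `sigma - sigma_m I`, a measure
#' of the maximum shear loading. Invariant under rotation of the tensor and
#' zero for hydrostatic states.
#'
#' @param sigma Symmetric stress tensor (3 x 3).
#' @return First deviatoric principal stress (same unit as `sigma`).
#' @export
first_deviatoric_principal_stress <- function(sigma) {
  stopifnot(is.matrix(sigma), nrow(sigma) == 3, ncol(sigma) == 3)
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    abort("stress tensor must be symmetric")
  }
  dev <- sigma - diag(mean(diag(sigma)), 3)
  max(eigen(dev, symmetric = TRUE, only.values = TRUE)$values)
}

#' Stress attenuation percentage
#'
#' `100 * (1 - protected / unprotected)`. Negative values (amplification)
#' are allowed and flagged with a warning.
#'
#' @param protected_peak Peak value in the protected scenario.
#' @param unprotected_peak Peak value in the unprotected reference (> 0).
#' @return Attenuation in percent.
#' @export
attenuation_percent <- function(protected_peak, unprotected_peak) {
  if (any(unprotected_peak <= 0)) {
    abort("unprotected reference peak must be positive")
  }
  out <- 100 * (1 - protected_peak / unprotected_peak)
  if (any(out < 0)) {
    warning("protected peak exceeds the unprotected reference (amplification)")
  }
  out
}
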
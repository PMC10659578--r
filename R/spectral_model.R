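#' Gaussian absorption bands
#'
#' A band table describes the absorption spectrum of one redox species as a
#' sum of Gaussian bands in wavelength. `gaussian_bands()` builds a validated
#' band table; one row per band.
#'
#' @param center_nm Band centres (nm); must lie within 300--800 nm.
#' @param fwhm_nm Full widths at half maximum (nm); strictly positive.
#' @param peak_epsilon Molar absorptivity at the band centre
#'   (mM\eqn{^{-1}} cm\eqn{^{-1}}); non-negative.
#'
#' @return A tibble with columns `center_nm`, `fwhm_nm`, `peak_epsilon`.
#' @examples
#' gaussian_bands(center_nm = c(413, 550), fwhm_nm = c(28, 90),
#'                peak_epsilon = c(100, 10))
#' @export
gaussian_bands <- function(center_nm = numeric(), fwhm_nm = numeric(),
                           peak_epsilon = numeric()) {
  n <- length(center_nm)
  if (length(fwhm_nm) != n || length(peak_epsilon) != n) {
    stopf("band fields must have equal length (got %d, %d, %d).",
          n, length(fwhm_nm), length(peak_epsilon))
  }
  if (n > 0) {
    if (any(!is.finite(center_nm)) || any(center_nm < 300) || any(center_nm > 800)) {
      stopf("band centres must lie within [300, 800] nm.")
    }
    if (any(!is.finite(fwhm_nm)) || any(fwhm_nm <= 0)) {
      stopf("band fwhm_nm must be > 0.")
    }
    if (any(!is.finite(peak_epsilon)) || any(peak_epsilon < 0)) {
      stopf("band peak_epsilon must be >= 0.")
    }
  }
  tibble(center_nm = as.numeric(center_nm), fwhm_nm = as.numeric(fwhm_nm),
         peak_epsilon = as.numeric(peak_epsilon))
}

#' Default wavelength grid
#'
#' 350--700 nm at 1 nm spacing, covering the Soret and Q/alpha/beta regions
#' of b-type hemes and the flavin bands.
#'
#' @param from,to,by Grid limits and spacing in nm.
#' @return Numeric vector of wavelengths (nm).
#' @export
default_grid_nm <- function(from = 350, to = 700, by = 1) {
  seq(from, to, by = by)
}

#' Build a species absorption spectrum from Gaussian bands
#'
#' Evaluates \eqn{\epsilon(\lambda) = \sum_b \epsilon_b
#' \exp(-4 \ln 2 (\lambda - c_b)^2 / w_b^2)} on a uniform wavelength grid.
#' An empty band table yields an all-zero spectrum.
#'
#' @param bands A band table from [gaussian_bands()] (or any data frame with
#'   those columns). All band centres must lie within the grid range.
#' @param grid_nm Strictly increasing, uniformly spaced wavelength grid (nm).
#' @param name Species identifier.
#' @param redox_state One of `"ferric"`, `"ferrous"`, `"oxidized_flavin"`,
#'   `"reduced_flavin"`, `"other"`.
#'
#' @return A `species_spectrum`: a tibble with columns `wavelength_nm` and
#'   `epsilon` (mM\eqn{^{-1}} cm\eqn{^{-1}}) and attributes `name` and
#'   `redox_state`.
#' @examples
#' ferric <- build_species_spectrum(
#'   gaussian_bands(c(413, 550), c(28, 90), c(100, 10)),
#'   default_grid_nm(), "ferric_heme", "ferric")
#' ferric$wavelength_nm[which.max(ferric$epsilon)]  # 413
#' @export
build_species_spectrum <- function(bands, grid_nm = default_grid_nm(),
                                   name = "species",
                                   redox_state = c("other", "ferric", "ferrous",
                                                   "oxidized_flavin",
                                                   "reduced_flavin")) {
  redox_state <- match.arg(redox_state)
  if (length(grid_nm) < 2L) stopf("`grid_nm` must have at least two points.")
  check_increasing(grid_nm, "grid_nm")
  sp <- diff(grid_nm)
  if (max(sp) - min(sp) > 1e-9 * mean(sp)) {
    stopf("`grid_nm` must be uniformly spaced.")
  }
  bands <- gaussian_bands(bands$center_nm, bands$fwhm_nm, bands$peak_epsilon)
  if (nrow(bands) > 0 &&
      (any(bands$center_nm < min(grid_nm)) || any(bands$center_nm > max(grid_nm)))) {
    stopf("band centre(s) %s nm fall outside the grid range [%g, %g] nm.",
          paste(bands$center_nm[bands$center_nm < min(grid_nm) |
                                  bands$center_nm > max(grid_nm)], collapse = ", "),
          min(grid_nm), max(grid_nm))
  }
  eps <- rep(0, length(grid_nm))
  for (i in seq_len(nrow(bands))) {
    eps <- eps + bands$peak_epsilon[i] *
      exp(-4 * log(2) * (grid_nm - bands$center_nm[i])^2 / bands$fwhm_nm[i]^2)
  }
  out <- tibble(wavelength_nm = as.numeric(grid_nm), epsilon = eps)
  attr(out, "name") <- name
  attr(out, "redox_state") <- redox_state
  class(out) <- c("species_spectrum", class(out))
  out
}

#' Assemble a species library on a shared wavelength grid
#'
#' @param ... `species_spectrum` objects (all on the identical grid), or a
#'   single list of them. Names are taken from the spectra.
#' @return A `species_library`: a tibble with `wavelength_nm` first and one
#'   epsilon column per species; redox states kept in the `redox_states`
#'   attribute.
#' @export
species_library <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "species_spectrum")) {
    specs <- specs[[1]]
  }
  if (length(specs) == 0L) stopf("a species library needs at least one spectrum.")
  nm <- vapply(specs, function(s) attr(s, "name") %||% NA_character_, character(1))
  if (anyNA(nm) || anyDuplicated(nm)) stopf("species names must be present and unique.")
  grid <- specs[[1]]$wavelength_nm
  for (s in specs[-1]) {
    if (length(s$wavelength_nm) != length(grid) ||
        any(abs(s$wavelength_nm - grid) > 1e-9)) {
      stopf("all spectra in a library must share one wavelength grid.")
    }
  }
  out <- tibble(wavelength_nm = grid)
  for (i in seq_along(specs)) out[[nm[i]]] <- specs[[i]]$epsilon
  attr(out, "redox_states") <- setNames(
    vapply(specs, function(s) attr(s, "redox_state") %||% "other", character(1)), nm)
  class(out) <- c("species_library", class(out))
  out
}

#' @export
print.species_library <- function(x, ...) {
  cat("<species_library> ", ncol(x) - 1L, " species on ",
      min(x$wavelength_nm), "-", max(x$wavelength_nm), " nm (",
      nrow(x), " points)\n", sep = "")
  cat("  species:", paste(names(x)[-1], collapse = ", "), "\n")
  invisible(x)
}

library_species <- function(library) names(library)[-1L]

#' Compose mixture absorbance by Beer--Lambert
#'
#' \eqn{A(\lambda) = \sum_i \epsilon_i(\lambda) \, (c_i/1000) \, \ell} with
#' concentrations in \eqn{\mu}M, absorptivities in mM\eqn{^{-1}}
#' cm\eqn{^{-1}} and pathlength \eqn{\ell} in cm. Exactly linear and
#' homogeneous in each concentration.
#'
#' @param library A [species_library()].
#' @param concentrations Named numeric vector of concentrations
#'   (\eqn{\mu}M); every name must be a library species; values >= 0.
#' @param pathlength_cm Optical pathlength (cm), default 1.
#' @return A tibble with columns `wavelength_nm` and `absorbance` (AU).
#' @export
compose_absorbance <- function(library, concentrations, pathlength_cm = 1) {
  if (!inherits(library, "species_library")) stopf("`library` must be a species_library.")
  check_number(pathlength_cm, "pathlength_cm", lower = 0)
  if (is.null(names(concentrations)) || any(names(concentrations) == "")) {
    stopf("`concentrations` must be a fully named vector.")
  }
  unknown <- setdiff(names(concentrations), library_species(library))
  if (length(unknown) > 0) {
    stopf("species not in library: %s", paste(unknown, collapse = ", "))
  }
  if (any(concentrations < 0)) stopf("concentrations must be >= 0.")
  a <- rep(0, nrow(library))
  for (sp in names(concentrations)) {
    a <- a + library[[sp]] * (concentrations[[sp]] / 1000) * pathlength_cm
  }
  tibble(wavelength_nm = library$wavelength_nm, absorbance = a)
}

#' Locate isosbestic points of two species spectra
#'
#' Returns the wavelengths where the two absorptivities coincide: grid points
#' with \eqn{|\Delta\epsilon| <} `tol`, plus sign-change crossings between
#' grid points located by linear interpolation. At an isosbestic wavelength
#' the total absorbance of a closed two-species interconversion is
#' time-invariant, which makes these points a useful consistency check on
#' rapid-scan data.
#'
#' @param spec_a,spec_b `species_spectrum` objects on the same grid.
#' @param tol Absolute tolerance on \eqn{|\Delta\epsilon|} at grid points
#'   (mM\eqn{^{-1}} cm\eqn{^{-1}}).
#' @return Sorted numeric vector of wavelengths (nm); may be empty.
#' @export
find_isosbestic <- function(spec_a, spec_b, tol = 1e-6) {
  if (length(spec_a$wavelength_nm) != length(spec_b$wavelength_nm) ||
      any(abs(spec_a$wavelength_nm - spec_b$wavelength_nm) > 1e-9)) {
    stopf("the two spectra must share one wavelength grid.")
  }
  check_number(tol, "tol", lower = 0)
  w <- spec_a$wavelength_nm
  d <- spec_a$epsilon - spec_b$epsilon
  hits <- w[abs(d) < tol]
  s <- sign(d)
  cross <- which(s[-1] * s[-length(s)] < 0)
  for (i in cross) {
    # linear interpolation of the zero of d between grid points i and i+1
    lam <- w[i] + (w[i + 1] - w[i]) * d[i] / (d[i] - d[i + 1])
    hits <- c(hits, lam)
  }
  sort(unique(hits))
}

#' @rdname build_species_spectrum
#' @param x,... print arguments.
#' @export
print.species_spectrum <- function(x, ...) {
  cat("<species_spectrum> ", attr(x, "name"), " [", attr(x, "redox_state"), "], ",
      nrow(x), " points, peak ", round(max(x$epsilon), 3), " mM-1 cm-1 at ",
      x$wavelength_nm[which.max(x$epsilon)], " nm\n", sep = "")
  invisible(x)
}
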
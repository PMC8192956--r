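#' Treatment and tissue-layer vocabularies
#'
#' The six treatment groups of the study design (fresh control, freeze-dried,
#' freeze-dried + 1 month storage at 4 or 37 degrees C, and oxidative damage
#' induced with H2O2 or FeCl3) and the three tissue layers (valve leaflet,
#' arterial intima, arterial externa). The treatment order returned here is
#' the canonical class order used for one-hot encoding, confusion-matrix axes
#' and tie-breaking everywhere in the package.
#'
#' @return Character vector of admissible labels.
#' @export
treatment_levels <- function() {
  c("control", "freeze_dried", "stored_4C", "stored_37C", "H2O2", "FeCl3")
}

#' @rdname treatment_levels
#' @export
layer_levels <- function() {
  c("leaflet", "intima", "externa")
}

#' Specimen metadata
#'
#' @param valve_id Identifier of the valve/animal the specimen came from.
#' @param layer Tissue layer, one of [layer_levels()].
#' @param treatment Treatment group, one of [treatment_levels()].
#' @return A `specimen_meta` object.
#' @export
specimen_meta <- function(valve_id, layer, treatment) {
  if (!is.character(layer) || length(layer) != 1L || !(layer %in% layer_levels())) {
    vs_abort(sprintf("unknown tissue layer '%s'", paste(layer, collapse = ",")),
             "valvespectra_metadata_error")
  }
  if (!is.character(treatment) || length(treatment) != 1L ||
      !(treatment %in% treatment_levels())) {
    vs_abort(sprintf("unknown treatment '%s'", paste(treatment, collapse = ",")),
             "valvespectra_metadata_error")
  }
  structure(list(valve_id = as.character(valve_id), layer = layer,
                 treatment = treatment),
            class = "specimen_meta")
}

#' A single absorbance spectrum
#'
#' Wavenumbers are stored ascending internally regardless of input order
#' (FTIR spectra are conventionally displayed with decreasing wavenumber; the
#' writer can emit descending order).
#'
#' @param wavenumbers Numeric vector of wavenumbers (cm^-1), strictly monotone.
#' @param absorbance Numeric vector of absorbance values, same length.
#' @param meta Optional [specimen_meta()].
#' @return An `ftir_spectrum` object.
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, meta = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    vs_abort("wavenumbers and absorbance must have equal length",
             "valvespectra_format_error")
  }
  if (length(wavenumbers) < 1L) {
    vs_abort("empty spectrum", "valvespectra_format_error")
  }
  if (anyNA(wavenumbers) || anyNA(absorbance) ||
      any(!is.finite(wavenumbers)) || any(!is.finite(absorbance))) {
    vs_abort("non-finite values in spectrum", "valvespectra_value_error")
  }
  if (anyDuplicated(wavenumbers)) {
    vs_abort("duplicated wavenumbers", "valvespectra_format_error")
  }
  d <- diff(wavenumbers)
  if (length(d) > 0L && !(all(d > 0) || all(d < 0))) {
    vs_abort("wavenumbers must be strictly monotone", "valvespectra_format_error")
  }
  if (length(d) > 0L && all(d < 0)) {
    ord <- order(wavenumbers)
    wavenumbers <- wavenumbers[ord]
    absorbance <- absorbance[ord]
  }
  if (!is.null(meta) && !inherits(meta, "specimen_meta")) {
    vs_abort("meta must be a specimen_meta object", "valvespectra_metadata_error")
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance, meta = meta),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("<ftir_spectrum> %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), rng[1], rng[2]))
  if (!is.null(x$meta)) {
    cat(sprintf("  valve %s | %s | %s\n",
                x$meta$valve_id, x$meta$layer, x$meta$treatment))
  }
  invisible(x)
}

#' A collection of spectra, optionally on a shared wavenumber grid
#'
#' @param spectra List of [ftir_spectrum()] objects.
#' @param common_grid Optional numeric grid; if given, every member's
#'   wavenumbers must equal it exactly.
#' @return A `spectrum_set` object.
#' @export
spectrum_set <- function(spectra, common_grid = NULL) {
  if (!is.list(spectra) || !all(vapply(spectra, inherits, logical(1), "ftir_spectrum"))) {
    vs_abort("spectra must be a list of ftir_spectrum objects",
             "valvespectra_format_error")
  }
  if (!is.null(common_grid)) {
    common_grid <- as.numeric(common_grid)
    ok <- vapply(spectra, function(s) {
      length(s$wavenumbers) == length(common_grid) &&
        all(s$wavenumbers == common_grid)
    }, logical(1))
    if (!all(ok)) {
      vs_abort("not all spectra lie on the declared common grid",
               "valvespectra_format_error")
    }
  }
  structure(list(spectra = spectra, common_grid = common_grid),
            class = "spectrum_set")
}

#' @export
length.spectrum_set <- function(x) length(x$spectra)

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra%s\n", length(x$spectra),
              if (is.null(x$common_grid)) "" else
                sprintf(", common grid of %d points", length(x$common_grid))))
  invisible(x)
}

#' Specimen metadata of a set as a table
#'
#' @param set A [spectrum_set()].
#' @return A tibble with columns `valve_id`, `layer`, `treatment`.
#' @export
set_metadata <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  rows <- lapply(set$spectra, function(s) {
    m <- s$meta
    if (is.null(m)) {
      tibble::tibble(valve_id = NA_character_, layer = NA_character_,
                     treatment = NA_character_)
    } else {
      tibble::tibble(valve_id = m$valve_id, layer = m$layer, treatment = m$treatment)
    }
  })
  do.call(rbind, rows)
}

#' Default working wavenumber grid
#'
#' A uniform grid at 1 cm^-1 spacing spanning the instrument's 4000-525 cm^-1
#' acquisition range. The instrument resolution is 4 cm^-1 and the data-point
#' spacing after zero filling is finer; 1 cm^-1 is used because the 21-point
#' Savitzky-Golay second-derivative window then spans 21 cm^-1, narrow enough
#' to resolve sub-bands 20 cm^-1 apart (2850/2870, 1630/1650) as distinct
#' derivative extrema — at 2 cm^-1 spacing the same 21-point window spans
#' 42 cm^-1 and merges every such pair, defeating the band-ratio method.
#' Spacing is configurable here.
#'
#' @param lo,hi Range bounds in cm^-1.
#' @param by Spacing in cm^-1.
#' @return Ascending numeric vector of wavenumbers.
#' @export
default_grid <- function(lo = 525, hi = 4000, by = 1) {
  seq(lo, hi, by = by)
}
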
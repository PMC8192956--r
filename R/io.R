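#' Read specimen spectra from disk
#'
#' Two dialects are supported. `two_column`: one file per specimen with
#' columns wavenumber, absorbance (header optional); specimen metadata come
#' from a sidecar CSV with columns `file, valve_id, layer, treatment`.
#' `wide_table`: a single CSV whose first column is the wavenumber and every
#' further column one specimen; metadata CSV columns are
#' `specimen, valve_id, layer, treatment` where `specimen` matches the
#' spectrum column name.
#'
#' Spectra are stored with ascending wavenumbers regardless of file order;
#' values are not modified.
#'
#' @param path Path to the spectrum file (two_column) or the wide CSV.
#' @param dialect `"two_column"` or `"wide_table"`.
#' @param metadata Optional path to the metadata CSV (or a data.frame).
#'   Required for `wide_table` if treatment/layer information is wanted.
#' @return A [spectrum_set()].
#' @export
read_spectrum_table <- function(path, dialect = c("two_column", "wide_table"),
                                metadata = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    vs_abort(sprintf("file not found: %s", path), "valvespectra_format_error")
  }
  meta_df <- NULL
  if (!is.null(metadata)) {
    meta_df <- if (is.data.frame(metadata)) metadata else {
      if (!file.exists(metadata)) {
        vs_abort(sprintf("metadata file not found: %s", metadata),
                 "valvespectra_metadata_error")
      }
      read.csv(metadata, stringsAsFactors = FALSE)
    }
  }

  if (dialect == "two_column") {
    df <- tryCatch(read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#"),
                   error = function(e) vs_abort(conditionMessage(e),
                                                "valvespectra_format_error"))
    # tolerate a header line
    if (nrow(df) > 0 && any(is.na(suppressWarnings(as.numeric(df[1, ]))))) {
      df <- df[-1, , drop = FALSE]
    }
    if (ncol(df) < 2) {
      vs_abort("two_column file must have two columns", "valvespectra_format_error")
    }
    nu <- suppressWarnings(as.numeric(df[[1]]))
    ab <- suppressWarnings(as.numeric(df[[2]]))
    if (anyNA(nu) || anyNA(ab)) {
      vs_abort("non-numeric entries in spectrum file", "valvespectra_value_error")
    }
    meta <- NULL
    if (!is.null(meta_df)) {
      hit <- meta_df[basename(as.character(meta_df$file)) == basename(path), , drop = FALSE]
      if (nrow(hit) == 1L) {
        meta <- specimen_meta(hit$valve_id, hit$layer, hit$treatment)
      }
    }
    s <- ftir_spectrum(nu, ab, meta = meta)
    return(spectrum_set(list(s), common_grid = s$wavenumbers))
  }

  # wide_table
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) vs_abort(conditionMessage(e),
                                              "valvespectra_format_error"))
  if (ncol(df) < 2) {
    vs_abort("wide table needs a wavenumber column plus >= 1 specimen column",
             "valvespectra_format_error")
  }
  nu <- suppressWarnings(as.numeric(df[[1]]))
  if (anyNA(nu)) vs_abort("non-numeric wavenumber column", "valvespectra_value_error")
  specs <- lapply(names(df)[-1], function(nm) {
    ab <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(ab)) {
      vs_abort(sprintf("non-numeric absorbance in column '%s'", nm),
               "valvespectra_value_error")
    }
    meta <- NULL
    if (!is.null(meta_df)) {
      hit <- meta_df[as.character(meta_df$specimen) == nm, , drop = FALSE]
      if (nrow(hit) == 0L) {
        vs_abort(sprintf("no metadata row for specimen '%s'", nm),
                 "valvespectra_metadata_error")
      }
      meta <- specimen_meta(hit$valve_id[1], hit$layer[1], hit$treatment[1])
    }
    ftir_spectrum(nu, ab, meta = meta)
  })
  spectrum_set(specs, common_grid = sort(nu))
}

#' Write a spectrum set as a wide CSV
#'
#' All spectra must share a common grid. Column names are taken from valve id,
#' layer and treatment when metadata are present.
#'
#' @param set A [spectrum_set()] with a common grid.
#' @param path Output CSV path.
#' @param descending Emit rows in descending wavenumber order (the usual FTIR
#'   display convention) instead of the ascending internal order.
#' @return `path`, invisibly. Writes a `<path>_metadata.csv` sidecar when all
#'   spectra carry metadata.
#' @export
write_spectrum_table <- function(set, path, descending = FALSE) {
  stopifnot(inherits(set, "spectrum_set"))
  if (is.null(set$common_grid)) {
    vs_abort("set has no common grid; resample first", "valvespectra_format_error")
  }
  nms <- vapply(seq_along(set$spectra), function(i) {
    m <- set$spectra[[i]]$meta
    if (is.null(m)) sprintf("spec%03d", i) else
      sprintf("%s_%s_%s", m$valve_id, m$layer, m$treatment)
  }, character(1))
  nms <- make.unique(nms, sep = "_")
  mat <- vapply(set$spectra, function(s) s$absorbance,
                numeric(length(set$common_grid)))
  df <- data.frame(wavenumber = set$common_grid, mat, check.names = FALSE)
  names(df)[-1] <- nms
  if (descending) df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  if (all(!vapply(set$spectra, function(s) is.null(s$meta), logical(1)))) {
    md <- set_metadata(set)
    md <- cbind(specimen = nms, md)
    write.csv(md, sub("\\.csv$", "_metadata.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' Resample a spectrum onto a new grid by linear interpolation
#'
#' Grid points that coincide with source nodes reproduce the source values
#' exactly; extrapolation is refused.
#'
#' @param s An [ftir_spectrum()].
#' @param grid Target wavenumber grid, within the spectrum's range.
#' @return An `ftir_spectrum` on `grid`.
#' @export
resample_to_grid <- function(s, grid) {
  stopifnot(inherits(s, "ftir_spectrum"))
  grid <- sort(as.numeric(grid))
  rng <- range(s$wavenumbers)
  if (min(grid) < rng[1] || max(grid) > rng[2]) {
    vs_abort("requested grid extends beyond the spectrum's range (extrapolation refused)",
             "valvespectra_range_error")
  }
  idx <- match(grid, s$wavenumbers)
  ab <- numeric(length(grid))
  hit <- !is.na(idx)
  ab[hit] <- s$absorbance[idx[hit]]
  if (any(!hit)) {
    ab[!hit] <- approx(s$wavenumbers, s$absorbance, xout = grid[!hit])$y
  }
  ftir_spectrum(grid, ab, meta = s$meta)
}

#' Extract a closed wavenumber interval from a spectrum
#'
#' Returns all points with `lo <= wavenumber <= hi` (both endpoints
#' inclusive); metadata are preserved.
#'
#' @param s An [ftir_spectrum()].
#' @param lo,hi Interval bounds in cm^-1, `lo < hi`.
#' @return An `ftir_spectrum` restricted to the interval.
#' @export
extract_region <- function(s, lo, hi) {
  stopifnot(inherits(s, "ftir_spectrum"))
  if (!(lo < hi)) vs_abort("lo must be < hi", "valvespectra_region_error")
  keep <- s$wavenumbers >= lo & s$wavenumbers <= hi
  if (!any(keep)) {
    vs_abort(sprintf("region [%g, %g] contains no data points", lo, hi),
             "valvespectra_region_error")
  }
  ftir_spectrum(s$wavenumbers[keep], s$absorbance[keep], meta = s$meta)
}

#' JCAMP-DX import (not implemented)
#'
#' JCAMP-DX ingestion is a documented non-goal of this package; convert to
#' two-column or wide CSV upstream.
#'
#' @param path Ignored.
#' @export
read_jcampdx <- function(path) {
  vs_abort("JCAMP-DX import is not implemented; export your spectra as CSV",
           "valvespectra_format_error")
}
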
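#' CH2/CH3 symmetric-stretch band intensity ratio
#'
#' The lipid/protein acyl-chain marker I(nu_sy CH2)/I(nu_sy CH3). The
#' 2900-2830 cm^-1 region is extracted, vector-normalized, and the inverted
#' Savitzky-Golay second derivative computed; the ratio is the peak intensity
#' near 2850 cm^-1 (CH2 symmetric stretch) over the peak intensity near
#' 2870 cm^-1 (CH3 symmetric stretch).
#'
#' @param s An [ftir_spectrum()] covering 2830-2900 cm^-1.
#' @param sg_window,sg_poly Savitzky-Golay window length and polynomial order.
#' @param halfwidth Peak-search half-width around the nominal centers (cm^-1).
#' @param normalize Normalization method, see [vector_normalize()].
#' @return Ratio (numeric scalar) with attributes `located_centers` (named,
#'   cm^-1) and `boundary` (logical).
#' @export
ch2_ch3_ratio <- function(s, sg_window = 21, sg_poly = 3, halfwidth = 10,
                          normalize = "unit_norm") {
  d <- region_derivative(s, 2830, 2900, sg_window, sg_poly,
                         normalize = normalize)
  p_ch2 <- peak_intensity(d, band_definition("CH2_sym", 2850, halfwidth))
  p_ch3 <- peak_intensity(d, band_definition("CH3_sym", 2870, halfwidth))
  r <- extract_region(s, 2830, 2900)
  eps <- 1e-12 * max(abs(vector_normalize(r$absorbance, method = normalize)))
  if (!(p_ch3$intensity > eps)) {
    vs_abort("CH3 symmetric-stretch peak is absent or negligible; ratio undefined",
             "valvespectra_degenerate_ratio_error")
  }
  structure(p_ch2$intensity / p_ch3$intensity,
            located_centers = c(CH2_sym = p_ch2$located_center,
                                CH3_sym = p_ch3$located_center),
            boundary = p_ch2$boundary || p_ch3$boundary)
}

# Inverted SG second derivative over [lo, hi], computed on a region padded by
# the SG half-window so the band-search windows never touch the one-sided
# edge fits. When `normalize` is a method name, values are scaled to match
# the derivative of the normalized [lo, hi] region (the scale cancels in any
# intensity ratio, but keeps exported intensities on the conventional scale).
region_derivative <- function(s, lo, hi, sg_window, sg_poly, normalize = NULL) {
  spacing <- mean(diff(s$wavenumbers))
  pad <- (sg_window - 1) / 2 * spacing
  rng <- range(s$wavenumbers)
  rp <- extract_region(s, max(rng[1], lo - pad), min(rng[2], hi + pad))
  d <- second_derivative(rp, window_points = sg_window, poly_order = sg_poly,
                         invert = TRUE)
  keep <- d$wavenumbers >= lo & d$wavenumbers <= hi
  vals <- d$values[keep]
  if (!is.null(normalize)) {
    raw <- extract_region(s, lo, hi)$absorbance
    scl <- if (normalize == "snv") sd(raw) else sqrt(sum(raw^2))
    if (scl == 0) {
      vs_abort("cannot normalize a constant region",
               "valvespectra_degenerate_input_error")
    }
    vals <- vals / scl
  }
  structure(list(wavenumbers = d$wavenumbers[keep], values = vals,
                 inverted = TRUE, meta = s$meta),
            class = "derivative_spectrum")
}

#' Amide-I / amide-II band area ratio
#'
#' A(nu CO)/A(delta NH): the baseline-corrected area of the amide-I band
#' (integrated between 1709 and 1591 cm^-1) over that of the amide-II band
#' (between 1592 and 1520 cm^-1), both computed on the original
#' (non-derivative, non-normalized) spectrum. The printed integration limits
#' are used verbatim, including the 1 cm^-1 seam at 1591/1592.
#'
#' @param s An [ftir_spectrum()] covering 1520-1709 cm^-1.
#' @return Ratio (numeric scalar).
#' @export
amide_area_ratio <- function(s) {
  a1 <- baseline_corrected_area(s, 1591, 1709)
  a2 <- baseline_corrected_area(s, 1520, 1592)
  eps <- 1e-12 * (1592 - 1520) *
    max(abs(extract_region(s, 1520, 1592)$absorbance))
  if (!(a2 > eps)) {
    vs_abort("amide-II area is zero or negative; area ratio undefined",
             "valvespectra_degenerate_ratio_error")
  }
  a1 / a2
}

#' beta-sheet / alpha-helix intensity ratio from the amide-I sub-bands
#'
#' I(beta-sheet)/I(alpha-helix): inverted Savitzky-Golay second derivative of
#' the 1700-1600 cm^-1 region; ratio of the peak intensity near 1630 cm^-1
#' (beta-sheet) over that near 1650 cm^-1 (alpha-helix). Boundary-maximum
#' warnings from either peak are propagated: a single broad band spanning
#' both windows has no resolved sub-bands.
#'
#' @inheritParams ch2_ch3_ratio
#' @param s An [ftir_spectrum()] covering 1600-1700 cm^-1.
#' @return Ratio (numeric scalar) with attributes as in [ch2_ch3_ratio()].
#' @export
beta_alpha_ratio <- function(s, sg_window = 21, sg_poly = 3, halfwidth = 10) {
  d <- region_derivative(s, 1600, 1700, sg_window, sg_poly, normalize = NULL)
  p_beta <- peak_intensity(d, band_definition("beta_sheet", 1630, halfwidth))
  p_alpha <- peak_intensity(d, band_definition("alpha_helix", 1650, halfwidth))
  eps <- 1e-12 * max(abs(extract_region(s, 1600, 1700)$absorbance))
  if (!(p_alpha$intensity > eps)) {
    vs_abort("alpha-helix peak is absent or negligible; ratio undefined",
             "valvespectra_degenerate_ratio_error")
  }
  structure(p_beta$intensity / p_alpha$intensity,
            located_centers = c(beta_sheet = p_beta$located_center,
                                alpha_helix = p_alpha$located_center),
            boundary = p_beta$boundary || p_alpha$boundary)
}

#' Compute all three band-ratio biomarkers for every specimen of a set
#'
#' Ratios that cannot be computed (degenerate spectra) are reported as `NA`
#' with the failure message in the `note` column — never silently zero.
#'
#' @param set A [spectrum_set()].
#' @return A tibble with one row per specimen: metadata, `ch2_ch3`,
#'   `amide_area_ratio`, `beta_alpha`, located band centers, and `note`.
#' @export
band_ratio_table <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  rows <- lapply(set$spectra, function(s) {
    m <- s$meta
    note <- character(0)
    grab <- function(expr) {
      tryCatch(suppressWarnings(expr), error = function(e) {
        note <<- c(note, conditionMessage(e)); NA_real_
      })
    }
    cc <- grab(ch2_ch3_ratio(s))
    aa <- grab(amide_area_ratio(s))
    ba <- grab(beta_alpha_ratio(s))
    ctr <- function(x, nm) {
      lc <- attr(x, "located_centers")
      if (is.null(lc)) NA_real_ else unname(lc[nm])
    }
    tibble::tibble(
      valve_id = if (is.null(m)) NA_character_ else m$valve_id,
      layer = if (is.null(m)) NA_character_ else m$layer,
      treatment = if (is.null(m)) NA_character_ else m$treatment,
      ch2_ch3 = as.numeric(cc),
      amide_area_ratio = as.numeric(aa),
      beta_alpha = as.numeric(ba),
      ch2_center = ctr(cc, "CH2_sym"), ch3_center = ctr(cc, "CH3_sym"),
      beta_center = ctr(ba, "beta_sheet"), alpha_center = ctr(ba, "alpha_helix"),
      note = if (length(note)) paste(note, collapse = "; ") else NA_character_
    )
  })
  do.call(rbind, rows)
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' Fixed-effects one-way ANOVA across treatment groups followed by Tukey's
#' honestly-significant-difference pairwise comparisons (Tukey-Kramer on
#' unbalanced designs, via [stats::TukeyHSD()]). Groups are labelled with a
#' compact letter display assigned by insert-and-absorb over the pairwise
#' significance graph: groups sharing a letter are not significantly
#' different at `alpha`. Letters start at the group with the largest mean;
#' ties are broken by treatment enum order.
#'
#' @param values Numeric vector, one biomarker value per specimen.
#' @param groups Group label per specimen (character or factor).
#' @param feature_name Optional label carried through to the output.
#' @param alpha Significance level for the letter display. Default 0.05.
#' @return A `group_comparison` object: list with `feature_name`, `anova_p`,
#'   `tukey` (pairwise table), and `table` (tibble: group, n, mean, sd,
#'   letters).
#' @export
group_comparison <- function(values, groups, feature_name = NULL, alpha = 0.05) {
  values <- as.numeric(values)
  lev <- if (all(unique(as.character(groups)) %in% treatment_levels())) {
    intersect(treatment_levels(), unique(as.character(groups)))
  } else unique(as.character(groups))
  g <- factor(as.character(groups), levels = lev)
  if (length(values) != length(g)) {
    vs_abort("values and groups must have equal length",
             "valvespectra_precondition_error")
  }
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]; g <- droplevels(g[keep])
  cnt <- table(g)
  if (nlevels(g) < 2L || any(cnt < 2L)) {
    vs_abort("need >= 2 groups with >= 2 specimens each",
             "valvespectra_precondition_error")
  }
  within_var <- tapply(values, g, stats::var)
  if (all(within_var == 0)) {
    vs_abort("zero within-group variance in every group; ANOVA undefined",
             "valvespectra_degenerate_statistics_error")
  }
  fit <- aov(values ~ g, data = data.frame(values = values, g = g))
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  means <- tapply(values, g, mean)
  sds <- tapply(values, g, sd)
  letters <- cld_insert_absorb(rownames(tk), tk[, "p adj"] <= alpha,
                               means, levels(g))
  structure(list(
    feature_name = feature_name,
    anova_p = anova_p,
    tukey = tk,
    table = tibble::tibble(group = levels(g), n = as.integer(cnt),
                           mean = as.numeric(means), sd = as.numeric(sds),
                           letters = letters[levels(g)])
  ), class = "group_comparison")
}

# compact letter display by insert-and-absorb: start from one set holding all
# groups; for every significant pair split each set containing both; absorb
# redundant subsets; assign letters to sets ordered by descending member mean
# (enum order on ties).
cld_insert_absorb <- function(pair_names, significant, means, lev) {
  sets <- list(lev)
  pairs <- strsplit(pair_names, "-", fixed = TRUE)
  for (k in seq_along(pairs)) {
    if (!significant[k]) next
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    new_sets <- list()
    for (S in sets) {
      if (a %in% S && b %in% S) {
        new_sets <- c(new_sets, list(setdiff(S, a)), list(setdiff(S, b)))
      } else {
        new_sets <- c(new_sets, list(S))
      }
    }
    # absorb: canonicalize member order, then drop duplicates and subsets
    new_sets <- lapply(new_sets[lengths(new_sets) > 0],
                       function(S) lev[lev %in% S])
    new_sets <- unique(new_sets)
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] && length(new_sets[[i]]) < length(new_sets[[j]]) &&
            all(new_sets[[i]] %in% new_sets[[j]])) {
          keep[i] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  # order sets by the largest member mean, descending; enum order breaks ties
  set_rank <- vapply(sets, function(S) max(means[S]), numeric(1))
  set_tie <- vapply(sets, function(S) min(match(S, lev)), numeric(1))
  sets <- sets[order(-set_rank, set_tie)]
  out <- setNames(rep("", length(lev)), lev)
  for (i in seq_along(sets)) {
    for (gname in sets[[i]]) out[gname] <- paste0(out[gname], letters[i])
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s ANOVA p = %.4g\n",
              if (is.null(x$feature_name)) "" else paste0(" ", x$feature_name, ":"),
              x$anova_p))
  print(x$table)
  invisible(x)
}

#' Group-comparison summary of all band ratios, per tissue layer
#'
#' Applies [group_comparison()] to each biomarker within each layer present
#' in a [band_ratio_table()] result, producing the mean +/- SD + letters
#' layout of a treatment-effect figure.
#'
#' @param ratios Tibble from [band_ratio_table()].
#' @param alpha Significance level.
#' @return Tibble: layer, feature, group, n, mean, sd, letters, anova_p.
#' @export
summarize_band_ratios <- function(ratios, alpha = 0.05) {
  feats <- c("ch2_ch3", "amide_area_ratio", "beta_alpha")
  out <- list()
  for (ly in unique(ratios$layer)) {
    sub <- ratios[ratios$layer == ly, , drop = FALSE]
    for (f in feats) {
      gc <- group_comparison(sub[[f]], sub$treatment, feature_name = f,
                             alpha = alpha)
      tb <- gc$table
      tb <- tibble::add_column(tb, layer = ly, feature = f, .before = 1)
      tb$anova_p <- gc$anova_p
      out[[paste(ly, f)]] <- tb
    }
  }
  do.call(rbind, out)
}
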
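# Chlorophyll a/b quantification from buffered 80 %-acetone extracts.

# Coefficient matrix of the two-wavelength quantification in buffered
# 80 % acetone (ug/ml from absorbances at 663.6 and 646.6 nm, 1 cm
# pathlength): chl_a = 12.25 A663.6 - 2.55 A646.6;
# chl_b = 20.31 A646.6 - 4.91 A663.6.
.CHL_COEF <- matrix(c(12.25, -2.55,
                      -4.91, 20.31),
                    nrow = 2L, byrow = TRUE,
                    dimnames = list(c("chl_a", "chl_b"),
                                    c("a663_6", "a646_6")))

#' Describe a pigment extract measurement
#'
#' @param a663_6,a646_6 Absorbances at 663.6 and 646.6 nm (1 cm path).
#' @param a750 Turbidity reference absorbance, subtracted from both
#'   readings before quantification (default 0).
#' @param dilution_factor Dilution applied before reading (>= 1).
#' @param extract_volume_ml Extract volume, ml.
#' @param fresh_weight_mg Fresh weight of the extracted tissue, mg.
#' @return An object of class `pigment_sample`.
#' @export
pigment_sample <- function(a663_6, a646_6, a750 = 0,
                           dilution_factor = 1,
                           extract_volume_ml = 1,
                           fresh_weight_mg = NA_real_) {
  if (dilution_factor < 1) {
    stop("dilution_factor must be >= 1", call. = FALSE)
  }
  if (a663_6 - a750 < 0 || a646_6 - a750 < 0) {
    stop("absorbances must be >= 0 after turbidity correction",
         call. = FALSE)
  }
  structure(list(a663_6 = a663_6, a646_6 = a646_6, a750 = a750,
                 dilution_factor = dilution_factor,
                 extract_volume_ml = extract_volume_ml,
                 fresh_weight_mg = fresh_weight_mg),
            class = "pigment_sample")
}

#' Chlorophyll a and b concentrations from absorbances
#'
#' Applies the buffered 80 %-acetone two-wavelength equations
#' (`chl_a = 12.25 A663.6 - 2.55 A646.6`,
#' `chl_b = 20.31 A646.6 - 4.91 A663.6`) after turbidity (A750)
#' subtraction and dilution scaling. Slightly negative results (above
#' -0.01 ug/ml, numerical noise for blank extracts) are clamped to 0;
#' anything more negative signals inconsistent spectra.
#'
#' @param sample A [pigment_sample()], or an absorbance at 663.6 nm when
#'   `a646_6` is given.
#' @param a646_6 Absorbance at 646.6 nm (when `sample` is a plain
#'   number).
#' @param coefficients 2x2 coefficient matrix mapping
#'   `(A663.6, A646.6)` to `(chl_a, chl_b)`; replaceable for other
#'   solvent systems.
#' @return Named vector `c(chl_a, chl_b)` in ug/ml.
#' @export
chl_from_absorbance <- function(sample, a646_6 = NULL,
                                coefficients = .CHL_COEF) {
  if (inherits(sample, "pigment_sample")) {
    a <- c(sample$a663_6 - sample$a750, sample$a646_6 - sample$a750) *
      sample$dilution_factor
  } else {
    if (is.null(a646_6)) {
      stop("give a pigment_sample or both absorbances", call. = FALSE)
    }
    a <- c(sample, a646_6)
  }
  conc <- as.numeric(coefficients %*% a)
  if (any(conc < -0.01)) {
    stop(sprintf(
      "spectra-inconsistency error: negative concentration (%.4g ug/ml)",
      min(conc)), call. = FALSE)
  }
  conc <- pmax(conc, 0)
  c(chl_a = conc[1L], chl_b = conc[2L])
}

#' Total chlorophyll per fresh weight
#'
#' `(chl_a + chl_b) * extract_volume / fresh_weight`, in ug chlorophyll
#' per mg fresh weight. Homogeneous of degree one in concentrations and
#' volume.
#'
#' @param chl_a,chl_b Concentrations, ug/ml.
#' @param extract_volume_ml Extract volume, ml (> 0).
#' @param fresh_weight_mg Fresh weight, mg (> 0).
#' @return ug chlorophyll per mg fresh weight.
#' @export
chl_per_fresh_weight <- function(chl_a, chl_b, extract_volume_ml,
                                 fresh_weight_mg) {
  if (extract_volume_ml <= 0 || fresh_weight_mg <= 0) {
    stop("domain error: volume and fresh weight must be > 0",
         call. = FALSE)
  }
  (chl_a + chl_b) * extract_volume_ml / fresh_weight_mg
}

#' Chlorophyll a/b ratio
#'
#' @param chl_a,chl_b Concentrations, ug/ml (`chl_b > 0`).
#' @return `chl_a / chl_b`.
#' @export
chl_ab_ratio <- function(chl_a, chl_b) {
  if (chl_b <= 0) {
    stop("domain error: chl_b must be > 0", call. = FALSE)
  }
  chl_a / chl_b
}
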
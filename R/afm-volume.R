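#' Integrate molecular volume above background
#'
#' Computes `V = rx * ry * sum(h_p - h_b)` over the pixels of a molecule
#' region: the physical volume of the adsorbed molecule above the mean
#' background height. Because segmentation thresholds at the noise floor,
#' the region clips the sub-threshold skirt that tip broadening spreads
#' around every molecule; the region is therefore grown by a disc of radius
#' `grow_px` pixels before integration. The grown ring adds only zero-mean
#' background noise (heights are deliberately not clipped at zero), while
#' recovering the skirt volume.
#'
#' @param hm a [height_map].
#' @param region a `molecule_region` from [segment_molecules()], or a
#'   logical mask of the full image size.
#' @param bg a `background_model` (or a number to use as `h_b` directly).
#' @param grow_px radius (pixels) by which the integration region is grown;
#'   the default 4 is about twice the tip-broadening sigma of the imaging
#'   conditions emulated here, enough to capture a Gaussian skirt to well
#'   under 1%. Set to 0 to integrate the thresholded region as-is.
#' @return volume in nm^3.
#' @export
integrate_volume <- function(hm, region, bg, grow_px = 4) {
  stopifnot(inherits(hm, "height_map"))
  check_positive(grow_px, "grow_px", strict = FALSE)
  h_b <- if (inherits(bg, "background_model")) bg$h_b else as.numeric(bg)
  mask <- if (inherits(region, "molecule_region")) {
    region_full_mask(region, dim(hm$heights))
  } else {
    region
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(hm$heights))) {
    abort_rmquant("`region` must be a molecule_region or full-size logical mask",
                  "rmquant_parameter_error")
  }
  if (!any(mask)) {
    abort_rmquant("empty region", "rmquant_volume_error")
  }
  if (grow_px > 0) {
    brush <- EBImage::makeBrush(2 * as.integer(grow_px) + 1, "disc")
    mask <- EBImage::dilate(mask * 1, brush) > 0
  }
  hm$rx * hm$ry * sum(hm$heights[mask] - h_b)
}

#' Volume of one protein complex from its molecular weight
#'
#' Converts a molecular weight to a molecular volume assuming an average
#' protein density (default 1.44 g/cm^3): `V_p = MW / (rho * N_A)`,
#' returned in nm^3.
#'
#' @param MW molecular weight in g/mol (> 0).
#' @param rho protein density in g/cm^3 (> 0).
#' @return volume in nm^3.
#' @export
trimer_volume <- function(MW, rho = 1.44) {
  check_positive(MW, "MW")
  check_positive(rho, "rho")
  N_A <- 6.02214076e23
  MW / (rho * N_A) * 1e21  # cm^3 -> nm^3
}

#' Stoichiometry inputs
#'
#' Bundles the quantities entering the trimer-count estimator: the mean
#' volume difference between protein-bound and free DNA molecules (`V_d`),
#' the per-trimer volume (`V_p`, default 20.7 nm^3 when no molecular weight
#' is supplied), and the mean number of particles per molecule (`N_p_mean`).
#'
#' @param V_d mean bound-minus-free volume difference, nm^3 (>= 0).
#' @param V_p per-trimer volume, nm^3 (> 0); derived from `MW` when given.
#' @param N_p_mean mean particles per DNA molecule (> 0).
#' @param MW optional molecular weight (g/mol) used to derive `V_p`.
#' @param rho protein density, g/cm^3.
#' @return A list of class `stoichiometry_inputs`.
#' @export
stoichiometry_inputs <- function(V_d, V_p = 20.7, N_p_mean, MW = NULL,
                                 rho = 1.44) {
  check_positive(V_d, "V_d", strict = FALSE)
  check_positive(N_p_mean, "N_p_mean")
  check_positive(rho, "rho")
  if (!is.null(MW)) V_p <- trimer_volume(MW, rho)
  check_positive(V_p, "V_p")
  structure(list(V_d = V_d, V_p = V_p, N_p_mean = N_p_mean,
                 MW = MW, rho = rho),
            class = "stoichiometry_inputs")
}

#' Estimate trimers per binding site
#'
#' The average number of trimeric complexes per protein particle (binding
#' site) is `V_d / (V_p * N_p_mean)`; the nearest integer is reported
#' alongside.
#'
#' @param s a [stoichiometry_inputs] object.
#' @return A tibble with `trimers_per_site` and `trimers_rounded` plus the
#'   inputs.
#' @export
count_trimers <- function(s) {
  stopifnot(inherits(s, "stoichiometry_inputs"))
  denom <- s$V_p * s$N_p_mean
  if (denom == 0) {
    abort_rmquant("V_p * N_p_mean must be nonzero", "rmquant_parameter_error")
  }
  val <- s$V_d / denom
  tibble::tibble(V_d = s$V_d, V_p = s$V_p, N_p_mean = s$N_p_mean,
                 trimers_per_site = val,
                 trimers_rounded = as.integer(round(val)))
}
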
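# Material property assignment: CT grayscale -> apparent density -> isotropic
# elastic constants, binned heterogeneous cortical bone, fixed properties for
# the remaining tissues, and the PDL material variants.

#' Grayscale-to-elasticity calibration model
#'
#' Encodes the linear theoretical calibration relating CT grayscale values
#' (GV) to apparent density and then to isotropic elastic constants:
#' \deqn{\rho = a + b \cdot GV,\quad
#'       \nu = c + d \cdot \rho,\quad
#'       E = e + f \cdot \rho}
#' with the raw \eqn{E} clamped from below by `E_floor` and \eqn{\nu}
#' clamped into `[v_floor, v_cap]` so the resulting isotropic stiffness is
#' positive definite (the raw lines go negative at low density and exceed
#' physical bounds at high density). Defaults are the published calibration
#' coefficients; all are configurable.
#'
#' @param density_intercept,density_slope coefficients of the density line
#'   (density per GV unit).
#' @param v_intercept,v_slope coefficients of the Poisson's-ratio line.
#' @param E_intercept,E_slope coefficients of the Young's-modulus line (MPa).
#' @param E_floor lower clamp on E, MPa (> 0).
#' @param v_floor,v_cap clamps on Poisson's ratio, strictly inside (0, 0.5).
#' @param n_bins number of heterogeneous cortical material bins (default 80).
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(density_intercept = -0.01979662,
                              density_slope = 1.0577433,
                              v_intercept = 0.400595880819907,
                              v_slope = -0.00000913165104192569,
                              E_intercept = -2.7501977952777819,
                              E_slope = 0.0082389155811676013,
                              E_floor = 50,
                              v_floor = 0.05,
                              v_cap = 0.49,
                              n_bins = 80L) {
  if (E_floor <= 0) stop("E_floor must be > 0")
  if (v_floor <= 0 || v_cap >= 0.5 || v_floor > v_cap)
    stop("need 0 < v_floor <= v_cap < 0.5")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  structure(list(density_intercept = density_intercept,
                 density_slope = density_slope,
                 v_intercept = v_intercept, v_slope = v_slope,
                 E_intercept = E_intercept, E_slope = E_slope,
                 E_floor = E_floor, v_floor = v_floor, v_cap = v_cap,
                 n_bins = n_bins),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("calibration_model:\n")
  cat(sprintf("  rho = %.8g + %.8g * GV\n", x$density_intercept, x$density_slope))
  cat(sprintf("  v   = %.15g + %.15g * rho   (clamped to [%g, %g])\n",
              x$v_intercept, x$v_slope, x$v_floor, x$v_cap))
  cat(sprintf("  E   = %.15g + %.15g * rho MPa (floor %g MPa)\n",
              x$E_intercept, x$E_slope, x$E_floor))
  cat(sprintf("  cortical bins: %d\n", x$n_bins))
  invisible(x)
}

.calibrate_rho <- function(rho, model) {
  E_raw <- model$E_intercept + model$E_slope * rho
  v_raw <- model$v_intercept + model$v_slope * rho
  list(rho = rho,
       E = pmax(model$E_floor, E_raw),
       v = pmin(model$v_cap, pmax(model$v_floor, v_raw)),
       E_raw = E_raw, v_raw = v_raw)
}

#' Calibrate grayscale values to elastic properties
#'
#' Applies the density, Poisson's-ratio and Young's-modulus lines of a
#' [calibration_model()] to one or more grayscale values. Vectorised.
#'
#' @param gv numeric vector of grayscale values (finite).
#' @param model a `calibration_model`.
#' @return data.frame with columns `gv`, `rho`, `E` (MPa, clamped), `v`
#'   (clamped), `E_raw`, `v_raw` (pre-clamp line values).
#' @export
calibrate_element <- function(gv, model = calibration_model()) {
  if (!is.numeric(gv) || any(!is.finite(gv)))
    stop("gv must be finite numeric")
  rho <- model$density_intercept + model$density_slope * gv
  p <- .calibrate_rho(rho, model)
  data.frame(gv = gv, rho = p$rho, E = p$E, v = p$v,
             E_raw = p$E_raw, v_raw = p$v_raw)
}

.empty_material_field <- function(mesh, variant = "custom") {
  ne <- nrow(mesh$elems)
  structure(list(E = rep(NA_real_, ne), v = rep(NA_real_, ne),
                 variant = variant, n_elem = ne),
            class = "material_field")
}

#' @export
print.material_field <- function(x, ...) {
  ok <- !is.na(x$E)
  cat("material_field (variant ", x$variant, "): ", sum(ok), "/", x$n_elem,
      " elements assigned\n", sep = "")
  if (any(ok))
    cat(sprintf("  E range: %.4g .. %.4g MPa; v range: %.3g .. %.3g\n",
                min(x$E[ok]), max(x$E[ok]), min(x$v[ok]), max(x$v[ok])))
  invisible(x)
}

#' Assign binned heterogeneous properties to cortical bone
#'
#' Maps per-element grayscale values to density and then to elastic
#' constants, optionally quantised into `model$n_bins` equal-width density
#' bins over the observed density range (each bin represented by its
#' midpoint density), giving at most `n_bins` distinct cortical materials.
#' Non-cortical elements are left unassigned (filled in later by
#' [make_variant()]).
#'
#' @param mesh a `tet_mesh` with a non-empty cortical region.
#' @param gv per-element grayscale values: either a numeric vector named by
#'   element id covering (at least) all cortical elements, or a data.frame
#'   with columns `element` and `gv`.
#' @param model a `calibration_model`.
#' @param binned quantise into `n_bins` density bins (default TRUE).
#' @return a `material_field` with values on cortical elements only.
#' @export
assign_cortical <- function(mesh, gv, model = calibration_model(),
                            binned = TRUE) {
  cort <- which(mesh$region == "cortical")
  if (length(cort) == 0) stop("mesh has no cortical elements")
  if (is.data.frame(gv)) gv <- setNames(gv$gv, as.character(gv$element))
  if (is.null(names(gv))) {
    if (length(gv) != nrow(mesh$elems))
      stop("unnamed gv must have one value per element")
    names(gv) <- as.character(seq_along(gv))
  }
  key <- as.character(cort)
  missing <- key[!(key %in% names(gv)) | !is.finite(gv[key])]
  if (length(missing))
    stop("missing grayscale value for cortical element(s): ",
         paste(utils::head(missing, 10L), collapse = ", "))
  gvc <- unname(gv[key])
  rho <- model$density_intercept + model$density_slope * gvc
  if (binned) {
    lo <- min(rho); hi <- max(rho)
    if (hi > lo) {
      edges <- seq(lo, hi, length.out = model$n_bins + 1L)
      idx <- findInterval(rho, edges, rightmost.closed = TRUE,
                          all.inside = TRUE)
      mids <- (edges[-1L] + edges[-length(edges)]) / 2
      rho <- mids[idx]
    } else {
      rho <- rep((lo + hi) / 2, length(rho))
    }
  }
  p <- .calibrate_rho(rho, model)
  fld <- .empty_material_field(mesh, variant = "cortical-only")
  fld$E[cort] <- p$E
  fld$v[cort] <- p$v
  fld
}

# fixed isotropic properties for the non-calibrated tissues (MPa)
FIXED_TISSUE_PROPS <- list(
  tooth      = c(E = 24500, v = 0.49),
  trabecular = c(E = 10000, v = 0.30),
  screw      = c(E = 105000, v = 0.36)
)

# PDL material variants: Young's modulus (MPa), Poisson's ratio fixed 0.49
PDL_VARIANTS <- list(
  PDL     = c(E = 0.68,  v = 0.49),
  NO_PDL  = c(E = 24500, v = 0.49),   # PDL given tooth properties
  MODEL_1 = c(E = 0.07,  v = 0.49),
  MODEL_2 = c(E = 0.18,  v = 0.49),
  MODEL_3 = c(E = 13.8,  v = 0.49),
  MODEL_4 = c(E = 1750,  v = 0.49)
)

#' Build a complete material field for a PDL model variant
#'
#' Starting from the cortical assignment, fills in the fixed tissue
#' properties (teeth E=24500 MPa, v=0.49; trabecular E=10000 MPa, v=0.3;
#' screws E=105000 MPa, v=0.36) and the PDL-region properties selected by
#' `variant`:
#' \itemize{
#'   \item `PDL`: E = 0.68 MPa (the validated baseline ligament)
#'   \item `NO_PDL`: tooth properties (E = 24500 MPa), i.e. the ligament is
#'     materially removed while its geometry is kept
#'   \item `MODEL_1`..`MODEL_4`: E = 0.07, 0.18, 13.8, 1750 MPa, the span of
#'     published ligament moduli
#' }
#' Poisson's ratio of the ligament is 0.49 in every variant. A custom
#' variant may be given as `list(E = , v = )`.
#'
#' @param mesh a `tet_mesh`.
#' @param cortical a `material_field` from [assign_cortical()].
#' @param variant one of `names(pdl_variants())`, or a list with `E` and `v`.
#' @return a complete `material_field` labelled with the variant.
#' @export
make_variant <- function(mesh, cortical, variant = "PDL") {
  if (is.list(variant)) {
    props <- c(E = as.numeric(variant$E), v = as.numeric(variant$v))
    label <- if (!is.null(variant$label)) variant$label else "custom"
  } else {
    if (!variant %in% names(PDL_VARIANTS))
      stop("unknown PDL variant '", variant, "'; expected one of: ",
           paste(names(PDL_VARIANTS), collapse = ", "))
    props <- PDL_VARIANTS[[variant]]
    label <- variant
  }
  for (r in c("tooth", "trabecular", "screw"))
    if (!any(mesh$region == r))
      stop("mesh has no '", r, "' region elements")
  fld <- cortical
  fld$variant <- label
  for (r in names(FIXED_TISSUE_PROPS)) {
    ids <- which(mesh$region == r)
    fld$E[ids] <- FIXED_TISSUE_PROPS[[r]][["E"]]
    fld$v[ids] <- FIXED_TISSUE_PROPS[[r]][["v"]]
  }
  ids <- which(mesh$region == "pdl")
  fld$E[ids] <- props[["E"]]
  fld$v[ids] <- props[["v"]]
  if (anyNA(fld$E))
    stop("material field incomplete: ", sum(is.na(fld$E)),
         " element(s) without properties (is the cortical assignment missing?)")
  if (any(fld$E <= 0) || any(fld$v <= 0 | fld$v >= 0.5))
    stop("invalid elastic properties (need E > 0, 0 < v < 0.5)")
  fld
}

#' The named PDL material variants
#' @return named list of `c(E, v)` pairs (MPa, dimensionless).
#' @export
pdl_variants <- function() PDL_VARIANTS

#' Export a material field as a data.frame (element, region, E, v)
#' @param mesh a `tet_mesh`.
#' @param field a `material_field`.
#' @return data.frame, one row per element.
#' @export
material_table <- function(mesh, field) {
  data.frame(element = seq_len(nrow(mesh$elems)), region = mesh$region,
             E = field$E, v = field$v)
}
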
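#' CT-to-bone calibration constants
#'
#' Bundles the empirical coefficients that map CT intensity to bone mineral
#' density (BMD), BMD to apparent density, apparent density to elastic
#' modulus, and apparent density to trabecular shear strength.  Defaults are
#' the published air-fat-muscle calibration (BMD = 0.0008 INT - 0.8037), the
#' apparent-density divisor 0.626, the modulus power law E = 2017.3 rho^2.46
#' (MPa), the compressive strength power law 19.08 rho^2.15 (MPa) and the
#' 0.44 shear-to-compressive strength ratio.
#'
#' @param hu_slope BMD per Hounsfield unit (g/cm^3 per HU).
#' @param hu_intercept BMD offset (g/cm^3).
#' @param density_divisor BMD-to-apparent-density divisor (unitless, > 0).
#' @param modulus_coeff Modulus power-law coefficient (MPa).
#' @param modulus_exp Modulus power-law exponent (> 0).
#' @param strength_coeff Compressive-strength power-law coefficient (MPa).
#' @param strength_exp Compressive-strength power-law exponent (> 0).
#' @param shear_ratio Shear-to-compressive strength ratio.
#' @return An object of class `ct_calibration`.
#' @export
ct_calibration <- function(hu_slope = 0.0008, hu_intercept = -0.8037,
                           density_divisor = 0.626,
                           modulus_coeff = 2017.3, modulus_exp = 2.46,
                           strength_coeff = 19.08, strength_exp = 2.15,
                           shear_ratio = 0.44) {
  cal <- list(hu_slope = hu_slope, hu_intercept = hu_intercept,
              density_divisor = density_divisor,
              modulus_coeff = modulus_coeff, modulus_exp = modulus_exp,
              strength_coeff = strength_coeff, strength_exp = strength_exp,
              shear_ratio = shear_ratio)
  vals <- unlist(cal)
  if (!all(is.finite(vals)))
    stop("ct_calibration: all coefficients must be finite")
  if (density_divisor <= 0 || modulus_coeff <= 0)
    stop("ct_calibration: density_divisor and modulus_coeff must be > 0")
  if (modulus_exp <= 0 || strength_exp <= 0)
    stop("ct_calibration: exponents must be > 0")
  structure(cal, class = "ct_calibration")
}

#' Screw geometry specification
#'
#' Thread and segment geometry for one compression screw.  The screw is a
#' head + shank + threaded core; the threaded part is treated as a plain
#' cylindrical core of diameter `D_minor` in the FE model, with thread
#' mechanics entering only through the analytic pullout/torque chain.
#' The free zone is the part of the core that does not contact bone,
#' immediately before the screw enters the bone.
#'
#' @param id Screw label.
#' @param category `"cancellous"` or `"cortical"`.
#' @param D_major Thread major diameter (mm).
#' @param D_minor Thread minor (core) diameter (mm), 0 < D_minor < D_major.
#' @param pitch Thread pitch (mm).
#' @param head_diameter,shank_diameter,shank_length Head and shank geometry (mm).
#' @param core_length Core length from shank-core junction to tip (mm).
#' @param engagement_length Thread length engaged in bone, L (mm); may be
#'   `NA` when the pullout threshold is supplied directly as an override.
#' @param free_zone_length Free-zone length at the start of the core (mm).
#' @param partial_embed_length Partially embedded zone length (mm).
#' @param d_km Mean bearing diameter under the head (mm).  Not part of the
#'   catalogue geometry; defaults to the mean of head and shank diameters.
#' @return An object of class `screw_spec`.
#' @export
screw_spec <- function(id = "screw", category = c("cancellous", "cortical"),
                       D_major = 6.5, D_minor = 3.0, pitch = 2.75,
                       head_diameter = 8.0, shank_diameter = 4.9,
                       shank_length = 2.5, core_length = 40,
                       engagement_length = NA_real_,
                       free_zone_length = 3, partial_embed_length = 2,
                       d_km = (head_diameter + shank_diameter) / 2) {
  category <- match.arg(category)
  s <- list(id = id, category = category, D_major = D_major,
            D_minor = D_minor, pitch = pitch,
            head_diameter = head_diameter, shank_diameter = shank_diameter,
            shank_length = shank_length, core_length = core_length,
            engagement_length = engagement_length,
            free_zone_length = free_zone_length,
            partial_embed_length = partial_embed_length, d_km = d_km)
  if (!(D_minor > 0 && D_minor < D_major))
    stop("screw_spec: need 0 < D_minor < D_major")
  if (pitch <= 0) stop("screw_spec: pitch must be > 0")
  lens <- c(core_length, free_zone_length, partial_embed_length,
            shank_length, head_diameter, shank_diameter)
  if (any(lens < 0)) stop("screw_spec: lengths must be >= 0")
  if (!is.na(engagement_length)) {
    if (engagement_length < 0) stop("screw_spec: engagement_length must be >= 0")
    if (engagement_length > core_length)
      stop("screw_spec: engagement_length must not exceed core_length")
  }
  if (free_zone_length + partial_embed_length > core_length)
    stop("screw_spec: free + partial zones exceed core_length")
  structure(s, class = "screw_spec")
}

#' Interface friction coefficients
#'
#' @param mu_bone_screw Bone-screw friction (stripping torque relation).
#' @param mu_thread Thread friction (torque-to-force relation).
#' @param mu_head Under-head titanium-on-titanium friction.
#' @return An object of class `friction_set`.
#' @export
friction_set <- function(mu_bone_screw = 0.42, mu_thread = 0.42,
                         mu_head = 0.441) {
  f <- list(mu_bone_screw = mu_bone_screw, mu_thread = mu_thread,
            mu_head = mu_head)
  if (any(unlist(f) <= 0) || any(unlist(f) >= 1))
    stop("friction_set: coefficients must lie in (0, 1)")
  structure(f, class = "friction_set")
}

#' Ti-6Al-4V screw fatigue limit specification
#'
#' Marin-style endurance-limit correction `Se = K * Se_specimen`.  When both
#' inputs are `NULL` the packaged screw endurance limit of 542.2 MPa is
#' returned by [fatigue_limit()].
#'
#' @param Se_specimen Rotary-beam specimen endurance limit (MPa).
#' @param marin_K Product of Marin modifying factors (surface, gradient,
#'   load, temperature, ...).
#' @return An object of class `fatigue_spec`.
#' @export
fatigue_spec <- function(Se_specimen = NULL, marin_K = NULL) {
  if (xor(is.null(Se_specimen), is.null(marin_K)))
    stop("fatigue_spec: supply both Se_specimen and marin_K, or neither")
  if (!is.null(Se_specimen)) {
    if (!is.finite(Se_specimen) || Se_specimen <= 0)
      stop("fatigue_spec: Se_specimen must be > 0")
    if (!is.finite(marin_K) || marin_K <= 0)
      stop("fatigue_spec: marin_K must be > 0")
  }
  structure(list(Se_specimen = Se_specimen, marin_K = marin_K),
            class = "fatigue_spec")
}

## packaged screw endurance limit (MPa) when no Marin factors are supplied
.SE_SCREW_DEFAULT <- 542.2

#' Convert CT intensity to bone mineral density
#'
#' Affine map `BMD = hu_slope * INT + hu_intercept` (g/cm^3).  The result
#' may be negative; callers clamp at zero before density conversion.
#'
#' @param intensity CT intensity (HU); vectorized.
#' @param calib A [ct_calibration()].
#' @return BMD in g/cm^3.
#' @export
hu_to_bmd <- function(intensity, calib = ct_calibration()) {
  if (!all(is.finite(intensity))) stop("hu_to_bmd: intensity must be finite")
  calib$hu_slope * intensity + calib$hu_intercept
}

#' Convert bone mineral density to apparent density
#'
#' `rho_app = BMD / density_divisor`.  Negative BMD must be clamped to zero
#' by the caller before this conversion.
#'
#' @param bmd BMD in g/cm^3, >= 0; vectorized.
#' @param calib A [ct_calibration()].
#' @return Apparent density in g/cm^3.
#' @export
bmd_to_density <- function(bmd, calib = ct_calibration()) {
  if (any(!is.finite(bmd)) || any(bmd < 0))
    stop("bmd_to_density: bmd must be finite and >= 0 (clamp negatives first)")
  bmd / calib$density_divisor
}

#' Convert apparent density to elastic modulus
#'
#' Power law `E = modulus_coeff * rho^modulus_exp` (MPa).
#'
#' @param rho Apparent density in g/cm^3, >= 0; vectorized.
#' @param calib A [ct_calibration()].
#' @return Young's modulus in MPa.
#' @export
density_to_modulus <- function(rho, calib = ct_calibration()) {
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("density_to_modulus: rho must be finite and >= 0")
  calib$modulus_coeff * rho^calib$modulus_exp
}

#' Trabecular bone ultimate shear strength
#'
#' `S = shear_ratio * strength_coeff * rho^strength_exp` (MPa): the
#' compressive ultimate strength power law scaled by the
#' shear-to-compressive ratio.
#'
#' @param rho_app Apparent density in g/cm^3, > 0; vectorized.
#' @param calib A [ct_calibration()].
#' @return Ultimate shear strength in MPa.
#' @export
trabecular_shear_strength <- function(rho_app, calib = ct_calibration()) {
  if (any(!is.finite(rho_app)) || any(rho_app <= 0))
    stop("trabecular_shear_strength: rho_app must be > 0")
  calib$shear_ratio * calib$strength_coeff * rho_app^calib$strength_exp
}

#' Thread shape factor
#'
#' `TSF = 0.5 + 0.57735 d / p` with thread depth
#' `d = (D_major - D_minor) / 2`.
#'
#' @param spec A [screw_spec()].
#' @return Dimensionless thread shape factor.
#' @export
thread_shape_factor <- function(spec) {
  if (spec$pitch <= 0) stop("thread_shape_factor: pitch must be > 0")
  d <- (spec$D_major - spec$D_minor) / 2
  0.5 + 0.57735 * d / spec$pitch
}

#' Screw pullout failure threshold
#'
#' `F_PO = S * L * pi * D_major * TSF`: the axial force at which the bone
#' threads strip, from the bone shear strength S, engaged thread length L,
#' major diameter and thread shape factor.
#'
#' @param S Bone ultimate shear strength (MPa).
#' @param spec A [screw_spec()] with a resolvable `engagement_length`.
#' @return Pullout threshold in N.
#' @export
pullout_threshold <- function(S, spec) {
  L <- spec$engagement_length
  if (is.na(L)) stop("pullout_threshold: engagement_length is not set for ",
                     spec$id)
  if (!is.finite(S) || S <= 0) stop("pullout_threshold: S must be > 0")
  S * L * pi * spec$D_major * thread_shape_factor(spec)
}

#' Pitch radius of a screw thread
#' @param spec A [screw_spec()].
#' @return `(D_major + D_minor) / 4` in mm.
#' @export
pitch_radius <- function(spec) (spec$D_major + spec$D_minor) / 4

#' Stripping torque
#'
#' `T_str = F_PO * r * (p + 2 mu r) / (2 r - mu p)` with pitch radius
#' `r = (D_major + D_minor)/4` and bone-screw friction `mu`.
#'
#' @param F_PO Pullout threshold (N).
#' @param spec A [screw_spec()].
#' @param fric A [friction_set()].
#' @return Stripping torque in N mm.
#' @export
stripping_torque <- function(F_PO, spec, fric = friction_set()) {
  if (any(F_PO <= 0)) stop("stripping_torque: F_PO must be > 0")
  r <- pitch_radius(spec)
  mu <- fric$mu_bone_screw
  den <- 2 * r - mu * spec$pitch
  if (den <= 0)
    stop("stripping_torque: non-positive denominator (2r <= mu * pitch) for ",
         spec$id)
  F_PO * r * (spec$pitch + 2 * mu * r) / den
}

#' Optimal insertion torque
#'
#' 65% of the predicted stripping torque.
#'
#' @param T_str Stripping torque (N mm).
#' @return Insertion torque in N mm.
#' @export
insertion_torque <- function(T_str) {
  if (any(T_str < 0)) stop("insertion_torque: T_str must be >= 0")
  0.65 * T_str
}

#' Inferred pretension force from insertion torque
#'
#' Torque-to-force relation
#' `F_P = T_ins / (0.159 p + 0.578 * 2r * mu_G + (d_km / 2) * mu_K)`,
#' with thread friction `mu_G` and under-head friction `mu_K` acting on the
#' mean bearing diameter `d_km`.
#'
#' @param T_ins Insertion torque (N mm).
#' @param spec A [screw_spec()] (supplies pitch, pitch radius and `d_km`).
#' @param fric A [friction_set()].
#' @return Pretension force in N.
#' @export
pretension_force <- function(T_ins, spec, fric = friction_set()) {
  if (any(T_ins < 0)) stop("pretension_force: T_ins must be >= 0")
  r <- pitch_radius(spec)
  den <- 0.159 * spec$pitch + 0.578 * 2 * r * fric$mu_thread +
    (spec$d_km / 2) * fric$mu_head
  if (den <= 0) stop("pretension_force: non-positive torque-to-force ",
                     "denominator for ", spec$id)
  T_ins / den
}

#' Infer per-screw pretension forces
#'
#' Runs the full chain F_PO -> T_str -> T_ins -> F_P for a list of screws.
#' The pullout threshold is computed from the bone shear strength and each
#' screw's engagement length, unless a per-screw `F_PO` override is given
#' (used when reproducing published thresholds whose engagement lengths are
#' not recoverable).
#'
#' @param specs A list of [screw_spec()] objects.
#' @param rho_app Bone apparent density (g/cm^3) used for the shear
#'   strength; ignored for screws with an override.
#' @param fric A [friction_set()].
#' @param calib A [ct_calibration()].
#' @param F_PO_override Optional named numeric vector (names = screw ids) of
#'   pullout thresholds in N.
#' @return A data.frame with columns `screw_id`, `F_PO` (N), `T_str` (N mm),
#'   `T_ins` (N mm) and `F_P` (N).
#' @export
infer_pretension_table <- function(specs, rho_app = 0.422,
                                   fric = friction_set(),
                                   calib = ct_calibration(),
                                   F_PO_override = NULL) {
  if (length(specs) == 0)
    return(data.frame(screw_id = character(), F_PO = numeric(),
                      T_str = numeric(), T_ins = numeric(),
                      F_P = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(specs, function(sp) {
    fpo <- if (!is.null(F_PO_override) && sp$id %in% names(F_PO_override)) {
      F_PO_override[[sp$id]]
    } else {
      S <- trabecular_shear_strength(rho_app, calib)
      tryCatch(pullout_threshold(S, sp),
               error = function(e) stop("screw '", sp$id, "': ",
                                        conditionMessage(e), call. = FALSE))
    }
    tstr <- stripping_torque(fpo, sp, fric)
    tins <- insertion_torque(tstr)
    fp <- pretension_force(tins, sp, fric)
    data.frame(screw_id = sp$id, F_PO = fpo, T_str = tstr, T_ins = tins,
               F_P = fp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screw endurance limit
#'
#' Marin correction `Se = K * Se_specimen`.  With a default (empty)
#' [fatigue_spec()] the packaged Ti-6Al-4V screw endurance limit of
#' 542.2 MPa is returned.
#'
#' @param fat A [fatigue_spec()].
#' @return Endurance limit of the screw in MPa.
#' @export
fatigue_limit <- function(fat = fatigue_spec()) {
  if (is.null(fat$Se_specimen)) return(.SE_SCREW_DEFAULT)
  fat$marin_K * fat$Se_specimen
}
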
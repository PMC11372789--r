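## Post-processing of screw solutions: axial force profiles along the core,
## free-zone end forces, peak von Mises stress with the stress-concentration
## exclusion, and pullout/fatigue failure classification.

resolve_screw <- function(assembly, screw) {
  if (is.numeric(screw)) return(assembly$screws[[screw]])
  ids <- vapply(assembly$screws, `[[`, "", "id")
  k <- match(screw, ids)
  if (is.na(k)) stop("unknown screw '", screw, "'")
  assembly$screws[[k]]
}

# Mean axial stress over a thin slab of core elements times the core area.
slab_force <- function(depth_c, szz, area, depth, halfwidth) {
  inslab <- abs(depth_c - depth) <= halfwidth + 1e-9
  if (!any(inslab)) return(NA_real_)
  mean(szz[inslab]) * area
}

#' Axial force profile along a screw core
#'
#' At stations along the core (0% = shank-core junction, 100% = tip) the
#' axial force is the mean axial stress over core elements whose centroids
#' lie within a slab of one element-edge half-width, multiplied by the core
#' cross-section area.  The free-zone end force is evaluated at the deepest
#' station whose slab lies entirely inside the free zone, i.e. at the end
#' of the free zone, away from the shank.  Screws whose free zone is
#' shorter than three element layers get a reliability warning: their
#' free-zone force cannot be separated from the junction stress
#' concentration.
#'
#' @param assembly An `assembly`.
#' @param sol An [fe_solve()] solution.
#' @param screw Screw index or id.
#' @param n_stations Number of stations (default: two per element layer).
#' @return A data.frame (`station_pct`, `depth_mm`, `force_N`, `zone`) with
#'   attributes `free_zone_end_force`, `free_zone_end_depth`, `plateau_cov`
#'   (coefficient of variation over free-zone stations), and `reliable`.
#' @export
axial_force_profile <- function(assembly, sol, screw, n_stations = NULL) {
  s <- resolve_screw(assembly, screw)
  mesh <- assembly$mesh
  core <- which(mesh$region == s$core_regions)
  if (length(core) == 0) stop("axial_force_profile: screw has no core elements")
  cent_z <- (mesh$nodes[mesh$elems[core, 1], 3] +
               mesh$nodes[mesh$elems[core, 2], 3] +
               mesh$nodes[mesh$elems[core, 3], 3] +
               mesh$nodes[mesh$elems[core, 4], 3]) / 4
  depth_c <- s$junction_z - cent_z          # depth below junction, mm
  szz <- sol$stress[core, 3]
  hw <- mesh$h
  L <- s$core_len
  if (is.null(n_stations)) n_stations <- max(11, round(2 * L / mesh$h) + 1)
  depths <- seq(0, L, length.out = n_stations)
  force <- vapply(depths, function(d)
    slab_force(depth_c, szz, s$core_area, d, hw), numeric(1))
  zone <- ifelse(depths < s$free_len, "free",
                 ifelse(depths < s$free_len + s$partial_len,
                        "partial", "full"))
  prof <- data.frame(station_pct = 100 * depths / L, depth_mm = depths,
                     force_N = force, zone = zone,
                     stringsAsFactors = FALSE)
  prof <- prof[!is.na(prof$force_N), ]

  # the end-force slab [fl - 2h, fl] must clear the first element layer at
  # the junction, where the preload devices concentrate stress; short free
  # zones cannot separate the two
  reliable <- s$free_len >= 3 * hw
  if (!reliable)
    warning("screw '", s$id, "': free zone (", s$free_len, " mm) is not ",
            "longer than the junction stress-concentration layer; its ",
            "free-zone force is unreliable", call. = FALSE)
  end_depth <- if (reliable) s$free_len - hw else s$free_len / 2
  end_force <- slab_force(depth_c, szz, s$core_area, end_depth, hw)
  infree <- prof$depth_mm + hw <= s$free_len + 1e-9
  cov <- if (sum(infree) >= 2 && abs(mean(prof$force_N[infree])) > 0) {
    stats::sd(prof$force_N[infree]) / abs(mean(prof$force_N[infree]))
  } else NA_real_
  attr(prof, "free_zone_end_force") <- end_force
  attr(prof, "free_zone_end_depth") <- end_depth
  attr(prof, "plateau_cov") <- cov
  attr(prof, "reliable") <- reliable
  prof
}

#' Free-zone axial force of a screw
#'
#' @inheritParams axial_force_profile
#' @return Axial force (N) at the end of the free zone.
#' @export
free_zone_force <- function(assembly, sol, screw) {
  attr(axial_force_profile(assembly, sol, screw), "free_zone_end_force")
}

#' Peak von Mises stress in a screw core with the junction exclusion
#'
#' The first `exclusion_mm` of the core (one core diameter by default)
#' carry stress concentrations from the preload devices and are neglected.
#'
#' @inheritParams axial_force_profile
#' @param exclusion_mm Excluded length at the start of the core (mm).
#' @return Maximum centroid von Mises stress (MPa) beyond the exclusion.
#' @export
peak_von_mises <- function(assembly, sol, screw, exclusion_mm = 3) {
  s <- resolve_screw(assembly, screw)
  if (exclusion_mm >= s$core_len)
    stop("peak_von_mises: exclusion is not shorter than the core")
  mesh <- assembly$mesh
  core <- which(mesh$region == s$core_regions)
  cent_z <- (mesh$nodes[mesh$elems[core, 1], 3] +
               mesh$nodes[mesh$elems[core, 2], 3] +
               mesh$nodes[mesh$elems[core, 3], 3] +
               mesh$nodes[mesh$elems[core, 4], 3]) / 4
  depth_c <- s$junction_z - cent_z
  keep <- depth_c > exclusion_mm
  max(sol$vm[core[keep]])
}

#' Classify pullout and fatigue failure likelihood
#'
#' Pullout is flagged when the free-zone axial force reaches the pullout
#' threshold in any load case (inclusive, conservative); fatigue when the
#' peak von Mises stress reaches the screw endurance limit.  Negative
#' free-zone forces are compressive and never count towards pullout.
#'
#' @param forces Matrix (screws x load cases) of free-zone axial forces (N).
#' @param peaks Matrix (screws x load cases) of peak von Mises stresses
#'   (MPa, junction zone excluded).
#' @param F_PO Per-screw pullout thresholds (N), recycled.
#' @param Se Screw endurance limit (MPa).
#' @param ids Screw labels.
#' @return A data.frame per screw: `max_force_ratio`, `peak_vm`,
#'   `pullout`, `fatigue`, `compressive` (TRUE when any load case gives a
#'   negative free-zone force).
#' @export
classify_failure <- function(forces, peaks, F_PO, Se = fatigue_limit(),
                             ids = rownames(forces)) {
  forces <- as.matrix(forces); peaks <- as.matrix(peaks)
  if (any(F_PO <= 0) || Se <= 0)
    stop("classify_failure: thresholds must be positive")
  F_PO <- rep_len(F_PO, nrow(forces))
  ratio <- sweep(forces, 1, F_PO, "/")
  data.frame(
    screw = ids %||% paste0("screw_", seq_len(nrow(forces))),
    max_force_ratio = apply(ratio, 1, max),
    peak_vm = apply(peaks, 1, max),
    pullout = apply(ratio, 1, function(x) any(x >= 1)),
    fatigue = apply(peaks, 1, function(x) any(x >= Se)),
    compressive = apply(forces, 1, function(x) any(x < 0)),
    stringsAsFactors = FALSE)
}

#' Length of the stress-concentration zone at the core start
#'
#' Shortest depth beyond which the axial-force profile stays within a
#' relative band around the free-zone end force for the remainder of the
#' free zone.  Used to compare how quickly the preload devices' local
#' disturbances die out.
#'
#' @inheritParams axial_force_profile
#' @param band Relative tolerance around the free-zone end force.
#' @return Depth (mm) below the junction at which the profile settles.
#' @export
concentration_zone_length <- function(assembly, sol, screw, band = 0.05) {
  s <- resolve_screw(assembly, screw)
  prof <- axial_force_profile(assembly, sol, screw,
                              n_stations = max(41, round(8 * s$core_len)))
  ref <- attr(prof, "free_zone_end_force")
  infree <- prof$depth_mm + assembly$mesh$h <= s$free_len + 1e-9
  p <- prof[infree, ]
  ok <- abs(p$force_N - ref) <= band * abs(ref)
  bad <- which(!ok)
  if (length(bad) == 0) return(0)
  p$depth_mm[max(bad)]
}
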
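#' One-dimensional bolted-joint (joint-diagram) model
#'
#' Closed-form spring model of a pretensioned bolted joint, used as an
#' independent oracle for the finite-element pretension devices.  The bolt
#' (screw) of stiffness `kb` and the clamped members of stiffness `km` share
#' an external axial load according to the load factor
#' `phi = kb / (kb + km)`.
#'
#' @param kb Bolt stiffness (N/mm), > 0.  For a uniform segment
#'   `kb = E A / L`.
#' @param km Clamped-member stiffness (N/mm), > 0.
#' @param N0 Pretension (preload) force (N).
#' @param Fe External axial load applied across the joint (N), positive when
#'   it further tensions the bolt.
#' @return An object of class `joint_model` with fields `kb`, `km`, `N0`,
#'   `Fe` and derived `phi`.
#' @export
joint_model <- function(kb, km, N0 = 0, Fe = 0) {
  if (!is.finite(kb) || kb <= 0 || !is.finite(km) || km <= 0)
    stop("joint_model: kb and km must be > 0")
  structure(list(kb = kb, km = km, N0 = N0, Fe = Fe,
                 phi = kb / (kb + km)), class = "joint_model")
}

#' Bolt force under external load
#'
#' Below the separation load the bolt force is affine in the external load,
#' `Fb = N0 + phi * Fe`; at `Fe >= N0 / (1 - phi)` the joint separates and
#' the bolt carries the full external load.
#'
#' @param joint A [joint_model()].
#' @return Bolt axial force in N.
#' @export
bolt_force_under_load <- function(joint) {
  Fe_sep <- joint$N0 / (1 - joint$phi)
  if (joint$Fe >= Fe_sep) joint$Fe else joint$N0 + joint$phi * joint$Fe
}

#' Joint separation load
#' @param joint A [joint_model()].
#' @return External load at which the clamped interface opens (N).
#' @export
separation_load <- function(joint) joint$N0 / (1 - joint$phi)

#' Preload induced by thermal contraction of a bolt segment
#'
#' A stress-free contraction strain `x < 0` applied over a segment of length
#' `L_segment` shortens the bolt by `|x| * L_segment`.  Working against the
#' series stack of bolt and member, the resulting preload is
#' `N0 = |x| * L_segment * kb * km / (kb + km)`.
#' In the rigid-member limit (`km -> Inf`) with the whole bolt heated
#' (`L_segment = L_bolt`, `kb = E A / L_bolt`) this reduces to
#' `N0 = |x| E A`.
#'
#' @param x Control strain (alpha * dT), negative for contraction.
#' @param joint A [joint_model()] giving `kb` and `km`.
#' @param L_segment Length of the contracted segment (mm).
#' @return Preload N0 in N.
#' @export
preload_from_thermal <- function(x, joint, L_segment) {
  if (x >= 0) stop("preload_from_thermal: x must be negative (contraction)")
  abs(x) * L_segment * joint$kb * joint$km / (joint$kb + joint$km)
}

#' Preload induced by an equal-and-opposite force pair on the shank
#'
#' The pair of compressive forces `F` squeezes the shank spring `ks`; the
#' two end nodes bypass into ground through the member path `km` (head and
#' clamped parts) and the anchored-core path `kc`.  Static condensation of
#' the three-spring network gives
#' `N0 = F * km * kc / (ks * (km + kc) + km * kc)`,
#' i.e. `N0 -> F` when the bypass paths are rigid relative to the shank, and
#' a partition factor `1 / (1 + ks (1/km + 1/kc))` in general.
#'
#' @param F_applied Magnitude of the compressive force pair (N), > 0.
#' @param ks Shank segment stiffness (N/mm).
#' @param km Member (head-side bypass) stiffness (N/mm).
#' @param kc Anchored-core (bone-side bypass) stiffness (N/mm).
#' @return Preload N0 in N (the free-zone/core axial force).
#' @export
preload_from_force_pair <- function(F_applied, ks, km, kc) {
  if (F_applied <= 0) stop("preload_from_force_pair: F_applied must be > 0")
  F_applied * km * kc / (ks * (km + kc) + km * kc)
}

#' Series combination of segment stiffnesses
#' @param ... Segment stiffnesses in N/mm.
#' @return Stiffness of the segments in series (N/mm).
#' @export
series_stiffness <- function(...) 1 / sum(1 / c(...))
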
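## The six screw modeling methods.
##
## TIE    : screw heads tied to the implant, no pretension step.
## BL-CF  : bolt-load section force, kept constant in the simulation step.
## BL-CL  : bolt-load section force, section length locked afterwards.
## ISO    : isotropic pseudo-thermal contraction of the shank, calibrated.
## ORT    : axial-only pseudo-thermal contraction of the shank, calibrated.
## FOR    : equal-and-opposite force pair applied through moment-free
##          rigid-plane reference couplings of the shank end faces,
##          calibrated.
## All methods tie the screws to bone over the embedded zones; all except
## TIE use hard frictionless contact between head and implant.  The
## pretension step applies no external loads; the simulation step maintains
## each method's preload conditions and adds the external load case.

#' Canonical screw modeling method names
#' @export
SCREW_METHODS <- c("TIE", "BL_CF", "BL_CL", "ISO", "ORT", "FOR")

normalize_method <- function(method) {
  m <- toupper(gsub("-", "_", method))
  if (!m %in% SCREW_METHODS)
    stop("unknown screw modeling method '", method, "' (use one of ",
         paste(SCREW_METHODS, collapse = ", "), ")")
  m
}

#' Build the constraint/load plan realizing one screw modeling method
#'
#' @param method One of `"TIE"`, `"BL_CF"`, `"BL_CL"`, `"ISO"`, `"ORT"`,
#'   `"FOR"` (case/dash insensitive).
#' @param assembly An `assembly`.
#' @return An object of class `method_plan` with the head interface mode,
#'   per-screw preload device and simulation-step carryover rule.
#' @export
build_plan <- function(method, assembly) {
  m <- normalize_method(method)
  plan <- switch(m,
    TIE   = list(head_mode = "tie", device = "none",
                 carryover = "none", iterative = FALSE),
    BL_CF = list(head_mode = "contact", device = "section",
                 carryover = "constant_force", iterative = FALSE),
    BL_CL = list(head_mode = "contact", device = "section",
                 carryover = "locked_length", iterative = FALSE),
    ISO   = list(head_mode = "contact", device = "thermal_iso",
                 carryover = "maintained_control", iterative = TRUE),
    ORT   = list(head_mode = "contact", device = "thermal_axial",
                 carryover = "maintained_control", iterative = TRUE),
    FOR   = list(head_mode = "contact", device = "force_pair",
                 carryover = "maintained_control", iterative = TRUE))
  plan$method <- m
  plan$n_screws <- length(assembly$screws)
  structure(plan, class = "method_plan")
}

# The fe_case realizing a plan.  `lock` (named numeric) prescribes section
# scalars, used by BL-CL's simulation step.  Cases (and their factored
# stiffness) are memoised on the assembly: ISO and ORT share one case, the
# two bolt-load pretension steps share another.
method_case <- function(assembly, plan, lock = NULL) {
  key <- paste(plan$head_mode, plan$device == "section",
               plan$device == "force_pair",
               if (is.null(lock)) "" else paste(signif(lock, 15),
                                                collapse = ","))
  hit <- assembly$case_cache[[key]]
  if (!is.null(hit)) return(hit)
  cs <- .method_case_build(assembly, plan, lock)
  assembly$case_cache[[key]] <- cs
  cs
}

.method_case_build <- function(assembly, plan, lock = NULL) {
  scr <- assembly$screws
  ties <- c(vapply(scr, `[[`, "", "junction"), vapply(scr, `[[`, "", "embed"),
            vapply(scr, `[[`, "", "bore"))
  sections <- character(0)
  couplings <- list()
  if (plan$device == "section") {
    sections <- vapply(scr, `[[`, "", "section")
  } else {
    ties <- c(ties, vapply(scr, `[[`, "", "section"))
  }
  if (plan$device == "force_pair") {
    for (s in scr) {
      for (side in c("top", "bot")) {
        nset <- assembly$mesh$nsets[[s[[paste0("shank_", side)]]]]
        couplings <- c(couplings, list(list(
          name = paste0("sq_", side, "_", s$k), nset = nset, comp = 3L,
          mode = "plane",
          coords = sweep(assembly$mesh$nodes[nset, 1:2, drop = FALSE],
                         2, s$center))))
      }
    }
  }
  contacts <- "plate_bone"
  if (plan$head_mode == "tie") {
    ties <- c(ties, vapply(scr, `[[`, "", "head"))
  } else {
    contacts <- c(contacts, vapply(scr, `[[`, "", "head"))
  }
  fixed_scalars <- numeric(0)
  if (!is.null(lock)) fixed_scalars <- lock
  fe_case(assembly$model, ties = ties, contacts = contacts,
          sections = sections, couplings = couplings,
          fixed_scalars = fixed_scalars)
}

# Device loads for given per-screw control values (named by screw index).
device_loads <- function(assembly, plan, controls) {
  scr <- assembly$screws
  loads <- list()
  if (plan$device == "section") {
    sf <- stats::setNames(as.numeric(controls),
                          vapply(scr, `[[`, "", "section"))
    loads$scalar_forces <- sf
  } else if (plan$device %in% c("thermal_iso", "thermal_axial")) {
    mode <- if (plan$device == "thermal_iso") "isotropic" else "axial"
    loads$thermals <- lapply(seq_along(scr), function(k) {
      elems <- which(assembly$mesh$region == scr[[k]]$shank_region)
      thermal_load(elems, controls[[k]], mode, axis = c(0, 0, 1))
    })
  } else if (plan$device == "force_pair") {
    # equal-and-opposite compressive forces on the rigid-plane reference
    # scalars of the shank end faces
    sf <- numeric(0)
    for (k in seq_along(scr)) {
      sf[paste0("sq_top_", scr[[k]]$k)] <- -controls[[k]]
      sf[paste0("sq_bot_", scr[[k]]$k)] <- +controls[[k]]
    }
    loads$scalar_forces <- sf
  }
  loads
}

#' Run the pretension step of a screw modeling method
#'
#' No external forces are applied, so the step resembles tightening of the
#' screws.  Bolt-load methods apply the target pretension forces directly as
#' section forces; the iterative methods require calibrated control values
#' (see [calibrate_assembly()]); TIE has no pretension step and returns a
#' stress-free state.
#'
#' @param assembly An `assembly`.
#' @param plan A [build_plan()].
#' @param targets Per-screw pretension forces F_P (N), recycled.
#' @param controls Per-screw device control values: section forces (N) for BL
#'   methods (defaults to `targets`), control strain for ISO/ORT, force-pair
#'   magnitude (N) for FOR.
#' @return An object of class `two_step_result` with the pretension
#'   solution, the control values used and the locked section lengths.
#' @export
run_pretension_step <- function(assembly, plan, targets,
                                controls = NULL) {
  n <- length(assembly$screws)
  targets <- rep_len(targets, n)
  res <- structure(list(plan = plan, targets = targets,
                        controls = controls, pretension = NULL,
                        lock = NULL, simulation = list()),
                   class = "two_step_result")
  if (plan$method == "TIE") return(res)
  if (plan$device == "section" && is.null(controls)) controls <- targets
  if (is.null(controls))
    stop("run_pretension_step: method ", plan$method,
         " requires calibrated control values")
  controls <- rep_len(controls, n)
  case <- method_case(assembly, plan)
  sol <- fe_solve(assembly$model, case, device_loads(assembly, plan, controls))
  res$controls <- controls
  res$pretension <- sol
  if (plan$device == "section")
    res$lock <- sol$scalars[vapply(assembly$screws, `[[`, "", "section")]
  res
}

#' Run the simulation step of a screw modeling method
#'
#' The conditions used to induce the pretension are maintained (constant
#' section force for BL-CF, locked section length for BL-CL, fixed control
#' strain or force pair for ISO/ORT/FOR) and the external load case is
#' applied.  The contact active set restarts from the pretension state.
#'
#' @param assembly An `assembly`.
#' @param plan A [build_plan()].
#' @param result A [run_pretension_step()] result.
#' @param load_case Name of an assembly load case (or a list
#'   `list(node=, F=)`).
#' @return `result` with `simulation[[load_case]]` filled in.
#' @export
run_simulation_step <- function(assembly, plan, result, load_case) {
  lc <- if (is.character(load_case)) {
    if (is.null(assembly$loads[[load_case]]))
      stop("run_simulation_step: unknown load case '", load_case, "'")
    assembly$loads[[load_case]]
  } else load_case
  lc_name <- if (is.character(load_case)) load_case else "custom"
  point <- data.frame(node = rep(lc$node, 3), comp = 1:3, value = lc$F)

  loads <- list(point = point)
  lock <- NULL
  if (plan$method != "TIE") {
    if (plan$carryover == "locked_length") {
      lock <- result$lock
    } else {
      dl <- device_loads(assembly, plan, result$controls)
      if (!is.null(dl$point)) loads$point <- rbind(loads$point, dl$point)
      loads$thermals <- dl$thermals
      loads$scalar_forces <- dl$scalar_forces
    }
  }
  case <- method_case(assembly, plan, lock = lock)
  seed <- if (length(result$simulation) > 0)
    result$simulation[[length(result$simulation)]] else result$pretension
  sol <- fe_solve(assembly$model, case, loads, state0 = seed)
  result$simulation[[lc_name]] <- sol
  result
}

#' Run a full two-step analysis for one method
#'
#' @param assembly An `assembly`.
#' @param method Method name.
#' @param targets Per-screw pretension forces (N).
#' @param controls Calibrated controls for the iterative methods.
#' @param load_cases Character vector of assembly load-case names.
#' @return A `two_step_result` with all simulation solutions.
#' @export
run_two_step <- function(assembly, method, targets, controls = NULL,
                         load_cases = names(assembly$loads)) {
  plan <- build_plan(method, assembly)
  res <- run_pretension_step(assembly, plan, targets, controls)
  for (lc in load_cases) res <- run_simulation_step(assembly, plan, res, lc)
  res
}
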
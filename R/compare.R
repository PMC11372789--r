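## End-to-end drivers: pretension-table inference from a screw CSV, and the
## multi-method comparison producing per-method/per-screw/per-load-case
## free-zone forces, peak stresses, failure flags and calibration traces.
## These functions are the package's scripted entry points.

#' Read a screw specification table
#'
#' CSV schema: `id, category, D_major_mm, D_minor_mm, pitch_mm, head_mm,
#' shank_mm, shank_len_mm, core_len_mm, L_mm, FPO_override_N`.  `L_mm`
#' (engagement length) may be empty for rows carrying an override.
#'
#' @param path CSV file.
#' @return List with `specs` (list of [screw_spec()]) and `overrides`
#'   (named vector of pullout thresholds, N).
#' @export
read_screw_table <- function(path) {
  need <- c("id", "category", "D_major_mm", "D_minor_mm", "pitch_mm",
            "head_mm", "shank_mm", "shank_len_mm", "core_len_mm", "L_mm",
            "FPO_override_N")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0)
    return(list(specs = list(), overrides = NULL))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("read_screw_table: missing columns: ", paste(miss, collapse = ", "))
  specs <- vector("list", nrow(df))
  overrides <- numeric(0)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    specs[[i]] <- tryCatch(
      screw_spec(id = row$id, category = row$category,
                 D_major = row$D_major_mm, D_minor = row$D_minor_mm,
                 pitch = row$pitch_mm, head_diameter = row$head_mm,
                 shank_diameter = row$shank_mm,
                 shank_length = row$shank_len_mm,
                 core_length = row$core_len_mm,
                 engagement_length = suppressWarnings(as.numeric(row$L_mm))),
      error = function(e) stop("read_screw_table: row ", i, " (", row$id,
                               "): ", conditionMessage(e), call. = FALSE))
    ov <- suppressWarnings(as.numeric(row$FPO_override_N))
    if (!is.na(ov)) overrides[row$id] <- ov
    if (is.na(ov) && is.na(suppressWarnings(as.numeric(row$L_mm))))
      stop("read_screw_table: row ", i, " (", row$id, "): needs either ",
           "L_mm or FPO_override_N")
  }
  list(specs = specs, overrides = if (length(overrides)) overrides else NULL)
}

#' Infer the pretension table for a screw CSV
#'
#' Runs the pullout/stripping-torque/insertion-torque/pretension chain and
#' writes a table-shaped CSV (`id, FPO_N, Tstr_Nm, Tins_Nm, FP_N`; torques
#' in N m rounded to one decimal) plus a JSON echo of all constants used.
#'
#' @param input_csv Screw table (see [read_screw_table()]).
#' @param output_csv Output path (optional).
#' @param output_json Constants-echo path (optional).
#' @param rho_app Apparent density for the shear strength (g/cm^3).
#' @param fric A [friction_set()].
#' @param calib A [ct_calibration()].
#' @return The result data.frame, invisibly when writing.
#' @export
infer_pretension_csv <- function(input_csv, output_csv = NULL,
                                 output_json = NULL, rho_app = 0.422,
                                 fric = friction_set(),
                                 calib = ct_calibration()) {
  st <- read_screw_table(input_csv)
  tab <- infer_pretension_table(st$specs, rho_app = rho_app, fric = fric,
                                calib = calib, F_PO_override = st$overrides)
  out <- data.frame(id = tab$screw_id,
                    FPO_N = round(tab$F_PO, 1),
                    Tstr_Nm = round(tab$T_str / 1000, 1),
                    Tins_Nm = round(tab$T_ins / 1000, 1),
                    FP_N = round(tab$F_P, 1),
                    stringsAsFactors = FALSE)
  if (!is.null(output_csv)) utils::write.csv(out, output_csv,
                                             row.names = FALSE)
  if (!is.null(output_json)) {
    echo <- list(rho_app = rho_app, friction = unclass(fric),
                 calibration = unclass(calib),
                 d_km = vapply(st$specs, `[[`, 0, "d_km"),
                 Se_screw = fatigue_limit())
    jsonlite::write_json(echo, output_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (is.null(output_csv)) out else invisible(out)
}

#' Run all requested screw modeling methods on one assembly
#'
#' Calibrates the iterative methods, runs every method's two-step analysis
#' over the load cases, extracts free-zone forces and peak von Mises
#' stresses (3 mm junction exclusion), classifies pullout/fatigue
#' likelihood, and computes the pairwise method-agreement matrix of
#' free-zone forces.
#'
#' @param assembly An `assembly`.
#' @param methods Methods to run (default all six).
#' @param targets Per-screw pretension forces; default from
#'   [assembly_targets()].
#' @param load_cases Load-case names (default all; the agreement matrix
#'   uses the first).
#' @param tol,max_iter Calibration settings.
#' @param exclusion_mm Von Mises exclusion length.
#' @return An object of class `method_comparison`: `forces` and `peaks`
#'   (method x screw x load case arrays), `flags` (per method),
#'   `agreement` (pairwise max relative free-zone-force deviation over
#'   non-liftoff load cases), `calibrations`, `results`, `targets`.
#' @export
run_method_comparison <- function(assembly, methods = SCREW_METHODS,
                                  targets = NULL,
                                  load_cases = names(assembly$loads),
                                  tol = 0.05, max_iter = 50,
                                  exclusion_mm = 3) {
  methods <- vapply(methods, normalize_method, "")
  n <- length(assembly$screws)
  ids <- vapply(assembly$screws, `[[`, "", "id")
  ttab <- assembly_targets(assembly)
  if (is.null(targets)) targets <- ttab$F_P
  targets <- rep_len(targets, n)

  forces <- array(NA_real_, c(length(methods), n, length(load_cases)),
                  dimnames = list(methods, ids, load_cases))
  peaks <- forces
  calibrations <- list(); results <- list(); flags <- list()
  for (m in methods) {
    controls <- NULL
    if (m %in% c("ISO", "ORT", "FOR")) {
      cal <- calibrate_assembly(assembly, m, targets, tol = tol,
                                max_iter = max_iter)
      calibrations[[m]] <- cal
      controls <- cal$controls
    }
    res <- run_two_step(assembly, m, targets, controls, load_cases)
    results[[m]] <- res
    for (lc in load_cases) {
      sol <- res$simulation[[lc]]
      for (k in seq_len(n)) {
        forces[m, k, lc] <- suppressWarnings(free_zone_force(assembly, sol, k))
        peaks[m, k, lc] <- peak_von_mises(assembly, sol, k, exclusion_mm)
      }
    }
    flags[[m]] <- classify_failure(forces[m, , , drop = TRUE],
                                   peaks[m, , , drop = TRUE],
                                   F_PO = ttab$F_PO, ids = ids)
  }

  std <- setdiff(load_cases, "liftoff")
  agreement <- matrix(NA_real_, length(methods), length(methods),
                      dimnames = list(methods, methods))
  for (m1 in methods) for (m2 in methods) {
    d <- abs(forces[m1, , std] - forces[m2, , std]) /
      pmax(abs(forces[m2, , std]), 1e-9)
    agreement[m1, m2] <- max(d)
  }

  structure(list(methods = methods, forces = forces, peaks = peaks,
                 flags = flags, agreement = agreement,
                 calibrations = calibrations, results = results,
                 targets = targets, pretension_table = ttab,
                 load_cases = load_cases),
            class = "method_comparison")
}

#' Write a method-comparison report as JSON
#'
#' @param cmp A [run_method_comparison()] result.
#' @param file Output path.
#' @return Invisibly, the file path.
#' @export
write_comparison_json <- function(cmp, file) {
  out <- list(
    methods = cmp$methods,
    targets = cmp$targets,
    free_zone_forces = apply(cmp$forces, 1, function(m)
      as.data.frame(m), simplify = FALSE),
    peak_von_mises = apply(cmp$peaks, 1, function(m)
      as.data.frame(m), simplify = FALSE),
    agreement = as.data.frame(cmp$agreement),
    calibration_iterations = lapply(cmp$calibrations, `[[`, "iterations"),
    calibration_errors = lapply(cmp$calibrations, `[[`, "errors"))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
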
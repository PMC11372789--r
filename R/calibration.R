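## Secant-method calibration of the iterative preload devices.
##
## The physics-based methods (ISO, ORT, FOR) cannot impose the inferred
## pretension force directly: the control value (thermal contraction strain
## or force-pair magnitude) that induces it must be found by root finding on
## f(x) = F_induced(x) - F_P.  Per-screw scalar Secant updates are applied
## to all screws simultaneously; each iteration costs one full-model
## pretension solve.  Initial guesses come from an isolated single-screw
## model, whose (linear) control-to-force slope is probed once.

#' One Secant update for a scalar control
#'
#' `x_next = x_curr - f_curr (x_curr - x_prev) / (f_curr - f_prev)`.
#' A degenerate (flat) secant falls back to a 1% perturbation of the
#' current control, flagged via the `"degenerate"` attribute.
#'
#' @param x_prev,x_curr Previous and current control values.
#' @param f_prev,f_curr Residuals `F_induced - F_P` (N) at those controls.
#' @return The next control value.
#' @export
secant_update <- function(x_prev, x_curr, f_prev, f_curr) {
  if (f_curr == f_prev) {
    x <- if (x_curr != 0) 1.01 * x_curr else 1e-6
    attr(x, "degenerate") <- TRUE
    return(x)
  }
  x_curr - f_curr * (x_curr - x_prev) / (f_curr - f_prev)
}

# Probe scale for the first single-screw evaluation, from the 1D
# joint-diagram oracle: a member-stiffness estimate sets the contraction
# needed for a target-sized preload; the force pair is probed at the
# target itself.
.probe_scale <- function(assembly, method, F_P) {
  r <- assembly$recipe
  if (method == "FOR") return(F_P)
  m <- r$materials
  A_m <- r$plate[1] * r$plate[2]
  km_est <- m$E_trabecular * A_m / r$bone[1]
  kb_est <- m$E_implant * assembly$screws[[1]]$core_area /
    assembly$screws[[1]]$core_len
  L_sh <- r$plate[3]
  # invert preload_from_thermal for N0 = F_P
  -F_P * (kb_est + km_est) / (kb_est * km_est) / L_sh
}

#' Control-to-force response of an isolated single-screw model
#'
#' Solves the single-screw pretension state at a probe control and returns
#' the induced free-zone force per unit control.  The pretension response
#' is linear in the control, so the slope fixes the initial guess
#' `x0 = F_P / slope`.
#'
#' @param assembly1 A single-screw `assembly`.
#' @param method `"ISO"`, `"ORT"` or `"FOR"`.
#' @param F_P Reference pretension force (sets the probe scale).
#' @return List with `slope` (N per control unit) and the probe solution.
#' @export
single_screw_response <- function(assembly1, method, F_P = 500) {
  method <- normalize_method(method)
  if (!method %in% c("ISO", "ORT", "FOR"))
    stop("single_screw_response: method must be ISO, ORT or FOR")
  if (length(assembly1$screws) != 1)
    stop("single_screw_response: assembly must have exactly one screw")
  plan <- build_plan(method, assembly1)
  xp <- .probe_scale(assembly1, method, F_P)
  res <- run_pretension_step(assembly1, plan, targets = F_P, controls = xp)
  Fp <- free_zone_force(assembly1, res$pretension, 1)
  list(slope = Fp / xp, probe = xp, induced = Fp, result = res)
}

#' Initial control guess from a single-screw model
#'
#' @param assembly1 A single-screw `assembly` built with the screw's
#'   geometry and materials.
#' @param method `"ISO"`, `"ORT"` or `"FOR"`.
#' @param F_P Target pretension force (N).
#' @return Control value inducing `F_P` in the isolated model.
#' @export
single_screw_initial_guess <- function(assembly1, method, F_P) {
  if (F_P == 0) return(0)
  resp <- single_screw_response(assembly1, method, F_P)
  F_P / resp$slope
}

# Single-screw recipe matching a multi-screw assembly's first screw
# (homogeneous trabecular modulus at the field mean for sampled fields).
single_screw_recipe_of <- function(assembly) {
  r <- assembly$recipe
  mat <- r$materials
  if (r$bone_field == "sampled") mat$E_trabecular <- r$field$mean_E
  pl <- max(13, r$screw$head_w[1] + 6 * r$h)
  # snap the plate size so the centred odd screw sections land on grid planes
  widths <- c(r$screw$core_w[1], r$screw$shank_w[1], r$screw$head_w[1])
  ok <- function(p2) all(abs((p2 / 2 + widths / 2) / r$h -
                               round((p2 / 2 + widths / 2) / r$h)) < 1e-9)
  while (!ok(pl)) pl <- pl + r$h
  assembly_recipe(n_screws = 1, plate = c(pl, pl, r$plate[3]),
                  bone = r$bone,
                  screw = lapply(r$screw, `[`, 1),
                  spec = r$spec, materials = mat,
                  bone_field = "homogeneous",
                  springs = r$springs, h = r$h, order = r$order)
}

#' Calibrate the iterative preload controls of an assembly
#'
#' Simultaneous per-screw Secant iteration: every iteration performs one
#' full-model pretension solve evaluating all screws' induced free-zone
#' forces, then updates every control.  Convergence requires the maximum
#' per-screw percent error below `tol`; the second initial guess is 0.9
#' times the single-screw guess.
#'
#' @param assembly An `assembly`.
#' @param method `"ISO"`, `"ORT"` or `"FOR"`.
#' @param targets Per-screw pretension forces F_P (N), recycled.
#' @param tol Relative convergence tolerance (default 0.05 = 5%).
#' @param max_iter Iteration cap.
#' @param x0 Optional per-screw initial guesses (skips the single-screw
#'   model).
#' @return An object of class `calibration`: `controls`, `trace`
#'   (iteration, per-screw percent errors, mean, max), `iterations`
#'   (= full-model solves), `converged`, and the final pretension
#'   `result`.
#' @export
calibrate_assembly <- function(assembly, method, targets, tol = 0.05,
                               max_iter = 50, x0 = NULL) {
  method <- normalize_method(method)
  n <- length(assembly$screws)
  targets <- rep_len(targets, n)
  if (any(targets <= 0)) stop("calibrate_assembly: targets must be positive")
  plan <- build_plan(method, assembly)

  if (is.null(x0)) {
    a1 <- build_assembly(single_screw_recipe_of(assembly))
    slope <- single_screw_response(a1, method, F_P = mean(targets))$slope
    x0 <- targets / slope
  } else x0 <- rep_len(x0, n)

  evaluate <- function(x, state) {
    res <- run_pretension_step(assembly, plan, targets, controls = x)
    Find <- vapply(seq_len(n), function(k)
      free_zone_force(assembly, res$pretension, k), numeric(1))
    list(res = res, F = Find, f = Find - targets,
         err = abs(Find - targets) / targets * 100)
  }

  trace <- NULL
  push <- function(it, err) {
    rbind(trace, data.frame(iteration = it, t(err),
                            mean_err = mean(err), max_err = max(err)))
  }

  x_prev <- x0
  ev_prev <- evaluate(x_prev, NULL)
  trace <- push(1L, ev_prev$err)
  niter <- 1L
  converged <- max(ev_prev$err) < tol * 100
  x_curr <- x_prev; ev_curr <- ev_prev

  if (!converged) {
    x_curr <- 0.9 * x0
    ev_curr <- evaluate(x_curr, ev_prev$res$pretension)
    niter <- 2L
    trace <- push(2L, ev_curr$err)
    converged <- max(ev_curr$err) < tol * 100
  }
  while (!converged && niter < max_iter) {
    x_next <- vapply(seq_len(n), function(k)
      as.numeric(secant_update(x_prev[k], x_curr[k],
                               ev_prev$f[k], ev_curr$f[k])), numeric(1))
    x_prev <- x_curr; ev_prev <- ev_curr
    x_curr <- x_next
    ev_curr <- evaluate(x_curr, ev_prev$res$pretension)
    niter <- niter + 1L
    trace <- push(niter, ev_curr$err)
    converged <- max(ev_curr$err) < tol * 100
  }
  if (!converged)
    warning("calibrate_assembly: ", method, " did not reach ",
            tol * 100, "% in ", max_iter, " iterations (max error ",
            round(max(ev_curr$err), 2), "%)", call. = FALSE)
  ids <- vapply(assembly$screws, `[[`, "", "id")
  names(trace)[2:(1 + n)] <- paste0("err_", ids)
  rownames(trace) <- NULL
  structure(list(method = method, controls = x_curr, targets = targets,
                 trace = trace, iterations = niter, converged = converged,
                 induced = ev_curr$F, errors = ev_curr$err,
                 result = ev_curr$res),
            class = "calibration")
}
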
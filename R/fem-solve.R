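## Constrained linear-elastic solver.
##
## Equality constraints (ties, slide fits, pretension sections, rigid axial
## couplings, prescribed displacements) are eliminated exactly through a
## sparse transformation u_ext = T q + g, where u_ext stacks the nodal dofs
## and the constraint scalars (one relative-axial-length scalar per
## pretension section, one per coupled face).
##
## Hard frictionless contact on conforming node pairs is exact as well:
## every contact node pair gets a gap scalar lambda >= 0 in the same
## transformation (u_slave = u_master - sign * lambda).  The stiffness
## block over the non-gap dofs is the fully-closed (all pairs active)
## operator, which is bounded and positive definite; it is factored once
## per case and condensed into the dense Delassus matrix
## D = H_ll - H_lq K_act^-1 H_ql over the gaps.  The complementarity
## system 0 <= lambda  perp  p = p0 - D lambda >= 0 is then solved by an
## active-set iteration on D (Murty's least-index rule on cycling, which
## terminates finitely since D is positive definite).  Each solve after
## the cached setup costs two sparse backsolves plus small dense algebra.

#' Build a finite-element model (mesh + materials + springs)
#'
#' Assembles and caches the elastic stiffness plus the linear boundary
#' springs.  Compression-only spring sets are kept separate and handled in
#' the solver's active-set loop.
#'
#' @param mesh An `fe_mesh`.
#' @param E,nu Per-element material fields (scalars recycled).
#' @param springs List of [spring_set()].
#' @return An object of class `fe_model`.
#' @export
fe_model <- function(mesh, E, nu, springs = list()) {
  ndof <- 3L * nrow(mesh$nodes)
  K_el <- assemble_stiffness(mesh, E, nu)
  lin <- Filter(function(s) s$mode == "linear", springs)
  conly <- Filter(function(s) s$mode == "compression_only", springs)
  K <- K_el + spring_matrix(ndof, lin)
  structure(list(mesh = mesh, E = rep_len(E, nrow(mesh$elems)),
                 nu = rep_len(nu, nrow(mesh$elems)),
                 springs = springs, conly = conly,
                 K = K, K_elastic = K_el, ndof = ndof),
            class = "fe_model")
}

#' Define the constraint configuration of an analysis step
#'
#' @param model An [fe_model()].
#' @param ties Names of mesh pairs to bond.  Tie-type pairs bond all
#'   components, slide-type pairs bond only the components transverse to
#'   their axis, and section-type pairs listed here are fully bonded (no
#'   relative axial scalar), which is how the non-bolt-load methods treat
#'   the cut.
#' @param contacts Names of mesh pairs treated as hard frictionless contact
#'   (pair normals must be axis-aligned).
#' @param sections Names of section-type pairs given a relative axial
#'   length scalar (the bolt-load device).
#' @param couplings List of `list(name=, nset=, comp=, mode=, coords=)`:
#'   rigid coupling of the listed nodal components to reference scalars.
#'   Mode `"equal"` constrains every component to one scalar; mode
#'   `"plane"` constrains them to a rigid plane
#'   `u_i = s + dx_i * tx + dy_i * ty` with free tilt scalars `<name>.tx`,
#'   `<name>.ty` (`coords` = two-column matrix of in-plane offsets), i.e.
#'   a moment-free rigid reference-node coupling of a face.
#' @param fixed Data frame `node`, `comp`, `value` of prescribed nodal
#'   displacements (mm).
#' @param fixed_scalars Named numeric of prescribed constraint scalars,
#'   e.g. a locked section length.
#' @return An object of class `fe_case`.  The case carries a private cache
#'   of factored operators, reused across solves.
#' @export
fe_case <- function(model, ties = character(), contacts = character(),
                    sections = character(), couplings = list(),
                    fixed = NULL, fixed_scalars = numeric()) {
  mesh <- model$mesh
  ndof <- model$ndof
  getpair <- function(nm) {
    p <- mesh$pairs[[nm]]
    if (is.null(p)) stop("fe_case: unknown pair '", nm, "'")
    p
  }
  # contact gap scalars come after the user-facing scalars
  mC <- 0L
  cpair <- character(0); csdof <- integer(0); cmdof <- integer(0)
  csign <- numeric(0)
  for (nm in contacts) {
    p <- getpair(nm)
    comp <- which(abs(abs(p$normal) - 1) < 1e-12)
    if (length(comp) != 1)
      stop("fe_case: contact pair '", nm, "' normal must be axis-aligned")
    m <- length(p$a)
    cpair <- c(cpair, rep(nm, m))
    csdof <- c(csdof, 3L * (p$b - 1L) + comp)
    cmdof <- c(cmdof, 3L * (p$a - 1L) + comp)
    csign <- c(csign, rep(p$normal[comp], m))
    mC <- mC + m
  }
  scalar_names <- c(sections,
                    unlist(lapply(couplings, function(cp) {
                      if (identical(cp$mode, "plane"))
                        c(cp$name, paste0(cp$name, ".tx"),
                          paste0(cp$name, ".ty"))
                      else cp$name
                    })))
  if (anyDuplicated(scalar_names)) stop("fe_case: duplicate scalar names")
  nsc <- length(scalar_names)
  next_ <- ndof + nsc + mC
  scid <- function(nm) ndof + match(nm, scalar_names)

  slave <- integer(0); col <- integer(0); coef <- numeric(0)
  add_rel <- function(s, c2, x) {
    slave <<- c(slave, s); col <<- c(col, c2); coef <<- c(coef, x)
  }
  for (nm in ties) {
    p <- getpair(nm)
    comps <- if (p$type == "slide") {
      ax <- p$axis %||% c(0, 0, 1)
      which(abs(ax) < 1e-12)
    } else 1:3
    for (cc in comps) add_rel(3L * (p$b - 1L) + cc, 3L * (p$a - 1L) + cc,
                              rep(1, length(p$a)))
  }
  for (nm in sections) {
    p <- getpair(nm)
    if (p$type != "section") stop("fe_case: pair '", nm, "' is not a section")
    ax <- if (is.null(p$axis)) c(0, 0, 1) else p$axis
    for (cc in 1:3) {
      add_rel(3L * (p$b - 1L) + cc, 3L * (p$a - 1L) + cc,
              rep(1, length(p$a)))
      if (abs(ax[cc]) > 0)
        add_rel(3L * (p$b - 1L) + cc, rep(scid(nm), length(p$a)),
                rep(ax[cc], length(p$a)))
    }
  }
  for (cp in couplings) {
    n_cp <- length(cp$nset)
    add_rel(3L * (cp$nset - 1L) + cp$comp, rep(scid(cp$name), n_cp),
            rep(1, n_cp))
    if (identical(cp$mode, "plane")) {
      add_rel(3L * (cp$nset - 1L) + cp$comp,
              rep(scid(paste0(cp$name, ".tx")), n_cp), cp$coords[, 1])
      add_rel(3L * (cp$nset - 1L) + cp$comp,
              rep(scid(paste0(cp$name, ".ty")), n_cp), cp$coords[, 2])
    }
  }
  # contact gap relations: u_slave = u_master - sign * lambda
  if (mC > 0) {
    add_rel(csdof, cmdof, rep(1, mC))
    add_rel(csdof, ndof + nsc + seq_len(mC), -csign)
  }

  fixed_idx <- integer(0); fixed_val <- numeric(0)
  if (!is.null(fixed) && nrow(fixed) > 0) {
    fixed_idx <- 3L * (fixed$node - 1L) + fixed$comp
    fixed_val <- fixed$value
  }
  if (length(fixed_scalars) > 0) {
    fixed_idx <- c(fixed_idx, vapply(names(fixed_scalars), scid, 0L))
    fixed_val <- c(fixed_val, unname(fixed_scalars))
  }

  structure(list(model_ndof = ndof, nscalar = nsc, mC = mC, next_ = next_,
                 scalar_names = scalar_names,
                 ties = ties, contacts = contacts, sections = sections,
                 couplings = couplings,
                 slave = slave, col = col, coef = coef,
                 fixed_idx = fixed_idx, fixed_val = fixed_val,
                 cpair = cpair, csdof = csdof, csign = csign,
                 cache = new.env(parent = emptyenv())),
            class = "fe_case")
}

# Exact elimination operator for linear multi-point constraints.
# slave/col/coef define rows "u[slave] = sum coef * u_ext[col]"; chains are
# resolved by substitution.  Returns T (next x nfree), g (next), free ids.
build_transform <- function(next_, slave, col, coef, fixed_idx, fixed_val) {
  uslave <- unique(slave)
  if (length(intersect(uslave, fixed_idx)) > 0)
    stop("build_transform: a slave dof cannot also be prescribed")
  A <- NULL
  if (length(uslave) > 0) {
    A <- Matrix::sparseMatrix(i = match(slave, uslave), j = col, x = coef,
                              dims = c(length(uslave), next_))
    for (pass in 1:10) {
      Asl <- A[, uslave, drop = FALSE]
      if (Matrix::nnzero(Asl) == 0) break
      if (pass == 10) stop("build_transform: constraint chain did not resolve",
                           " (cyclic dependency?)")
      A[, uslave] <- 0
      A <- A + Asl %*% A
      A <- Matrix::drop0(A)
    }
  }
  free <- setdiff(seq_len(next_), union(uslave, fixed_idx))
  nfree <- length(free)
  ii <- free; jj <- seq_len(nfree); xx <- rep(1, nfree)
  g <- numeric(next_)
  if (length(fixed_idx) > 0) g[fixed_idx] <- fixed_val
  if (length(uslave) > 0) {
    Af <- A[, free, drop = FALSE]
    sm <- Matrix::summary(Af)
    ii <- c(ii, uslave[sm$i]); jj <- c(jj, sm$j); xx <- c(xx, sm$x)
    if (length(fixed_idx) > 0)
      g[uslave] <- as.numeric(A[, fixed_idx, drop = FALSE] %*% fixed_val)
  }
  T <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(next_, nfree))
  list(T = T, g = g, free = free)
}

# Assemble the full applied load vector from the loads description.
.full_load <- function(model, case, loads) {
  f <- numeric(case$next_)
  if (!is.null(loads$f)) f[seq_along(loads$f)] <- f[seq_along(loads$f)] + loads$f
  if (!is.null(loads$point) && nrow(loads$point) > 0) {
    dof <- 3L * (loads$point$node - 1L) + loads$point$comp
    for (r in seq_along(dof)) f[dof[r]] <- f[dof[r]] + loads$point$value[r]
  }
  for (th in loads$thermals %||% list())
    f[seq_len(model$ndof)] <- f[seq_len(model$ndof)] +
      thermal_load_vector(model$mesh, model$E, model$nu, th)
  sf <- loads$scalar_forces %||% numeric()
  for (nm in names(sf)) {
    k <- match(nm, case$scalar_names)
    if (is.na(k)) stop("fe_solve: unknown scalar '", nm, "'")
    f[model$ndof + k] <- f[model$ndof + k] + sf[[nm]]
  }
  f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-time (cached) setup: eliminate, factor the fully-closed block,
# condense the contact flexibility.
.case_setup <- function(model, case) {
  cache <- case$cache
  if (!is.null(cache$fact)) return(cache)
  tr <- build_transform(case$next_, case$slave, case$col, case$coef,
                        case$fixed_idx, case$fixed_val)
  T1 <- tr$T[seq_len(model$ndof), , drop = FALSE]
  lam_ext <- model$ndof + case$nscalar + seq_len(case$mC)
  lcols <- match(lam_ext, tr$free)
  if (case$mC > 0 && any(is.na(lcols)))
    stop("fe_solve: a contact gap scalar was eliminated or fixed")
  qcols <- setdiff(seq_along(tr$free), lcols)
  H <- Matrix::t(T1) %*% (model$K %*% T1)
  Kact <- Matrix::forceSymmetric(H[qcols, qcols, drop = FALSE])
  fact <- tryCatch(Matrix::Cholesky(Kact, LDL = FALSE),
                   error = function(e)
                     stop("fe_solve: fully-closed reduced stiffness not ",
                          "positive definite (free rigid modes?)",
                          call. = FALSE))
  cache$tr <- tr; cache$T1 <- T1; cache$fact <- fact
  cache$qcols <- qcols; cache$lcols <- lcols
  cache$Kg1 <- as.numeric(model$K %*% tr$g[seq_len(model$ndof)])
  if (case$mC > 0) {
    Hql <- H[qcols, lcols, drop = FALSE]
    Hll <- as.matrix(H[lcols, lcols, drop = FALSE])
    W <- Matrix::solve(fact, Hql)
    cache$Hql <- Hql
    D <- Hll - as.matrix(Matrix::t(Hql) %*% W)
    cache$D <- (D + t(D)) / 2
  }
  cache
}

# Active-set solution of 0 <= lambda  perp  p = p_all + D lambda >= 0,
# where p_all is the contact pressure in the fully-closed state.
.contact_lcp <- function(D, p_all, released, tol_p, tol_l, max_iter = 500L,
                         verbose = FALSE) {
  m <- length(p_all)
  seen <- character(0); pivot_mode <- FALSE
  for (it in seq_len(max_iter)) {
    lam <- numeric(m)
    R <- which(released)
    if (length(R) > 0)
      lam[R] <- solve(D[R, R, drop = FALSE], -p_all[R])
    p <- p_all + as.numeric(D %*% lam)
    # released pairs must open (lam >= 0), closed pairs must press (p >= 0)
    viol_cl <- released & (lam < -tol_l)
    viol_op <- (!released) & (p < -tol_p)
    if (verbose)
      message(sprintf("lcp %d: released %d, close %d, open %d",
                      it, length(R), sum(viol_cl), sum(viol_op)))
    if (!any(viol_cl) && !any(viol_op))
      return(list(lambda = pmax(lam, 0), p = p, released = released,
                  iterations = it))
    if (it == max_iter)
      stop("fe_solve: contact active-set iteration did not converge")
    if (!pivot_mode) {
      newrel <- (released & !viol_cl) | viol_op
      key <- paste(which(newrel), collapse = ",")
      if (key %in% seen) pivot_mode <- TRUE else seen <- c(seen, key)
    }
    if (pivot_mode) {
      # cycling: Murty's least-index single pivot terminates finitely for
      # positive definite D
      newrel <- released
      k <- min(c(which(viol_cl), which(viol_op)))
      newrel[k] <- !newrel[k]
    }
    released <- newrel
  }
}

#' Solve a constrained load case
#'
#' Sparse Cholesky solve of the eliminated system; hard frictionless
#' contact is resolved exactly on the cached contact flexibility operator.
#'
#' @param model An [fe_model()].
#' @param case An [fe_case()].
#' @param loads List with any of: `f` (full load vector), `point` (data
#'   frame `node`, `comp`, `value` in N), `thermals` (list of
#'   [thermal_load()]), `scalar_forces` (named numeric, N, conjugate to
#'   section/coupling scalars).
#' @param state0 Optional previous [fe_solve()] solution used to seed the
#'   contact active set (the serialized pretension state).
#' @param max_iter Active-set iteration cap.
#' @param verbose Print active-set progress.
#' @return An object of class `fe_solution`: displacements `u` (nnodes x 3,
#'   mm), `scalars`, element `stress` and `vm` (MPa), `contact` summary
#'   (per node pair: active flag, pressure, gap), relative equilibrium
#'   `residual`, and the constraint reaction vector `reaction` (K u - f at
#'   every dof; nonzero only where a constraint or prescribed displacement
#'   acts).
#' @export
fe_solve <- function(model, case, loads = list(), state0 = NULL,
                     max_iter = 500L, verbose = FALSE) {
  if (length(model$conly) > 0)
    return(.fe_solve_conly(model, case, loads, state0, verbose = verbose))
  ndof <- model$ndof
  cache <- .case_setup(model, case)
  tr <- cache$tr
  f_full <- .full_load(model, case, loads)
  fred <- as.numeric(Matrix::t(tr$T) %*% f_full -
                       Matrix::t(cache$T1) %*% cache$Kg1)
  fq <- fred[cache$qcols]
  q <- as.numeric(Matrix::solve(cache$fact, fq))

  mC <- case$mC
  lam <- numeric(mC); p <- numeric(mC); lcp_it <- 0L
  released <- logical(mC)
  if (mC > 0) {
    # contact pressure in the fully-closed state
    p_all <- as.numeric(Matrix::t(cache$Hql) %*% q) - fred[cache$lcols]
    f_scale <- max(sum(abs(f_full)), 1)
    if (!is.null(state0) && length(state0$released) == mC)
      released <- state0$released
    lcp <- .contact_lcp(cache$D, p_all, released,
                        tol_p = 1e-10 * f_scale, tol_l = 1e-12,
                        verbose = verbose)
    lam <- lcp$lambda; p <- lcp$p; released <- lcp$released
    lcp_it <- lcp$iterations
    if (any(lam > 0))
      q <- q - as.numeric(Matrix::solve(cache$fact,
                                        as.numeric(cache$Hql %*% lam)))
  }
  z <- numeric(ncol(tr$T))
  z[cache$qcols] <- q
  if (mC > 0) z[cache$lcols] <- lam
  u_ext <- as.numeric(tr$T %*% z) + tr$g
  u <- matrix(u_ext[seq_len(ndof)], ncol = 3, byrow = TRUE)
  scalars <- if (case$nscalar > 0) {
    stats::setNames(u_ext[ndof + seq_len(case$nscalar)], case$scalar_names)
  } else numeric(0)

  # reduced equilibrium residual over the structural dofs
  Ku <- as.numeric(model$K %*% u_ext[seq_len(ndof)])
  r_red <- as.numeric(Matrix::t(tr$T) %*%
                        c(Ku - f_full[seq_len(ndof)],
                          -f_full[ndof + seq_len(case$next_ - ndof)]))
  residual <- sqrt(sum(r_red[cache$qcols]^2)) /
    max(sqrt(sum(fq^2)), 1e-12)

  r_full <- Ku - f_full[seq_len(ndof)]
  contact <- NULL
  if (mC > 0)
    contact <- data.frame(pair = case$cpair, active = !released & p > 0,
                          pressure = p, gap = lam,
                          stringsAsFactors = FALSE)
  thermals <- loads$thermals %||% list()
  stress <- recover_stress(model$mesh, model$E, model$nu, u, thermals)
  structure(list(u = u, scalars = scalars, stress = stress,
                 vm = von_mises(stress), contact = contact,
                 released = released, conly_active = list(),
                 residual = residual, reaction = r_full,
                 f_applied = f_full, iterations = lcp_it),
            class = "fe_solution")
}

# Elimination-based loop for models with compression-only springs (their
# stiffness changes per iteration, defeating the cached factorization);
# contact pairs are not supported here.  Suitable for the small models
# those spring sets appear in.
.fe_solve_conly <- function(model, case, loads = list(), state0 = NULL,
                            max_iter = 60L, verbose = FALSE) {
  ndof <- model$ndof
  if (case$mC > 0)
    stop("fe_solve: contact together with compression-only springs is not ",
         "supported")
  f_full <- .full_load(model, case, loads)
  conly_active <- lapply(model$conly, function(s) rep(TRUE, length(s$nset)))
  tr <- build_transform(case$next_, case$slave, case$col, case$coef,
                        case$fixed_idx, case$fixed_val)
  T1 <- tr$T[seq_len(ndof), , drop = FALSE]
  tol_g <- 1e-10
  u_ext <- NULL; Ks <- NULL; q <- NULL; Kred <- NULL; fred <- NULL
  for (it in seq_len(max_iter)) {
    Ks <- model$K + spring_matrix(ndof, model$conly, conly_active)
    Kred <- Matrix::forceSymmetric(Matrix::t(T1) %*% Ks %*% T1)
    fred <- as.numeric(Matrix::t(tr$T) %*% f_full -
                         Matrix::t(T1) %*% (Ks %*% tr$g[seq_len(ndof)]))
    q <- as.numeric(Matrix::solve(Kred, fred))
    u_ext <- as.numeric(tr$T %*% q) + tr$g
    sp_change <- FALSE
    for (s in seq_along(model$conly)) {
      sp <- model$conly[[s]]
      un <- as.numeric(matrix(u_ext[3 * rep(sp$nset - 1, each = 3) +
                                      rep(1:3, length(sp$nset))],
                              ncol = 3, byrow = TRUE) %*% sp$normal)
      want <- un <= tol_g
      if (any(want != conly_active[[s]])) {
        conly_active[[s]] <- want
        sp_change <- TRUE
      }
    }
    if (verbose) message("conly-iter ", it)
    if (!sp_change) break
    if (it == max_iter)
      stop("fe_solve: compression-only spring iteration did not converge")
  }
  u <- matrix(u_ext[seq_len(ndof)], ncol = 3, byrow = TRUE)
  scalars <- if (case$nscalar > 0) {
    stats::setNames(u_ext[ndof + seq_len(case$nscalar)], case$scalar_names)
  } else numeric(0)
  r <- as.numeric(Kred %*% q - fred)
  residual <- sqrt(sum(r^2)) / max(sqrt(sum(fred^2)), 1e-12)
  r_full <- as.numeric(Ks %*% u_ext[seq_len(ndof)]) - f_full[seq_len(ndof)]
  thermals <- loads$thermals %||% list()
  stress <- recover_stress(model$mesh, model$E, model$nu, u, thermals)
  structure(list(u = u, scalars = scalars, stress = stress,
                 vm = von_mises(stress), contact = NULL,
                 released = logical(0), conly_active = conly_active,
                 residual = residual, reaction = r_full,
                 f_applied = f_full, iterations = it),
            class = "fe_solution")
}

#' Total constraint force transmitted to the b side of an interface pair
#'
#' For tied pairs this is the bonding force (its axial component reveals
#' whether a tie carries tension); for contact pairs it matches the summed
#' contact pressures.
#'
#' @param model An [fe_model()].
#' @param sol An [fe_solve()] solution.
#' @param pair_name Name of a mesh pair.
#' @return Numeric length 3: total force (N) exerted on side b.
#' @export
interface_force <- function(model, sol, pair_name) {
  p <- model$mesh$pairs[[pair_name]]
  if (is.null(p)) stop("interface_force: unknown pair")
  vapply(1:3, function(cc) sum(sol$reaction[3L * (p$b - 1L) + cc]),
         numeric(1))
}
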
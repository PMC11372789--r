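## Linear-elastic stiffness assembly for 4- and 10-node tetrahedra.
##
## Isotropic elasticity is assembled directly from shape-function gradients:
##   K[ia, jb] = sum_qp w V ( lambda g_i,a g_j,b
##                           + mu (g_i,b g_j,a + delta_ab g_i . g_j) )
## which avoids forming B and D matrices and vectorizes across elements.
## Straight-sided tets have a constant Jacobian, so quadratic elements use
## the same per-element Jacobian as linear ones with a 4-point rule.

# Barycentric coordinates (L1..L4) of the quadrature points and weights.
.tet_quadrature <- function(order) {
  if (order == 1L) {
    list(pts = matrix(0.25, 1, 4), w = 1)
  } else {
    a <- 0.5854101966249685; b <- 0.1381966011250105
    pts <- matrix(b, 4, 4); diag(pts) <- a
    list(pts = pts, w = rep(0.25, 4))
  }
}

# dN/dxi (xi = L2, L3, L4) for the 10-node tet at barycentric point L.
.dndxi_tet10 <- function(L) {
  dL <- rbind(c(-1, -1, -1), diag(3))   # dL_i/dxi_a, rows i = 1..4
  dN <- matrix(0, 10, 3)
  for (i in 1:4) dN[i, ] <- (4 * L[i] - 1) * dL[i, ]
  edge <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  for (e in 1:6) {
    i <- edge[e, 1]; j <- edge[e, 2]
    dN[4 + e, ] <- 4 * (L[j] * dL[i, ] + L[i] * dL[j, ])
  }
  dN
}

.dndxi_tet4 <- rbind(c(-1, -1, -1), diag(3))

# Per-element inverse Jacobians and volumes.
# Returns list(vol, Jinv = list over b of (ne x 3): Jinv[[b]][e, a]).
.element_geometry <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  c1 <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  c2 <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  c3 <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  r1 <- cross(c2, c3); r2 <- cross(c3, c1); r3 <- cross(c1, c2)
  det <- c1[, 1] * r1[, 1] + c1[, 2] * r1[, 2] + c1[, 3] * r1[, 3]
  if (any(det <= 0)) stop("element_geometry: inverted or degenerate element")
  list(vol = det / 6,
       Jinv = list(r1 / det, r2 / det, r3 / det))
}

# Shape-function gradients dN/dx at one quadrature point:
# list over node i of (ne x 3) matrices.
.grad_at <- function(geom, dndxi) {
  nn <- nrow(dndxi)
  lapply(seq_len(nn), function(i) {
    g <- 0
    for (b in 1:3) if (dndxi[i, b] != 0) g <- g + dndxi[i, b] * geom$Jinv[[b]]
    if (is.matrix(g)) g else matrix(0, nrow(geom$Jinv[[1]]), 3)
  })
}

.lame <- function(E, nu) {
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

#' Assemble the global elastic stiffness matrix
#'
#' @param mesh An `fe_mesh` (order 1 or 2).
#' @param E,nu Per-element Young's modulus (MPa) and Poisson ratio
#'   (scalars recycled).
#' @return Sparse symmetric stiffness matrix (3 nnodes x 3 nnodes), N/mm.
#' @export
assemble_stiffness <- function(mesh, E, nu) {
  ne <- nrow(mesh$elems)
  E <- rep_len(E, ne); nu <- rep_len(nu, ne)
  if (any(E <= 0)) stop("assemble_stiffness: E must be > 0")
  if (any(nu < 0 | nu >= 0.5)) stop("assemble_stiffness: need 0 <= nu < 0.5")
  lm <- .lame(E, nu)
  geom <- .element_geometry(mesh)
  quad <- .tet_quadrature(mesh$order)
  nn <- if (mesh$order == 1L) 4L else 10L
  ncomb <- (3L * nn)^2
  vals <- matrix(0, ne, ncomb)
  for (q in seq_along(quad$w)) {
    dndxi <- if (mesh$order == 1L) .dndxi_tet4 else
      .dndxi_tet10(quad$pts[q, ])
    g <- .grad_at(geom, dndxi)
    w <- quad$w[q] * geom$vol
    col <- 0L
    for (i in seq_len(nn)) for (a in 1:3) for (j in seq_len(nn)) for (b in 1:3) {
      col <- col + 1L
      v <- lm$lambda * g[[i]][, a] * g[[j]][, b] +
        lm$mu * g[[i]][, b] * g[[j]][, a]
      if (a == b)
        v <- v + lm$mu * (g[[i]][, 1] * g[[j]][, 1] +
                          g[[i]][, 2] * g[[j]][, 2] +
                          g[[i]][, 3] * g[[j]][, 3])
      vals[, col] <- vals[, col] + w * v
    }
  }
  rows <- matrix(0L, ne, ncomb); cols <- matrix(0L, ne, ncomb)
  col <- 0L
  for (i in seq_len(nn)) for (a in 1:3) for (j in seq_len(nn)) for (b in 1:3) {
    col <- col + 1L
    rows[, col] <- 3L * (mesh$elems[, i] - 1L) + a
    cols[, col] <- 3L * (mesh$elems[, j] - 1L) + b
  }
  ndof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = as.vector(rows), j = as.vector(cols),
                            x = as.vector(vals), dims = c(ndof, ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Thermal (stress-free strain) load description
#'
#' The control scalar `x = alpha * dT` is a strain (negative = contraction);
#' mode `"isotropic"` applies the eigenstrain x I, mode `"axial"` applies
#' x a (x) a along the given axis only.
#'
#' @param elems Element indices carrying the eigenstrain.
#' @param x Control strain.
#' @param mode `"isotropic"` or `"axial"`.
#' @param axis Unit axis vector (for `"axial"`).
#' @return An object of class `thermal_load`.
#' @export
thermal_load <- function(elems, x, mode = c("isotropic", "axial"),
                         axis = c(0, 0, 1)) {
  mode <- match.arg(mode)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(elems = elems, x = x, mode = mode, axis = axis),
            class = "thermal_load")
}

# Eigenstrain tensor (Voigt: xx, yy, zz, xy, yz, zx with tensor shears)
.eigenstrain <- function(th) {
  a <- th$axis
  if (th$mode == "isotropic") th$x * c(1, 1, 1, 0, 0, 0)
  else th$x * c(a[1]^2, a[2]^2, a[3]^2, a[1] * a[2], a[2] * a[3], a[3] * a[1])
}

#' Equivalent nodal forces of a thermal load
#'
#' @param mesh An `fe_mesh`.
#' @param E,nu Per-element material fields.
#' @param th A [thermal_load()].
#' @return Load vector of length 3 nnodes (N).
#' @export
thermal_load_vector <- function(mesh, E, nu, th) {
  ne <- nrow(mesh$elems)
  E <- rep_len(E, ne)[th$elems]; nu <- rep_len(nu, ne)[th$elems]
  lm <- .lame(E, nu)
  eps <- .eigenstrain(th)
  tr <- eps[1] + eps[2] + eps[3]
  # constant eigenstress per element: sigma* = lambda tr(e*) I + 2 mu e*
  sig <- cbind(lm$lambda * tr + 2 * lm$mu * eps[1],
               lm$lambda * tr + 2 * lm$mu * eps[2],
               lm$lambda * tr + 2 * lm$mu * eps[3],
               2 * lm$mu * eps[4], 2 * lm$mu * eps[5], 2 * lm$mu * eps[6])
  sub <- mesh
  sub$elems <- mesh$elems[th$elems, , drop = FALSE]
  geom <- .element_geometry(sub)
  quad <- .tet_quadrature(mesh$order)
  nn <- if (mesh$order == 1L) 4L else 10L
  ndof <- 3L * nrow(mesh$nodes)
  ii <- integer(0); xx <- numeric(0)
  for (q in seq_along(quad$w)) {
    dndxi <- if (mesh$order == 1L) .dndxi_tet4 else
      .dndxi_tet10(quad$pts[q, ])
    g <- .grad_at(geom, dndxi)
    w <- quad$w[q] * geom$vol
    for (i in seq_len(nn)) {
      gi <- g[[i]]
      fx <- w * (sig[, 1] * gi[, 1] + sig[, 4] * gi[, 2] + sig[, 6] * gi[, 3])
      fy <- w * (sig[, 4] * gi[, 1] + sig[, 2] * gi[, 2] + sig[, 5] * gi[, 3])
      fz <- w * (sig[, 6] * gi[, 1] + sig[, 5] * gi[, 2] + sig[, 3] * gi[, 3])
      dof <- 3L * (sub$elems[, i] - 1L)
      ii <- c(ii, dof + 1L, dof + 2L, dof + 3L)
      xx <- c(xx, fx, fy, fz)
    }
  }
  # accumulate duplicated node contributions
  as.numeric(Matrix::sparseMatrix(i = ii, j = rep(1L, length(ii)), x = xx,
                                  dims = c(ndof, 1L)))
}

#' Grounded boundary spring set
#'
#' Total normal stiffness is distributed evenly over the node set; the
#' stiffness transverse to the normal is a fraction of the normal value.
#'
#' @param nset Node indices.
#' @param normal Unit normal direction of the spring set.
#' @param k_total Total normal stiffness (N/mm) summed over the set.
#' @param tangential_fraction Transverse-to-normal stiffness ratio.
#' @param mode `"linear"` or `"compression_only"` (normal direction engages
#'   only while the node moves against the normal; handled in the solver's
#'   active-set loop, transverse term absent).
#' @return An object of class `spring_set`.
#' @export
spring_set <- function(nset, normal, k_total, tangential_fraction = 0.10,
                       mode = c("linear", "compression_only")) {
  mode <- match.arg(mode)
  if (k_total < 0) stop("spring_set: k_total must be >= 0")
  normal <- normal / sqrt(sum(normal^2))
  structure(list(nset = nset, normal = normal, k_total = k_total,
                 tangential_fraction = tangential_fraction, mode = mode),
            class = "spring_set")
}

# Sparse stiffness of a list of spring sets; compression-only sets may be
# restricted to an active subset of their nodes.
spring_matrix <- function(ndof, springs, active = NULL) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (s in seq_along(springs)) {
    sp <- springs[[s]]
    nset <- sp$nset
    if (sp$mode == "compression_only" && !is.null(active))
      nset <- nset[active[[s]]]
    if (length(nset) == 0 || sp$k_total == 0) next
    kn <- sp$k_total / length(sp$nset)
    n <- sp$normal
    kt <- if (sp$mode == "linear") sp$tangential_fraction * kn else 0
    kmat <- kn * outer(n, n) + kt * (diag(3) - outer(n, n))
    for (a in 1:3) for (b in 1:3) {
      if (abs(kmat[a, b]) < .Machine$double.eps) next
      ii <- c(ii, 3L * (nset - 1L) + a)
      jj <- c(jj, 3L * (nset - 1L) + b)
      xx <- c(xx, rep(kmat[a, b], length(nset)))
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
}

#' Recover element stresses at centroids
#'
#' @param mesh An `fe_mesh`.
#' @param E,nu Per-element material fields.
#' @param u Displacement matrix (nnodes x 3, mm).
#' @param thermals List of [thermal_load()] whose eigenstrains are
#'   subtracted before applying the material law.
#' @return Matrix ne x 6 of stresses (MPa), Voigt order
#'   xx, yy, zz, xy, yz, zx.
#' @export
recover_stress <- function(mesh, E, nu, u, thermals = list()) {
  ne <- nrow(mesh$elems)
  E <- rep_len(E, ne); nu <- rep_len(nu, ne)
  lm <- .lame(E, nu)
  geom <- .element_geometry(mesh)
  dndxi <- if (mesh$order == 1L) .dndxi_tet4 else
    .dndxi_tet10(rep(0.25, 4))
  g <- .grad_at(geom, dndxi)
  nn <- if (mesh$order == 1L) 4L else 10L
  H <- matrix(0, ne, 9)  # displacement gradient du_a/dx_b, columns (a-1)*3+b
  for (i in seq_len(nn)) {
    ui <- u[mesh$elems[, i], , drop = FALSE]
    for (a in 1:3) for (b in 1:3)
      H[, (a - 1) * 3 + b] <- H[, (a - 1) * 3 + b] + ui[, a] * g[[i]][, b]
  }
  eps <- cbind(H[, 1], H[, 5], H[, 9],
               (H[, 2] + H[, 4]) / 2, (H[, 6] + H[, 8]) / 2,
               (H[, 3] + H[, 7]) / 2)
  for (th in thermals) {
    e0 <- .eigenstrain(th)
    eps[th$elems, ] <- sweep(eps[th$elems, , drop = FALSE], 2, e0)
  }
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  cbind(lm$lambda * tr + 2 * lm$mu * eps[, 1],
        lm$lambda * tr + 2 * lm$mu * eps[, 2],
        lm$lambda * tr + 2 * lm$mu * eps[, 3],
        2 * lm$mu * eps[, 4], 2 * lm$mu * eps[, 5], 2 * lm$mu * eps[, 6])
}

#' Von Mises equivalent stress
#' @param stress Stress matrix from [recover_stress()] (Voigt columns
#'   xx, yy, zz, xy, yz, zx).
#' @return Numeric vector of von Mises stresses (MPa).
#' @export
von_mises <- function(stress) {
  sqrt(0.5 * ((stress[, 1] - stress[, 2])^2 +
                (stress[, 2] - stress[, 3])^2 +
                (stress[, 3] - stress[, 1])^2) +
         3 * (stress[, 4]^2 + stress[, 5]^2 + stress[, 6]^2))
}
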
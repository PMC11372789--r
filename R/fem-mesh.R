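## Structured tetrahedral mesh construction on a regular grid.
##
## Parts (implant plate, bone block, screw segments) are built as unions of
## axis-aligned voxel boxes on a shared grid of spacing h, each voxel split
## into six tetrahedra by the Kuhn subdivision.  The Kuhn rule picks every
## face diagonal from the face's minimum to maximum corner, so triangulations
## of neighbouring voxels agree and meshes of different parts built on the
## same grid have coincident (conforming) surface nodes wherever the parts
## touch.  Parts never share node numbers: interfaces are explicit pairs of
## coincident nodes, which is exactly what tie/contact constraints need.

# Six Kuhn tetrahedra of the unit voxel, as 0/1 corner offsets.
# Row blocks of 4 rows = one tet; orientation fixed to positive volume.
.kuhn_offsets <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  sgn <- function(p) {
    s <- 1
    for (i in 1:2) for (j in (i + 1):3) if (p[i] > p[j]) s <- -s
    s
  }
  out <- vector("list", 6)
  for (t in seq_along(perms)) {
    p <- perms[[t]]
    v0 <- c(0, 0, 0)
    v1 <- v0; v1[p[1]] <- 1
    v2 <- v1; v2[p[2]] <- 1
    v3 <- c(1, 1, 1)
    tet <- rbind(v0, v1, v2, v3)
    if (sgn(p) < 0) tet <- tet[c(1, 2, 4, 3), ]
    out[[t]] <- tet
  }
  out
})

#' Voxel cells covering an axis-aligned box
#'
#' @param box Numeric length 6: `c(x0, x1, y0, y1, z0, z1)` in mm; bounds
#'   must be (near) multiples of `h`.
#' @param h Grid spacing (mm).
#' @return Integer matrix of 0-based voxel indices (columns i, j, k).
#' @export
cells_from_box <- function(box, h) {
  idx <- round(box / h)
  if (max(abs(box / h - idx)) > 1e-9)
    stop("cells_from_box: box bounds must be multiples of h")
  if (idx[2] <= idx[1] || idx[4] <= idx[3] || idx[6] <= idx[5])
    stop("cells_from_box: empty box")
  g <- expand.grid(i = idx[1]:(idx[2] - 1),
                   j = idx[3]:(idx[4] - 1),
                   k = idx[5]:(idx[6] - 1))
  as.matrix(g)
}

# Set difference of voxel cell matrices.
cells_diff <- function(cells, minus) {
  if (is.null(minus) || nrow(minus) == 0) return(cells)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  cells[!(key(cells) %in% key(minus)), , drop = FALSE]
}

# Union (deduplicated) of voxel cell matrices.
cells_union <- function(...) {
  m <- do.call(rbind, list(...))
  key <- paste(m[, 1], m[, 2], m[, 3])
  m[!duplicated(key), , drop = FALSE]
}

#' Build one meshed part from labelled voxel cells
#'
#' @param cells Integer matrix of 0-based voxel indices.
#' @param region Character vector of region labels, one per cell (recycled
#'   if length 1).
#' @param h Grid spacing (mm).
#' @return List with `nodes` (mm coordinates), `elems` (6 per voxel, 4-node
#'   tets, positive volume) and `region` (per element).
#' @export
grid_part <- function(cells, region, h) {
  nc <- nrow(cells)
  if (nc == 0) stop("grid_part: no cells")
  region <- rep_len(region, nc)
  # 8 corner node indices per cell, keyed on the global integer grid
  corners <- expand.grid(di = 0:1, dj = 0:1, dk = 0:1)
  allk <- matrix(0L, nc * 8, 3)
  for (c8 in 1:8) {
    rows <- ((c8 - 1) * nc + 1):(c8 * nc)
    allk[rows, ] <- cbind(cells[, 1] + corners$di[c8],
                          cells[, 2] + corners$dj[c8],
                          cells[, 3] + corners$dk[c8])
  }
  key <- paste(allk[, 1], allk[, 2], allk[, 3])
  ukey <- unique(key)
  id <- match(key, ukey)
  first <- match(ukey, key)
  nodes <- allk[first, , drop = FALSE] * h
  # corner ids per cell: nc x 8, local corner c8 = (di,dj,dk)
  cid <- matrix(id, nc, 8)
  corner_col <- function(off) 1 + off[1] + 2 * off[2] + 4 * off[3]
  elems <- matrix(0L, nc * 6, 4)
  for (t in 1:6) {
    off <- .kuhn_offsets[[t]]
    for (v in 1:4) {
      elems[((t - 1) * nc + 1):(t * nc), v] <- cid[, corner_col(off[v, ])]
    }
  }
  # interleave so elements of one voxel are adjacent (cosmetic)
  ord <- order(rep(seq_len(nc), times = 6))
  elems <- elems[ord, , drop = FALSE]
  list(nodes = nodes, elems = elems, region = rep(region, each = 6))
}

#' Combine parts into one finite-element mesh
#'
#' Node numbering is concatenated across parts; parts never share nodes.
#'
#' @param parts Named list of parts from [grid_part()].
#' @param h Grid spacing (mm), stored for station/slab defaults.
#' @return An object of class `fe_mesh` with fields `nodes`, `elems`,
#'   `order` (1 = 4-node tets), `region`, `part` (part label per node),
#'   `nsets` (named node sets), `pairs` (interface pairs), `h`.
#' @export
mesh_from_parts <- function(parts, h) {
  stopifnot(length(names(parts)) == length(parts))
  offs <- 0L
  nodes <- NULL; elems <- NULL; region <- character(); partlab <- character()
  offsets <- integer(length(parts)); names(offsets) <- names(parts)
  for (pn in names(parts)) {
    p <- parts[[pn]]
    offsets[pn] <- offs
    nodes <- rbind(nodes, p$nodes)
    elems <- rbind(elems, p$elems + offs)
    region <- c(region, p$region)
    partlab <- c(partlab, rep(pn, nrow(p$nodes)))
    offs <- offs + nrow(p$nodes)
  }
  structure(list(nodes = nodes, elems = elems, order = 1L,
                 region = region, part = partlab,
                 nsets = list(), pairs = list(),
                 part_offsets = offsets, h = h),
            class = "fe_mesh")
}

#' Select node indices of a part inside a coordinate box
#'
#' @param mesh An `fe_mesh`.
#' @param part Part label (or `NULL` for all parts).
#' @param box `c(x0, x1, y0, y1, z0, z1)` in mm; a thin box selects a face.
#' @param tol Coordinate tolerance (mm).
#' @return Integer node indices, ordered by (z, y, x) coordinate.
#' @export
select_nodes <- function(mesh, part = NULL, box, tol = 1e-7) {
  sel <- mesh$nodes[, 1] >= box[1] - tol & mesh$nodes[, 1] <= box[2] + tol &
    mesh$nodes[, 2] >= box[3] - tol & mesh$nodes[, 2] <= box[4] + tol &
    mesh$nodes[, 3] >= box[5] - tol & mesh$nodes[, 3] <= box[6] + tol
  if (!is.null(part)) sel <- sel & mesh$part %in% part
  idx <- which(sel)
  idx[order(mesh$nodes[idx, 3], mesh$nodes[idx, 2], mesh$nodes[idx, 1])]
}

# Match two coincident node sets by coordinates; returns b reordered to a.
match_coincident <- function(nodes, a_idx, b_idx, tol = 1e-9) {
  if (length(a_idx) != length(b_idx))
    stop("match_coincident: sets differ in size (", length(a_idx), " vs ",
         length(b_idx), ")")
  keyf <- function(i) paste(round(nodes[i, 1] / tol), round(nodes[i, 2] / tol),
                            round(nodes[i, 3] / tol))
  m <- match(keyf(a_idx), keyf(b_idx))
  if (any(is.na(m))) stop("match_coincident: sets are not coincident")
  b_idx[m]
}

#' Register an interface pair of coincident nodes
#'
#' @param mesh An `fe_mesh`.
#' @param name Pair name.
#' @param a_idx,b_idx Coincident node index sets (matched internally).
#' @param normal Unit normal pointing from side b towards side a (the
#'   direction in which side a separates).
#' @param type `"tie"` (all components bonded), `"contact"` (hard
#'   frictionless), `"section"` (bonded laterally, relative axial length
#'   controlled by a scalar), or `"slide"` (bonded transverse to the axis,
#'   free axially: a snug screw shank in its clearance hole).
#' @param axis For `"section"`/`"slide"`: screw axis unit vector.
#' @return The mesh with the pair appended.
#' @export
add_pair <- function(mesh, name, a_idx, b_idx, normal = c(0, 0, 1),
                     type = c("tie", "contact", "section", "slide"),
                     axis = NULL) {
  type <- match.arg(type)
  b_idx <- match_coincident(mesh$nodes, a_idx, b_idx)
  mesh$pairs[[name]] <- list(name = name, a = a_idx, b = b_idx,
                             normal = normal, type = type, axis = axis)
  mesh
}

#' Maximum coordinate mismatch over all interface pairs
#' @param mesh An `fe_mesh`.
#' @return Largest distance (mm) between paired nodes; 0 for conforming.
#' @export
pair_mismatch <- function(mesh) {
  if (length(mesh$pairs) == 0) return(0)
  max(vapply(mesh$pairs, function(p) {
    d <- mesh$nodes[p$a, , drop = FALSE] - mesh$nodes[p$b, , drop = FALSE]
    if (length(d) == 0) 0 else max(abs(d))
  }, numeric(1)))
}

#' Signed volumes of the (corner) tetrahedra
#' @param mesh An `fe_mesh`.
#' @return Numeric vector of element volumes (mm^3).
#' @export
tet_volumes <- function(mesh) {
  nd <- mesh$nodes; el <- mesh$elems
  a <- nd[el[, 2], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  b <- nd[el[, 3], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  c3 <- nd[el[, 4], , drop = FALSE] - nd[el[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
     a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
     a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Consistent nodal weights for a uniform traction on a planar face
#'
#' For every element face whose nodes all belong to `nset`, distributes the
#' face area onto its nodes with the element order's consistent-load rule
#' (linear triangle: A/3 per vertex; quadratic triangle: A/3 per mid-edge
#' node, zero at corners).  Used to apply uniform tractions, e.g. the
#' equal-and-opposite force pair on the screw shank end faces.
#'
#' @param mesh An `fe_mesh`.
#' @param nset Node indices of one planar face of a part.
#' @return Named numeric of weights summing to 1 (names = node indices).
#' @export
surface_weights <- function(mesh, nset) {
  el <- mesh$elems
  corners <- el[, 1:4, drop = FALSE]
  inset <- matrix(corners %in% nset, nrow(corners), 4)
  rows <- which(rowSums(inset) == 3)
  if (length(rows) == 0) stop("surface_weights: no element face on the set")
  w <- stats::setNames(numeric(length(nset)), nset)
  # mid-edge lookup for quadratic tets: columns 5..10 are midpoints of
  # edges (1,2),(2,3),(3,1),(1,4),(2,4),(3,4)
  edge <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  for (r in rows) {
    vloc <- which(inset[r, ])
    tri <- corners[r, vloc]
    a <- mesh$nodes[tri[2], ] - mesh$nodes[tri[1], ]
    b <- mesh$nodes[tri[3], ] - mesh$nodes[tri[1], ]
    A <- 0.5 * sqrt(sum(c(a[2] * b[3] - a[3] * b[2],
                          a[3] * b[1] - a[1] * b[3],
                          a[1] * b[2] - a[2] * b[1])^2))
    if (mesh$order == 1L) {
      w[as.character(tri)] <- w[as.character(tri)] + A / 3
    } else {
      onface <- apply(edge, 1, function(e) all(e %in% vloc))
      mids <- el[r, 4L + which(onface)]
      w[as.character(mids)] <- w[as.character(mids)] + A / 3
    }
  }
  w / sum(w)
}

#' Convert a 4-node tet mesh to 10-node quadratic tets
#'
#' Mid-edge nodes are inserted per part (edges of different parts stay
#' duplicated), node sets and interface pairs are extended with mid-edge
#' nodes whose both end nodes belong to the set, and pair sides are
#' re-matched by coordinates so conformity is preserved.
#'
#' @param mesh An order-1 `fe_mesh`.
#' @return An order-2 `fe_mesh` (element columns 5-10 are the midpoints of
#'   edges 1-2, 2-3, 3-1, 1-4, 2-4, 3-4).
#' @export
mesh_to_tet10 <- function(mesh) {
  if (mesh$order != 1L) stop("mesh_to_tet10: mesh is already quadratic")
  el <- mesh$elems
  edges <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)],
                 el[, c(1, 4)], el[, c(2, 4)], el[, c(3, 4)])
  e1 <- pmin(edges[, 1], edges[, 2]); e2 <- pmax(edges[, 1], edges[, 2])
  key <- paste(e1, e2)
  ukey <- unique(key)
  mid_id <- match(key, ukey) + nrow(mesh$nodes)
  first <- match(ukey, key)
  pa <- e1[first]; pb <- e2[first]
  mid_nodes <- (mesh$nodes[pa, , drop = FALSE] +
                  mesh$nodes[pb, , drop = FALSE]) / 2
  ne <- nrow(el)
  elems10 <- cbind(el, matrix(mid_id, ne, 6))
  out <- mesh
  out$nodes <- rbind(mesh$nodes, mid_nodes)
  out$elems <- elems10
  out$order <- 2L
  out$part <- c(mesh$part, mesh$part[pa])
  out$edge_parents <- cbind(pa, pb)   # parents of nodes beyond the corners
  # extend node sets
  extend <- function(idx) {
    inset <- (pa %in% idx) & (pb %in% idx)
    c(idx, (nrow(mesh$nodes) + seq_along(pa))[inset])
  }
  out$nsets <- lapply(mesh$nsets, extend)
  out$pairs <- lapply(mesh$pairs, function(p) {
    a2 <- extend(p$a); b2 <- extend(p$b)
    p$a <- a2
    p$b <- match_coincident(out$nodes, a2, b2)
    p
  })
  out
}
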
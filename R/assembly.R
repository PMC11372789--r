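## Synthetic screw-implant-bone assembly generator.
##
## Geometry is blocky and extruded on a regular grid (spacing h): an implant
## plate on top of a layered bone block, clamped by 1-9 screws.  Each screw
## is head + shank + cylindrical core (threads are not meshed; thread
## mechanics live in the analytic pullout/torque chain).  The core is split
## at a grid plane inside the free zone so every mesh carries a pretension
## section; non-bolt-load methods simply bond the cut.  All interfaces are
## conforming node pairs by construction.  Axes: z is the screw axis, bone
## occupies z < 0, the plate z in [0, tp], heads above the plate.

#' Assembly recipe
#'
#' Describes a synthetic assembly: plate and bone dimensions, per-screw
#' geometry, materials, boundary springs, load cases and mesh density.
#' All lengths in mm and multiples of `h`; screw cross-sections are squares
#' of odd width so screws centre on the grid.
#'
#' @param n_screws Number of screws (1-9).
#' @param centers Matrix/list of screw centres `(x, y)`; default lays the
#'   screws out along x with 8 mm spacing.
#' @param plate `c(Lx, Ly, thickness)` of the implant plate.
#' @param bone `c(depth, cortical_top, cortical_bottom)`: block depth and
#'   cortical layer thicknesses (0 = none).
#' @param screw Named list of per-screw FE geometry defaults: `core_w`,
#'   `shank_w`, `head_w` (odd widths, mm), `head_h`, `core_len`, `free_len`
#'   (>= 2 h), `partial_len`.  Entries may be vectors (one per screw).
#' @param spec A [screw_spec()] giving the analytic thread geometry shared
#'   by the screws (ids are suffixed per screw).
#' @param materials Named list with `E_implant`, `nu_implant`,
#'   `E_cortical`, `nu_cortical`, `E_trabecular` (used when homogeneous),
#'   `nu_trabecular`.
#' @param bone_field `"homogeneous"` or `"sampled"`: trabecular modulus
#'   source; sampled fields pass a smooth random density field through the
#'   density-modulus power law.
#' @param field Named list for sampled fields: `mean_E` (MPa), `cv`,
#'   `E_min`, `E_max`, `seed`.
#' @param springs Named list: `k_base` (N/mm, bottom face, sacroiliac-like),
#'   `k_side` (N/mm, x = 0 face, pubic-like), `tangential_fraction`.
#' @param loads Named list of load cases `list(point = c(x, y, z),
#'   F = c(Fx, Fy, Fz))` applied at the nearest plate node.
#' @param h Grid spacing (mm).
#' @param order Element order (1 = 4-node, 2 = 10-node tets).
#' @return An object of class `assembly_recipe`.
#' @export
assembly_recipe <- function(n_screws = 1,
                            centers = NULL,
                            plate = c(13, 13, 3),
                            bone = c(26, 2, 0),
                            screw = list(),
                            spec = screw_spec(id = "screw"),
                            materials = list(),
                            bone_field = c("homogeneous", "sampled"),
                            field = list(),
                            springs = list(),
                            loads = NULL,
                            h = 1, order = 1L) {
  bone_field <- match.arg(bone_field)
  sdef <- list(core_w = 3, shank_w = 5, head_w = 7, head_h = 2,
               core_len = 22, free_len = 3, partial_len = 2)
  screw <- utils::modifyList(sdef, screw)
  mdef <- list(E_implant = 115000, nu_implant = 0.35,
               E_cortical = 8000, nu_cortical = 0.3,
               E_trabecular = 661.4, nu_trabecular = 0.3)
  materials <- utils::modifyList(mdef, materials)
  fdef <- list(mean_E = 661.4, cv = 0.25, E_min = 100, E_max = 6704.7,
               seed = 42)
  field <- utils::modifyList(fdef, field)
  spdef <- list(k_base = 103090, k_side = 4240, tangential_fraction = 0.10)
  springs <- utils::modifyList(spdef, springs)
  if (is.null(centers)) {
    centers <- cbind(plate[1] / 2 + (seq_len(n_screws) -
                                       (n_screws + 1) / 2) * 8,
                     plate[2] / 2)
  }
  centers <- matrix(unlist(centers), ncol = 2)
  if (nrow(centers) != n_screws) stop("assembly_recipe: need one centre per screw")
  per <- function(x) rep_len(x, n_screws)
  screw <- lapply(screw, per)
  if (is.null(loads)) {
    # gait-like loads are a few times the per-screw preload, as hip contact
    # forces are; the liftoff case presses the plate onto the bone hard
    # enough to unseat the screw heads
    gait_scale <- 750 * n_screws
    cmid <- c(plate[1] / 2, plate[2] / 2)
    loads <- list(
      gait1 = list(point = c(cmid[1] - 2, cmid[2] - 2, plate[3]),
                   F = c(0.2, 0.1, 0.7) * gait_scale),
      gait2 = list(point = c(cmid[1] + 2, cmid[2] + 1, plate[3]),
                   F = c(-0.35, 0.2, 1.1) * gait_scale),
      liftoff = list(point = c(cmid[1], cmid[2], plate[3]),
                     F = c(0, 0, -750) * n_screws))
  }
  r <- structure(list(n_screws = n_screws, centers = centers, plate = plate,
                      bone = bone, screw = screw, spec = spec,
                      materials = materials, bone_field = bone_field,
                      field = field, springs = springs, loads = loads,
                      h = h, order = as.integer(order)),
                 class = "assembly_recipe")
  validate_recipe(r)
  r
}

validate_recipe <- function(r) {
  h <- r$h
  mult <- function(x) all(abs(x / h - round(x / h)) < 1e-9)
  if (!mult(c(r$plate, r$bone, unlist(r$screw))))
    stop("assembly_recipe: all dimensions must be multiples of h")
  for (k in seq_len(r$n_screws)) {
    cw <- r$screw$core_w[k]; sw <- r$screw$shank_w[k]; hw <- r$screw$head_w[k]
    if (!(cw < sw && sw < hw)) stop("assembly_recipe: need core_w < shank_w < head_w")
    if (!mult(c(r$centers[k, 1] + c(cw, sw, hw) / 2,
                r$centers[k, 2] + c(cw, sw, hw) / 2)))
      stop("assembly_recipe: screw ", k, " cross-sections do not land on ",
           "grid planes (centre +/- width/2 must be multiples of h)")
    if (r$screw$free_len[k] < 2 * h)
      stop("assembly_recipe: free_len must be at least 2 h (cut plane must ",
           "fall on an interior grid plane of the free zone)")
    if (r$screw$free_len[k] + r$screw$partial_len[k] >= r$screw$core_len[k])
      stop("assembly_recipe: free + partial zones must leave a fully embedded zone")
    if (r$screw$core_len[k] > r$bone[1] - h)
      stop("assembly_recipe: screw ", k, " longer than the bone block")
    cx <- r$centers[k, 1]; cy <- r$centers[k, 2]
    if (cx - hw / 2 < 0 || cx + hw / 2 > r$plate[1] ||
        cy - hw / 2 < 0 || cy + hw / 2 > r$plate[2])
      stop("assembly_recipe: screw ", k, " head outside the plate footprint")
  }
  if (r$n_screws > 1) {
    d <- as.matrix(stats::dist(r$centers))
    diag(d) <- Inf
    if (min(d) < max(r$screw$head_w))
      stop("assembly_recipe: overlapping screws")
  }
  invisible(r)
}

# Smooth random trabecular modulus field: low-frequency cosine field ->
# apparent density -> modulus power law, rescaled to the target mean and
# clipped to the physiological range.
sample_bone_field_at <- function(xyz, field, calib = ct_calibration()) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(field$seed)
  nmodes <- 8
  f <- numeric(nrow(xyz))
  for (j in seq_len(nmodes)) {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    wl <- stats::runif(1, 6, 16)            # wavelength, mm
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::rnorm(1)
    f <- f + amp * cos(2 * pi / wl * (xyz %*% dir) + ph)
  }
  f <- as.numeric(f)
  if (stats::sd(f) > 0) f <- (f - mean(f)) / stats::sd(f)
  rho_mean <- (field$mean_E / calib$modulus_coeff)^(1 / calib$modulus_exp)
  rho <- pmax(rho_mean * (1 + field$cv * f), 0.05)
  E <- density_to_modulus(rho, calib)
  E <- E * field$mean_E / mean(E)
  pmin(pmax(E, field$E_min), field$E_max)
}

#' Build a synthetic assembly from a recipe
#'
#' Meshes all parts on the shared grid, registers interface pairs (bonded
#' screw-bone zones, head-plate and plate-bone contact surfaces, the
#' pretension section in each free zone), attaches boundary springs,
#' resolves the load-case application nodes and assembles the FE model.
#'
#' @param recipe An [assembly_recipe()].
#' @return An object of class `assembly`: fields `mesh`, `model`
#'   ([fe_model()]), `E`, `nu`, `screws` (per-screw registry), `springs`,
#'   `loads` (resolved to node ids), `recipe`.
#' @export
build_assembly <- function(recipe) {
  r <- validate_recipe(recipe)
  h <- r$h
  Lx <- r$plate[1]; Ly <- r$plate[2]; tp <- r$plate[3]
  depth <- r$bone[1]; tc_top <- r$bone[2]; tc_bot <- r$bone[3]

  parts <- list()
  # ---- bone block with per-screw clearance + core holes
  bone_cells <- cells_from_box(c(0, Lx, 0, Ly, -depth, 0), h)
  for (k in seq_len(r$n_screws)) {
    cx <- r$centers[k, 1]; cy <- r$centers[k, 2]
    cw2 <- r$screw$core_w[k] / 2; sw2 <- r$screw$shank_w[k] / 2
    fl <- r$screw$free_len[k]; cl <- r$screw$core_len[k]
    bone_cells <- cells_diff(bone_cells,
      cells_from_box(c(cx - sw2, cx + sw2, cy - sw2, cy + sw2, -fl, 0), h))
    bone_cells <- cells_diff(bone_cells,
      cells_from_box(c(cx - cw2, cx + cw2, cy - cw2, cy + cw2, -cl, -fl), h))
  }
  zc <- (bone_cells[, 3] + 0.5) * h
  bone_region <- ifelse(zc > -tc_top, "bone_cortical",
                        ifelse(zc < -depth + tc_bot, "bone_cortical",
                               "bone_trabecular"))
  parts$bone <- grid_part(bone_cells, bone_region, h)

  # ---- implant plate with screw holes
  plate_cells <- cells_from_box(c(0, Lx, 0, Ly, 0, tp), h)
  for (k in seq_len(r$n_screws)) {
    cx <- r$centers[k, 1]; cy <- r$centers[k, 2]
    sw2 <- r$screw$shank_w[k] / 2
    plate_cells <- cells_diff(plate_cells,
      cells_from_box(c(cx - sw2, cx + sw2, cy - sw2, cy + sw2, 0, tp), h))
  }
  parts$plate <- grid_part(plate_cells, "implant", h)

  # ---- per-screw parts
  cuts <- numeric(r$n_screws)
  for (k in seq_len(r$n_screws)) {
    cx <- r$centers[k, 1]; cy <- r$centers[k, 2]
    cw2 <- r$screw$core_w[k] / 2; sw2 <- r$screw$shank_w[k] / 2
    hw2 <- r$screw$head_w[k] / 2
    fl <- r$screw$free_len[k]; cl <- r$screw$core_len[k]
    hh <- r$screw$head_h[k]
    cut <- h * max(1, floor(fl / (2 * h)))   # grid plane inside free zone
    cuts[k] <- cut
    hs <- rbind(
      cbind(cells_from_box(c(cx - hw2, cx + hw2, cy - hw2, cy + hw2,
                             tp, tp + hh), h), region = 1L),
      cbind(cells_from_box(c(cx - sw2, cx + sw2, cy - sw2, cy + sw2,
                             0, tp), h), region = 2L))
    parts[[paste0("screw_hs_", k)]] <-
      grid_part(hs[, 1:3, drop = FALSE],
                c(paste0("screw_head_", k),
                  paste0("screw_shank_", k))[hs[, 4]], h)
    parts[[paste0("core_upper_", k)]] <-
      grid_part(cells_from_box(c(cx - cw2, cx + cw2, cy - cw2, cy + cw2,
                                 -cut, 0), h),
                paste0("screw_core_", k), h)
    parts[[paste0("core_lower_", k)]] <-
      grid_part(cells_from_box(c(cx - cw2, cx + cw2, cy - cw2, cy + cw2,
                                 -cl, -cut), h),
                paste0("screw_core_", k), h)
  }

  mesh <- mesh_from_parts(parts, h)

  # ---- interface pairs and node sets
  eps <- 1e-7
  box_xy <- function(cx, cy, w2, zlo, zhi) c(cx - w2, cx + w2, cy - w2,
                                             cy + w2, zlo, zhi)
  screws <- list()
  for (k in seq_len(r$n_screws)) {
    cx <- r$centers[k, 1]; cy <- r$centers[k, 2]
    cw2 <- r$screw$core_w[k] / 2; sw2 <- r$screw$shank_w[k] / 2
    hw2 <- r$screw$head_w[k] / 2
    fl <- r$screw$free_len[k]; pl <- r$screw$partial_len[k]
    cl <- r$screw$core_len[k]; cut <- cuts[k]
    hsp <- paste0("screw_hs_", k)
    cup <- paste0("core_upper_", k); clo <- paste0("core_lower_", k)

    # shank-core junction tie (core_upper top face is the slave side)
    a <- select_nodes(mesh, hsp, box_xy(cx, cy, cw2, 0, 0))
    b <- select_nodes(mesh, cup, box_xy(cx, cy, cw2, 0, 0))
    mesh <- add_pair(mesh, paste0("junction_", k), a, b, c(0, 0, 1), "tie")

    # pretension section at the cut plane (core_lower top is the slave)
    a <- select_nodes(mesh, cup, box_xy(cx, cy, cw2, -cut, -cut))
    b <- select_nodes(mesh, clo, box_xy(cx, cy, cw2, -cut, -cut))
    mesh <- add_pair(mesh, paste0("section_", k), a, b, c(0, 0, 1),
                     "section", axis = c(0, 0, 1))

    # embedded-zone ties: partial zone bonds the two x-normal faces only,
    # full zone bonds all four lateral faces and the tip
    sel_faces <- function(part, xfaces, yfaces, zlo, zhi, tip = FALSE) {
      idx <- integer(0)
      if (xfaces) {
        bx <- select_nodes(mesh, part, c(cx - cw2, cx - cw2, cy - cw2,
                                         cy + cw2, zlo, zhi))
        bx2 <- select_nodes(mesh, part, c(cx + cw2, cx + cw2, cy - cw2,
                                          cy + cw2, zlo, zhi))
        idx <- c(idx, bx, bx2)
      }
      if (yfaces) {
        by <- select_nodes(mesh, part, c(cx - cw2, cx + cw2, cy - cw2,
                                         cy - cw2, zlo, zhi))
        by2 <- select_nodes(mesh, part, c(cx - cw2, cx + cw2, cy + cw2,
                                          cy + cw2, zlo, zhi))
        idx <- c(idx, by, by2)
      }
      if (tip) idx <- c(idx, select_nodes(mesh, part,
                                          box_xy(cx, cy, cw2, -cl, -cl)))
      sort(unique(idx))
    }
    core_part_sel <- function(...) sel_faces(clo, ...)
    bone_sel <- function(...) sel_faces("bone", ...)
    b <- c(core_part_sel(TRUE, FALSE, -fl - pl, -fl),
           core_part_sel(TRUE, TRUE, -cl, -fl - pl - eps, tip = TRUE))
    a <- c(bone_sel(TRUE, FALSE, -fl - pl, -fl),
           bone_sel(TRUE, TRUE, -cl, -fl - pl - eps, tip = TRUE))
    b <- sort(unique(b)); a <- sort(unique(a))
    mesh <- add_pair(mesh, paste0("embed_", k), a, b, c(1, 0, 0), "tie")

    # head-plate bearing annulus (head side separates upward)
    ann <- function(part) {
      all7 <- select_nodes(mesh, part, box_xy(cx, cy, hw2, tp, tp))
      inner <- select_nodes(mesh, part,
                            c(cx - sw2 + eps, cx + sw2 - eps,
                              cy - sw2 + eps, cy + sw2 - eps, tp, tp))
      setdiff(all7, inner)
    }
    mesh <- add_pair(mesh, paste0("head_", k), ann(hsp), ann("plate"),
                     c(0, 0, 1), "contact")

    # snug shank fit in the plate bore: transverse components bonded, axial
    # sliding free; grounds the plate laterally through the screws, as the
    # shank bearing against its hole does in the physical joint.  The top
    # ring (z = tp) stays out so its nodes remain free for the head tie.
    bore_sel <- function(part) sort(unique(c(
      select_nodes(mesh, part, c(cx - sw2, cx - sw2, cy - sw2, cy + sw2,
                                 0, tp - r$h)),
      select_nodes(mesh, part, c(cx + sw2, cx + sw2, cy - sw2, cy + sw2,
                                 0, tp - r$h)),
      select_nodes(mesh, part, c(cx - sw2, cx + sw2, cy - sw2, cy - sw2,
                                 0, tp - r$h)),
      select_nodes(mesh, part, c(cx - sw2, cx + sw2, cy + sw2, cy + sw2,
                                 0, tp - r$h)))))
    mesh <- add_pair(mesh, paste0("bore_", k), bore_sel(hsp),
                     bore_sel("plate"), c(1, 0, 0), "slide",
                     axis = c(0, 0, 1))

    # shank end faces for the force-pair rigid axial couplings
    mesh$nsets[[paste0("shank_top_", k)]] <-
      select_nodes(mesh, hsp, box_xy(cx, cy, sw2, tp, tp))
    mesh$nsets[[paste0("shank_bot_", k)]] <-
      select_nodes(mesh, hsp, box_xy(cx, cy, sw2, 0, 0))

    screws[[k]] <- list(
      id = paste0(r$spec$id, "_", k), k = k, center = c(cx, cy),
      axis = c(0, 0, -1), junction_z = 0,
      core_len = cl, free_len = fl, partial_len = pl, cut = cut,
      core_area = r$screw$core_w[k]^2,
      core_regions = paste0("screw_core_", k),
      shank_region = paste0("screw_shank_", k),
      section = paste0("section_", k), junction = paste0("junction_", k),
      embed = paste0("embed_", k), head = paste0("head_", k),
      bore = paste0("bore_", k),
      shank_top = paste0("shank_top_", k),
      shank_bot = paste0("shank_bot_", k),
      spec = within_spec(r$spec, k, cl, fl, pl))
  }

  # plate-bone seating contact (plate separates upward)
  a <- select_nodes(mesh, "plate", c(0, Lx, 0, Ly, 0, 0))
  b <- select_nodes(mesh, "bone", c(0, Lx, 0, Ly, 0, 0))
  keep <- match_keep(mesh, a, b)
  mesh <- add_pair(mesh, "plate_bone", keep$a, keep$b, c(0, 0, 1), "contact")

  mesh$nsets$bone_bottom <- select_nodes(mesh, "bone",
                                         c(0, Lx, 0, Ly, -depth, -depth))
  mesh$nsets$bone_side <- select_nodes(mesh, "bone",
                                       c(0, 0, 0, Ly, -depth, 0))

  if (r$order == 2L) mesh <- mesh_to_tet10(mesh)

  # consistent nodal weights of the shank end faces (force-pair tractions)
  for (k in seq_len(r$n_screws)) {
    screws[[k]]$w_top <- surface_weights(mesh, mesh$nsets[[screws[[k]]$shank_top]])
    screws[[k]]$w_bot <- surface_weights(mesh, mesh$nsets[[screws[[k]]$shank_bot]])
  }

  # ---- materials
  E <- numeric(nrow(mesh$elems)); nu <- numeric(nrow(mesh$elems))
  m <- r$materials
  ti <- grepl("^(implant|screw_)", mesh$region)
  E[ti] <- m$E_implant; nu[ti] <- m$nu_implant
  co <- mesh$region == "bone_cortical"
  E[co] <- m$E_cortical; nu[co] <- m$nu_cortical
  tr <- mesh$region == "bone_trabecular"
  nu[tr] <- m$nu_trabecular
  if (r$bone_field == "homogeneous") {
    E[tr] <- m$E_trabecular
  } else {
    cent <- (mesh$nodes[mesh$elems[tr, 1], , drop = FALSE] +
               mesh$nodes[mesh$elems[tr, 2], , drop = FALSE] +
               mesh$nodes[mesh$elems[tr, 3], , drop = FALSE] +
               mesh$nodes[mesh$elems[tr, 4], , drop = FALSE]) / 4
    E[tr] <- sample_bone_field_at(cent, r$field)
  }

  # weak stabilization springs keep the plate (held only by contact)
  # non-singular when every contact pair opens; ~1e-5 of the structural
  # stiffness, mechanically negligible
  plate_top <- select_nodes(mesh, "plate", c(0, Lx, 0, Ly, tp, tp))
  springs <- list(
    spring_set(mesh$nsets$bone_bottom, c(0, 0, 1), r$springs$k_base,
               r$springs$tangential_fraction),
    spring_set(mesh$nsets$bone_side, c(1, 0, 0), r$springs$k_side,
               r$springs$tangential_fraction),
    spring_set(plate_top, c(0, 0, 1), 1.0, 1.0))

  loads <- lapply(r$loads, function(lc) {
    pn <- which(mesh$part == "plate")
    d2 <- rowSums(sweep(mesh$nodes[pn, , drop = FALSE], 2, lc$point)^2)
    list(node = pn[which.min(d2)], F = lc$F, point = lc$point)
  })

  model <- fe_model(mesh, E, nu, springs)
  structure(list(mesh = mesh, model = model, E = E, nu = nu,
                 screws = screws, springs = springs, loads = loads,
                 recipe = r, case_cache = new.env(parent = emptyenv())),
            class = "assembly")
}

# Per-screw analytic spec derived from the shared recipe spec.
within_spec <- function(spec, k, core_len, free_len, partial_len) {
  s <- unclass(spec)
  s$id <- paste0(spec$id, "_", k)
  s$core_length <- core_len
  s$free_zone_length <- free_len
  s$partial_embed_length <- partial_len
  if (is.na(s$engagement_length)) s$engagement_length <- core_len - free_len
  class(s) <- "screw_spec"
  s
}

# Drop unmatched nodes from two nearly-coincident sets (plate and bone
# bottom faces share the footprint except each screw's clearance ring).
match_keep <- function(mesh, a, b, tol = 1e-9) {
  keyf <- function(i) paste(round(mesh$nodes[i, 1] / tol),
                            round(mesh$nodes[i, 2] / tol),
                            round(mesh$nodes[i, 3] / tol))
  ka <- keyf(a); kb <- keyf(b)
  common <- intersect(ka, kb)
  list(a = a[ka %in% common], b = b[kb %in% common])
}

#' Build a single-screw assembly
#'
#' Convenience wrapper producing the isolated one-screw model used for
#' calibration initial guesses and the small verification fixtures.
#'
#' @param spec A [screw_spec()].
#' @param screw Per-screw FE geometry overrides (see [assembly_recipe()]).
#' @param ... Further arguments passed to [assembly_recipe()].
#' @return An `assembly`.
#' @export
build_single_screw <- function(spec = screw_spec(), screw = list(), ...) {
  build_assembly(assembly_recipe(n_screws = 1, spec = spec,
                                 screw = screw, ...))
}

#' Per-screw pretension targets of an assembly
#'
#' Applies the pullout -> stripping torque -> insertion torque -> pretension
#' chain to every screw of the assembly.
#'
#' @param assembly An `assembly`.
#' @param rho_app Bone apparent density (g/cm^3).
#' @param fric A [friction_set()].
#' @param calib A [ct_calibration()].
#' @return The [infer_pretension_table()] data frame for the assembly.
#' @export
assembly_targets <- function(assembly, rho_app = 0.422,
                             fric = friction_set(),
                             calib = ct_calibration()) {
  specs <- lapply(assembly$screws, `[[`, "spec")
  infer_pretension_table(specs, rho_app = rho_app, fric = fric, calib = calib)
}

#' Load a packaged assembly recipe
#'
#' Reads one of the YAML recipes shipped with the package
#' (`single_cancellous`, `single_cortical`, `three_screw`,
#' `nine_screw_mini`) or a user file.
#'
#' @param name Recipe name or path to a YAML file.
#' @return An [assembly_recipe()].
#' @export
load_recipe <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", paste0(name, ".yaml"), package = "screwfe")
  if (!nzchar(path) || !file.exists(path))
    stop("load_recipe: recipe '", name, "' not found")
  y <- yaml::read_yaml(path)
  spec <- if (!is.null(y$spec)) do.call(screw_spec, y$spec) else
    screw_spec(id = "screw")
  loads <- if (!is.null(y$loads))
    lapply(y$loads, function(l) list(point = unlist(l$point),
                                     F = unlist(l$F)))
  else NULL
  centers <- if (!is.null(y$centers)) do.call(rbind, y$centers) else NULL
  args <- list(n_screws = y$n_screws %||% 1,
               centers = centers,
               screw = y$screw %||% list(),
               spec = spec,
               materials = y$materials %||% list(),
               bone_field = y$bone_field %||% "homogeneous",
               field = y$field %||% list(),
               springs = y$springs %||% list(),
               loads = loads,
               h = y$h %||% 1,
               order = y$order %||% 1L)
  if (!is.null(y$plate)) args$plate <- unlist(y$plate)
  if (!is.null(y$bone)) args$bone <- unlist(y$bone)
  do.call(assembly_recipe, args)
}
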
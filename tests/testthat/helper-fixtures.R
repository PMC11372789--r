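# Shared fixtures, memoised so expensive builds/calibrations run once per
# test session.

.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

single_assembly <- function() {
  memo("single", build_assembly(load_recipe("single_cancellous")))
}

three_assembly <- function() {
  memo("three", build_assembly(load_recipe("three_screw")))
}

cortical_assembly <- function() {
  memo("cortical", build_assembly(load_recipe("single_cortical")))
}

# full six-method comparison on the single-screw fixture
single_comparison <- function() {
  memo("cmp1", run_method_comparison(single_assembly()))
}

# full six-method comparison on the three-screw fixture
three_comparison <- function() {
  memo("cmp3", run_method_comparison(three_assembly()))
}

# a small meshed bar: nx x ny x nz cells of size h
bar_mesh <- function(nx = 6, ny = 2, nz = 2, h = 1, order = 1L) {
  part <- grid_part(cells_from_box(c(0, nx * h, 0, ny * h, 0, nz * h), h),
                    "bar", h)
  m <- mesh_from_parts(list(bar = part), h)
  if (order == 2L) m <- mesh_to_tet10(m)
  m
}

# minimal statically determinate support for a bar along x
bar_supports <- function(mesh, L, W) {
  n000 <- select_nodes(mesh, NULL, c(0, 0, 0, 0, 0, 0))
  nL00 <- select_nodes(mesh, NULL, c(L, L, 0, 0, 0, 0))
  n0W0 <- select_nodes(mesh, NULL, c(0, 0, W, W, 0, 0))
  data.frame(node = c(n000, n000, n000, nL00, nL00, n0W0),
             comp = c(1, 2, 3, 2, 3, 3), value = 0)
}

# two stacked blocks with a z-normal interface pair at z = 2
stacked_blocks <- function(type = "contact", E = 1000, nu = 0) {
  lo <- grid_part(cells_from_box(c(0, 2, 0, 2, 0, 2), 1), "lo", 1)
  hi <- grid_part(cells_from_box(c(0, 2, 0, 2, 2, 4), 1), "hi", 1)
  mesh <- mesh_from_parts(list(lo = lo, hi = hi), 1)
  a <- select_nodes(mesh, "hi", c(0, 2, 0, 2, 2, 2))
  b <- select_nodes(mesh, "lo", c(0, 2, 0, 2, 2, 2))
  mesh <- add_pair(mesh, "iface", a, b, c(0, 0, 1), type,
                   axis = if (type == "section") c(0, 0, 1) else NULL)
  top <- select_nodes(mesh, "hi", c(0, 2, 0, 2, 4, 4))
  bot <- select_nodes(mesh, "lo", c(0, 2, 0, 2, 0, 0))
  # weak springs keep the upper block well-posed under full separation
  springs <- list(spring_set(top, c(0, 0, 1), 1e-3, 1))
  model <- fe_model(mesh, E, nu, springs)
  list(mesh = mesh, model = model, top = top, bot = bot)
}

# verification stack for the 1D bolted-joint oracle: a bolt core through a
# member tube, clamped between a stiff base and a stiff head plate.
# nu = 0 everywhere so column stiffness formulas are exact in 1D.
oracle_stack <- function() {
  memo("stack", {
    h <- 1
    E_soft <- 2000; E_stiff <- 2e5
    base <- grid_part(cells_from_box(c(0, 9, 0, 9, -2, 0), h), "base", h)
    ring_cells <- cells_diff(cells_from_box(c(1, 8, 1, 8, 0, 10), h),
                             cells_from_box(c(3, 6, 3, 6, 0, 10), h))
    member <- grid_part(ring_cells, "member", h)
    core <- grid_part(cells_from_box(c(3, 6, 3, 6, 0, 10), h), "core", h)
    head <- grid_part(cells_from_box(c(1, 8, 1, 8, 10, 12), h), "head", h)
    mesh <- mesh_from_parts(list(base = base, member = member,
                                 core = core, head = head), h)
    pairit <- function(mesh, name, pa, pb, box, type) {
      add_pair(mesh, name, select_nodes(mesh, pa, box),
               select_nodes(mesh, pb, box), c(0, 0, 1), type)
    }
    bm <- select_nodes(mesh, "base", c(1, 8, 1, 8, 0, 0))
    xy <- mesh$nodes[bm, ]
    bm <- bm[!(xy[, 1] > 3 + 1e-9 & xy[, 1] < 6 - 1e-9 &
                 xy[, 2] > 3 + 1e-9 & xy[, 2] < 6 - 1e-9)]
    mesh <- add_pair(mesh, "base_member", bm,
                     select_nodes(mesh, "member", c(1, 8, 1, 8, 0, 0)),
                     c(0, 0, 1), "tie")
    mesh <- pairit(mesh, "base_core", "base", "core",
                   c(3, 6, 3, 6, 0, 0), "tie")
    mesh <- pairit(mesh, "head_core", "head", "core",
                   c(3, 6, 3, 6, 10, 10), "tie")
    # head seats on the member: hard frictionless contact (can separate);
    # the head face over the open hole interior has no member partner
    hseat <- select_nodes(mesh, "head", c(1, 8, 1, 8, 10, 10))
    xy <- mesh$nodes[hseat, ]
    hseat <- hseat[!(xy[, 1] > 3 + 1e-9 & xy[, 1] < 6 - 1e-9 &
                       xy[, 2] > 3 + 1e-9 & xy[, 2] < 6 - 1e-9)]
    mesh <- add_pair(mesh, "seat", hseat,
                     select_nodes(mesh, "member", c(1, 8, 1, 8, 10, 10)),
                     c(0, 0, 1), "contact")
    E <- ifelse(mesh$region %in% c("base", "head"), E_stiff, E_soft)
    head_top <- select_nodes(mesh, "head", c(1, 8, 1, 8, 12, 12))
    springs <- list(spring_set(head_top, c(0, 0, 1), 1e-3, 1))
    model <- fe_model(mesh, E, 0, springs)
    bot <- select_nodes(mesh, "base", c(0, 9, 0, 9, -2, -2))
    fixed <- data.frame(node = rep(bot, each = 3),
                        comp = rep(1:3, length(bot)), value = 0)
    core_elems <- which(mesh$region == "core")
    cz <- (mesh$nodes[mesh$elems[core_elems, 1], 3] +
             mesh$nodes[mesh$elems[core_elems, 2], 3] +
             mesh$nodes[mesh$elems[core_elems, 3], 3] +
             mesh$nodes[mesh$elems[core_elems, 4], 3]) / 4
    list(mesh = mesh, model = model, fixed = fixed,
         head_top = head_top, core_elems = core_elems, core_z = cz,
         E_soft = E_soft, A_core = 9, A_member = 40, L = 10,
         kb = E_soft * 9 / 10, km = E_soft * 40 / 10)
  })
}

# axial force in the oracle stack core at height z (slab average)
stack_core_force <- function(stack, sol, z = 5) {
  sel <- abs(stack$core_z - z) <= 1
  mean(sol$stress[stack$core_elems[sel], 3]) * stack$A_core
}

# uniform-traction nodal loads on a node set
traction_loads <- function(mesh, nset, F) {
  w <- surface_weights(mesh, nset)
  data.frame(node = rep(as.integer(names(w)), 3),
             comp = rep(1:3, each = length(w)),
             value = as.vector(outer(unname(w), F)))
}

# the small two-level single-screw recipes for the refinement study
mini_recipe <- function(h) {
  assembly_recipe(n_screws = 1, plate = c(9, 9, 2), bone = c(10, 2, 0),
                  screw = list(core_len = 8, free_len = 4, partial_len = 2,
                               head_h = 1),
                  h = h)
}
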
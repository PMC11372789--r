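test_that("a single unconstrained tet has exactly six rigid-body modes", {
  part <- grid_part(cells_from_box(c(0, 1, 0, 1, 0, 1), 1), "t", 1)
  part$elems <- part$elems[1, , drop = FALSE]
  part$region <- part$region[1]
  keep <- sort(unique(as.vector(part$elems)))
  part$nodes <- part$nodes[keep, , drop = FALSE]
  part$elems <- matrix(match(part$elems, keep), 1)
  m <- mesh_from_parts(list(t = part), 1)
  K <- as.matrix(assemble_stiffness(m, 1000, 0.3))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
  expect_true(all(ev > -1e-8 * max(ev)))
})

test_that("patch test: a prescribed linear field is reproduced exactly", {
  A <- matrix(c(1e-3, 2e-4, 3e-4, 2e-4, -5e-4, 1e-4, 3e-4, 1e-4, 7e-4), 3, 3)
  for (ord in c(1L, 2L)) {
    m <- bar_mesh(3, 3, 3, order = ord)
    md <- fe_model(m, 200, 0.25)
    nd <- m$nodes
    tol <- 1e-9
    bnd <- which(nd[, 1] < tol | nd[, 1] > 3 - tol |
                   nd[, 2] < tol | nd[, 2] > 3 - tol |
                   nd[, 3] < tol | nd[, 3] > 3 - tol)
    ub <- nd[bnd, ] %*% A
    cs <- fe_case(md, fixed = data.frame(node = rep(bnd, 3),
                                         comp = rep(1:3, each = length(bnd)),
                                         value = as.vector(ub)))
    s <- fe_solve(md, cs)
    expect_lt(max(abs(s$u - nd %*% A)), 1e-12)
    expect_lt(max(apply(s$stress, 2, stats::sd)), 1e-10)
  }
})

test_that("quadratic cantilever matches beam theory within 5%", {
  L <- 12; W <- 2
  m <- bar_mesh(L, W, W, order = 2L)
  E <- 1000; nu <- 0.3
  md <- fe_model(m, E, nu)
  root <- select_nodes(m, NULL, c(0, 0, 0, W, 0, W))
  cs <- fe_case(md, fixed = data.frame(node = rep(root, each = 3),
                                       comp = rep(1:3, length(root)),
                                       value = 0))
  Ftip <- 1
  tipface <- select_nodes(m, NULL, c(L, L, 0, W, 0, W))
  s <- fe_solve(md, cs, list(point = traction_loads(m, tipface, c(0, 0, Ftip))))
  tip <- mean(s$u[tipface, 3])
  I <- W^4 / 12; G <- E / (2 * (1 + nu))
  delta <- Ftip * L^3 / (3 * E * I) + Ftip * L / (5 / 6 * G * W^2)
  expect_equal(tip, delta, tolerance = 0.05)
})

test_that("stacked blocks: tie and contact agree in compression, differ in tension", {
  P <- 40
  for (type in c("tie", "contact")) {
    st <- stacked_blocks(type)
    fixed <- data.frame(node = rep(st$bot, each = 3),
                        comp = rep(1:3, length(st$bot)), value = 0)
    cs <- if (type == "tie") fe_case(st$model, ties = "iface", fixed = fixed)
    else fe_case(st$model, contacts = "iface", fixed = fixed)
    # compression: both carry the load; uz = -P L / (E A) for nu = 0
    s <- fe_solve(st$model, cs, list(point = traction_loads(st$mesh, st$top,
                                                            c(0, 0, -P))))
    expect_equal(mean(s$u[st$top, 3]), -P * 4 / (1000 * 4), tolerance = 1e-5)
    expect_equal(interface_force(st$model, s, "iface")[3], -P,
                 tolerance = 1e-5)
    # tension
    s2 <- fe_solve(st$model, cs, list(point = traction_loads(st$mesh, st$top,
                                                             c(0, 0, P))))
    if (type == "tie") {
      expect_equal(interface_force(st$model, s2, "iface")[3], P,
                   tolerance = 1e-5)
      expect_equal(mean(s2$u[st$top, 3]), P * 4 / (1000 * 4),
                   tolerance = 1e-5)
    } else {
      # the interface opens: zero transmitted force, upper block rides on
      # the weak stabilization springs only
      expect_lt(abs(interface_force(st$model, s2, "iface")[3]), 1e-6)
      expect_true(all(s2$contact$pressure > -1e-6))
      expect_true(all(s2$contact$gap > 1e-3))
      expect_gt(mean(s2$u[st$top, 3]), 1)
    }
    # zero load gives zero displacement
    s0 <- fe_solve(st$model, cs, list())
    expect_lt(max(abs(s0$u)), 1e-12)
  }
})

test_that("pretension section: force control sets the section force exactly,
           length control freezes the state", {
  st <- stacked_blocks("section")
  fixed <- data.frame(node = rep(c(st$bot, st$top), each = 3),
                      comp = rep(1:3, length(st$bot) + length(st$top)),
                      value = 0)
  cs <- fe_case(st$model, sections = "iface", fixed = fixed)
  s <- fe_solve(st$model, cs, list(scalar_forces = c(iface = 100)))
  # both ends clamped: tension 100 N over 4 mm^2 everywhere
  expect_equal(unique(round(s$stress[, 3], 9)), 25)
  expect_equal(unname(s$scalars["iface"]), 2 * (25 / 1000) * 2)
  # length control at the converged relative length reproduces the state
  cs2 <- fe_case(st$model, sections = "iface", fixed = fixed,
                 fixed_scalars = c(iface = unname(s$scalars["iface"])))
  s2 <- fe_solve(st$model, cs2)
  expect_equal(s2$stress, s$stress, tolerance = 1e-9)
  # a cut with no force and free length carries nothing
  s3 <- fe_solve(st$model, cs, list())
  expect_lt(max(abs(s3$stress)), 1e-12)
})

test_that("thermal loads: stress-free shrinkage and clamped-bar force", {
  m <- bar_mesh(6, 2, 2)
  E <- 1000
  md <- fe_model(m, E, 0.3)
  x <- -0.01
  # statically determinate support: free shrinkage, no stress
  cs <- fe_case(md, fixed = bar_supports(m, 6, 2))
  th <- thermal_load(seq_len(nrow(m$elems)), x, "isotropic")
  s <- fe_solve(md, cs, list(thermals = list(th)))
  expect_lt(max(abs(s$stress)), 1e-8 * E * abs(x))
  right <- select_nodes(m, NULL, c(6, 6, 0, 2, 0, 2))
  expect_equal(mean(s$u[right, 1]), x * 6, tolerance = 1e-9)

  # clamped axially: tensile force |x| E A for both modes, but only the
  # isotropic mode contracts laterally
  left <- select_nodes(m, NULL, c(0, 0, 0, 2, 0, 2))
  fx <- rbind(data.frame(node = c(left, right), comp = 1, value = 0),
              bar_supports(m, 6, 2))
  csc <- fe_case(md, fixed = fx)
  force <- lat <- numeric(2)
  for (i in 1:2) {
    mode <- c("isotropic", "axial")[i]
    th2 <- thermal_load(seq_len(nrow(m$elems)), x, mode, axis = c(1, 0, 0))
    s2 <- fe_solve(md, csc, list(thermals = list(th2)))
    force[i] <- mean(s2$stress[, 1]) * 4
    topy <- select_nodes(m, NULL, c(0, 6, 2, 2, 0, 2))
    lat[i] <- mean(s2$u[topy, 2])
  }
  expect_equal(force[1], abs(x) * E * 4, tolerance = 1e-9)
  expect_equal(force[2], abs(x) * E * 4, tolerance = 1e-9)
  expect_lt(lat[1], -1e-3)            # isotropic: lateral shrinkage
  expect_gt(abs(lat[1] - lat[2]), 1e-3)
})

test_that("solutions are linear, superpose, and balance reactions", {
  m <- bar_mesh(4, 2, 2)
  md <- fe_model(m, 500, 0.3)
  left <- select_nodes(m, NULL, c(0, 0, 0, 2, 0, 2))
  cs <- fe_case(md, fixed = data.frame(node = rep(left, each = 3),
                                       comp = rep(1:3, length(left)),
                                       value = 0))
  right <- select_nodes(m, NULL, c(4, 4, 0, 2, 0, 2))
  A <- list(point = data.frame(node = right, comp = 1,
                               value = 3 / length(right)))
  B <- list(point = data.frame(node = right, comp = 3,
                               value = -7 / length(right)))
  sA <- fe_solve(md, cs, A); sB <- fe_solve(md, cs, B)
  sAB <- fe_solve(md, cs, list(point = rbind(A$point, B$point)))
  expect_equal(sAB$u, sA$u + sB$u, tolerance = 1e-10)
  s2A <- fe_solve(md, cs, list(point = transform(A$point, value = 2 * value)))
  expect_equal(s2A$u, 2 * sA$u, tolerance = 1e-10)
  # equilibrium: residual tiny, reactions balance the applied load
  expect_lt(sAB$residual, 1e-6)
  dofx <- 3 * (seq_len(nrow(m$nodes)) - 1) + 1
  expect_equal(sum(sAB$reaction[dofx]), -3, tolerance = 1e-8)
  dofz <- 3 * (seq_len(nrow(m$nodes)) - 1) + 3
  expect_equal(sum(sAB$reaction[dofz]), 7, tolerance = 1e-8)
})

test_that("two-material stacked bar matches the series-spring closed form", {
  lo <- grid_part(cells_from_box(c(0, 2, 0, 2, 0, 3), 1), "lo", 1)
  hi <- grid_part(cells_from_box(c(0, 2, 0, 2, 3, 6), 1), "hi", 1)
  mesh <- mesh_from_parts(list(lo = lo, hi = hi), 1)
  a <- select_nodes(mesh, "hi", c(0, 2, 0, 2, 3, 3))
  b <- select_nodes(mesh, "lo", c(0, 2, 0, 2, 3, 3))
  mesh <- add_pair(mesh, "j", a, b, c(0, 0, 1), "tie")
  E <- ifelse(mesh$region == "lo", 1000, 4000)
  md <- fe_model(mesh, E, 0)
  bot <- select_nodes(mesh, "lo", c(0, 2, 0, 2, 0, 0))
  cs <- fe_case(md, ties = "j",
                fixed = data.frame(node = rep(bot, each = 3),
                                   comp = rep(1:3, length(bot)), value = 0))
  top <- select_nodes(mesh, "hi", c(0, 2, 0, 2, 6, 6))
  F <- 8
  s <- fe_solve(md, cs, list(point = traction_loads(mesh, top, c(0, 0, F))))
  u_exp <- F * (3 / (1000 * 4) + 3 / (4000 * 4))
  expect_equal(mean(s$u[top, 3]), u_exp, tolerance = 1e-9)
})

test_that("compression-only springs engage only under compression", {
  m <- bar_mesh(2, 2, 1)
  bot <- select_nodes(m, NULL, c(0, 2, 0, 2, 0, 0))
  top <- select_nodes(m, NULL, c(0, 2, 0, 2, 1, 1))
  springs <- list(spring_set(bot, c(0, 0, 1), 100, 0, "compression_only"),
                  spring_set(bot, c(0, 0, 1), 1e-3, 1),
                  spring_set(top, c(0, 0, 1), 1e-3, 1))
  md <- fe_model(m, 1000, 0, springs)
  cs <- fe_case(md)
  sdn <- fe_solve(md, cs, list(point = traction_loads(m, top, c(0, 0, -10))))
  expect_true(all(sdn$conly_active[[1]]))
  expect_equal(mean(sdn$u[bot, 3]), -10 / 100, tolerance = 1e-3)
  sup <- fe_solve(md, cs, list(point = traction_loads(m, top, c(0, 0, 10))))
  expect_false(any(sup$conly_active[[1]]))
  expect_gt(mean(sup$u[bot, 3]), 100)   # only the weak springs remain
})
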
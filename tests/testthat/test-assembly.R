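test_that("recipes validate their geometric invariants", {
  expect_error(assembly_recipe(screw = list(free_len = 1)), "2 h")
  expect_error(assembly_recipe(screw = list(core_len = 40)), "longer than")
  expect_error(assembly_recipe(screw = list(core_len = 6, free_len = 3,
                                            partial_len = 3)),
               "fully embedded")
  expect_error(assembly_recipe(plate = c(5, 5, 3)), "outside the plate")
  expect_error(assembly_recipe(n_screws = 2, centers = rbind(c(6.5, 6.5),
                                                             c(9.5, 6.5)),
                               plate = c(17, 13, 3)),
               "overlapping")
  expect_error(assembly_recipe(screw = list(core_w = 4)), "grid planes")
})

test_that("generated assemblies are conforming and structurally complete", {
  a <- single_assembly()
  expect_s3_class(a, "assembly")
  expect_lte(pair_mismatch(a$mesh), 1e-9)
  expect_true(all(tet_volumes(a$mesh) > 0))
  s <- a$screws[[1]]
  expect_setequal(c(s$section, s$junction, s$embed, s$head, s$bore,
                    "plate_bone") , names(a$mesh$pairs))
  # screw zones are mutually consistent
  expect_lte(s$free_len + s$partial_len, s$core_len)
  expect_true(s$cut > 0 && s$cut < s$free_len)
  # every element belongs to exactly one region and materials are set
  expect_false(any(is.na(a$E)) || any(a$E <= 0))
  expect_true(all(a$nu >= 0 & a$nu < 0.5))
  expect_equal(sort(unique(a$mesh$region)),
               sort(c("bone_cortical", "bone_trabecular", "implant",
                      "screw_head_1", "screw_shank_1", "screw_core_1")))
})

test_that("same recipe builds byte-identical assemblies", {
  r <- load_recipe("three_screw")
  a1 <- build_assembly(r)
  a2 <- build_assembly(r)
  expect_identical(a1$mesh$nodes, a2$mesh$nodes)
  expect_identical(a1$mesh$elems, a2$mesh$elems)
  expect_identical(a1$E, a2$E)
})

test_that("sampled bone fields honour mean, bounds and seed", {
  xyz <- as.matrix(expand.grid(x = 0:12, y = 0:12, z = -(0:12)))
  f <- list(mean_E = 661.4, cv = 0.25, E_min = 100, E_max = 6704.7, seed = 42)
  E1 <- sample_bone_field_at(xyz, f)
  E2 <- sample_bone_field_at(xyz, f)
  expect_identical(E1, E2)
  expect_true(all(E1 >= 100 & E1 <= 6704.7))
  expect_equal(mean(E1), 661.4, tolerance = 0.02)
  # zero-variance field collapses to the homogeneous mean
  f0 <- utils::modifyList(f, list(cv = 0))
  expect_equal(unique(round(sample_bone_field_at(xyz, f0), 6)), 661.4)
  # different seed, different field
  f2 <- utils::modifyList(f, list(seed = 43))
  expect_false(identical(E1, sample_bone_field_at(xyz, f2)))
  # the heterogeneous fixture stays inside the physiological bounds
  a3 <- three_assembly()
  tr <- a3$mesh$region == "bone_trabecular"
  expect_true(all(a3$E[tr] >= 100 & a3$E[tr] <= 6704.7))
  expect_equal(mean(a3$E[tr]), 661.4, tolerance = 0.02)
})

test_that("a one-screw recipe reduces to the single-screw builder", {
  r <- assembly_recipe(n_screws = 1, plate = c(9, 9, 2), bone = c(10, 2, 0),
                       screw = list(core_len = 8, free_len = 4,
                                    partial_len = 2, head_h = 1))
  a <- build_assembly(r)
  b <- build_single_screw(screw = list(core_len = 8, free_len = 4,
                                       partial_len = 2, head_h = 1),
                          plate = c(9, 9, 2), bone = c(10, 2, 0))
  expect_identical(a$mesh$nodes, b$mesh$nodes)
  expect_identical(a$E, b$E)
})

test_that("tightening one screw perturbs its seated neighbours (elastic
           interaction)", {
  a3 <- three_assembly()
  plan <- build_plan("ORT", a3)
  # all three screws preloaded (heads seated), then screw 1 is tightened
  # further: the neighbours' free-zone forces must respond through the
  # shared plate and bone, the nearer one more strongly
  x0 <- c(-2e-3, -2e-3, -2e-3)
  f_at <- function(x) {
    res <- run_pretension_step(a3, plan, targets = 100, controls = x)
    vapply(1:3, function(k) free_zone_force(a3, res$pretension, k),
           numeric(1))
  }
  fa <- f_at(x0)
  fb <- f_at(x0 * c(1.5, 1, 1))
  expect_gt(fb[1] - fa[1], 10)
  expect_gt(abs(fb[2] - fa[2]), 0.05)      # nonzero cross-compliance
  expect_gt(abs(fb[2] - fa[2]), abs(fb[3] - fa[3]))
})

test_that("assembly pretension targets follow the analytic chain", {
  a3 <- three_assembly()
  tgt <- assembly_targets(a3)
  expect_equal(nrow(tgt), 3)
  # engagement length defaults to the embedded core length
  L <- vapply(a3$screws, function(s) s$core_len - s$free_len, numeric(1))
  expect_equal(tgt$F_PO / tgt$F_PO[1], L / L[1])
  expect_equal(tgt$F_PO / tgt$F_P, rep(1.4785, 3), tolerance = 1e-4)
})
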
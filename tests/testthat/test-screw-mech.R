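test_that("CT intensity chain maps HU to density and modulus", {
  cal <- ct_calibration()
  # root, intercept and a direct evaluation of the affine map
  expect_equal(hu_to_bmd(0.8037 / 0.0008, cal), 0)
  expect_equal(hu_to_bmd(0, cal), -0.8037)
  expect_equal(hu_to_bmd(2000, cal), 0.7963)
  expect_error(hu_to_bmd(NaN), "finite")

  expect_equal(bmd_to_density(0.626, cal), 1)
  expect_equal(bmd_to_density(0, cal), 0)
  expect_equal(bmd_to_density(0.264, cal), 0.264 / 0.626)
  expect_error(bmd_to_density(-0.1), "clamp")

  expect_equal(density_to_modulus(1, cal), 2017.3)
  expect_equal(density_to_modulus(0, cal), 0)
  # the density whose modulus equals the reported trabecular mean
  expect_equal(density_to_modulus(0.6356, cal), 661.4, tolerance = 5e-4)
  expect_error(density_to_modulus(-1), ">= 0")

  # monotone non-decreasing above the BMD root
  int <- seq(1005, 3000, by = 5)
  E <- density_to_modulus(bmd_to_density(pmax(hu_to_bmd(int), 0)))
  expect_true(all(diff(E) >= 0))
})

test_that("shear strength and thread shape factor evaluate their closed forms", {
  expect_equal(trabecular_shear_strength(1), 0.44 * 19.08)
  expect_equal(trabecular_shear_strength(0.422), 0.44 * 19.08 * 0.422^2.15)
  expect_equal(trabecular_shear_strength(0.422), 1.3136, tolerance = 1e-4)
  expect_error(trabecular_shear_strength(0), "> 0")
  expect_equal(trabecular_shear_strength(1, ct_calibration(shear_ratio = 1e-12)),
               19.08e-12)

  sp <- screw_spec(D_major = 6.5, D_minor = 3.0, pitch = 2.75)
  expect_equal(thread_shape_factor(sp), 0.5 + 0.57735 * 1.75 / 2.75)
  expect_equal(thread_shape_factor(sp), 0.8674, tolerance = 1e-4)
  # zero thread depth and monotone decrease with pitch
  sp0 <- screw_spec(D_major = 6.5, D_minor = 6.499999, pitch = 2.75)
  expect_equal(thread_shape_factor(sp0), 0.5, tolerance = 1e-6)
  sp2 <- screw_spec(D_major = 6.5, D_minor = 3.0, pitch = 5.5)
  expect_lt(thread_shape_factor(sp2), thread_shape_factor(sp))
  expect_gt(thread_shape_factor(sp2), 0.5)
})

test_that("pullout threshold is linear in engagement length and strength", {
  sp <- screw_spec(engagement_length = 9, core_length = 40)
  S <- trabecular_shear_strength(0.422)
  f1 <- pullout_threshold(S, sp)
  expect_equal(f1, S * 9 * pi * 6.5 * thread_shape_factor(sp))
  sp2 <- screw_spec(engagement_length = 18, core_length = 40)
  expect_equal(pullout_threshold(S, sp2), 2 * f1)
  expect_equal(pullout_threshold(2 * S, sp), 2 * f1)
  spna <- screw_spec()
  expect_error(pullout_threshold(S, spna), "engagement_length")
})

test_that("torque chain matches its closed forms and limits", {
  sp <- screw_spec()
  fr <- friction_set()
  r <- pitch_radius(sp)
  expect_equal(r, (6.5 + 3.0) / 4)
  # frictionless limit: T = F r p / (2 r) = F p / 2
  fr0 <- friction_set(1e-9, 1e-9, 1e-9)
  expect_equal(stripping_torque(100, sp, fr0), 100 * 2.75 / 2,
               tolerance = 1e-6)
  # linearity in F_PO
  expect_equal(stripping_torque(200, sp, fr), 2 * stripping_torque(100, sp, fr))
  # direct evaluation at the published screw geometry
  expect_equal(stripping_torque(1026.7, sp, fr),
               1026.7 * r * (2.75 + 2 * 0.42 * r) / (2 * r - 0.42 * 2.75))
  # geometry error when the denominator closes
  spb <- screw_spec(D_major = 1.2, D_minor = 1.0, pitch = 5.5,
                    free_zone_length = 0, partial_embed_length = 0,
                    core_length = 40)
  expect_error(stripping_torque(100, spb, fr), "denominator")

  expect_equal(insertion_torque(1000), 650)
  expect_equal(insertion_torque(0), 0)

  # zero-friction limit of the torque-to-force relation
  expect_equal(pretension_force(100, sp, fr0), 100 / (0.159 * 2.75),
               tolerance = 1e-4)
  expect_equal(pretension_force(200, sp, fr), 2 * pretension_force(100, sp, fr))
})

test_that("published pretension table is reproduced from the printed thresholds", {
  # printed pullout thresholds and the expected insertion torques (N m,
  # 1 decimal) and pretension forces (N, 1 decimal)
  tab3 <- data.frame(
    id = c("cancellous1", "cancellous2", "cancellous3", "cortical1",
           "cortical2", "cortical3", "cortical4", "cortical5", "cortical6"),
    F_PO = c(1026.7, 1060.9, 295.2, 221.4, 221.4, 221.4, 312.3, 393.6, 702.6),
    T_ins = c(2.1, 2.2, 0.6, 0.5, 0.5, 0.5, 0.6, 0.8, 1.4),
    F_P = c(694.4, 717.5, 199.6, 149.7, 149.7, 149.7, 211.2, 266.2, 475.2))
  specs <- lapply(tab3$id, function(id) screw_spec(id = id))
  ov <- stats::setNames(tab3$F_PO, tab3$id)
  out <- infer_pretension_table(specs, F_PO_override = ov)
  expect_equal(round(out$T_ins / 1000, 1), tab3$T_ins)
  expect_equal(out$F_P, tab3$F_P, tolerance = 0.1 / min(tab3$F_P))
  expect_true(all(abs(out$F_P - tab3$F_P) < 0.1))
  # the threshold-to-pretension ratio is a geometry/friction constant
  expect_equal(unique(round(out$F_PO / out$F_P, 2)), 1.48)
  expect_true(all(out$F_P < out$F_PO))
  # empty input
  expect_equal(nrow(infer_pretension_table(list())), 0)
})

test_that("pretension chain reports per-screw failures with the screw id", {
  sp <- screw_spec(id = "nolength")
  expect_error(infer_pretension_table(list(sp)), "nolength")
})

test_that("fatigue limit applies the endurance correction", {
  expect_equal(fatigue_limit(), 542.2)
  expect_equal(fatigue_limit(fatigue_spec(100, 0.5)), 50)
  expect_equal(fatigue_limit(fatigue_spec(700, 1)), 700)
  expect_error(fatigue_spec(-5, 0.5), "> 0")
  expect_error(fatigue_spec(100, NULL), "both")
})
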
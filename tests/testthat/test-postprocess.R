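test_that("axial profile of a force-controlled screw plateaus at the section
           force and decays into the bone", {
  a <- single_assembly()
  plan <- build_plan("BL_CF", a)
  res <- run_pretension_step(a, plan, targets = 300)
  prof <- axial_force_profile(a, res$pretension, 1)
  expect_true(all(diff(prof$station_pct) > 0))
  expect_true(all(prof$station_pct >= 0 & prof$station_pct <= 100))
  expect_setequal(unique(prof$zone), c("free", "partial", "full"))
  # free-zone plateau: coefficient of variation below 5%
  expect_lt(attr(prof, "plateau_cov"), 0.05)
  expect_equal(attr(prof, "free_zone_end_force"), 300, tolerance = 0.01)
  # profile at the junction equals the section force within 2% (statics)
  expect_equal(prof$force_N[1], 300, tolerance = 0.02)
  # embedded decay: the tip carries at most 5% of the free-zone force
  expect_lt(abs(prof$force_N[nrow(prof)]),
            0.05 * attr(prof, "free_zone_end_force"))
  # zero-load solution gives an all-zero profile
  case0 <- screwfe:::method_case(a, plan)
  s0 <- fe_solve(a$model, case0, list())
  prof0 <- axial_force_profile(a, s0, 1)
  expect_lt(max(abs(prof0$force_N)), 1e-9)
})

test_that("von Mises closed forms and the junction exclusion", {
  # pure uniaxial stress: vM equals its magnitude; hydrostatic: zero
  expect_equal(von_mises(matrix(c(-7, 0, 0, 0, 0, 0), 1)), 7)
  expect_equal(von_mises(matrix(c(5, 5, 5, 0, 0, 0), 1)), 0)
  expect_equal(von_mises(matrix(c(0, 0, 0, 3, 0, 0), 1)), sqrt(3) * 3)

  a <- single_assembly()
  plan <- build_plan("BL_CF", a)
  res <- run_pretension_step(a, plan, targets = 300)
  # in the plateau the core is nearly uniaxial: peak ~ F / A
  pk <- peak_von_mises(a, res$pretension, 1)
  expect_equal(pk, 300 / a$screws[[1]]$core_area, tolerance = 0.10)
  expect_error(peak_von_mises(a, res$pretension, 1, exclusion_mm = 30),
               "not shorter")
})

test_that("failure classification applies inclusive thresholds", {
  forces <- rbind(s1 = c(101, 80), s2 = c(-50, 30), s3 = c(99.9, 100))
  peaks <- rbind(s1 = c(200, 300), s2 = c(542.2, 100), s3 = c(10, 20))
  rep_ <- classify_failure(forces, peaks, F_PO = 100, Se = 542.2,
                           ids = rownames(forces))
  expect_equal(rep_$pullout, c(TRUE, FALSE, TRUE))
  expect_equal(rep_$fatigue, c(FALSE, TRUE, FALSE))
  expect_equal(rep_$compressive, c(FALSE, TRUE, FALSE))
  expect_equal(rep_$max_force_ratio, c(1.01, 0.30, 1.00))
  expect_error(classify_failure(forces, peaks, F_PO = -1), "positive")
})

test_that("screws with a sub-element free zone raise the reliability warning", {
  a <- cortical_assembly()
  expect_lt(a$screws[[1]]$free_len, 3 * a$mesh$h)
  plan <- build_plan("BL_CF", a)
  res <- run_pretension_step(a, plan, targets = 100)
  expect_warning(axial_force_profile(a, res$pretension, 1), "unreliable")
  prof <- suppressWarnings(axial_force_profile(a, res$pretension, 1))
  expect_false(attr(prof, "reliable"))
})
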
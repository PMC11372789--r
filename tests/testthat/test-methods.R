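test_that("method plans encode the six configurations", {
  a <- single_assembly()
  tie <- build_plan("tie", a)
  expect_equal(tie$head_mode, "tie")
  expect_equal(tie$device, "none")
  expect_false(tie$iterative)
  for_ <- build_plan("FOR", a)
  expect_equal(for_$device, "force_pair")
  expect_true(for_$iterative)
  blcl <- build_plan("bl-cl", a)
  expect_equal(blcl$device, "section")
  expect_equal(blcl$carryover, "locked_length")
  expect_error(build_plan("XYZ", a), "unknown screw modeling method")
})

test_that("TIE skips the pretension step and starts stress-free", {
  a <- single_assembly()
  plan <- build_plan("TIE", a)
  res <- run_pretension_step(a, plan, targets = 500)
  expect_null(res$pretension)
  res <- run_simulation_step(a, plan, res, "gait1")
  expect_s3_class(res$simulation$gait1, "fe_solution")
})

test_that("bolt-load pretension matches its target exactly and the
           simulation step reproduces it under zero load", {
  a <- single_assembly()
  plan <- build_plan("BL_CF", a)
  res <- run_pretension_step(a, plan, targets = 500)
  expect_equal(free_zone_force(a, res$pretension, 1), 500, tolerance = 2e-4)
  expect_lt(res$pretension$residual, 1e-6)
  # no external load: the simulation step reproduces the pretension state
  res2 <- run_simulation_step(a, plan, res,
                              list(node = a$loads$gait1$node, F = c(0, 0, 0)))
  expect_equal(res2$simulation$custom$u, res$pretension$u, tolerance = 1e-8)
  # same for the locked-length variant
  planL <- build_plan("BL_CL", a)
  resL <- run_pretension_step(a, planL, targets = 500)
  resL <- run_simulation_step(a, planL, resL,
                              list(node = a$loads$gait1$node, F = c(0, 0, 0)))
  expect_equal(free_zone_force(a, resL$simulation$custom, 1), 500,
               tolerance = 1e-3)
})

test_that("BL-CF keeps the section force constant under external load", {
  cmp <- single_comparison()
  tgt <- cmp$targets[1]
  for (lc in c("gait1", "gait2", "liftoff")) {
    dev <- abs(cmp$forces["BL_CF", 1, lc] - tgt) / tgt
    expect_lt(dev, 0.02)
  }
})

test_that("locked-length and force-pair methods respond identically to an
           axial external load (joint-diagram behaviour)", {
  a <- single_assembly()
  tgt <- assembly_targets(a)$F_P
  axial <- list(node = a$loads$liftoff$node, F = c(0, 0, 0.6 * tgt))
  planL <- build_plan("BL_CL", a)
  resL <- run_pretension_step(a, planL, targets = tgt)
  resL <- run_simulation_step(a, planL, resL, axial)
  calF <- calibrate_assembly(a, "FOR", tgt)
  planF <- build_plan("FOR", a)
  resF <- run_pretension_step(a, planF, tgt, controls = calF$controls)
  resF <- run_simulation_step(a, planF, resF, axial)
  fL <- free_zone_force(a, resL$simulation$custom, 1)
  fF <- free_zone_force(a, resF$simulation$custom, 1)
  expect_equal(fF, fL, tolerance = 0.02)
  # both rose above the preload: the screw takes its share of the load
  expect_gt(fL, tgt)
})

test_that("under head-lifting load the tie transmits head tension while
           contact interfaces cannot", {
  cmp <- single_comparison()
  a <- single_assembly()
  sTIE <- cmp$results$TIE$simulation$liftoff
  # axial component of the constraint force on the plate side of the head
  # interface: positive z = the screw head pulls the plate up = tension
  fz_tie <- interface_force(a$model, sTIE, "head_1")[3]
  expect_gt(fz_tie, 1)
  for (m in c("BL_CL", "ISO", "ORT", "FOR")) {
    s <- cmp$results[[m]]$simulation$liftoff
    hc <- s$contact[s$contact$pair == "head_1", ]
    expect_true(all(hc$pressure >= -1e-6))
    # compression-only: the net axial force on the plate side cannot be
    # directed upwards
    expect_lt(interface_force(a$model, s, "head_1")[3], 1e-6)
  }
})

test_that("calibrated iterative methods and BL-CL agree; TIE and BL-CF
           fall outside the cluster", {
  cmp <- single_comparison()
  cl <- c("ISO", "ORT", "FOR", "BL_CL")
  expect_lt(max(cmp$agreement[cl, cl]), 0.05)
  # BL-CF cannot follow the load response of the cluster
  expect_gt(min(cmp$agreement["BL_CF", cl]), 0.2)
  # TIE has no preload: under gait loads it deviates from the cluster
  expect_gt(min(cmp$agreement["TIE", cl]), 0.05)
})
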
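test_that("outlet midpoint velocity interpolates the nodal field", {
  p <- fix_poiseuille()
  # Poiseuille: midpoint value is the centreline 1.5 U
  U <- p$sol$flux_out / 0.006
  expect_equal(mv_euo(p$sol, p$mesh), 1.5 * U, tolerance = 0.01)
  # synthetic uniform field: identity
  synth <- p$sol
  sp <- 2.0
  synth$u_node <- rep(0, nrow(p$mesh$nodes))
  synth$v_node <- rep(-sp, nrow(p$mesh$nodes))
  expect_equal(mv_euo(synth, p$mesh), sp, tolerance = 1e-12)
})

test_that("velocity profiles span the local width and respect no-slip", {
  cc <- fix_cats1_coarse()
  pr <- velocity_profile(cc$sol, cc$mesh, 17.5)   # mid-PU station
  w2 <- cc$dom$halfwidth(17.5)
  # boundary samples sit on wall-edge chords, inside the true curve by O(h^2)
  expect_equal(min(pr$x), -w2, tolerance = 5e-3)
  expect_equal(max(pr$x), w2, tolerance = 5e-3)
  peak <- max(abs(pr$v_axial))
  expect_lt(abs(pr$v_axial[1]), 0.05 * peak)
  # reverse (upward) flow on both flanks at mid-PU: the recirculation signature
  expect_gt(max(pr$v_axial[pr$x > 0]), 0)
  expect_gt(max(pr$v_axial[pr$x < 0]), 0)
  expect_lt(min(pr$v_axial), 0)
  expect_error(velocity_profile(cc$sol, cc$mesh, 40), "does not intersect")
})

test_that("vortex detection finds both PU recirculation zones in the index case", {
  cc <- fix_cats1_coarse()
  vm <- detect_vortices(cc$sol, cc$mesh, cc$dom)
  expect_true(vm$vortex)
  expect_true(vm$left$present)
  expect_true(vm$right$present)
  expect_gt(vm$td_v, 0)
  expect_gt(vm$ld_v, 0)
  # a side vortex fits inside its half-lumen
  expect_lte(vm$td_v, cats1_spec()$td_pu / 2 + 0.3)
  # presence symmetric in the symmetric solution; diameters close
  expect_equal(vm$left$td, vm$right$td, tolerance = 0.25)
})

test_that("unidirectional channel flow contains no vortex", {
  p <- fix_poiseuille()
  vm <- detect_vortices(p$sol, p$mesh, p$dom)
  expect_false(vm$vortex)
  expect_true(is.na(vm$td_v))
})

test_that("creeping flow through a tapering cavity does not separate", {
  # straight-walled trapezoid limit: a contracting lumen with no belly
  dom <- assemble_domain(make_case(3.8, 3.4, 2.0))
  mesh <- triangulate(dom, 2000)
  sol <- solve_steady_flow(mesh, bc = boundary_set(inlet_pressure = 0.01),
                           cfg = numerics_config(turbulence = "laminar"))
  expect_true(sol$converged)
  vm <- detect_vortices(sol, mesh, dom)
  expect_false(vm$vortex)
})

test_that("summarize_case assembles a complete deterministic record", {
  cc <- fix_cats1_coarse()
  rec <- summarize_case(cats1_spec(), cc$sol, cc$mesh, cc$dom)
  expect_equal(rec$case_id, "II-C-4.2")
  expect_equal(rec$rpu1, 1.4)
  expect_equal(rec$rpu2, 1.4 / 38)
  expect_true(rec$converged)
  expect_true(rec$vortex)
  expect_gt(rec$mv_euo, 0)
  rec2 <- summarize_case(cats1_spec(), cc$sol, cc$mesh, cc$dom)
  expect_identical(rec, rec2)
})
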
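test_that("configuration objects validate their inputs", {
  expect_error(fluid_properties(density = -1))
  expect_error(boundary_set(inlet_pressure = 0, outlet_pressure = 0))
  expect_error(numerics_config(urf_momentum = 0))
  expect_error(numerics_config(urf_pressure = 1.2))
  cfg <- numerics_config()
  expect_equal(cfg$coupling, "simplec")
  expect_equal(cfg$turbulence, "rng-ke")
  expect_equal(cfg$scheme, "upwind2")
})

test_that("pressure-driven laminar channel reproduces plane Poiseuille", {
  p <- fix_poiseuille()
  sol <- p$sol
  expect_true(sol$converged)
  # conservation audit: inlet and outlet volumetric flux agree
  expect_lt(abs(sol$flux_in - sol$flux_out) / abs(sol$flux_in), 1e-3)
  expect_lt(sol$mass_imbalance, 1e-3)
  # profile at mid-channel vs the closed form v(x) = 1.5 U (1 - (2x/w)^2),
  # with U taken from the computed flux
  U <- sol$flux_out / 0.006
  pr <- velocity_profile(sol, p$mesh, 2)
  closed <- -1.5 * U * (1 - (pr$x / 0.3)^2)   # x in cm, half-width 0.3 cm
  expect_lt(max(abs(pr$v_axial - closed)) / (1.5 * U), 0.01)
  # wall-adjacent samples echo no-slip
  expect_lt(abs(pr$v_axial[1]), 0.05 * 1.5 * U)
  expect_lt(abs(pr$v_axial[nrow(pr)]), 0.05 * 1.5 * U)
  # mean velocity agrees with the Poiseuille pressure balance within a few %
  U_poi <- 0.006^2 * 0.02 / (12 * 8.583e-4 * 0.03)
  expect_lt(abs(U - U_poi) / U_poi, 0.05)
})

test_that("streamfunction reproduces its closed forms and wall constancy", {
  p <- fix_poiseuille()
  psi <- compute_streamfunction(p$sol, p$mesh)
  wallf <- p$sol$faces[, "tag"] == 3
  wn <- unique(c(p$sol$faces[wallf, "n1"], p$sol$faces[wallf, "n2"]))
  left <- wn[p$mesh$nodes[wn, 1] < 0]
  right <- wn[p$mesh$nodes[wn, 1] > 0]
  jump <- abs(median(psi[right]) - median(psi[left]))
  # psi constant along each wall to 1e-4 of the inlet-outlet jump
  expect_lt(diff(range(psi[left])) / jump, 1e-4)
  expect_lt(diff(range(psi[right])) / jump, 1e-4)
  # jump equals the volumetric flux per unit depth
  expect_equal(jump, abs(p$sol$flux_out), tolerance = 1e-3)
  # Poiseuille: psi is cubic in x (linear fit residual large, cubic tiny)
  mid <- abs(p$mesh$nodes[, 2] - 0.015) < 2.5e-4
  x <- p$mesh$nodes[mid, 1]; ps <- psi[mid]
  cub <- lm(ps ~ poly(x, 3))
  expect_gt(summary(cub)$r.squared, 0.9999)
})

test_that("non-converged runs are flagged rather than silently returned", {
  p <- fix_poiseuille()
  short <- suppressWarnings(solve_steady_flow(
    p$mesh, bc = p$bc, cfg = numerics_config(turbulence = "laminar",
                                             max_iter = 40L)))
  expect_false(short$converged)
  expect_error(mv_euo(short, p$mesh), "converged")
  expect_error(detect_vortices(short, p$mesh, p$dom), "converged")
})

test_that("turbulence fields are physical on the solved index case", {
  cc <- fix_cats1_coarse()
  expect_true(cc$sol$converged)
  expect_true(all(cc$sol$k >= 0))
  expect_true(all(cc$sol$epsilon >= 0))
  expect_true(all(is.finite(cc$sol$mu_t)))
  expect_lt(cc$sol$mass_imbalance, 1e-3)
})

test_that("mirror symmetry holds to within 1% of peak speed", {
  # stations span the cavity and bladder, where the observables live; the
  # thin jet shear layer in the axially stretched distal channel shows
  # larger (few percent) asymmetry on the unstructured discretization
  cc <- fix_cats1_coarse()
  peak <- max(sqrt(cc$sol$u_node^2 + cc$sol$v_node^2))
  for (station in c(16, 17.5, 21)) {
    pr <- velocity_profile(cc$sol, cc$mesh, station)
    mirrored <- approx(-pr$x, pr$v_axial, xout = pr$x, rule = 2)$y
    expect_lt(max(abs(pr$v_axial - mirrored)) / peak, 0.01,
              label = sprintf("asymmetry at station %.1f cm", station))
  }
})
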
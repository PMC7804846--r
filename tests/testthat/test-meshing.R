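test_that("triangulation honours the mesh contract", {
  dom <- fix_cats1_domain()
  mesh <- triangulate(dom, 5000)
  # element budget within +/-15%
  expect_lt(abs(mesh$n_elements - 5000) / 5000, 0.15)
  # positive orientation everywhere
  areas <- catsflow:::triangle_areas(mesh$nodes, mesh$triangles)
  expect_true(all(areas > 0))
  # quality floor
  expect_gte(min(mesh$quality), 15)
  # triangulated area equals the area enclosed by the mesh's own boundary loop
  # (exact consistency of the triangulation)
  lens <- catsflow:::boundary_tag_lengths(mesh)
  expect_equal(unname(lens[["inlet"]]), 0.100, tolerance = 1e-9)
  expect_equal(unname(lens[["outlet"]]), 0.006, tolerance = 1e-9)
  # mesh area matches the analytic domain area to discretization accuracy
  yy <- seq(0, dom$landmarks[["y_in"]], length.out = 20000)
  area_cm2 <- sum(2 * dom$halfwidth(pmin(yy, dom$landmarks[["y_in"]] - 1e-12))) *
    (yy[2] - yy[1])
  expect_equal(sum(areas), area_cm2 * 1e-4, tolerance = 2e-3)
  # every boundary edge belongs to exactly one triangle
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tri_edges <- rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3],
                     mesh$triangles[, c(3, 1)])
  counts <- table(key(tri_edges))
  expect_true(all(counts[key(mesh$boundary_edges)] == 1))
})

test_that("meshing is deterministic and resolves the distal channel", {
  dom <- fix_cats1_domain()
  m1 <- triangulate(dom, 4000, seed = 7L)
  m2 <- triangulate(dom, 4000, seed = 7L)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$triangles, m2$triangles)
  # >= 8 elements across the 0.6 cm channel: a horizontal cut through the
  # distal channel crosses roughly two edges per cell plus one
  te <- rbind(m1$triangles[, 1:2], m1$triangles[, 2:3], m1$triangles[, c(3, 1)])
  te <- te[te[, 1] < te[, 2], ]
  te <- te[!duplicated(te), ]
  ym <- 0.0512345   # off any mesh row
  y1 <- m1$nodes[te[, 1], 2]; y2 <- m1$nodes[te[, 2], 2]
  crossings <- sum((y1 - ym) * (y2 - ym) < 0)
  expect_gte(floor(crossings / 2), 8)
})

test_that("budget ladder lands inside the study's window at 25k", {
  dom <- fix_cats1_domain()
  mesh <- triangulate(dom, 25000)
  expect_gt(mesh$n_elements, 18000)
  expect_lt(mesh$n_elements, 35000)
  expect_gte(min(mesh$quality), 15)
})

test_that("channel domains mesh cleanly for validation runs", {
  p <- fix_poiseuille()
  expect_gte(min(p$mesh$quality), 15)
  lens <- catsflow:::boundary_tag_lengths(p$mesh)
  expect_equal(unname(lens[["inlet"]]), 0.006, tolerance = 1e-9)
})

test_that("grid independence report flags deltas between consecutive budgets", {
  gs <- fix_gridstudy()
  expect_equal(nrow(gs), 4L)
  expect_true(all(gs$converged))
  expect_true(all(is.na(gs[1, c("d_mv_euo_pct", "d_td_v_pct")])))
  expect_true(all(gs$d_mv_euo_pct[-1] >= 0))
  # refinement self-consistency between the coarsest and finest budget
  expect_lt(abs(gs$mv_euo[4] - gs$mv_euo[1]) / gs$mv_euo[1], 0.05)
})
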
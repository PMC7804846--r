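test_that("case construction validates the anatomical invariants", {
  s <- make_case(3.8, 3.0, 4.2)
  expect_s3_class(s, "cats_spec")
  expect_equal(s$bladder_d, 10.0)
  expect_equal(s$ru_d, 0.6)
  expect_equal(s$ru_len, 15.7)
  # boundary of td_pu >= ru_d is admissible
  expect_s3_class(make_case(3.8, 3.0, 0.6), "cats_spec")
  expect_error(make_case(3.8, 0.5, 4.2), "ru_d < td_bn")
  expect_error(make_case(3.8, 3.0, 0.5), "td_pu >= ru_d")
  expect_error(make_case(3.8, 12.0, 4.2), "bladder_d > td_bn")
  expect_error(make_case(-1, 3.0, 4.2), "> 0")
})

test_that("amplification array enumerates the 3 x 5 x 14 design", {
  arr <- amplification_array()
  expect_length(arr, 210)
  man <- case_manifest(arr)
  expect_equal(as.integer(table(man$ld_pu)), c(70L, 70L, 70L))
  expect_setequal(unique(man$td_bn), c(2.6, 2.8, 3.0, 3.2, 3.4))
  sub <- man[man$ld_pu == 3.8 & man$td_bn == 3.0, ]
  expect_equal(sort(sub$td_pu), seq(2.0, 4.6, by = 0.2))
  expect_true("II-C-4.2" %in% man$case_id)
  # deterministic enumeration
  expect_identical(case_manifest(amplification_array()), man)
})

test_that("diameter ratios follow their definitions and unit convention", {
  r <- rpu_ratios(make_case(3.8, 3.0, 4.2))
  expect_equal(r[["rpu1"]], 1.4)
  expect_equal(r[["rpu2"]], 1.4 / 38)     # LD-PU in millimetres
  expect_equal(rpu_ratios(make_case(3.8, 3.0, 3.0))[["rpu1"]], 1)
  # monotonicity: rpu1 increases with td_pu at fixed td_bn; rpu2 decreases
  # with ld_pu at fixed widths
  r1 <- sapply(seq(2.0, 4.6, 0.2), function(tp)
    rpu_ratios(make_case(3.8, 3.0, tp))[["rpu1"]])
  expect_true(all(diff(r1) > 0))
  r2 <- sapply(c(3.6, 3.8, 4.0), function(ld)
    rpu_ratios(make_case(ld, 3.0, 4.2))[["rpu2"]])
  expect_true(all(diff(r2) < 0))
})

test_that("PU wall curves satisfy the three width constraints", {
  # index case: elliptical bulge
  pr <- pu_wall_profile(cats1_spec())
  expect_equal(pr$family, "ellipse")
  expect_equal(2 * pr$right$x[1L], 0.6, tolerance = 1e-9)          # apex plane
  expect_equal(2 * pr$right$x[nrow(pr$right)], 3.0, tolerance = 1e-9)  # BN plane
  expect_equal(pr$max_width, 4.2, tolerance = 1e-9)
  expect_equal(max(2 * pr$right$x), 4.2, tolerance = 1e-3)
  # mirror symmetry
  expect_equal(pr$left$x, -pr$right$x, tolerance = 1e-9)
  # trapezoid-limit case: conic through the mid-height constraint, widest at BN
  pr2 <- pu_wall_profile(make_case(3.8, 3.4, 2.0))
  expect_equal(pr2$family, "conic")
  expect_true(all(diff(pr2$right$x) >= -1e-12))   # monotone toward BN
  expect_equal(max(2 * pr2$right$x), 3.4, tolerance = 1e-9)
  mid <- (nrow(pr2$right) + 1L) / 2
  expect_equal(2 * pr2$right$x[mid], 2.0, tolerance = 1e-6)
  # narrower-than-neck case: circular belly joined tangentially to the planes
  pr3 <- pu_wall_profile(make_case(3.8, 3.0, 2.8), n = 401L)
  expect_equal(pr3$family, "sphere")
  expect_equal(2 * pr3$right$x[401], 3.0, tolerance = 1e-9)     # BN plane
  expect_equal(2 * pr3$right$x[1], 0.6, tolerance = 1e-9)       # apex plane
  expect_equal(2 * pr3$right$x[201], 2.8, tolerance = 0.02)     # mid-height
  # the belly protrudes beyond the straight BN-to-apex taper
  taper <- 0.3 + (1.5 - 0.3) * (200 / 400)
  expect_gt(pr3$right$x[201], taper)
  # single-valued in y
  expect_true(all(diff(pr$right$y) > 0))
})

test_that("assembled domains are simple, tagged and symmetric", {
  dom <- fix_cats1_domain()
  lens <- tapply(
    sqrt(diff(c(dom$boundary$x, dom$boundary$x[1]))^2 +
         diff(c(dom$boundary$y, dom$boundary$y[1]))^2),
    dom$tag, sum)
  expect_equal(unname(lens[["inlet"]]), 10.0, tolerance = 1e-9)
  expect_equal(unname(lens[["outlet"]]), 0.6, tolerance = 1e-9)
  # exactly one contiguous run each
  r <- rle(dom$tag)
  expect_equal(sum(r$values == "inlet"), 1L)
  expect_equal(sum(r$values == "outlet"), 1L)
  # total vertical extent: half bladder + PU + distal channel
  expect_equal(diff(range(dom$boundary$y)), 5.0 + 3.8 + 15.7, tolerance = 1e-9)
  # mirror symmetry of the width function
  yy <- seq(1e-6, dom$landmarks[["y_in"]] - 1e-6, length.out = 200)
  expect_true(all(dom$halfwidth(yy) > 0))
  # simplicity via a direct O(n^2) segment-intersection scan (decimated)
  dec <- dom$boundary[seq(1, nrow(dom$boundary), by = 3), ]
  expect_true(catsflow:::is_simple_polygon(dec))
})

test_that("every spec in the amplification array yields a valid domain", {
  arr <- amplification_array()
  ok <- vapply(arr, function(s) {
    d <- assemble_domain(s)
    yy <- seq(1e-6, d$landmarks[["y_in"]] - 1e-6, length.out = 100)
    all(d$halfwidth(yy) > 0)
  }, logical(1))
  expect_true(all(ok))
})
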
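test_that("Mann-Whitney exact path agrees with brute-force enumeration", {
  # frozen hand-checked case: complete separation of {1,2,3} and {4,5,6}
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)     # 2 of the 20 arrangements are as extreme
  expect_equal(mw$method, "exact")
  # randomized small samples, with and without ties
  set.seed(42)
  for (i in 1:12) {
    a <- sample(1:8, sample(3:6, 1), replace = TRUE)
    b <- sample(2:9, sample(3:8, 1), replace = TRUE)
    got <- mann_whitney_u(a, b)
    ref <- enum_mw(a, b)
    expect_equal(got$U, ref$U, label = sprintf("U case %d", i))
    expect_equal(got$p, ref$p, tolerance = 1e-12,
                 label = sprintf("p case %d", i))
  }
})

test_that("Mann-Whitney normal approximation matches the reference route", {
  set.seed(7)
  a <- rnorm(30); b <- rnorm(25, mean = 0.8)
  got <- mann_whitney_u(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = FALSE))
  expect_equal(got$method, "normal")
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # heavy ties exercise the tie correction
  a2 <- rep(1:3, each = 8); b2 <- rep(2:4, each = 7)
  got2 <- mann_whitney_u(a2, b2)
  ref2 <- suppressWarnings(stats::wilcox.test(a2, b2, exact = FALSE,
                                              correct = FALSE))
  expect_equal(got2$p, ref2$p.value, tolerance = 1e-10)
  # degenerate: everything tied
  expect_equal(mann_whitney_u(rep(1, 5), rep(1, 9))$p, 1)
})

mock_results <- function() {
  arr <- amplification_array()
  man <- case_manifest(arr)
  # synthetic but structured: vortex iff rpu1 > 0.8; td_v linear in rpu1;
  # mv_euo decreasing in rpu1 with deterministic jitter
  man$converged <- TRUE
  man$vortex <- man$rpu1 > 0.8
  man$td_v <- ifelse(man$vortex, 2.0 * man$rpu1 - 1.5, NA)
  man$ld_v <- ifelse(man$vortex, 3.0 * man$rpu1 - 2.0, NA)
  man$mv_euo <- 3.2 - 0.3 * man$rpu1 + 0.001 * sin(seq_len(nrow(man)))
  man$vortex_left <- man$vortex
  man$vortex_right <- man$vortex
  man$elements <- 2000L
  man$iterations <- 100L
  man$mass_imbalance <- 1e-5
  man
}

test_that("group summaries satisfy the counting and ordering invariants", {
  res <- mock_results()
  summ <- summarize_groups(res)
  cn <- summ$counts
  expect_setequal(cn$group, c("I", "II", "III", "All"))
  expect_equal(cn$n[cn$group == "All"], 210)
  expect_equal(sum(cn$n[cn$group != "All"]), 210)
  expect_equal(cn$vortex_n + cn$nonvortex_n, cn$n)
  expect_equal(cn$vortex_pct, 100 * cn$vortex_n / cn$n)
  # IQR ordering: q1 <= median <= q3 everywhere
  expect_true(all(summ$stats$q1 <= summ$stats$median + 1e-12))
  expect_true(all(summ$stats$median <= summ$stats$q3 + 1e-12))
  # a stratum of identical values collapses its IQR
  res2 <- res; res2$mv_euo <- 2.5
  s2 <- summarize_groups(res2)
  mv <- s2$stats[s2$stats$variable == "mv_euo", ]
  expect_true(all(mv$median == 2.5 & mv$q1 == 2.5 & mv$q3 == 2.5))
  # empty stratum omitted, not zero-filled
  res3 <- res; res3$vortex <- TRUE
  s3 <- summarize_groups(res3)
  expect_false(any(s3$stats$stratum == "nonvortex"))
})

test_that("TD-V regression recovers known coefficients", {
  res <- mock_results()
  # exactly linear synthetic data: R^2 = 1, slope 2.0
  fit <- regress_tdv(res, "rpu1")
  expect_equal(fit$slope, rep(2.0, 4), tolerance = 1e-9)
  expect_equal(fit$r2, rep(1, 4), tolerance = 1e-9)
  # slope recovery under small noise
  res$td_v <- res$td_v + 0.01 * sin(7 * seq_len(nrow(res)))
  fit2 <- regress_tdv(res, "rpu1")
  expect_equal(fit2$slope[fit2$group == "All"], 2.0, tolerance = 0.05)
  # too-few points flagged
  few <- res[res$vortex, ][1:2, ]
  fit3 <- regress_tdv(few, "rpu1")
  expect_true(all(is.na(fit3$slope)))
})

test_that("vortex thresholds report minima and bracketing context", {
  res <- mock_results()
  th <- vortex_thresholds(res)
  expect_equal(th$min_rpu1, min(res$rpu1[res$vortex]))
  expect_equal(th$min_rpu2, min(res$rpu2[res$vortex]))
  expect_lt(th$max_nonvortex_rpu1, 0.8 + 1e-12)
  expect_equal(th$n_vortex + th$n_nonvortex, 210)
  # degenerate: all cases vortex-positive -> minima are the array's minima
  res2 <- res; res2$vortex <- TRUE
  th2 <- vortex_thresholds(res2)
  expect_equal(th2$min_rpu1, min(res$rpu1))
  # degenerate: no vortex cases -> flagged absent result
  res3 <- res; res3$vortex <- FALSE
  th3 <- vortex_thresholds(res3)
  expect_true(th3$flagged)
  expect_true(is.na(th3$min_rpu1))
})

test_that("run_cohort records failures without dropping cases", {
  specs <- list(cats1_spec(), make_case(3.8, 3.0, 2.2, case_id = "II-C-2.2"))
  res <- run_cohort(specs, cfg = cohort_numerics(max_iter = 30L))
  expect_equal(nrow(res), 2L)
  expect_false(any(res$converged))
  expect_true(all(is.na(res$mv_euo)))
})
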
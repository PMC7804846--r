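# Batch execution over the amplification array and the cohort statistics:
# group summaries, Mann-Whitney comparison of vortex vs non-vortex cases,
# TD-V ~ RPU regressions and the vortex-threshold extraction.

#' Run the solver over a collection of cases
#'
#' One CaseResult row per spec; geometry, meshing or solver failures are
#' recorded per case (flagged non-converged, error message kept) and never
#' silently dropped. Execution is deterministic given the configuration.
#'
#' @param specs List of `cats_spec` (e.g. [amplification_array()]).
#' @param cfg [numerics_config()]; defaults to the desk-scale
#'   [cohort_numerics()] profile.
#' @param element_budget Mesh element budget per case.
#' @param fluid,bc Fluid and boundary settings.
#' @param verbose Print one progress line per case.
#' @return data.frame of case results with attribute `"errors"` (named list
#'   of failure messages, empty when all cases ran).
#' @export
run_cohort <- function(specs, cfg = cohort_numerics(), element_budget = 3000,
                       fluid = fluid_properties(), bc = boundary_set(),
                       verbose = FALSE) {
  if (inherits(specs, "cats_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1)
  errors <- list()
  rows <- lapply(specs, function(s) {
    res <- tryCatch({
      dom <- assemble_domain(s)
      mesh <- triangulate(dom, element_budget)
      sol <- solve_with_retry(mesh, fluid, bc, cfg, init = dom)
      summarize_case(s, sol, mesh, dom)
    }, error = function(e) {
      errors[[s$case_id]] <<- conditionMessage(e)
      r <- rpu_ratios(s)
      data.frame(case_id = s$case_id, ld_pu = s$ld_pu, td_bn = s$td_bn,
                 td_pu = s$td_pu, rpu1 = r[["rpu1"]], rpu2 = r[["rpu2"]],
                 converged = FALSE, elements = NA_integer_,
                 iterations = NA_integer_, mass_imbalance = NA_real_,
                 mv_euo = NA_real_, vortex = NA, vortex_left = NA,
                 vortex_right = NA, td_v = NA_real_, ld_v = NA_real_,
                 stringsAsFactors = FALSE)
    })
    if (verbose)
      message(sprintf("%-12s conv=%s vortex=%s mv_euo=%.3f td_v=%.2f",
                      res$case_id, res$converged,
                      res$vortex, res$mv_euo, res$td_v))
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "errors") <- errors
  out
}

# group label from LD-PU: roman numerals in ascending LD-PU order
cohort_groups <- function(results) {
  lev <- sort(unique(results$ld_pu))
  as.character(utils::as.roman(match(results$ld_pu, lev)))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. Exact permutation enumeration (with midranks for
#' ties) when the smaller sample has at most 8 observations; otherwise the
#' tie-corrected normal approximation without continuity correction.
#'
#' @param sample_a,sample_b Numeric samples.
#' @return List: `U` (for `sample_a`), `p`, `method`, and `all_tied`.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  a <- sample_a[!is.na(sample_a)]; b <- sample_b[!is.na(sample_b)]
  if (!length(a) || !length(b)) stop("both samples must be nonempty", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(U = U, p = 1, method = "degenerate", all_tied = TRUE))
  if (min(na, nb) <= 8 && choose(n, na) <= 500000) {
    idx <- utils::combn(n, na)
    Us <- colSums(matrix(rk[idx], nrow = na)) - na * (na + 1) / 2
    m <- na * nb
    lo <- min(U, m - U); hi <- max(U, m - U)
    tol <- 1e-9
    p <- (sum(Us <= lo + tol) + sum(Us >= hi - tol)) / length(Us)
    if (lo == hi) p <- min(1, p)   # centre value counted twice
    list(U = U, p = min(1, p), method = "exact", all_tied = FALSE)
  } else {
    ties <- table(pooled)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - na * nb / 2) / sqrt(sig2)
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal",
         all_tied = FALSE)
  }
}

#' Regress vortex transverse diameter on a diameter ratio
#'
#' Ordinary least squares of TD-V on RPU-1 or RPU-2 over the vortex-positive
#' converged cases, per LD-PU group and overall.
#'
#' @param results A [run_cohort()] table.
#' @param which_rpu `"rpu1"` or `"rpu2"`.
#' @return data.frame: group, n, slope, intercept, r2 (NA when fewer than
#'   three points).
#' @export
regress_tdv <- function(results, which_rpu = c("rpu1", "rpu2")) {
  which_rpu <- match.arg(which_rpu)
  res <- results[results$converged & !is.na(results$vortex) & results$vortex &
                   !is.na(results$td_v), , drop = FALSE]
  grp <- cohort_groups(res)
  fit1 <- function(d) {
    if (nrow(d) < 3)
      return(data.frame(n = nrow(d), slope = NA_real_, intercept = NA_real_,
                        r2 = NA_real_))
    m <- stats::lm(td_v ~ x, data = data.frame(td_v = d$td_v, x = d[[which_rpu]]))
    data.frame(n = nrow(d), slope = coef(m)[[2L]], intercept = coef(m)[[1L]],
               r2 = summary(m)$r.squared)
  }
  groups <- c(sort(unique(grp)), "All")
  out <- do.call(rbind, lapply(groups, function(g) {
    d <- if (g == "All") res else res[grp == g, , drop = FALSE]
    cbind(data.frame(group = g, rpu = which_rpu), fit1(d))
  }))
  rownames(out) <- NULL
  out
}

#' Minimum diameter ratios among vortex-positive cases
#'
#' The cohort-level vortex thresholds: the smallest RPU-1 and RPU-2 at which
#' a recirculation zone is still present, with the largest non-vortex ratios
#' for context.
#'
#' @param results A [run_cohort()] table.
#' @return List: `min_rpu1`, `min_rpu2`, `max_nonvortex_rpu1`,
#'   `max_nonvortex_rpu2`, `n_vortex`, `n_nonvortex`.
#' @export
vortex_thresholds <- function(results) {
  conv <- results[results$converged & !is.na(results$vortex), , drop = FALSE]
  vx <- conv[conv$vortex, , drop = FALSE]
  nv <- conv[!conv$vortex, , drop = FALSE]
  if (!nrow(vx))
    return(list(min_rpu1 = NA_real_, min_rpu2 = NA_real_,
                max_nonvortex_rpu1 = if (nrow(nv)) max(nv$rpu1) else NA_real_,
                max_nonvortex_rpu2 = if (nrow(nv)) max(nv$rpu2) else NA_real_,
                n_vortex = 0L, n_nonvortex = nrow(nv), flagged = TRUE))
  list(min_rpu1 = min(vx$rpu1), min_rpu2 = min(vx$rpu2),
       max_nonvortex_rpu1 = if (nrow(nv)) max(nv$rpu1) else NA_real_,
       max_nonvortex_rpu2 = if (nrow(nv)) max(nv$rpu2) else NA_real_,
       n_vortex = nrow(vx), n_nonvortex = nrow(nv), flagged = FALSE)
}

#' Cohort summary in the shape of the study's characteristics table
#'
#' Counts, medians and interquartile ranges (linear-interpolation quantiles,
#' type 7) of TD-V, RPU-1, RPU-2 and MV-EUO split by vortex status, per
#' LD-PU group and overall, plus Mann-Whitney comparisons of MV-EUO between
#' vortex and non-vortex cases, TD-V ~ RPU regressions, and the minimum
#' vortex ratios. TD-V is reported in millimetres, as in the study table.
#' Empty strata are omitted, not zero-filled; non-converged cases are
#' excluded from statistics and counted in `$quality`.
#'
#' @param results A [run_cohort()] table.
#' @return A `cohort_summary` list: `counts`, `stats`, `tests`,
#'   `regressions`, `thresholds`, `quality`.
#' @export
summarize_groups <- function(results) {
  stopifnot(nrow(results) >= 1)
  conv <- results[results$converged & !is.na(results$vortex), , drop = FALSE]
  grp <- cohort_groups(conv)
  groups <- c(sort(unique(grp)), "All")
  q3 <- function(x) stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  counts <- do.call(rbind, lapply(groups, function(g) {
    d <- if (g == "All") conv else conv[grp == g, , drop = FALSE]
    data.frame(group = g, n = nrow(d), vortex_n = sum(d$vortex),
               vortex_pct = 100 * mean(d$vortex),
               nonvortex_n = sum(!d$vortex),
               nonvortex_pct = 100 * mean(!d$vortex))
  }))
  strata <- list(
    c(var = "td_v_mm", stratum = "vortex"),
    c(var = "rpu1", stratum = "vortex"), c(var = "rpu1", stratum = "nonvortex"),
    c(var = "rpu2", stratum = "vortex"), c(var = "rpu2", stratum = "nonvortex"),
    c(var = "mv_euo", stratum = "vortex"), c(var = "mv_euo", stratum = "nonvortex"))
  stats_rows <- list()
  for (g in groups) {
    d <- if (g == "All") conv else conv[grp == g, , drop = FALSE]
    for (s in strata) {
      dd <- if (s[["stratum"]] == "vortex") d[d$vortex, , drop = FALSE]
            else d[!d$vortex, , drop = FALSE]
      x <- switch(s[["var"]], td_v_mm = 10 * dd$td_v, dd[[s[["var"]]]])
      x <- x[!is.na(x)]
      if (!length(x)) next
      qq <- q3(x)
      stats_rows[[length(stats_rows) + 1L]] <-
        data.frame(group = g, variable = s[["var"]], stratum = s[["stratum"]],
                   n = length(x), median = qq[1L], q1 = qq[2L], q3 = qq[3L])
    }
  }
  tests <- do.call(rbind, lapply(groups, function(g) {
    d <- if (g == "All") conv else conv[grp == g, , drop = FALSE]
    a <- d$mv_euo[d$vortex]; b <- d$mv_euo[!d$vortex]
    if (!length(a) || !length(b))
      return(data.frame(group = g, U = NA_real_, p = NA_real_,
                        method = "empty stratum"))
    mw <- mann_whitney_u(a, b)
    data.frame(group = g, U = mw$U, p = mw$p, method = mw$method)
  }))
  structure(list(counts = counts, stats = do.call(rbind, stats_rows),
                 tests = tests,
                 regressions = rbind(regress_tdv(results, "rpu1"),
                                     regress_tdv(results, "rpu2")),
                 thresholds = vortex_thresholds(results),
                 quality = list(n_total = nrow(results),
                                n_converged = nrow(conv),
                                n_nonconverged = nrow(results) - nrow(conv))),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n==============\n")
  print(x$counts, row.names = FALSE)
  cat("\nMedians (IQR):\n")
  print(x$stats, row.names = FALSE, digits = 4)
  cat("\nMV-EUO vortex vs non-vortex (Mann-Whitney):\n")
  print(x$tests, row.names = FALSE, digits = 4)
  th <- x$thresholds
  cat(sprintf("\nMinimum vortex ratios: RPU-1 %.3f, RPU-2 %.4f (%d vortex / %d non-vortex)\n",
              th$min_rpu1, th$min_rpu2, th$n_vortex, th$n_nonvortex))
  if (x$quality$n_nonconverged > 0)
    cat(sprintf("NOTE: %d case(s) did not converge and were excluded.\n",
                x$quality$n_nonconverged))
  invisible(x)
}
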
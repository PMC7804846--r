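#' @useDynLib catsflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile lm coef pnorm approx setNames
#' @importFrom utils write.csv read.csv packageVersion
NULL

# Fixed anatomical constants (cm). The lower half of the bladder is 10.0 cm
# across, the distal urethra (RU) is a 0.6 cm x 15.7 cm channel.
.BLADDER_D <- 10.0
.RU_D <- 0.6
.RU_LEN <- 15.7

#' Define one idealized post-surgery lower-urinary-tract case
#'
#' A case is fully determined by the three diameters that transurethral surgery
#' changes: the longitudinal diameter of the prostatic urethra (LD-PU, midpoint
#' of the bladder-neck plane to midpoint of the prostate-apex plane), the
#' transverse diameter of the bladder neck (TD-BN) and the transverse diameter
#' of the prostatic urethra (TD-PU). The bladder (10.0 cm), distal urethra
#' width (0.6 cm) and distal urethra length (15.7 cm) are fixed anatomical
#' constants.
#'
#' @param ld_pu Longitudinal diameter of the PU, cm.
#' @param td_bn Transverse diameter of the bladder neck, cm.
#' @param td_pu Transverse diameter of the PU, cm.
#' @param case_id Optional label; generated from the dimensions when `NULL`.
#' @return An object of class `cats_spec`.
#' @examples
#' cats1 <- make_case(3.8, 3.0, 4.2)  # the index case
#' rpu_ratios(cats1)
#' @export
make_case <- function(ld_pu, td_bn, td_pu, case_id = NULL) {
  stopifnot(is.numeric(ld_pu), is.numeric(td_bn), is.numeric(td_pu),
            length(ld_pu) == 1L, length(td_bn) == 1L, length(td_pu) == 1L)
  if (!(ld_pu > 0 && td_bn > 0 && td_pu > 0))
    stop("invariant violated: all lengths must be > 0", call. = FALSE)
  if (!(.RU_D < td_bn))
    stop(sprintf("invariant violated: ru_d < td_bn (ru_d = %.2f, td_bn = %.2f)",
                 .RU_D, td_bn), call. = FALSE)
  if (!(td_pu >= .RU_D))
    stop(sprintf("invariant violated: td_pu >= ru_d (td_pu = %.2f, ru_d = %.2f)",
                 td_pu, .RU_D), call. = FALSE)
  if (!(.BLADDER_D > td_bn))
    stop(sprintf("invariant violated: bladder_d > td_bn (td_bn = %.2f)", td_bn),
         call. = FALSE)
  if (is.null(case_id))
    case_id <- sprintf("case_%.1f_%.1f_%.1f", ld_pu, td_bn, td_pu)
  structure(list(ld_pu = ld_pu, td_bn = td_bn, td_pu = td_pu,
                 bladder_d = .BLADDER_D, ru_d = .RU_D, ru_len = .RU_LEN,
                 case_id = case_id),
            class = "cats_spec")
}

#' @export
print.cats_spec <- function(x, ...) {
  cat(sprintf("<cats_spec %s>  LD-PU %.1f  TD-BN %.1f  TD-PU %.1f cm  (RPU-1 %.3f, RPU-2 %.4f)\n",
              x$case_id, x$ld_pu, x$td_bn, x$td_pu,
              rpu_ratios(x)[["rpu1"]], rpu_ratios(x)[["rpu2"]]))
  invisible(x)
}

#' Enumerate the 210-case amplification array
#'
#' The parametric cohort is a \[3\]\[5\]\[14\] array: three LD-PU groups
#' (I: 3.6, II: 3.8, III: 4.0 cm), five TD-BN subgroups (A: 2.6 ... E: 3.4 cm)
#' and fourteen TD-PU values (2.0 to 4.6 cm in 0.2 cm steps). The index case
#' sits at (II, C, TD-PU = 4.2). The enumeration is deterministic: group, then
#' subgroup, then TD-PU, each ascending.
#'
#' @return A list of 210 [make_case()] specs with ids like `"II-C-4.2"`.
#' @export
amplification_array <- function() {
  groups <- c(I = 3.6, II = 3.8, III = 4.0)
  subgroups <- c(A = 2.6, B = 2.8, C = 3.0, D = 3.2, E = 3.4)
  td_pu_vals <- seq(20L, 46L, by = 2L) / 10
  out <- vector("list", length(groups) * length(subgroups) * length(td_pu_vals))
  i <- 0L
  for (g in names(groups)) for (s in names(subgroups)) for (tp in td_pu_vals) {
    i <- i + 1L
    out[[i]] <- make_case(groups[[g]], subgroups[[s]], tp,
                          case_id = sprintf("%s-%s-%.1f", g, s, tp))
  }
  out
}

#' Diameter ratios of the prostatic urethra
#'
#' RPU-1 = TD-PU / TD-BN (dimensionless); RPU-2 = RPU-1 / LD-PU with LD-PU in
#' millimetres, which puts RPU-2 on the 0.01-0.05 scale on which the cohort
#' threshold of 0.02 lives.
#'
#' @param spec A `cats_spec`.
#' @return Named numeric vector `c(rpu1, rpu2)`.
#' @export
rpu_ratios <- function(spec) {
  stopifnot(inherits(spec, "cats_spec"))
  rpu1 <- spec$td_pu / spec$td_bn
  c(rpu1 = rpu1, rpu2 = rpu1 / (spec$ld_pu * 10))
}

# Axial landmarks of a case, cm from the outlet: y = 0 outlet, y_ap prostate
# apex plane, y_bn bladder-neck plane, y_in inlet chord.
case_landmarks <- function(spec) {
  y_ap <- spec$ru_len
  y_bn <- y_ap + spec$ld_pu
  y_in <- y_bn + spec$bladder_d / 2
  c(y_out = 0, y_ap = y_ap, y_bn = y_bn, y_in = y_in)
}

# Half-width (cm) of the PU lumen as a function of height y (cm) above the
# apex plane, plus metadata about the curve family used.
pu_halfwidth_fun <- function(spec) {
  ld <- spec$ld_pu
  xa <- spec$ru_d / 2          # apex-plane half-opening
  xb <- spec$td_bn / 2         # BN-plane half-opening
  xm <- spec$td_pu / 2         # controlled half-width
  if (spec$td_pu > spec$td_bn) {
    # Bulging cavity: elliptical arc (near-sphere truncated by the BN and
    # apex planes), widest point td_pu/2 at height y0 inside the PU.
    su <- 1 - (xb / xm)^2
    sv <- 1 - (xa / xm)^2
    if (sv <= 0)
      stop("no PU curve satisfies the width constraints: td_pu <= ru_d", call. = FALSE)
    B <- ld / (sqrt(su) + sqrt(sv))
    y0 <- ld - B * sqrt(su)    # height of the widest station above the apex
    f <- function(t) xm * sqrt(pmax(0, 1 - ((t - y0) / B)^2))
    list(f = f, family = "ellipse", y_widest = y0, max_halfwidth = xm)
  } else if (xm > (xa + xb) / 2 + 1e-9) {
    # Narrower than the neck but still wider at mid-height than the straight
    # trapezoid: a near-spherical belly — a circular arc of diameter td_pu
    # centred at mid-height, joined tangentially to the BN and apex plane
    # openings by straight segments.
    R <- xm
    y0 <- ld / 2
    tangent_pt <- function(px, py) {
      dx <- px; dy <- py - y0
      d2 <- dx^2 + dy^2
      L <- sqrt(max(d2 - R^2, 0))
      base_x <- R^2 / d2 * dx; base_y <- y0 + R^2 / d2 * dy
      off_x <- R * L / d2 * (-dy); off_y <- R * L / d2 * dx
      t1 <- c(base_x + off_x, base_y + off_y)
      t2 <- c(base_x - off_x, base_y - off_y)
      if (t1[1L] >= t2[1L]) t1 else t2     # outermost: the wall wraps the
    }                                      # right side of the circle
    tB <- tangent_pt(xb, ld)               # from the BN opening
    tA <- tangent_pt(xa, 0)                # from the apex opening
    # the wall is the right boundary of the convex hull of the two plane
    # openings and the circle; the tangency points may sit on either side of
    # mid-height, but must be ordered and interior
    if (!(tA[2L] < tB[2L] && tB[2L] < ld && tA[2L] > 0))
      stop("no PU curve satisfies the width constraints: tangent construction degenerate",
           call. = FALSE)
    f <- function(t) {
      x <- numeric(length(t))
      up <- t >= tB[2L]
      lo <- t <= tA[2L]
      mid <- !up & !lo
      x[up] <- tB[1L] + (xb - tB[1L]) * (t[up] - tB[2L]) / (ld - tB[2L])
      x[lo] <- xa + (tA[1L] - xa) * t[lo] / tA[2L]
      x[mid] <- sqrt(pmax(0, R^2 - (t[mid] - y0)^2))
      x
    }
    list(f = f, family = "sphere", y_widest = y0, max_halfwidth = max(xb, R))
  } else {
    # Heavily tapered: conic (parabolic) arc through the apex, mid-height and
    # BN width constraints, monotone and single-valued in y.
    a <- 4 * xm - 3 * xa - xb
    b <- 2 * xa + 2 * xb - 4 * xm
    if (a < 0)
      stop(paste0("no PU curve satisfies the width constraints: mid-height ",
                  "width too small for a monotone conic arc"), call. = FALSE)
    f <- function(t) { s <- t / ld; xa + a * s + b * s^2 }
    y_w <- if (b < 0 && a / (-2 * b) < 1) ld * a / (-2 * b) else ld
    list(f = f, family = "conic", y_widest = y_w, max_halfwidth = f(y_w))
  }
}

# Full half-width profile w(y)/2 of the flow lumen, y in cm from the outlet.
domain_halfwidth_fun <- function(spec) {
  lm <- case_landmarks(spec)
  pu <- pu_halfwidth_fun(spec)
  A <- spec$bladder_d / 2
  # near-hemispheric bladder: half-ellipse meeting the BN opening exactly
  # bladder_d/2 below the inlet chord
  Bv <- A / sqrt(1 - (spec$td_bn / spec$bladder_d)^2)
  xa <- spec$ru_d / 2
  function(y) {
    w <- numeric(length(y))
    in_ru <- y <= lm[["y_ap"]]
    in_pu <- y > lm[["y_ap"]] & y <= lm[["y_bn"]]
    in_bl <- y > lm[["y_bn"]]
    w[in_ru] <- xa
    w[in_pu] <- pu$f(y[in_pu] - lm[["y_ap"]])
    s <- (lm[["y_in"]] - pmin(y[in_bl], lm[["y_in"]])) / Bv
    w[in_bl] <- A * sqrt(pmax(0, 1 - s^2))
    w
  }
}

#' Wall curves of the prostatic urethra
#'
#' Returns the left and right PU wall curves spanning the bladder-neck plane
#' endpoints (+/- TD-BN/2) down to the apex-plane endpoints (+/- 0.3 cm), with
#' vertical extent exactly LD-PU. When TD-PU >= TD-BN the curve is an
#' elliptical arc whose widest point equals TD-PU; when TD-PU < TD-BN it is a
#' conic arc constrained to width TD-PU at the PU mid-height, giving the
#' tapering shapes of heavily resected glands. Both curves are single-valued
#' in the vertical coordinate and exact mirror images.
#'
#' @param spec A `cats_spec`.
#' @param n Number of sample points per curve.
#' @return List with `right` and `left` data frames (`y`, `x` in cm, y measured
#'   from the outlet plane), the curve `family`, the height `y_widest` of the
#'   widest station and `max_width` (cm).
#' @export
pu_wall_profile <- function(spec, n = 201L) {
  stopifnot(inherits(spec, "cats_spec"))
  lm <- case_landmarks(spec)
  pu <- pu_halfwidth_fun(spec)
  y <- seq(lm[["y_ap"]], lm[["y_bn"]], length.out = n)
  x <- pu$f(y - lm[["y_ap"]])
  list(right = data.frame(y = y, x = x),
       left = data.frame(y = y, x = -x),
       family = pu$family,
       y_widest = lm[["y_ap"]] + pu$y_widest,
       max_width = 2 * pu$max_halfwidth)
}

#' Assemble the closed boundary outline of a case
#'
#' Builds the boundary-tagged planar flow domain: top inlet chord (the 10.0 cm
#' bladder equator), near-hemispheric bladder arcs down to the zero-thickness
#' bladder neck, the PU wall curves, the 0.6 x 15.7 cm distal-urethra channel
#' and the bottom outlet segment. The outline is a simple closed polygon,
#' counter-clockwise, mirror-symmetric about the axis x = 0, with exactly one
#' contiguous inlet run (top) and one outlet run (bottom); all other edges are
#' walls.
#'
#' @param spec A `cats_spec`.
#' @param ds Approximate boundary sampling step, cm.
#' @return An object of class `cats_domain`: `boundary` (data frame of `x`, `y`
#'   in cm), `tag` (per-edge, edge i joins vertex i to i+1, wrapping),
#'   `axis` (x location of the symmetry axis), `halfwidth` (function of y, cm),
#'   `landmarks`, and the `spec`.
#' @export
assemble_domain <- function(spec, ds = 0.05) {
  stopifnot(inherits(spec, "cats_spec"), ds > 0)
  lm <- case_landmarks(spec)
  hw <- domain_halfwidth_fun(spec)
  # wall sampled along y, denser than ds along arc-length is unnecessary for
  # the outline: meshing reads `halfwidth` analytically
  n_wall <- max(50L, ceiling(lm[["y_in"]] / ds))
  yw <- seq(0, lm[["y_in"]], length.out = n_wall + 1L)
  # snap the landmark planes into the sample set so corners are exact vertices
  yw <- sort(unique(c(yw, lm[["y_ap"]], lm[["y_bn"]])))
  xw <- hw(yw)
  x_right <- xw
  nw <- length(yw)
  xs <- c(-spec$ru_d / 2, spec$ru_d / 2,            # outlet run endpoints
          x_right[-1L],                             # right wall going up
          rev(-x_right)[-nw])                       # left wall going down (drop
                                                    # the closing outlet vertex)
  ys <- c(0, 0, yw[-1L], rev(yw)[-nw])
  # tags: edge i joins vertex i -> i+1 (wrap).  Edge 1 is the outlet; the edge
  # joining the two inlet-corner vertices (top of right wall -> top of left
  # wall) is the inlet; all others are walls.
  nv <- length(xs)
  tag <- rep("wall", nv)
  tag[1L] <- "outlet"
  tag[1L + nw] <- "inlet"   # vertex index of (+5, y_in) -> next is (-5, y_in)
  dom <- structure(list(boundary = data.frame(x = xs, y = ys),
                        tag = tag, axis = 0,
                        halfwidth = hw, landmarks = lm, spec = spec,
                        type = "cats"),
                   class = "cats_domain")
  chk <- domain_check(dom)
  if (!isTRUE(chk))
    stop("assembled outline rejected: ", chk, call. = FALSE)
  dom
}

#' Straight-channel validation domain
#'
#' A rectangular pressure-driven channel (the distal urethra in isolation by
#' default), used for plane-Poiseuille and streamfunction closed-form checks.
#'
#' @param width Channel width, cm.
#' @param length Channel length, cm.
#' @return A `cats_domain` with `type = "channel"`.
#' @export
channel_domain <- function(width = 0.6, length = 15.7) {
  stopifnot(width > 0, length > 0)
  hw <- local({ w2 <- width / 2; function(y) rep(w2, length(y)) })
  xs <- c(-width / 2, width / 2, width / 2, -width / 2)
  ys <- c(0, 0, length, length)
  tag <- c("outlet", "wall", "inlet", "wall")
  structure(list(boundary = data.frame(x = xs, y = ys), tag = tag, axis = 0,
                 halfwidth = hw,
                 landmarks = c(y_out = 0, y_ap = 0, y_bn = length, y_in = length),
                 spec = NULL, type = "channel"),
            class = "cats_domain")
}

# Validity of a planar domain: positive width everywhere strictly inside,
# simple closed polygon (checked via the single-valued-walls construction plus
# a direct segment-intersection scan on a decimated outline), one inlet run,
# one outlet run, mirror symmetry of the width function.
domain_check <- function(dom, full_intersection_scan = FALSE) {
  lmk <- dom$landmarks
  yy <- seq(1e-9, lmk[["y_in"]] - 1e-9, length.out = 400L)
  if (any(dom$halfwidth(yy) <= 0)) return("non-positive width inside the domain")
  r <- rle(dom$tag)
  runs <- r$values[r$values != "wall"]
  # wrap-around: tags start at the outlet so runs cannot be split across the seam
  if (sum(runs == "inlet") != 1L || sum(runs == "outlet") != 1L)
    return("inlet/outlet runs are not single and contiguous")
  if (full_intersection_scan && !is_simple_polygon(dom$boundary))
    return("self-intersecting outline")
  TRUE
}

# Brute-force O(n^2) segment intersection test on a polygon given as a
# data.frame of vertices. Used on decimated outlines in the test-suite.
is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  x <- poly$x; y <- poly$y
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]          # skip shared-vertex neighbours
    if (!length(js)) next
    d1 <- cross(x[i], y[i], x2[i], y2[i], x[js], y[js])
    d2 <- cross(x[i], y[i], x2[i], y2[i], x2[js], y2[js])
    d3 <- cross(x[js], y[js], x2[js], y2[js], rep(x[i], length(js)), rep(y[i], length(js)))
    d4 <- cross(x[js], y[js], x2[js], y2[js], rep(x2[i], length(js)), rep(y2[i], length(js)))
    hit <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(hit)) return(FALSE)
  }
  TRUE
}

#' @export
print.cats_domain <- function(x, ...) {
  cat(sprintf("<cats_domain %s>  %d boundary vertices, height %.2f cm, inlet %.2f cm, outlet %.2f cm\n",
              if (is.null(x$spec)) x$type else x$spec$case_id,
              nrow(x$boundary), x$landmarks[["y_in"]],
              2 * x$halfwidth(x$landmarks[["y_in"]] - 1e-9),
              2 * x$halfwidth(0)))
  invisible(x)
}

#' Case manifest table
#'
#' One row per spec: id, the three varied diameters and the two ratios.
#'
#' @param specs List of `cats_spec` objects.
#' @return data.frame.
#' @export
case_manifest <- function(specs) {
  if (inherits(specs, "cats_spec")) specs <- list(specs)
  do.call(rbind, lapply(specs, function(s) {
    r <- rpu_ratios(s)
    data.frame(case_id = s$case_id, ld_pu = s$ld_pu, td_bn = s$td_bn,
               td_pu = s$td_pu, rpu1 = r[["rpu1"]], rpu2 = r[["rpu2"]],
               stringsAsFactors = FALSE)
  }))
}
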
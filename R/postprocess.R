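# Observable extraction: outlet midpoint velocity, recirculation-zone
# ("vortex") detection via the streamfunction separatrix, transverse
# velocity profiles, and per-case summaries.

#' Midpoint velocity of the external urethral orifice (MV-EUO)
#'
#' Velocity magnitude linearly interpolated at the geometric midpoint of the
#' outlet segment.
#'
#' @param solution A converged `cats_solution`.
#' @param mesh Its mesh.
#' @return Speed, m/s.
#' @export
mv_euo <- function(solution, mesh) {
  if (!isTRUE(solution$converged))
    stop("mv_euo requires a converged solution", call. = FALSE)
  of <- solution$faces[solution$faces[, "tag"] == 2L, , drop = FALSE]
  if (!nrow(of)) stop("mesh has no outlet faces", call. = FALSE)
  onodes <- unique(c(of[, "n1"], of[, "n2"]))
  xm <- mean(range(mesh$nodes[onodes, 1L]))
  x1 <- mesh$nodes[of[, "n1"], 1L]; x2 <- mesh$nodes[of[, "n2"], 1L]
  hit <- which((x1 - xm) * (x2 - xm) <= 0)
  if (!length(hit))
    stop("outlet midpoint not bracketed by outlet faces (malformed tags)",
         call. = FALSE)
  f <- of[hit[1L], ]
  t <- if (abs(x2[hit[1L]] - x1[hit[1L]]) < 1e-300) 0.5 else
    (xm - x1[hit[1L]]) / (x2[hit[1L]] - x1[hit[1L]])
  sp <- sqrt(solution$u_node^2 + solution$v_node^2)
  (1 - t) * sp[f[["n1"]]] + t * sp[f[["n2"]]]
}

#' Transverse velocity profile at an axial station
#'
#' Samples the signed axial velocity along a horizontal cut. Sample points
#' are the intersections of the cut with mesh edges, so the profile spans
#' the full local width with no-slip zeros at the walls.
#'
#' @param solution A `cats_solution`.
#' @param mesh Its mesh.
#' @param station Axial coordinate of the cut, cm above the outlet plane.
#' @return data.frame with `x` (cm) and `v_axial` (m/s, negative = toward
#'   the outlet).
#' @export
velocity_profile <- function(solution, mesh, station) {
  ym <- station * 0.01
  n1 <- solution$faces[, "n1"]; n2 <- solution$faces[, "n2"]
  y1 <- mesh$nodes[n1, 2L]; y2 <- mesh$nodes[n2, 2L]
  hit <- which((y1 - ym) * (y2 - ym) <= 0 & abs(y1 - y2) > 1e-300)
  if (!length(hit))
    stop("station does not intersect the fluid domain", call. = FALSE)
  t <- (ym - y1[hit]) / (y2[hit] - y1[hit])
  x <- (1 - t) * mesh$nodes[n1[hit], 1L] + t * mesh$nodes[n2[hit], 1L]
  v <- (1 - t) * solution$v_node[n1[hit]] + t * solution$v_node[n2[hit]]
  o <- order(x)
  out <- data.frame(x = x[o] * 100, v_axial = v[o])
  out[!duplicated(round(out$x, 10)), ]
}

# connected components on a node subset, edges given as a 2-column matrix of
# node ids restricted to the subset (simple union-find)
node_components <- function(ids, edges) {
  parent <- seq_along(ids)
  idx <- integer(max(ids)); idx[ids] <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(idx[edges[r, 1L]]); b <- find(idx[edges[r, 2L]])
    if (a != b) parent[b] <- a
  }
  vapply(seq_along(ids), find, integer(1))
}

#' Detect recirculation zones in the prostatic urethra
#'
#' A side vortex is the closed region bounded by the separatrix streamline
#' (psi equal to the adjoining wall level). Nodes strictly beyond the wall
#' psi level inside the PU band are grouped into connected regions; each
#' region's axis-aligned extents give its transverse and longitudinal
#' diameters, measured through the interpolated psi = wall-level crossings
#' for sub-cell accuracy. Regions narrower than two local cell diameters are
#' discarded as numerical noise.
#'
#' @param solution A converged `cats_solution`.
#' @param mesh Its mesh.
#' @param domain The `cats_domain` of the case (provides the PU band).
#' @return A `cats_vortex`: per-side presence and diameters (cm), and the
#'   side-mean transverse (`td_v`) and longitudinal (`ld_v`) diameters.
#' @export
detect_vortices <- function(solution, mesh, domain) {
  if (!isTRUE(solution$converged))
    stop("vortex detection requires a converged solution", call. = FALSE)
  psi <- solution$psi_node
  faces <- solution$faces
  wall <- faces[, "tag"] == 3L
  wn <- unique(c(faces[wall, "n1"], faces[wall, "n2"]))
  left_wall <- wn[mesh$nodes[wn, 1L] < 0]
  right_wall <- wn[mesh$nodes[wn, 1L] > 0]
  psi_L <- stats::median(psi[left_wall])
  psi_R <- stats::median(psi[right_wall])
  Q <- psi_R - psi_L
  sgn <- sign(Q)
  if (sgn == 0) sgn <- 1
  band <- domain$landmarks[c("y_ap", "y_bn")] * 0.01
  ytol <- 1e-9
  nx <- mesh$nodes[, 1L]; ny <- mesh$nodes[, 2L]
  in_band <- ny >= band[1L] - ytol & ny <= band[2L] + ytol
  # local cell scale inside the PU band
  ctr_y <- (ny[mesh$triangles[, 1L]] + ny[mesh$triangles[, 2L]] +
              ny[mesh$triangles[, 3L]]) / 3
  a_pu <- triangle_areas(mesh$nodes, mesh$triangles)[ctr_y >= band[1L] &
                                                       ctr_y <= band[2L]]
  h_loc <- sqrt(2 * stats::median(a_pu))
  side <- function(excess, xsign) {
    sel <- which(excess > 0 & in_band & sign(nx) == xsign)
    empty <- list(present = FALSE, td = NA_real_, ld = NA_real_)
    if (!length(sel)) return(empty)
    inset <- logical(length(psi)); inset[sel] <- TRUE
    e_in <- faces[inset[faces[, "n1"]] & inset[faces[, "n2"]], c("n1", "n2"),
                  drop = FALSE]
    comp <- node_components(sel, e_in)
    best <- list(td = -Inf)
    for (cid in unique(comp)) {
      cn <- sel[comp == cid]
      incomp <- logical(length(psi)); incomp[cn] <- TRUE
      # separatrix crossings on edges leaving the region
      cross <- faces[xor(incomp[faces[, "n1"]], incomp[faces[, "n2"]]), ,
                     drop = FALSE]
      xs <- nx[cn]; ys <- ny[cn]
      if (nrow(cross)) {
        e1 <- excess[cross[, "n1"]]; e2 <- excess[cross[, "n2"]]
        t <- e1 / (e1 - e2)
        t[!is.finite(t)] <- 0.5
        t <- pmin(1, pmax(0, t))
        cx <- (1 - t) * nx[cross[, "n1"]] + t * nx[cross[, "n2"]]
        cy <- (1 - t) * ny[cross[, "n1"]] + t * ny[cross[, "n2"]]
        cy <- pmin(pmax(cy, band[1L]), band[2L])   # clip to the PU band
        xs <- c(xs, cx); ys <- c(ys, cy)
      }
      td <- diff(range(xs)); ld <- diff(range(ys))
      if (td >= 2 * h_loc && td > best$td) best <- list(td = td, ld = ld)
    }
    if (!is.finite(best$td) || best$td < 0) return(empty)
    list(present = TRUE, td = best$td * 100, ld = best$ld * 100)
  }
  delta <- 1e-6 * max(abs(Q), 1e-12)
  right <- side(sgn * (psi - psi_R) - delta, 1)
  left <- side(sgn * (psi_L - psi) - delta, -1)
  present <- c(left$present, right$present)
  td_v <- if (any(present)) mean(c(left$td, right$td), na.rm = TRUE) else NA_real_
  ld_v <- if (any(present)) mean(c(left$ld, right$ld), na.rm = TRUE) else NA_real_
  structure(list(left = left, right = right, vortex = any(present),
                 td_v = td_v, ld_v = ld_v),
            class = "cats_vortex")
}

#' @export
print.cats_vortex <- function(x, ...) {
  if (x$vortex)
    cat(sprintf("<cats_vortex>  present (left %s, right %s), TD-V %.2f cm, LD-V %.2f cm\n",
                x$left$present, x$right$present, x$td_v, x$ld_v))
  else cat("<cats_vortex>  no recirculation detected\n")
  invisible(x)
}

#' Assemble the per-case result record
#'
#' @param spec The case `cats_spec`.
#' @param solution Its `cats_solution`.
#' @param mesh Its mesh.
#' @param domain Optional `cats_domain`; rebuilt from `spec` when missing.
#' @return One-row data.frame (a CaseResult): ids, diameters, ratios,
#'   MV-EUO, vortex flag and diameters, convergence bookkeeping.
#' @export
summarize_case <- function(spec, solution, mesh, domain = NULL) {
  stopifnot(inherits(spec, "cats_spec"))
  if (is.null(domain)) domain <- assemble_domain(spec)
  r <- rpu_ratios(spec)
  if (isTRUE(solution$converged)) {
    vm <- detect_vortices(solution, mesh, domain)
    data.frame(case_id = spec$case_id, ld_pu = spec$ld_pu, td_bn = spec$td_bn,
               td_pu = spec$td_pu, rpu1 = r[["rpu1"]], rpu2 = r[["rpu2"]],
               converged = TRUE, elements = mesh$n_elements,
               iterations = solution$iterations,
               mass_imbalance = solution$mass_imbalance,
               mv_euo = mv_euo(solution, mesh),
               vortex = vm$vortex,
               vortex_left = vm$left$present, vortex_right = vm$right$present,
               td_v = vm$td_v, ld_v = vm$ld_v,
               stringsAsFactors = FALSE)
  } else {
    data.frame(case_id = spec$case_id, ld_pu = spec$ld_pu, td_bn = spec$td_bn,
               td_pu = spec$td_pu, rpu1 = r[["rpu1"]], rpu2 = r[["rpu2"]],
               converged = FALSE, elements = mesh$n_elements,
               iterations = solution$iterations,
               mass_imbalance = solution$mass_imbalance,
               mv_euo = NA_real_, vortex = NA, vortex_left = NA,
               vortex_right = NA, td_v = NA_real_, ld_v = NA_real_,
               stringsAsFactors = FALSE)
  }
}
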
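# Run configuration, file formats (CSV / Gmsh MSH 2.2 / VTK legacy / JSON
# metadata) and the command surface tying the pipeline together.
# Convention: geometry files carry cm (stated in column names), mesh and
# field files are SI (metres, Pa, m/s).

.config_defaults <- function() {
  list(case = NULL,            # list(ld_pu, td_bn, td_pu) for single-case runs
       selection = "all",      # "all" or list(ld_pu =, td_bn =) subgroup filter
       budget = 25000,
       budgets = c(13000, 18000, 25000, 35000),
       turbulence = "rng-ke",
       scheme = "upwind2",
       max_iter = 12000,
       tol = 1e-5,
       seed = 1,
       out_dir = "catsflow-out")
}

#' Validate and normalize a run configuration
#'
#' Accepts a list or a YAML/JSON file path. Unknown keys are rejected; known
#' keys are filled with defaults. The normalized configuration is echoed
#' into every output directory's metadata.
#'
#' @param x List, or path to a `.yaml`/`.yml`/`.json` file.
#' @return Normalized configuration list of class `cats_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE)) yaml::read_yaml(x)
         else jsonlite::read_json(x, simplifyVector = TRUE)
    if (is.null(x)) x <- list()
  }
  stopifnot(is.list(x))
  def <- .config_defaults()
  unknown <- setdiff(names(x), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(def, x)
  if (!is.null(cfg$case)) {
    need <- c("ld_pu", "td_bn", "td_pu")
    if (!all(need %in% names(cfg$case)))
      stop("config `case` needs ld_pu, td_bn and td_pu", call. = FALSE)
  }
  if (!cfg$turbulence %in% c("rng-ke", "ke", "laminar"))
    stop("turbulence must be one of rng-ke, ke, laminar", call. = FALSE)
  if (!cfg$scheme %in% c("upwind2", "upwind"))
    stop("scheme must be upwind2 or upwind", call. = FALSE)
  if (cfg$budget < 1000) stop("budget must be at least 1000", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "cats_config")
}

config_numerics <- function(cfg) {
  numerics_config(turbulence = cfg$turbulence, scheme = cfg$scheme,
                  max_iter = cfg$max_iter, tol = cfg$tol)
}

config_specs <- function(cfg) {
  if (!is.null(cfg$case))
    return(list(make_case(cfg$case$ld_pu, cfg$case$td_bn, cfg$case$td_pu)))
  specs <- amplification_array()
  sel <- cfg$selection
  if (identical(sel, "all")) return(specs)
  stopifnot(is.list(sel))
  keep <- vapply(specs, function(s) {
    ok <- TRUE
    if (!is.null(sel$ld_pu)) ok <- ok && isTRUE(all.equal(s$ld_pu, sel$ld_pu))
    if (!is.null(sel$td_bn)) ok <- ok && isTRUE(all.equal(s$td_bn, sel$td_bn))
    if (!is.null(sel$td_pu)) ok <- ok && isTRUE(all.equal(s$td_pu, sel$td_pu))
    ok
  }, logical(1))
  specs[keep]
}

#' Write a domain outline as CSV
#'
#' Columns `x_cm`, `y_cm`, `tag`: one row per boundary vertex, `tag` labelling
#' the edge that starts at the vertex.
#' @param domain A `cats_domain`.
#' @param path Output file.
#' @export
write_geometry_csv <- function(domain, path) {
  df <- data.frame(x_cm = domain$boundary$x, y_cm = domain$boundary$y,
                   tag = domain$tag)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Boundary edges are exported as 2-node lines in physical groups 1 (inlet),
#' 2 (outlet), 3 (wall); triangles in physical group 4 (fluid). Coordinates
#' in metres.
#' @param mesh A `cats_mesh`.
#' @param path Output file.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", "4",
               "1 1 \"inlet\"", "1 2 \"outlet\"", "1 3 \"wall\"",
               "2 4 \"fluid\"", "$EndPhysicalNames", "$Nodes",
               as.character(nrow(mesh$nodes))), con)
  writeLines(sprintf("%d %.12g %.12g 0", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  nb <- nrow(mesh$boundary_edges); nt <- nrow(mesh$triangles)
  writeLines(c("$EndNodes", "$Elements", as.character(nb + nt)), con)
  tagno <- c(inlet = 1L, outlet = 2L, wall = 3L)[mesh$boundary_tag]
  writeLines(sprintf("%d 1 2 %d %d %d %d", seq_len(nb), tagno, tagno,
                     mesh$boundary_edges[, 1L], mesh$boundary_edges[, 2L]), con)
  writeLines(sprintf("%d 2 2 4 4 %d %d %d", nb + seq_len(nt),
                     mesh$triangles[, 1L], mesh$triangles[, 2L],
                     mesh$triangles[, 3L]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

vtk_header <- function(con, mesh, title) {
  writeLines(c("# vtk DataFile Version 2.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(mesh$nodes))), con)
  writeLines(sprintf("%.12g %.12g 0", mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  nt <- nrow(mesh$triangles)
  writeLines(sprintf("CELLS %d %d", nt, 4L * nt), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1L] - 1L,
                     mesh$triangles[, 2L] - 1L, mesh$triangles[, 3L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("5", nt), con)
}

#' Write a mesh in VTK legacy ASCII format
#' @param mesh A `cats_mesh`.
#' @param path Output file.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  vtk_header(con, mesh, "catsflow mesh (units: m)")
  invisible(path)
}

#' Write a flow solution in VTK legacy ASCII format
#'
#' Point data: pressure (Pa), velocity (m/s), speed, streamfunction (m2/s)
#' and, when a turbulence closure was active, k and epsilon.
#' @param mesh A `cats_mesh`.
#' @param solution Its `cats_solution`.
#' @param path Output file.
#' @export
write_solution_vtk <- function(mesh, solution, path) {
  con <- file(path, "w")
  on.exit(close(con))
  vtk_header(con, mesh, "catsflow solution (SI units)")
  nn <- nrow(mesh$nodes)
  writeLines(sprintf("POINT_DATA %d", nn), con)
  scalar <- function(name, vals) {
    writeLines(c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", vals), con)
  }
  scalar("pressure", solution$p_node)
  scalar("speed", sqrt(solution$u_node^2 + solution$v_node^2))
  scalar("streamfunction", solution$psi_node)
  if (solution$cfg$turbulence != "laminar") {
    scalar("k", solution$k_node)
    scalar("epsilon", solution$epsilon_node)
  }
  writeLines("VECTORS velocity double", con)
  writeLines(sprintf("%.9g %.9g 0", solution$u_node, solution$v_node), con)
  invisible(path)
}

#' Write the solver residual history as CSV
#' @param solution A `cats_solution`.
#' @param path Output file.
#' @export
write_residuals_csv <- function(solution, path) {
  df <- data.frame(iteration = seq_len(nrow(solution$residuals)),
                   solution$residuals)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_metadata <- function(cfg, path, extra = list()) {
  meta <- c(list(package = "catsflow",
                 version = as.character(utils::packageVersion("catsflow")),
                 config = unclass(cfg)), extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

config_hash <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run one case end to end and write its artifacts
#'
#' Writes `geometry.csv`, `mesh.msh`, `mesh.vtk`, `fields.vtk`,
#' `residuals.csv`, `result.json` and `metadata.json` into the output
#' directory. Configuration errors are raised before any computation.
#'
#' @param config A [run_config()] or anything it accepts; must name one case.
#' @return Invisibly, 0 when converged, 1 otherwise.
#' @export
cmd_case <- function(config) {
  cfg <- run_config(if (inherits(config, "cats_config")) unclass(config) else config)
  if (is.null(cfg$case))
    stop("cmd_case needs a `case` entry in the configuration", call. = FALSE)
  spec <- config_specs(cfg)[[1L]]
  set.seed(cfg$seed)
  dom <- assemble_domain(spec)
  mesh <- triangulate(dom, cfg$budget, seed = cfg$seed)
  sol <- solve_with_retry(mesh, cfg = config_numerics(cfg), init = dom)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_geometry_csv(dom, file.path(cfg$out_dir, "geometry.csv"))
  write_mesh_msh(mesh, file.path(cfg$out_dir, "mesh.msh"))
  write_mesh_vtk(mesh, file.path(cfg$out_dir, "mesh.vtk"))
  write_solution_vtk(mesh, sol, file.path(cfg$out_dir, "fields.vtk"))
  write_residuals_csv(sol, file.path(cfg$out_dir, "residuals.csv"))
  res <- summarize_case(spec, sol, mesh, dom)
  jsonlite::write_json(as.list(res), file.path(cfg$out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_metadata(cfg, file.path(cfg$out_dir, "metadata.json"),
                 list(case_id = spec$case_id, converged = sol$converged))
  invisible(if (isTRUE(sol$converged)) 0L else 1L)
}

#' Run a cohort sweep and write its artifacts
#'
#' Writes per-case JSON records under `cases/`, plus `cohort.csv`,
#' `summary.csv`, `thresholds.json` and `metadata.json`. The sweep is
#' resumable: a case whose record exists with a matching configuration hash
#' is not recomputed.
#'
#' @param config A [run_config()] selecting one or more cases.
#' @return Invisibly, 0 when all cases converged, 2 when some failed.
#' @export
cmd_sweep <- function(config) {
  cfg <- run_config(if (inherits(config, "cats_config")) unclass(config) else config)
  specs <- config_specs(cfg)
  if (!length(specs)) stop("configuration selects no cases", call. = FALSE)
  dir.create(file.path(cfg$out_dir, "cases"), recursive = TRUE,
             showWarnings = FALSE)
  solver_cfg <- config_numerics(cfg)
  hash <- config_hash(list(budget = cfg$budget, turbulence = cfg$turbulence,
                           scheme = cfg$scheme, tol = cfg$tol,
                           max_iter = cfg$max_iter, seed = cfg$seed))
  case_cols <- list(case_id = NA_character_, ld_pu = NA_real_,
                    td_bn = NA_real_, td_pu = NA_real_, rpu1 = NA_real_,
                    rpu2 = NA_real_, converged = NA, elements = NA_integer_,
                    iterations = NA_integer_, mass_imbalance = NA_real_,
                    mv_euo = NA_real_, vortex = NA, vortex_left = NA,
                    vortex_right = NA, td_v = NA_real_, ld_v = NA_real_)
  rows <- lapply(specs, function(s) {
    f <- file.path(cfg$out_dir, "cases", paste0(s$case_id, ".json"))
    if (file.exists(f)) {
      rec <- jsonlite::read_json(f, simplifyVector = TRUE)
      if (identical(rec$hash, unname(hash))) {
        # JSON null (from NA fields) round-trips as NULL; restore typed NAs
        vals <- lapply(names(case_cols), function(k) {
          v <- rec$result[[k]]
          if (is.null(v)) case_cols[[k]] else v
        })
        names(vals) <- names(case_cols)
        return(as.data.frame(vals, stringsAsFactors = FALSE))
      }
    }
    res <- run_cohort(list(s), cfg = solver_cfg, element_budget = cfg$budget)
    jsonlite::write_json(list(hash = hash, result = as.list(res)), f,
                         auto_unbox = TRUE, digits = NA)
    res
  })
  cohort <- do.call(rbind, rows)
  utils::write.csv(format(cohort, digits = 10, trim = TRUE, justify = "none"),
                   file.path(cfg$out_dir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)
  summ <- summarize_groups(cohort)
  write_summary_csv(summ, file.path(cfg$out_dir, "summary.csv"))
  jsonlite::write_json(summ$thresholds, file.path(cfg$out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_metadata(cfg, file.path(cfg$out_dir, "metadata.json"),
                 list(n_cases = nrow(cohort),
                      n_converged = sum(cohort$converged)))
  invisible(if (all(cohort$converged)) 0L else 2L)
}

#' Write a cohort summary as a characteristics table
#'
#' Rows are the cohort characteristics (counts, medians with IQR by vortex
#' status, Mann-Whitney p), columns the LD-PU groups.
#' @param summary A `cohort_summary`.
#' @param path Output file.
#' @export
write_summary_csv <- function(summary, path) {
  groups <- summary$counts$group
  fmt_q <- function(g, var, stratum) {
    s <- summary$stats
    r <- s[s$group == g & s$variable == var & s$stratum == stratum, ]
    if (!nrow(r)) return("")
    sprintf("%.4g (%.4g, %.4g)", r$median, r$q1, r$q3)
  }
  rows <- list(
    c("models_n", summary$counts$n),
    c("vortex_n", sprintf("%d (%.2f%%)", summary$counts$vortex_n,
                          summary$counts$vortex_pct)),
    c("nonvortex_n", sprintf("%d (%.2f%%)", summary$counts$nonvortex_n,
                             summary$counts$nonvortex_pct)),
    c("td_v_mm", vapply(groups, fmt_q, "", var = "td_v_mm", stratum = "vortex")),
    c("rpu1_vortex", vapply(groups, fmt_q, "", var = "rpu1", stratum = "vortex")),
    c("rpu1_nonvortex", vapply(groups, fmt_q, "", var = "rpu1", stratum = "nonvortex")),
    c("rpu2_vortex", vapply(groups, fmt_q, "", var = "rpu2", stratum = "vortex")),
    c("rpu2_nonvortex", vapply(groups, fmt_q, "", var = "rpu2", stratum = "nonvortex")),
    c("mv_euo_vortex", vapply(groups, fmt_q, "", var = "mv_euo", stratum = "vortex")),
    c("mv_euo_nonvortex", vapply(groups, fmt_q, "", var = "mv_euo", stratum = "nonvortex")),
    c("mann_whitney_p", sprintf("%.4g", summary$tests$p)))
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("characteristic", paste0("group_", groups))
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' Grid-independence report
#'
#' Runs [grid_independence()] for the configured case over `budgets` and
#' writes `gridcheck.csv` with relative-change columns and a pass flag
#' against the 2% criterion beyond the second budget.
#'
#' @param config A [run_config()]; `case` defaults to the index case.
#' @return Invisibly, 0 when the criterion passes.
#' @export
cmd_gridcheck <- function(config) {
  cfg <- run_config(if (inherits(config, "cats_config")) unclass(config) else config)
  spec <- if (is.null(cfg$case)) make_case(3.8, 3.0, 4.2, case_id = "II-C-4.2")
          else config_specs(cfg)[[1L]]
  rep <- grid_independence(spec, cfg$budgets, cfg = config_numerics(cfg))
  beyond <- seq_len(nrow(rep)) > 2L
  pass <- all(rep$d_mv_euo_pct[beyond] < 2, rep$d_td_v_pct[beyond] < 2,
              na.rm = TRUE) && all(rep$converged)
  rep$pass_2pct <- c(NA, NA, rep$d_mv_euo_pct[beyond] < 2 &
                       rep$d_td_v_pct[beyond] < 2)[seq_len(nrow(rep))]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rep, file.path(cfg$out_dir, "gridcheck.csv"),
                   row.names = FALSE)
  write_metadata(cfg, file.path(cfg$out_dir, "metadata.json"),
                 list(case_id = spec$case_id, pass_2pct = pass))
  invisible(if (pass) 0L else 1L)
}

#' Summarize an existing cohort table
#'
#' Reads `cohort.csv` from the configured output directory and rewrites
#' `summary.csv` and `thresholds.json`.
#' @param config A [run_config()].
#' @return Invisibly, 0.
#' @export
cmd_summarize <- function(config) {
  cfg <- run_config(if (inherits(config, "cats_config")) unclass(config) else config)
  f <- file.path(cfg$out_dir, "cohort.csv")
  if (!file.exists(f)) stop("no cohort.csv in ", cfg$out_dir, call. = FALSE)
  cohort <- utils::read.csv(f, stringsAsFactors = FALSE)
  summ <- summarize_groups(cohort)
  write_summary_csv(summ, file.path(cfg$out_dir, "summary.csv"))
  jsonlite::write_json(summ$thresholds, file.path(cfg$out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(0L)
}
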
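# Shared fixtures, computed lazily and cached for the whole test run.
# The expensive ones (the coarse 210-case cohort, the four-budget grid
# study) are reused by several test files.

.fix <- new.env(parent = emptyenv())

fix <- function(key, expr) {
  if (!exists(key, envir = .fix, inherits = FALSE))
    assign(key, force(expr), envir = .fix)
  get(key, envir = .fix, inherits = FALSE)
}

cats1_spec <- function() make_case(3.8, 3.0, 4.2, case_id = "II-C-4.2")

fix_cats1_domain <- function() fix("cats1_domain", assemble_domain(cats1_spec()))

# plane-Poiseuille validation channel: low driving pressure (Re ~ 17, so the
# profile is fully developed well before the sampling station), laminar
fix_poiseuille <- function() fix("poiseuille", {
  dom <- channel_domain(0.6, 3.0)
  mesh <- triangulate(dom, 3000)
  bc <- boundary_set(inlet_pressure = 0.02)
  sol <- solve_steady_flow(mesh, bc = bc,
                           cfg = numerics_config(turbulence = "laminar"))
  list(dom = dom, mesh = mesh, bc = bc, sol = sol)
})

# index case solved at the coarsest study budget with default numerics
fix_cats1_coarse <- function() fix("cats1_coarse", {
  dom <- fix_cats1_domain()
  mesh <- triangulate(dom, 13000)
  sol <- catsflow:::solve_with_retry(mesh, init = dom)
  list(dom = dom, mesh = mesh, sol = sol)
})

# the full 210-case amplification sweep at the desk-scale cohort profile
fix_cohort <- function() fix("cohort", run_cohort(amplification_array()))

# grid-independence ladder at the four study budgets
fix_gridstudy <- function() fix("gridstudy",
  grid_independence(cats1_spec(), c(13000, 18000, 25000, 35000)))
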
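# Orchestration of the study matrix (4 fracture sites x 3 device materials x
# 2 plate thicknesses), the healthy-mandible bite-force run and the mesh
# convergence mode.

.SITES <- c("symphysis", "body", "angle", "condylar_neck")
.MATERIALS <- c("Ti-6Al-4V", "WE43", "PLA")
.THICKNESSES <- c(1.0, 1.5)

#' The full study scenario matrix
#'
#' @return data.frame of 24 scenarios (site x device material x thickness).
#' @export
study_scenarios <- function() {
  out <- expand.grid(site = .SITES, material = .MATERIALS,
                     thickness = .THICKNESSES,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # materials consecutive within a site/thickness pair, so the meshed and
  # tied model can be reused across the three device materials
  out <- out[order(out$site, out$thickness, out$material), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run configuration
#'
#' @param geometry list of [mandible_params()] arguments.
#' @param scenarios `"all"` or a data.frame with columns site, material,
#'   thickness.
#' @param scale loading scale (fraction of maximum muscle force).
#' @param gap_width fracture gap width, mm.
#' @param mode `"study"`, `"healthy"` or `"convergence"`.
#' @param levels refinement levels (edge lengths, mm) for convergence mode.
#' @param seed integer seed recorded in the manifest.
#' @param out optional output directory for CSV/VTU/manifest exports.
#' @return object of class `run_config`.
#' @export
run_config <- function(geometry = list(), scenarios = "all", scale = 0.2,
                       gap_width = 1.2, mode = c("study", "healthy",
                                                 "convergence"),
                       levels = c(2.0, 1.0, 0.5), seed = 1L, out = NULL) {
  mode <- match.arg(mode)
  if (scale <= 0 || scale > 1) stop("scale must lie in (0, 1]")
  if (identical(scenarios, "all")) scenarios <- study_scenarios()
  if (is.data.frame(scenarios)) {
    if (!all(c("site", "material", "thickness") %in% names(scenarios)))
      stop("scenarios need columns site, material, thickness")
    if (!all(scenarios$site %in% .SITES))
      stop("unknown fracture site in scenarios")
    if (!all(scenarios$thickness %in% .THICKNESSES))
      stop("plate thickness must be 1.0 or 1.5 mm")
  }
  structure(list(geometry = geometry, scenarios = scenarios, scale = scale,
                 gap_width = gap_width, mode = mode, levels = levels,
                 seed = as.integer(seed), out = out),
            class = "run_config")
}

#' Solve one fixation scenario
#'
#' @param mesh intact mandible mesh from [build_mandible()].
#' @param site fracture site.
#' @param material device material card name.
#' @param thickness plate thickness, mm.
#' @param cards material table.
#' @param table muscle table.
#' @param scale loading scale.
#' @param gap_width fracture gap width, mm.
#' @param prepared optional cached list (merged mesh, ties, load) from a
#'   previous scenario with the same site/thickness.
#' @return list with the solution, healing summary, device peak, report row
#'   and the reusable `prepared` cache.
#' @export
run_scenario <- function(mesh, site, material, thickness = 1.0,
                         cards = load_material_table(),
                         table = load_muscle_table(), scale = 0.2,
                         gap_width = 1.2, prepared = NULL) {
  if (is.null(prepared)) {
    frac <- insert_fracture(mesh, fracture_spec(site, gap_width))
    merged <- place_devices(frac, thickness)
    ties <- build_ties(merged)
    load <- build_load_case(merged, table, scale)
    prepared <- list(merged = merged, ties = ties, load = load)
  }
  mats <- assign_materials(prepared$merged, material, cards)
  sys <- assemble_system(prepared$merged, mats, prepared$load, prepared$ties)
  sol <- solve_system(sys)
  healing <- summarize_healing(sol, prepared$merged)
  peak <- device_peak(sol)
  reac <- reaction_forces(sol)
  row <- data.frame(
    site = site, material = material, thickness = thickness,
    n_elements = nrow(prepared$merged$elems),
    n_nodes = nrow(prepared$merged$nodes),
    residual = sol$residual,
    tensile_q1_pct = healing$tensile["q1"],
    tensile_median_pct = healing$tensile["median"],
    tensile_q3_pct = healing$tensile["q3"],
    compressive_q1_pct = healing$compressive["q1"],
    compressive_median_pct = healing$compressive["median"],
    compressive_q3_pct = healing$compressive["q3"],
    median_abs_strain_pct = healing$median_abs_pct,
    fraction_below_15 = healing$fraction_below_15,
    peak_vm_mpa = peak$peak,
    yield_ratio = peak$yield_ratio,
    elastic = peak$elastic,
    bite_force = reac$bite_force,
    row.names = NULL)
  list(solution = sol, healing = healing, peak = peak, reactions = reac,
       row = row, prepared = prepared)
}

#' Run the full fixation study
#'
#' Iterates the scenario matrix, reusing the meshed/tied/loaded model across
#' device materials of the same site/thickness combination. Scenario failures
#' are collected and reported without aborting the remaining scenarios.
#'
#' @param config a [run_config()].
#' @param keep_solutions retain full `fe_solution` objects (memory-heavy).
#' @return object of class `study_report`: `rows` (one per scenario),
#'   `failures`, `manifest`.
#' @export
run_study <- function(config = run_config(), keep_solutions = FALSE) {
  set.seed(config$seed)
  params <- do.call(mandible_params, c(config$geometry,
                                       list(seed = config$seed)))
  mesh <- build_mandible(params)
  cards <- load_material_table()
  table <- load_muscle_table()
  sc <- config$scenarios
  rows <- list(); failures <- list(); sols <- list()
  cache_key <- ""; prepared <- NULL
  for (i in seq_len(nrow(sc))) {
    s <- sc[i, ]
    key <- paste(s$site, s$thickness)
    res <- tryCatch({
      pr <- if (identical(key, cache_key)) prepared else NULL
      out <- run_scenario(mesh, s$site, s$material, s$thickness, cards,
                          table, config$scale, config$gap_width, pr)
      prepared <- out$prepared; cache_key <- key
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[paste(s$site, s$material, s$thickness, sep = "_")]] <-
        conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res$row
      if (keep_solutions)
        sols[[paste(s$site, s$material, s$thickness, sep = "_")]] <-
          res$solution
    }
  }
  report <- structure(list(
    rows = do.call(rbind, rows), failures = failures,
    solutions = if (keep_solutions) sols else NULL,
    manifest = list(seed = config$seed, scale = config$scale,
                    gap_width = config$gap_width,
                    geometry = unclass(params),
                    n_scenarios = nrow(sc),
                    package_version = as.character(utils::packageVersion("mandifix")))),
    class = "study_report")
  if (!is.null(config$out)) .write_report(report, config$out)
  report
}

#' Healthy-mandible run (bite-force readout)
#'
#' Solves the intact mandible under the full unilateral-clenching load case
#' and reports the occlusal vertical reaction ("bite force").
#'
#' @param config a [run_config()].
#' @return list with the solution, reactions and bite force (N).
#' @export
run_healthy <- function(config = run_config(mode = "healthy")) {
  set.seed(config$seed)
  params <- do.call(mandible_params, c(config$geometry,
                                       list(seed = config$seed)))
  mesh <- build_mandible(params)
  mats <- assign_materials(mesh)
  load <- build_load_case(mesh, scale = config$scale)
  sol <- solve_system(assemble_system(mesh, mats, load))
  reac <- reaction_forces(sol)
  list(solution = sol, reactions = reac, bite_force = reac$bite_force,
       strain_energy = strain_energy(sol))
}

#' Mesh convergence study
#'
#' Re-solves the intact mandible at a sequence of lattice edge lengths with
#' simplified isotropic bone properties (cortical 15000 MPa, trabecular
#' 300 MPa, Poisson 0.3) under the simplified masseter load (Fx = 0,
#' Fy = -50 N, Fz = 50 N on the right masseter patch), and reports the
#' relative change of the symphysis-region average von Mises stress and
#' average principal strains against the finest mesh.
#'
#' @param config a [run_config()] (its `levels` are the edge lengths, mm,
#'   coarsest first).
#' @return object of class `convergence_report` with per-level quantities and
#'   relative errors (%) versus the finest level.
#' @export
run_convergence <- function(config = run_config(mode = "convergence")) {
  set.seed(config$seed)
  levels <- sort(config$levels, decreasing = TRUE)
  iso_cort <- material_card("iso_cortical", 15000, nu12 = 0.3,
                            isotropic = TRUE)
  iso_trab <- material_card("iso_trabecular", 300, nu12 = 0.3,
                            isotropic = TRUE)
  override <- list(symphysis = iso_cort, body = iso_cort, angle = iso_cort,
                   ramus = iso_cort, condyle = iso_cort,
                   coronoid_process = iso_cort, teeth = iso_cort,
                   trabecular = iso_trab)
  res <- list()
  prev <- NULL   # coarse-level context reused as the two-grid coarse space
  for (h in levels) {
    geo <- config$geometry
    geo$target_edge_length <- h
    params <- do.call(mandible_params, c(geo, list(seed = config$seed)))
    mesh <- build_mandible(params)
    mats <- assign_materials(mesh, override = override)
    load <- build_load_case(mesh, convergence_mode = TRUE)
    sys <- assemble_system(mesh, mats, load)
    sol <- solve_system(sys, coarse = prev)
    pr <- region_average_principal(sol, "symphysis")
    res[[length(res) + 1L]] <-
      list(level = h, n_elements = nrow(mesh$elems),
           n_nodes = nrow(mesh$nodes),
           avg_vm = region_average_vm(sol, "symphysis"),
           eps_max = pr[1], eps_min = pr[2],
           reactions = reaction_forces(sol)$total)
    if (!is.null(sol$factor))
      prev <- list(mesh = mesh, system = sys, chol = sol$factor)
    rm(sol, mats); invisible(gc(FALSE))
  }
  fine <- res[[length(res)]]
  tb <- do.call(rbind, lapply(res, function(r)
    data.frame(level = r$level, n_elements = r$n_elements,
               n_nodes = r$n_nodes, avg_vm = r$avg_vm,
               eps_max = r$eps_max, eps_min = r$eps_min,
               rel_err_vm_pct = 100 * abs(r$avg_vm - fine$avg_vm) /
                 abs(fine$avg_vm),
               rel_err_eps_max_pct = 100 * abs(r$eps_max - fine$eps_max) /
                 abs(fine$eps_max),
               rel_err_eps_min_pct = 100 * abs(r$eps_min - fine$eps_min) /
                 abs(fine$eps_min))))
  structure(list(table = tb, reference_level = fine$level),
            class = "convergence_report")
}

#' Run the configured pipeline mode
#'
#' @param config a [run_config()].
#' @return the mode's report object.
#' @export
run <- function(config = run_config()) {
  switch(config$mode,
         study = run_study(config),
         healthy = run_healthy(config),
         convergence = run_convergence(config))
}

.write_report <- function(report, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  rows <- report$rows
  num <- vapply(rows, is.numeric, TRUE)
  rows[num] <- lapply(rows[num], function(x) signif(x, 12))
  utils::write.csv(rows, file.path(out, "study_report.csv"),
                   row.names = FALSE)
  writeLines(yaml::as.yaml(report$manifest),
             file.path(out, "manifest.yaml"))
  invisible(out)
}

#' @exportS3Method print study_report
print.study_report <- function(x, ...) {
  cat("mandifix study report:", nrow(x$rows), "scenarios solved,",
      length(x$failures), "failed\n")
  print(x$rows[, c("site", "material", "thickness",
                   "median_abs_strain_pct", "peak_vm_mpa", "yield_ratio")],
        digits = 3)
  invisible(x)
}

#' @exportS3Method print convergence_report
print.convergence_report <- function(x, ...) {
  cat("mesh convergence (reference edge length",
      x$reference_level, "mm)\n")
  print(x$table, digits = 4)
  invisible(x)
}
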
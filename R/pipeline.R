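# End-to-end experiment orchestration: solve every PDL variant on one
# mesh, extract principal/shear strain fields, gauge readouts, region
# summaries, element-level differential maps between variant pairs, and
# (when in-vivo samples are supplied) the validation report. All outputs
# are deterministic given the configuration and seed.

#' Configure an experiment run
#'
#' @param mesh a `tet_mesh` (typically from [make_phantom()]); gauge
#'   definitions are taken from its `"gauges"` attribute unless `gauges`
#'   is given.
#' @param variants character vector of PDL variants to solve
#'   (see [pdl_variants()]).
#' @param pairs list of 2-vectors of variant names to difference (a - b).
#' @param scenario constraint scenario for [build_chewing_case()].
#' @param muscles muscle table; default [default_muscles()] on the mesh.
#' @param emg_table replacement activations for the clenching scenario.
#' @param calibration a `calibration_model`.
#' @param gv per-element grayscale values; default [make_grayscale()] with
#'   the run seed.
#' @param gauges list of `gauge_site` objects (or NULL for none).
#' @param invivo in-vivo sample data.frame (or NULL to skip validation).
#' @param out_dir output directory (or NULL to keep results in memory only).
#' @param seed integer seed for every random input derived in the run.
#' @param write_vtk also write differential maps as VTK files.
#' @return object of class `run_config`.
#' @export
run_config <- function(mesh,
                       variants = c("PDL", "NO_PDL"),
                       pairs = list(c("NO_PDL", "PDL")),
                       scenario = "chewing",
                       muscles = NULL, emg_table = NULL,
                       calibration = calibration_model(),
                       gv = NULL, gauges = NULL, invivo = NULL,
                       out_dir = NULL, seed = 1L, write_vtk = FALSE) {
  if (length(variants) < 1L) stop("need at least one variant")
  for (p in pairs)
    if (!all(p %in% variants))
      stop("pair (", paste(p, collapse = ", "), ") not in variants")
  if (is.null(muscles)) muscles <- default_muscles(mesh)
  if (is.null(gauges)) gauges <- attr(mesh, "gauges")
  structure(list(mesh = mesh, variants = variants, pairs = pairs,
                 scenario = scenario, muscles = muscles,
                 emg_table = emg_table, calibration = calibration,
                 gv = gv, gauges = gauges, invivo = invivo,
                 out_dir = out_dir, seed = as.integer(seed),
                 write_vtk = isTRUE(write_vtk)),
            class = "run_config")
}

#' Run a full PDL-variant experiment
#'
#' For each configured variant: build the material field, assemble and
#' solve the static chewing load case, recover element strains
#' (microstrain), principal values and anatomical-plane shear components,
#' read out every gauge, and summarise each tissue region. Then compute
#' element-level differential maps (`e1`, `e_min`, sagittal `e12`, frontal
#' `e13`, transverse `e23`) for every configured variant pair, split by
#' cortical/tooth/pdl regions, and (if in-vivo data is supplied) the
#' gauge validation report. If `out_dir` is set, CSV summaries, optional
#' VTK difference maps and a JSON manifest (residuals, seeds, constraint
#' echo) are written; identical configurations produce byte-identical
#' files.
#'
#' @param cfg a [run_config()].
#' @return list (class `run_result`) with `solutions`, `strains`
#'   (microstrain), `principal`, `shear`, `gauge_readouts`,
#'   `region_summaries`, `differentials`, `validation`, `manifest`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  mesh <- cfg$mesh
  stage <- "inputs"
  res <- tryCatch({
    gv <- cfg$gv
    if (is.null(gv)) gv <- make_grayscale(mesh, seed = cfg$seed)
    cortical <- assign_cortical(mesh, gv, cfg$calibration, binned = TRUE)
    stage <- "load_case"
    load <- build_chewing_case(mesh, cfg$muscles, cfg$scenario,
                               emg_table = cfg$emg_table)
    surface <- extract_surface(mesh)
    solutions <- list(); strains <- list(); princ <- list(); shear <- list()
    readouts <- list(); summaries <- list()
    for (v in cfg$variants) {
      stage <- paste0("solve:", v)
      mat <- make_variant(mesh, cortical, v)
      sol <- solve_static(mesh, mat, load)
      st <- microstrain(recover_strains(mesh, sol))
      pv <- principal_values(st)
      sh <- shear_components(st)
      solutions[[v]] <- sol
      strains[[v]] <- st
      princ[[v]] <- pv
      shear[[v]] <- sh
      stage <- paste0("gauges:", v)
      readouts[[v]] <- lapply(cfg$gauges, function(g)
        gauge_readout(mesh, st, g, surface = surface))
      stage <- paste0("summaries:", v)
      summaries[[v]] <- do.call(rbind, list(
        cbind(variant = v, quantity = "e1", region_summaries(pv$e1, mesh)),
        cbind(variant = v, quantity = "e_min",
              region_summaries(pv$e_min, mesh))))
    }
    stage <- "differentials"
    quantities <- c("e1", "e_min", "e12", "e13", "e23")
    getq <- function(v, q) switch(q,
      e1 = princ[[v]]$e1, e_min = princ[[v]]$e_min,
      e12 = shear[[v]]$sagittal, e13 = shear[[v]]$frontal,
      e23 = shear[[v]]$transverse)
    diffs <- list()
    for (p in cfg$pairs) {
      key <- paste(p[1L], "vs", p[2L])
      diffs[[key]] <- list()
      for (q in quantities) {
        dm <- differential_map(getq(p[1L], q), getq(p[2L], q),
                               quantity = q, pair = p)
        per_region <- lapply(c("cortical", "tooth", "pdl"), function(r)
          if (any(mesh$region == r))
            region_summary(dm, which(mesh$region == r), region = r))
        diffs[[key]][[q]] <- list(map = dm,
                                  summary = do.call(rbind, per_region))
      }
    }
    stage <- "validation"
    validation <- NULL
    if (!is.null(cfg$invivo) && length(cfg$gauges)) {
      validation <- lapply(cfg$variants, function(v) {
        vr <- validation_report(lapply(readouts[[v]], validate_gauge,
                                       invivo = cfg$invivo))
        cbind(variant = v, vr)
      })
      validation <- do.call(rbind, validation)
    }
    manifest <- list(
      package = "jawstrain",
      version = as.character(utils::packageVersion("jawstrain")),
      seed = cfg$seed, scenario = cfg$scenario,
      variants = cfg$variants,
      n_nodes = nrow(mesh$nodes), n_elements = nrow(mesh$elems),
      residuals = vapply(solutions, `[[`, numeric(1), "residual"),
      equilibrium_errors = vapply(solutions, `[[`, numeric(1),
                                  "equilibrium_error"),
      constraints = lapply(load$constraints, function(cs)
        list(set = cs$set, n_nodes = length(cs$nodes),
             fixed = c("X", "Y", "Z")[cs$axes])),
      net_applied_force_N = colSums(load$forces))
    out <- list(config = cfg, load = load, solutions = solutions,
                strains = strains, principal = princ, shear = shear,
                gauge_readouts = readouts,
                region_summaries = do.call(rbind, summaries),
                differentials = diffs, validation = validation,
                manifest = manifest)
    class(out) <- "run_result"
    out
  }, error = function(e) {
    stop("experiment failed at stage [", stage, "] (seed ", cfg$seed, "): ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.null(cfg$out_dir)) .write_run(res, cfg$out_dir)
  res
}

.write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  utils::write.csv(res$region_summaries, fp("region_summaries.csv"),
                   row.names = FALSE)
  for (v in names(res$gauge_readouts))
    for (g in names(res$gauge_readouts[[v]]))
      utils::write.csv(res$gauge_readouts[[v]][[g]],
                       fp(sprintf("gauge_%s_%s.csv", v, g)),
                       row.names = FALSE)
  mesh <- res$config$mesh
  for (key in names(res$differentials)) {
    safe <- gsub(" ", "_", key)
    sums <- do.call(rbind, lapply(names(res$differentials[[key]]),
      function(q) cbind(quantity = q, res$differentials[[key]][[q]]$summary)))
    utils::write.csv(sums, fp(sprintf("differential_%s_summary.csv", safe)),
                     row.names = FALSE)
    maps <- lapply(res$differentials[[key]], function(x) as.numeric(x$map))
    names(maps) <- paste0("d_", names(res$differentials[[key]]))
    utils::write.csv(cbind(element = seq_len(nrow(mesh$elems)),
                           region = mesh$region, as.data.frame(maps)),
                     fp(sprintf("differential_%s_map.csv", safe)),
                     row.names = FALSE)
    if (res$config$write_vtk)
      write_vtk(mesh, fp(sprintf("differential_%s.vtk", safe)), maps)
  }
  if (!is.null(res$validation))
    utils::write.csv(res$validation, fp("validation_report.csv"),
                     row.names = FALSE)
  log_lines <- unlist(lapply(names(res$solutions), function(v)
    c(paste0("== variant ", v, " =="), res$solutions[[v]]$log)))
  writeLines(log_lines, fp("run_log.txt"))
  jsonlite::write_json(res$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Directional prediction metrics from a run
#'
#' Computes the region-mean quantities behind the study's directional
#' findings from a `run_result`:
#' \itemize{
#'   \item `p1`: mean maximum principal strain (`e1`) and mean
#'     `|e_min|` over the global cortical surface element set, per
#'     ligament-stiffness variant (the torsional-rigidity prediction: these
#'     decrease as ligament E increases);
#'   \item `h2`: mean `e1` and `|e_min|` over the unconstrained tooth roots
#'     (`tooth_root` set) and over the ligament region, for the PDL and
#'     NO_PDL variants (the stress-shielding prediction: removing the
#'     ligament raises root strains and collapses ligament strains);
#'   \item `p3`: mean absolute anatomical-plane shear (averaged over the
#'     sagittal, frontal and transverse components) over the alveolar
#'     cortical set (the torsion prediction: lower without the ligament).
#' }
#' Units: microstrain.
#'
#' @param res a `run_result`.
#' @return list of data.frames `p1`, `h2`, `p3` (entries NULL when the
#'   needed variants or element sets are absent).
#' @export
prediction_metrics <- function(res) {
  mesh <- res$config$mesh
  vars <- names(res$principal)
  surf <- extract_surface(mesh)
  cort_surf <- unique(surf$owner)
  cort_surf <- cort_surf[mesh$region[cort_surf] == "cortical"]
  p1 <- data.frame(
    variant = vars,
    surface_mean_e1 = vapply(vars, function(v)
      mean(res$principal[[v]]$e1[cort_surf]), numeric(1)),
    surface_mean_abs_emin = vapply(vars, function(v)
      mean(abs(res$principal[[v]]$e_min[cort_surf])), numeric(1)))
  h2 <- NULL
  if (all(c("PDL", "NO_PDL") %in% vars) &&
      !is.null(mesh$elem_sets$tooth_root)) {
    root <- mesh$elem_sets$tooth_root
    lig <- which(mesh$region == "pdl")
    h2 <- data.frame(
      variant = c("PDL", "NO_PDL"),
      root_mean_e1 = vapply(c("PDL", "NO_PDL"), function(v)
        mean(res$principal[[v]]$e1[root]), numeric(1)),
      root_mean_abs_emin = vapply(c("PDL", "NO_PDL"), function(v)
        mean(abs(res$principal[[v]]$e_min[root])), numeric(1)),
      pdl_mean_e1 = vapply(c("PDL", "NO_PDL"), function(v)
        mean(res$principal[[v]]$e1[lig]), numeric(1)),
      pdl_mean_abs_emin = vapply(c("PDL", "NO_PDL"), function(v)
        mean(abs(res$principal[[v]]$e_min[lig])), numeric(1)))
  }
  p3 <- NULL
  if (all(c("PDL", "NO_PDL") %in% vars) &&
      !is.null(mesh$elem_sets$alveolar)) {
    alv <- mesh$elem_sets$alveolar
    mean_shear <- function(v) mean(c(abs(res$shear[[v]]$sagittal[alv]),
                                     abs(res$shear[[v]]$frontal[alv]),
                                     abs(res$shear[[v]]$transverse[alv])))
    p3 <- data.frame(variant = c("PDL", "NO_PDL"),
                     alveolar_mean_abs_shear =
                       c(mean_shear("PDL"), mean_shear("NO_PDL")))
  }
  list(p1 = p1, h2 = h2, p3 = p3)
}

#' @export
print.run_result <- function(x, ...) {
  cat("run_result:", length(x$solutions), "variant(s) solved on",
      x$manifest$n_elements, "elements\n")
  cat("  residuals:", paste(sprintf("%s=%.1e", names(x$manifest$residuals),
                                    x$manifest$residuals), collapse = " "),
      "\n")
  if (length(x$differentials))
    cat("  differential pairs:", paste(names(x$differentials),
                                       collapse = "; "), "\n")
  invisible(x)
}
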
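# Configuration-driven orchestration of the analysis stages.

#' Package defaults for every protocol constant
#'
#' One place for each experimentally stated constant: the minimum gold
#' particle diameter (8 nm), the I-band ROI margin (20 nm), the AFM
#' trigger force (3 nN), bead radius (5 um) and cantilever spring
#' constant (0.035 N/m), the 10 s hold / 0.2 um step / 0.2 um/s ramp
#' protocol at 1000 Hz, and the 0-30 min timecourse grid.
#'
#' @return named list of defaults.
#' @export
sarcoquant_defaults <- function() {
  list(
    min_particle_diameter_nm = 8,
    iband_roi_margin_nm = 20,
    afm_trigger_nn = 3,
    afm_bead_radius_um = 5,
    afm_spring_constant_n_m = 0.035,
    afm_poisson_ratio = 0.5,
    ramp_step_um = 0.2,
    ramp_speed_um_s = 0.2,
    hold_s = 10,
    sampling_hz = 1000,
    slack_sl_um = 2.2,
    timecourse_grid_min = c(0:5, 10, 15, 20, 25, 30),
    theta_ref_deg = 45,
    min_zdisk_length_nm = 500,
    orientation_gate_deg = 30
  )
}

#' Run a configured pipeline
#'
#' Executes a list of stages in order, writing per-stage CSV/JSON
#' outputs plus a combined report and a provenance log into the output
#' directory. Configs may be a YAML/JSON file path or an R list with
#' fields `seed`, `out_dir` and `stages` (each stage a list with `name`
#' and a `params` block). Identical configs and seeds give byte-identical
#' outputs.
#'
#' Supported stage names: `simulate_em`, `simulate_trace`,
#' `simulate_afm`, `simulate_gel`, `fracture_score`, `afm_fit`,
#' `gel_quantify`, `balance`.
#'
#' @param config path to a YAML or JSON config, or an equivalent list.
#' @return list of per-stage results, invisibly; side effect: files
#'   under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  known <- c("simulate_em", "simulate_trace", "simulate_afm", "simulate_gel",
             "fracture_score", "afm_fit", "gel_quantify", "balance")
  if (is.null(config$stages) || length(config$stages) == 0)
    stop("config must list at least one stage")
  names_given <- vapply(config$stages, function(s) s$name %||% "", character(1))
  bad <- setdiff(names_given, known)
  if (length(bad)) stop("unknown stage name(s): ", paste(bad, collapse = ", "))
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop("config must set out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  state <- new.env(parent = emptyenv())
  results <- list()
  for (si in seq_along(config$stages)) {
    st <- config$stages[[si]]
    p <- st$params %||% list()
    res <- switch(st$name,
      simulate_em = {
        sim <- do.call(gen_em_micrograph, c(p, list(seed = seed)))
        state$em <- sim
        utils::write.csv(data.frame(
          zdisk = rep(seq_along(sim$truth$zdisk_paths),
                      vapply(sim$truth$zdisk_paths, nrow, integer(1))),
          do.call(rbind, sim$truth$zdisk_paths)),
          file.path(out_dir, sprintf("stage%02d_em_truth.csv", si)),
          row.names = FALSE)
        list(n_zdisks = length(sim$truth$zdisk_paths))
      },
      simulate_trace = {
        model <- do.call(viscoelastic_model, p$model %||% list(k_elastic = 1))
        prot <- if (is.null(p$protocol)) default_ramp_protocol()
                else as.data.frame(p$protocol)
        tr <- gen_ramp_hold_trace(model, prot, seed = seed)
        state$trace <- tr
        write_trace_csv(tr, file.path(out_dir, sprintf("stage%02d_trace.csv", si)))
        list(n_samples = nrow(tr))
      },
      simulate_afm = {
        spec <- do.call(hertz_curve_spec, p %||% list(E_kpa = 4.81))
        cv <- gen_indentation_curve(spec, seed = seed)
        state$afm <- cv
        write_curve_csv(cv, file.path(out_dir, sprintf("stage%02d_afm.csv", si)))
        list(n_samples = nrow(cv))
      },
      simulate_gel = {
        spec_args <- p
        if (!is.null(spec_args$composition))
          spec_args$composition <- unlist(spec_args$composition)
        spec <- do.call(lane_spec, spec_args)
        lane <- gen_gel_lane(spec, seed = seed)
        state$gel <- lane
        write_profile_csv(lane, file.path(out_dir, sprintf("stage%02d_gel.csv", si)))
        list(n_samples = nrow(lane))
      },
      fracture_score = {
        if (is.null(state$em)) stop("fracture_score needs a simulate_em stage first")
        fr <- do.call(score_image, c(list(img = state$em$image), p))
        utils::write.csv(fr$per_segment,
          file.path(out_dir, sprintf("stage%02d_fracture_segments.csv", si)),
          row.names = FALSE)
        list(fracture_area_nm2 = fr$fracture_area_nm2,
             n_segments = fr$n_segments)
      },
      afm_fit = {
        if (is.null(state$afm)) stop("afm_fit needs a simulate_afm stage first")
        fit <- do.call(fit_hertz, c(list(curve = state$afm), p))
        list(E_kpa = fit$E_kpa, depth_at_trigger_nm = fit$depth_at_trigger_nm)
      },
      gel_quantify = {
        if (is.null(state$gel)) stop("gel_quantify needs a simulate_gel stage first")
        q <- do.call(quantify_bands, c(list(profile = state$gel), p))
        list(percent_cleaved = q$percent_cleaved, areas = as.list(q$areas))
      },
      balance = {
        bp <- do.call(balance_params, p$params %||% list())
        b <- centering_force(bp, p$displacement_nm %||% 35,
                             p$convention %||% "one-sided")
        unclass(b)
      })
    results[[si]] <- list(stage = st$name, result = res)
  }
  report <- list(seed = seed,
                 package_version = as.character(utils::packageVersion("sarcoquant")),
                 stages = results)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
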
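# End-to-end pipeline: build -> contact -> synth -> extract -> fit
# [-> slide], with a typed config, deterministic per-stage seeds and plain
# CSV/JSON/PDB artifacts so every stage can be re-run independently.

.config_schema <- list(
  seed = NULL,
  out_dir = NULL,
  builder = c("n_units", "strands_per_sheet", "sheets_per_unit",
              "polyala_length", "n_bundles", "chains_per_bundle",
              "amorphous_sequence", "unit_gap"),
  sasa = c("probe", "n_points", "contact_threshold"),
  truth = c("bond", "xi_water_res", "n_contact", "n_total", "hold_length",
            "detach_length"),
  protocol = c("velocities", "spring_k", "n_springs", "n_replicas",
               "temperature"),
  extract = c("smooth_window", "d_shear"),
  fit = c("mode"),
  slider = c("enabled", "velocities", "inclined_velocity", "load_angle",
             "film_h", "film_eta")
)
.bond_keys <- c("ma", "U_bond", "m", "xi0", "temperature")

#' Validate a pipeline run configuration
#'
#' Reads a YAML config, checks every key against the schema (unknown keys
#' are errors, so misspellings cannot silently fall back to defaults),
#' type- and range-checks the values, and returns a complete config with
#' defaults filled in. All violations are reported together.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return A `silk_run_config` list.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else {
    path
  }
  errs <- character()
  bad_top <- setdiff(names(cfg), names(.config_schema))
  if (length(bad_top)) {
    errs <- c(errs, paste0("unknown top-level key(s): ",
                           paste(bad_top, collapse = ", ")))
  }
  for (sec in intersect(names(cfg), names(.config_schema))) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad)) {
      errs <- c(errs, paste0("unknown key(s) in '", sec, "': ",
                             paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(cfg$truth$bond)) {
    bad <- setdiff(names(cfg$truth$bond), .bond_keys)
    if (length(bad)) {
      errs <- c(errs, paste0("unknown key(s) in 'truth$bond': ",
                             paste(bad, collapse = ", ")))
    }
  }
  if (is.null(cfg$seed)) {
    errs <- c(errs, "missing required key: seed")
  } else if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)) {
    errs <- c(errs, "seed must be an integer")
  }
  # yaml keeps mixed int/float sequences as lists; flatten before checking
  if (!is.null(cfg$protocol$velocities)) {
    cfg$protocol$velocities <- unlist(cfg$protocol$velocities)
  }
  if (!is.null(cfg$slider$velocities)) {
    cfg$slider$velocities <- unlist(cfg$slider$velocities)
  }
  num_pos <- function(x, name) {
    if (!is.null(x) && (!is.numeric(x) || any(x <= 0))) {
      errs <<- c(errs, paste0(name, " must be positive numeric"))
    }
  }
  num_pos(cfg$truth$xi_water_res, "truth$xi_water_res")
  num_pos(cfg$truth$bond$xi0, "truth$bond$xi0")
  num_pos(cfg$protocol$velocities, "protocol$velocities")
  num_pos(cfg$protocol$spring_k, "protocol$spring_k")
  num_pos(cfg$slider$film_eta, "slider$film_eta")
  num_pos(cfg$slider$film_h, "slider$film_h")
  if (!is.null(cfg$fit$mode) &&
      !cfg$fit$mode %in% c("fix_Ubond", "fix_ma", "free")) {
    errs <- c(errs, "fit$mode must be one of fix_Ubond, fix_ma, free")
  }
  if (length(errs)) {
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  def <- function(x, d) if (is.null(x)) d else x
  bond_cfg <- cfg$truth$bond
  out <- list(
    seed = as.integer(cfg$seed),
    builder = do.call(builder_spec, def(cfg$builder, list())),
    sasa = list(probe = def(cfg$sasa$probe, 0.14),
                n_points = def(cfg$sasa$n_points, 960),
                contact_threshold = def(cfg$sasa$contact_threshold, 0.01)),
    bond = do.call(bond_params, def(bond_cfg, list())),
    truth_extra = list(xi_water_res = def(cfg$truth$xi_water_res, 1e-12),
                       n_contact = def(cfg$truth$n_contact, "auto"),
                       n_total = def(cfg$truth$n_total, "auto"),
                       hold_length = def(cfg$truth$hold_length, 5.6),
                       detach_length = def(cfg$truth$detach_length, 2.8)),
    protocol = list(velocities = def(cfg$protocol$velocities,
                                     c(0.02, 0.05, 0.2, 0.5, 2, 5, 20)),
                    spring_k = def(cfg$protocol$spring_k, 830),
                    n_springs = def(cfg$protocol$n_springs, 7),
                    n_replicas = def(cfg$protocol$n_replicas, 4),
                    temperature = def(cfg$protocol$temperature, 300)),
    extract = list(smooth_window = def(cfg$extract$smooth_window, 50),
                   d_shear = def(cfg$extract$d_shear, NULL)),
    fit = list(mode = def(cfg$fit$mode, "fix_Ubond")),
    slider = list(enabled = def(cfg$slider$enabled, FALSE),
                  velocities = def(cfg$slider$velocities, c(0.1, 1, 5)),
                  inclined_velocity = def(cfg$slider$inclined_velocity, 0.5),
                  load_angle = def(cfg$slider$load_angle, 10),
                  film_h = def(cfg$slider$film_h, 100),
                  film_eta = def(cfg$slider$film_eta, NULL)),
    out_dir = def(cfg$out_dir, NULL)
  )
  structure(out, class = "silk_run_config")
}

#' Run the full friction pipeline
#'
#' Stages: composite build (PDB), SASA contact area (JSON/CSV), synthetic
#' pulling dataset (CSV + manifest), peak-force extraction and water
#' subtraction (CSV), bond-model fit with viscous-limit extrapolation
#' (JSON), and optionally the slider velocity sweep (CSV). A Markdown
#' report with md5-hashed artifacts is written last. Identical config +
#' seed give identical artifacts.
#'
#' @param config A `silk_run_config` (from [validate_config()]) or a path
#'   to a YAML config.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return Invisibly, a list with every stage result.
#' @export
run_silk_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) || !inherits(config, "silk_run_config")) {
    config <- validate_config(config)
  }
  out_dir <- out_dir %||% config$out_dir %||% stop("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()

  # 1. build
  comp <- assemble_composite(config$builder)
  pdb_path <- file.path(out_dir, "composite.pdb")
  write_pdb(comp, pdb_path)
  artifacts <- c(artifacts, pdb_path)

  # 2. contact
  amor <- structure_phase(comp, "amorphous")
  crys <- structure_phase(comp, "crystalline")
  ct <- contact_area(amor, crys, probe = config$sasa$probe,
                     n_points = config$sasa$n_points,
                     threshold = config$sasa$contact_threshold)
  ct_path <- file.path(out_dir, "contact.json")
  jsonlite::write_json(list(area_nm2 = ct$area_contact,
                            n_contact = ct$n_contact,
                            n_contact_amorphous = ct$n_contact_a,
                            n_contact_crystalline = ct$n_contact_b,
                            probe = config$sasa$probe,
                            n_points = config$sasa$n_points),
                       ct_path, auto_unbox = TRUE, digits = NA)
  write.csv(ct$per_residue, file.path(out_dir, "contact_residues.csv"),
            row.names = FALSE)
  artifacts <- c(artifacts, ct_path)

  # 3. synth
  tx <- config$truth_extra
  n_contact <- if (identical(tx$n_contact, "auto")) ct$n_contact_a else tx$n_contact
  n_total <- if (identical(tx$n_total, "auto")) {
    length(unique(paste(amor$chain_id, amor$residue_index)))
  } else {
    tx$n_total
  }
  truth <- ground_truth(bond = config$bond, xi_water_res = tx$xi_water_res,
                        n_contact = n_contact, n_total = n_total,
                        hold_length = tx$hold_length,
                        detach_length = tx$detach_length)
  proto <- pull_protocol(1, spring_k = config$protocol$spring_k,
                         n_springs = config$protocol$n_springs,
                         n_replicas = config$protocol$n_replicas,
                         temperature = config$protocol$temperature)
  traces <- generate_dataset(config$protocol$velocities, proto, truth,
                             seed = config$seed)
  man <- write_traces(traces, file.path(out_dir, "traces"))
  artifacts <- c(artifacts, man)

  # 4. extract
  ds <- aggregate_traces(traces, smooth_window = config$extract$smooth_window)
  wl <- fit_water_law(ds)
  d_shear <- config$extract$d_shear %||% config$bond$a
  ds <- to_stress(ds, area = ct$area_contact, d_shear = d_shear)
  ds_path <- file.path(out_dir, "friction_dataset.csv")
  write.csv(ds, ds_path, row.names = FALSE)
  artifacts <- c(artifacts, ds_path)

  # 5. fit
  fit <- fit_bond_model(ds, mode = config$fit$mode, init = config$bond)
  fit_path <- file.path(out_dir, "fit_report.json")
  jsonlite::write_json(list(
    mode = fit$mode,
    params = fit$params[c("ma", "U_bond", "m", "xi0", "temperature")],
    param_errors = as.list(fit$param_errors),
    chi2 = fit$chi2, dof = fit$dof,
    xi_visc_res = fit$xi_visc_res,
    eta_viscous_res = fit$eta_viscous_res,
    eta_interface = fit$eta_interface,
    xi_water = wl$xi_water, xi_water_se = wl$se
  ), fit_path, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, fit_path)

  # 6. slide
  sweep <- NULL
  inclined <- NULL
  if (isTRUE(config$slider$enabled)) {
    eta_film <- config$slider$film_eta %||% fit$eta_interface %||% 200
    film <- film_card(eta = eta_film, h = config$slider$film_h)
    sweep <- velocity_sweep(config$slider$velocities,
                            slider_case(1), film = film)
    sw_path <- file.path(out_dir, "slider_sweep.csv")
    write.csv(sweep, sw_path, row.names = FALSE)
    artifacts <- c(artifacts, sw_path)
    inc_case <- slider_case(config$slider$inclined_velocity,
                            load_angle = config$slider$load_angle,
                            plate = c(1600, 600))
    inclined <- run_slider_case(inc_case, film = film)$steady
  }

  # 7. report
  hashes <- tools::md5sum(artifacts)
  rp <- file.path(out_dir, "report.md")
  lines <- c(
    "# silkfric pipeline report", "",
    sprintf("- seed: %d", config$seed),
    sprintf("- composite: %d atoms, %d chains", nrow(comp),
            length(unique(comp$chain_id))),
    sprintf("- contact area A = %.2f nm^2, contacting residues N = %d (amorphous side %d)",
            ct$area_contact, ct$n_contact, ct$n_contact_a),
    sprintf("- water friction xi_w = %.3g +/- %.2g Ns/m per residue",
            wl$xi_water, wl$se),
    sprintf("- fit (%s): %s, chi2 = %.3g on %d dof", fit$mode,
            paste(sprintf("%s = %.4g +/- %.2g", fit$free,
                          vapply(fit$free, function(n) fit$params[[n]], 0),
                          fit$param_errors[fit$free]), collapse = ", "),
            fit$chi2, fit$dof),
    sprintf("- viscous limit: xi = %.3g Ns/m per residue; eta_interface = %.3g Ns/m^2",
            fit$xi_visc_res, fit$eta_interface),
    "", "## Friction dataset", "",
    paste(utils::capture.output(print.data.frame(
      as.data.frame(ds)[, c("velocity", "F_total", "F_water", "F_ac", "f_res",
                            "tau_MPa")],
      digits = 4)), collapse = "\n"),
    "", "## Artifacts", "",
    sprintf("- `%s` md5 `%s`", basename(names(hashes)), unname(hashes))
  )
  if (!is.null(sweep)) {
    lines <- c(lines, "", "## Slider sweep", "",
               paste(utils::capture.output(print.data.frame(
                 as.data.frame(sweep), digits = 4)), collapse = "\n"))
  }
  writeLines(lines, rp)

  invisible(list(config = config, composite = comp, contact = ct,
                 truth = truth, traces = traces, dataset = ds,
                 water_law = wl, fit = fit, sweep = sweep,
                 inclined = inclined, report = rp, hashes = hashes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
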
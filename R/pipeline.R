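# Pipeline orchestration: a validated configuration object, a demo-scale
# design, the simulate -> process -> quantify -> report driver, and the
# fixture generator used by the test suite.

.config_keys <- c("design", "acq", "quant", "lod", "report", "seed")
.lod_keys <- c("atom_counts", "sensitivity", "threshold", "probe",
               "ref_averages", "n_averages", "recycle_delay")

#' Demo-scale study design
#'
#' The bundled two-group design used by the end-to-end demo and the analysis
#' scripts: CAR vs untransduced, five mice sacrificed per timepoint at days 2,
#' 7 and 14 (the study protocol group sizes), measuring tumor, spleen, liver,
#' lymph node, kidney and tail.  Smaller than the full default design only in
#' the organ panel; doses, loadings, fractions and noise levels are the study
#' conditions.
#'
#' @param ... Overrides passed through to [study_design()].
#' @return A [study_design()].
#' @export
demo_design <- function(...) {
  fr <- default_organ_fractions()
  fr <- fr[fr$organ %in% c("tumor", "spleen", "liver", "lymph_node", "kidney"), ]
  args <- list(
    groups = c("CAR", "untransduced"),
    n_mice_per_group = 15L,
    organ_fractions = fr,
    pooled_organs = "lymph_node"
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(study_design, args)
}

#' Assemble and validate a pipeline configuration
#'
#' Single configuration object for [run_pipeline()]: the study design, the
#' acquisition parameters, the quantification settings, the LOD calibration
#' protocol and the reporting options.  Unknown keys are rejected so that a
#' typo in a config file fails loudly before any stage runs.
#'
#' @param design A [study_design()].
#' @param acq An [acquisition_params()].
#' @param quant A [quant_config()]; `NULL` derives one from the design.
#' @param lod List of LOD calibration settings: `atom_counts`, `sensitivity`
#'   (per probe, SNR per 1e15 atoms at `ref_averages`), `threshold`,
#'   `n_averages`, `recycle_delay`.
#' @param report List of reporting options (currently `alpha`).
#' @param seed Top-level integer seed for every stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = demo_design(),
                            acq = acquisition_params(n_averages = 512L),
                            quant = NULL,
                            lod = list(atom_counts = 10^seq(15.5, 19, 0.5),
                                       sensitivity = c("5mm" = 2 / 1.4,
                                                       "10mm" = 2 / 8),
                                       threshold = 2,
                                       ref_averages = 128,
                                       n_averages = 128L,
                                       recycle_delay = 10),
                            report = list(alpha = 0.05),
                            seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(acq, "acq_params"))
  if (is.null(quant)) {
    quant <- quant_config(
      ref_capillary = design$ref_capillary,
      loading = cell_loading(design$loading_atoms_per_cell),
      injected_cells = design$injected_cells
    )
  }
  stopifnot(inherits(quant, "quant_config"))
  unknown <- setdiff(names(lod), .lod_keys)
  if (length(unknown)) {
    stop(sprintf("unknown lod config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (k in c("atom_counts", "sensitivity", "threshold")) {
    if (is.null(lod[[k]])) {
      stop(sprintf("lod config is missing required key '%s'", k),
           call. = FALSE)
    }
  }
  if (is.null(report$alpha)) report$alpha <- 0.05
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(
    list(design = design, acq = acq, quant = quant, lod = lod,
         report = report, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file with (a subset of) top-level keys `seed`, `acq`,
#' `design`, `lod`, `report` and builds a validated [pipeline_config()].
#' Scalar fields override the corresponding constructor defaults; unknown keys
#' at any level are rejected, naming the offending field.
#'
#' @param path Path to the YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), .config_keys)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  acq_args <- y$acq
  if (!is.null(acq_args)) {
    bad <- setdiff(names(acq_args), names(formals(acquisition_params)))
    if (length(bad)) {
      stop(sprintf("unknown acq key(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  acq <- do.call(acquisition_params,
                 if (is.null(acq_args)) list() else acq_args)
  des_args <- y$design
  if (!is.null(des_args)) {
    bad <- setdiff(names(des_args), names(formals(study_design)))
    if (length(bad)) {
      stop(sprintf("unknown design key(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    if (!is.null(des_args$organ_fractions)) {
      des_args$organ_fractions <- as.data.frame(des_args$organ_fractions)
    }
    if (!is.null(des_args$ref_capillary)) {
      des_args$ref_capillary <- do.call(reference_capillary,
                                        des_args$ref_capillary)
    }
    if (!is.null(des_args$noise_sensitivity)) {
      des_args$noise_sensitivity <- unlist(des_args$noise_sensitivity)
    }
    if (!is.null(des_args$probe_by_organ)) {
      des_args$probe_by_organ <- unlist(des_args$probe_by_organ)
    }
    if (!is.null(des_args$organ_mass_g)) {
      des_args$organ_mass_g <- unlist(des_args$organ_mass_g)
    }
  }
  design <- if (is.null(des_args)) demo_design() else
    do.call(demo_design, des_args)
  args <- list(design = design, acq = acq)
  if (!is.null(y$lod)) {
    y$lod$sensitivity <- unlist(y$lod$sensitivity)
    args$lod <- y$lod
  }
  if (!is.null(y$report)) args$report <- y$report
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(pipeline_config, args)
}

#' Run the full pipeline: simulate, quantify, calibrate LOD, report
#'
#' Executes the stages in order on one seed: (1) simulate the study dataset
#' and the auxiliary measurement tables; (2) process and quantify every FID
#' into the biodistribution table; (3) simulate and fit the LOD calibration
#' for each probe, flagging biodistribution rows below the fitted LOD;
#' (4) build the statistical report.  Every artifact is written under
#' `out_dir` and hashed into `manifest.json`; re-running with the same
#' configuration reproduces identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the `biodist` table, `report`, `lod` fits
#'   and the manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- character()

  say("stage simulate: study dataset (seed %d)", config$seed)
  dataset <- simulate_study(config$design, config$acq, seed = config$seed)
  meta <- do.call(rbind, lapply(dataset$samples, function(s) {
    data.frame(sample_id = s$sample_id, mouse_id = s$mouse_id,
               group = s$group, timepoint_d = s$timepoint_d, organ = s$organ,
               mass_g = s$mass_g, pooled_n = s$pooled_n, probe = s$probe,
               stringsAsFactors = FALSE)
  }))
  paths["samples"] <- write_table(meta, file.path(out_dir, "samples.csv"))
  paths["ground_truth"] <- write_table(dataset$truth,
                                       file.path(out_dir, "ground_truth.csv"))
  bli <- simulate_bli_table(seed = derive_seed(config$seed, 900001))
  cyto <- simulate_cytotoxicity_table(seed = derive_seed(config$seed, 900002))
  paths["bli"] <- write_table(bli, file.path(out_dir, "bli.csv"))
  paths["cytotoxicity"] <- write_table(cyto,
                                       file.path(out_dir, "cytotoxicity.csv"))

  say("stage quantify: %d samples", length(dataset$samples))
  biodist <- quantify_study(dataset, config$quant)

  say("stage lod: calibration for %d probe(s)",
      length(config$lod$sensitivity))
  lod_acq <- acquisition_params(
    n_averages = config$lod$n_averages %||% 128L,
    recycle_delay = config$lod$recycle_delay %||% 10
  )
  loading <- config$quant$loading
  lods <- list()
  for (probe in names(config$lod$sensitivity)) {
    series <- simulate_calibration_series(
      lod_acq, config$lod$atom_counts, config$lod$sensitivity[[probe]],
      seed = derive_seed(config$seed, 910000 + match(probe, names(config$lod$sensitivity))),
      ref_averages = config$lod$ref_averages %||% 128
    )
    snr <- vapply(series, function(f) {
      sp <- fid_to_spectrum(f)
      compute_snr(sp, peak_window(-76, 1.5), peak_window(-115, 5))
    }, numeric(1))
    lods[[probe]] <- estimate_lod(attr(series, "atom_counts"), snr,
                                  threshold = config$lod$threshold,
                                  loading = loading, probe = probe)
  }
  lod_df <- do.call(rbind, lapply(lods, function(l) {
    data.frame(probe = l$probe, slope = l$slope, threshold = l$threshold,
               lod_atoms = l$lod_atoms, lod_cells = l$lod_cells,
               r_squared = l$fit_diagnostics$r_squared)
  }))
  paths["lod"] <- write_table(lod_df, file.path(out_dir, "lod.csv"))
  paths["biodistribution"] <- write_table(
    biodist, file.path(out_dir, "biodistribution.csv"))

  # histology emulation: per-tumor counts against the measured tumor signal
  tumors <- biodist[biodist$organ == "tumor" & !biodist$below_lod, ]
  hist_tbl <- NULL
  if (nrow(tumors) >= 3) {
    hist_tbl <- simulate_histology_table(
      stats::setNames(tumors$f19_atoms, tumors$sample_id),
      seed = derive_seed(config$seed, 900003)
    )
    paths["histology"] <- write_table(hist_tbl,
                                      file.path(out_dir, "histology.csv"))
  }

  say("stage report")
  report <- biodistribution_report(biodist, alpha = config$report$alpha)
  paths["report"] <- render_report_md(report, file.path(out_dir, "report.md"))
  paths["tests"] <- write_table(report$tests,
                                file.path(out_dir, "report_tests.csv"))
  paths["summary"] <- write_table(report$summary,
                                  file.path(out_dir, "report_summary.csv"))

  manifest <- list(
    seed = config$seed,
    artifacts = lapply(stats::setNames(nm = names(paths)), function(k) {
      list(path = basename(paths[[k]]),
           md5 = unname(tools::md5sum(paths[[k]])))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: %d artifacts in %s", length(paths), out_dir)
  invisible(list(biodist = biodist, report = report, lod = lods,
                 manifest = manifest, dataset = dataset,
                 bli = bli, cytotoxicity = cyto, histology = hist_tbl))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Generate the small bundled fixture set used by the test suite
#'
#' Writes, under `dir`: six two-peak FIDs (tracer at -91.58 ppm, reference at
#' -76 ppm, known atom counts spanning 1e15 to 1e17) in the text container
#' format, a `metadata.csv` describing them (including ground truth), and a
#' noiseless `calibration.csv` of (atoms, snr) pairs.  Uses a compact
#' acquisition (4096 points) so the whole set stays small; checksums are
#' stable for a fixed seed.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Invisibly, a data.frame of written files and their MD5 checksums.
#' @export
make_fixtures <- function(seed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acq <- acquisition_params(n_points = 4096L, n_averages = 128L,
                            recycle_delay = 10)
  ref <- reference_capillary()
  # line widths scaled with the compact acquisition so the decay is fully
  # sampled, as in the full 32,000-point protocol
  t2_scale <- acq$n_points / 32000
  atoms <- 10^seq(15, 17, length.out = 6)
  meta <- data.frame(fid = sprintf("fid%02d", seq_along(atoms)),
                     true_atoms = atoms,
                     ref_atoms = reference_atoms(ref))
  for (i in seq_along(atoms)) {
    pfc <- pfc_line(atoms[i], T2_star = 0.05 * t2_scale)
    tfa <- tfa_line(reference_atoms(ref), T2_star = 0.08 * t2_scale)
    sigma <- noise_sigma_for_sensitivity(acq, pfc, sensitivity = 2 / 1.4)
    fid <- simulate_fid(acq, list(pfc, tfa), noise_sigma_per_scan = sigma,
                        seed = derive_seed(seed, i))
    write_fid_container(fid, file.path(dir, meta$fid[i]))
  }
  write_table(meta, file.path(dir, "metadata.csv"))
  cal_atoms <- 10^seq(15.5, 18.5, 0.5)
  cal <- data.frame(atoms = cal_atoms, snr = 2 / 1.4 * cal_atoms / 1e15)
  write_table(cal, file.path(dir, "calibration.csv"))
  files <- list.files(dir, full.names = TRUE)
  invisible(data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))))
}
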
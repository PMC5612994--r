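# End-to-end orchestration: simulate -> (estimate) -> decode -> infer -> rsa,
# from a single config with one top-level seed, writing a manifest with
# content hashes for provenance.

#' Pipeline configuration
#'
#' One top-level seed is expanded deterministically into per-stage,
#' per-subject seeds. Any component can be replaced; the defaults give a
#' desk-scale run that finishes in minutes.
#'
#' @param n_subjects simulated subjects (default 20).
#' @param grid a [volume_grid()] (default [default_grid()]).
#' @param design a [design_spec()].
#' @param signal a [signal_spec()] (per-subject seeds override its seed).
#' @param classifier a [classifier_spec()].
#' @param analysis `"familiarity"` or `"identity"`.
#' @param radius_vox searchlight radius in voxels (default 5).
#' @param use_timeseries simulate BOLD series and re-estimate betas instead of
#'   using the generated betas directly (default FALSE; slower, exercises the
#'   GLM stage).
#' @param n_identity_perms identity-null permutations per subject (default 20).
#' @param n_draws group null draws (default 10000).
#' @param z_threshold threshold applied to the z-map (default 1.65).
#' @param rois optional list of [roi_spec()] for the RSA stage (NULL skips it).
#' @param n_bootstrap bootstrap draws for the system contrast (default 1000).
#' @param seed top-level seed.
#' @export
pipeline_config <- function(n_subjects = 20, grid = default_grid(),
                            design = design_spec(), signal = signal_spec(),
                            classifier = classifier_spec(),
                            analysis = "familiarity", radius_vox = 5,
                            use_timeseries = FALSE, n_identity_perms = 20,
                            n_draws = 10000, z_threshold = 1.65,
                            rois = NULL, n_bootstrap = 1000, seed = 1L) {
  structure(list(n_subjects = n_subjects, grid = grid, design = design,
                 signal = signal, classifier = classifier, analysis = analysis,
                 radius_vox = radius_vox, use_timeseries = use_timeseries,
                 n_identity_perms = n_identity_perms, n_draws = n_draws,
                 z_threshold = z_threshold, rois = rois,
                 n_bootstrap = n_bootstrap, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline config from JSON
#'
#' Scalar fields override the defaults of [pipeline_config()]; nested
#' `design` and `signal` objects override the corresponding spec arguments.
#' @param path JSON file.
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- do.call(design_spec, as.list(js$design %||% list()))
  sig_args <- as.list(js$signal %||% list())
  if (!is.null(sig_args$regions)) {
    sig_args$regions <- lapply(seq_len(nrow(sig_args$regions)), function(i)
      as.list(sig_args$regions[i, ]))
  }
  signal <- do.call(signal_spec, sig_args)
  grid <- if (!is.null(js$grid)) volume_grid(js$grid$dims, js$grid$voxel_size)
          else default_grid()
  args <- js[setdiff(names(js), c("design", "signal", "grid"))]
  do.call(pipeline_config, c(args, list(design = design, signal = signal,
                                        grid = grid)))
}

pipeline_log <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full pipeline
#'
#' Simulates `n_subjects` datasets, computes observed and permutation-null
#' searchlight maps, performs group TFCE permutation inference, optionally
#' runs the ROI representational-geometry stage, and writes maps, tables,
#' logs and a machine-readable manifest (with md5 content hashes) to
#' `out_dir`. Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "log.txt"), "w")
  on.exit(close(log_con))
  manifest <- list(stages = list(), parameters = list(
    seed = config$seed, n_subjects = config$n_subjects,
    analysis = config$analysis, radius_vox = config$radius_vox,
    n_draws = config$n_draws, z_threshold = config$z_threshold,
    classifier = unclass(config$classifier),
    signal = unclass(config$signal[setdiff(names(config$signal), "regions")])))
  stage_files <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      files = basename(files),
      md5 = unname(tools::md5sum(files)))
  }
  tryCatch({
    # --- simulate ---------------------------------------------------------
    pipeline_log(log_con, "simulate: %d subjects", config$n_subjects)
    mask <- full_brain_mask(config$grid)
    subjects <- lapply(seq_len(config$n_subjects), function(s) {
      sig <- config$signal
      sig$seed <- derive_seed(config$seed, 100 + s)
      design <- generate_design(config$design, seed = derive_seed(config$seed, s))
      betas <- generate_betas(design, sig, config$grid, mask)
      if (config$use_timeseries) {
        ts <- generate_timeseries(design, betas,
                                  seed = derive_seed(config$seed, 200 + s))
        betas <- estimate_betas(ts, design, mask, config$grid)
      }
      list(design = design, betas = prepare_features(betas))
    })
    design_path <- file.path(out_dir, "trials_subject01.tsv")
    write_trial_table(subjects[[1]]$design, design_path)
    stage_files("simulate", design_path)

    # --- decode -----------------------------------------------------------
    pipeline_log(log_con, "decode: %s searchlight, radius %g vox",
                 config$analysis, config$radius_vox)
    observed <- vector("list", config$n_subjects)
    nulls <- vector("list", config$n_subjects)
    for (s in seq_len(config$n_subjects)) {
      observed[[s]] <- searchlight_map(subjects[[s]]$betas, config$analysis,
                                       config$radius_vox, config$classifier)
      nulls[[s]] <- searchlight_null_maps(subjects[[s]]$betas, config$analysis,
                                          config$radius_vox, config$classifier,
                                          n_perms = config$n_identity_perms,
                                          seed = derive_seed(config$seed, 300 + s))
    }
    group_acc <- Reduce(`+`, lapply(observed, function(m) m$values)) /
      config$n_subjects
    acc_vol <- array(0, config$grid$dims)
    acc_vol[mask$voxels] <- group_acc
    acc_path <- file.path(out_dir, "group_accuracy.nii.gz")
    write_nifti(acc_vol, config$grid, acc_path)
    stage_files("decode", acc_path)

    # --- infer ------------------------------------------------------------
    pipeline_log(log_con, "infer: %d group null draws", config$n_draws)
    zmap <- group_null_zmap(observed, nulls, n_draws = config$n_draws,
                            seed = derive_seed(config$seed, 400))
    z_vol <- array(0, config$grid$dims)
    z_vol[mask$voxels] <- zmap$values
    z_path <- file.path(out_dir, "zmap.nii.gz")
    write_nifti(z_vol, config$grid, z_path)
    flagged <- threshold_zmap(zmap, config$z_threshold)
    thr_path <- file.path(out_dir, "zmap_thresholded.nii.gz")
    write_nifti(array(as.numeric(flagged), config$grid$dims), config$grid, thr_path)
    manifest$results <- list(n_flagged = sum(flagged),
                             max_z = max(zmap$values))
    stage_files("infer", c(z_path, thr_path))
    pipeline_log(log_con, "infer: %d voxels at z >= %.2f", sum(flagged),
                 config$z_threshold)

    # --- rsa (optional) ---------------------------------------------------
    if (!is.null(config$rois)) {
      pipeline_log(log_con, "rsa: %d ROIs", length(config$rois))
      rois <- resolve_roi_overlaps(config$rois, mask)
      rdms <- lapply(subjects, function(su)
        lapply(rois, function(r) crossvalidated_rdm(su$betas, r)))
      systems <- vapply(rois, function(r) r$system, "")
      geom <- inter_roi_distances(rdms, systems = systems)
      mds <- classical_mds(geom$D, k = min(3, length(rois) - 1))
      d_path <- file.path(out_dir, "roi_distances.csv")
      write.csv(geom$D, d_path)
      mds_path <- file.path(out_dir, "mds_coords.csv")
      write.csv(data.frame(roi = geom$roi_names, system = systems, mds), mds_path)
      contrast <- lme_system_contrast(geom, n_bootstrap = config$n_bootstrap,
                                      seed = derive_seed(config$seed, 500))
      c_path <- file.path(out_dir, "system_contrast.csv")
      write.csv(contrast$estimates, c_path, row.names = FALSE)
      stage_files("rsa", c(d_path, mds_path, c_path))
    }

    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    pipeline_log(log_con, "done: %s", out_dir)
    invisible(manifest)
  }, error = function(e) {
    pipeline_log(log_con, "FAILED: %s", conditionMessage(e))
    stop(e)
  })
}
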
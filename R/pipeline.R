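# End-to-end pipeline and command-line entry points.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default: SUV threshold 3.0 (the
#' optimised operating point), HU threshold 110 (captures marrow plus
#' cortical bone), bone-mask smoothing of one voxel, per-slice hole
#' filling, 26-connectivity, inclusive thresholds, physical-coordinate
#' resampling with overshoot clamping.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(suv_th = 3.0, hu_th = 110,
       bone_sigma_mm = NULL, bone_fill = "2d",
       connectivity = 26, min_voxels = 1L,
       resample_mode = "physical", resample_clamp = TRUE,
       match_d_scale = 10, match_s_scale = 1, match_max_distance_mm = 20,
       domain = "bone")
}

#' Run the full segmentation pipeline on a PET/CT DICOM pair
#'
#' Read PET and CT series, convert PET to body-weight SUV, resample CT onto
#' the PET grid, segment bone, mask the SUV map, segment lesions by
#' absolute SUV threshold and quantify them.  When `out_dir` is given, the
#' SUV map, bone mask and lesion label map are written as NIfTI, the
#' per-lesion statistics as CSV and a JSON summary (echoing the effective
#' configuration) alongside.
#'
#' @param pet_dir,ct_dir DICOM series directories.
#' @param out_dir optional output directory.
#' @param config configuration list; see [default_config()].  Partial lists
#'   are completed with the defaults.
#' @param quiet suppress progress messages.
#' @return list with `suv`, `ct_on_pet`, `bone`, `masked_suv`, `labels`,
#'   `stats`, `factors`, `config` (and `files` when `out_dir` is given).
#' @export
run_pipeline <- function(pet_dir, ct_dir, out_dir = NULL,
                         config = default_config(), quiet = FALSE) {
  config <- utils::modifyList(default_config(), config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  say("[read] PET series from %s", pet_dir)
  pet <- stage("read_pet", read_dicom_series(pet_dir, "PET"))
  say("[read] CT series from %s", ct_dir)
  ct <- stage("read_ct", read_dicom_series(ct_dir, "CT"))
  factors <- stage("suv_factors", extract_suv_factors(pet))
  say("[suv] dose %.3g Bq, weight %.1f kg, dt %.0f s",
      factors$injected_dose, factors$patient_weight,
      decay_interval(factors))
  suv <- stage("to_suv", to_suv_map(pet, factors))
  say("[resample] CT %s -> PET grid (%s)",
      paste(dim(ct$data), collapse = "x"), config$resample_mode)
  ct_on_pet <- stage("resample",
    resample_ct_to_pet_grid(ct, pet, mode = config$resample_mode,
                            clamp = config$resample_clamp))
  say("[bone] HU threshold %g", config$hu_th)
  bone <- stage("bone_mask",
    segment_bone(ct_on_pet, hu_threshold = config$hu_th,
                 sigma_mm = config$bone_sigma_mm, fill = config$bone_fill))
  masked <- stage("apply_mask", apply_bone_mask(suv, bone))
  say("[lesion] SUV threshold %g", config$suv_th)
  labels <- stage("segment_lesions",
    segment_lesions(masked, suv_threshold = config$suv_th,
                    connectivity = config$connectivity,
                    min_voxels = config$min_voxels))
  stats <- stage("quantify", quantify_lesions(labels, suv))
  say("[lesion] %d lesion(s) found", nrow(stats))
  out <- list(suv = suv, ct_on_pet = ct_on_pet, bone = bone,
              masked_suv = masked, labels = labels, stats = stats,
              factors = factors, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(
      suv = file.path(out_dir, "suv.nii.gz"),
      bone = file.path(out_dir, "bone_mask.nii.gz"),
      labels = file.path(out_dir, "lesion_labels.nii.gz"),
      csv = file.path(out_dir, "lesions.csv"),
      json = file.path(out_dir, "summary.json"))
    write_nifti(suv, files$suv, suv_factors_obj = factors)
    write_nifti(bone, files$bone)
    write_nifti(labels, files$labels)
    utils::write.csv(stats, files$csv, row.names = FALSE)
    jsonlite::write_json(
      list(config = config[!vapply(config, is.null, logical(1))],
           n_lesions = nrow(stats),
           total_volume_ml = sum(stats$volume_ml)),
      files$json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$files <- files
  }
  out
}

## ---- command line ---------------------------------------------------------

.parse_flags <- function(args) {
  flags <- list(); positional <- character(0); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^--", a)) {
      key <- gsub("-", "_", sub("^--", "", a))
      if (i == length(args) || grepl("^--", args[i + 1L])) {
        flags[[key]] <- TRUE; i <- i + 1L
      } else {
        flags[[key]] <- args[i + 1L]; i <- i + 2L
      }
    } else {
      positional <- c(positional, a); i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

.cli_usage <- function() {
  cat("usage: osteoseg <command> [options]\n\n",
      "commands:\n",
      "  segment  --pet DIR --ct DIR --out DIR [--suv-th 3.0] [--hu-th 110]\n",
      "  validate --pet DIR --ct DIR --ref RTSTRUCT --out DIR [--suv-th 3.0]\n",
      "  sweep    --pet DIR --ct DIR --ref RTSTRUCT --out DIR",
      " [--thresholds 2.0,2.5,3.0,3.5,4,6]\n",
      "  phantom  --out DIR [--seed 1] [--preset widespread|oligo]\n",
      sep = "")
}

#' Command-line interface
#'
#' Dispatches the `segment`, `validate`, `sweep` and `phantom` subcommands.
#' Returns an exit status rather than quitting, so it is scriptable and
#' testable; the wrapper script in `inst/cli/osteoseg.R` forwards the
#' status to the shell.
#'
#' @param args character vector of arguments (default: the command line).
#' @return exit status, invisibly (0 on success, 1 on any error).
#' @export
osteoseg_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  fail <- function(msg) {
    message("error: ", msg)
    .cli_usage()
    invisible(1L)
  }
  if (!length(args)) return(fail("no command given"))
  cmd <- args[1]
  p <- .parse_flags(args[-1])
  fl <- p$flags
  need <- function(key) {
    v <- fl[[key]]
    if (is.null(v)) stop(sprintf("usage error: --%s is required",
                                 gsub("_", "-", key)), call. = FALSE)
    v
  }
  cfg_from_flags <- function() {
    cfg <- default_config()
    if (!is.null(fl$suv_th)) cfg$suv_th <- as.numeric(fl$suv_th)
    if (!is.null(fl$hu_th)) cfg$hu_th <- as.numeric(fl$hu_th)
    if (!is.null(fl$domain)) cfg$domain <- fl$domain
    cfg
  }
  res <- tryCatch({
    switch(cmd,
      segment = {
        pet <- need("pet"); ct <- need("ct"); out <- need("out")
        if (!dir.exists(ct)) stop("usage error: CT directory not found: ",
                                  ct, call. = FALSE)
        if (!dir.exists(pet)) stop("usage error: PET directory not found: ",
                                   pet, call. = FALSE)
        run_pipeline(pet, ct, out_dir = out, config = cfg_from_flags(),
                     quiet = isTRUE(fl$quiet))
        0L
      },
      validate = {
        pet <- need("pet"); ct <- need("ct")
        ref <- need("ref"); out <- need("out")
        cfg <- cfg_from_flags()
        pl <- run_pipeline(pet, ct, config = cfg, quiet = isTRUE(fl$quiet))
        ref_labels <- rasterise_contours(read_rtstruct(ref), pl$suv)
        case <- list(suv = pl$suv, bone = pl$bone, ref_labels = ref_labels)
        rep <- patient_report(list(case), threshold = cfg$suv_th,
                              domain = cfg$domain)
        ev <- .evaluate_case(case, cfg$suv_th, domain = cfg$domain)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(rep$table, file.path(out, "validation.csv"),
                         row.names = FALSE)
        utils::write.csv(unmatched_report(ev$match),
                         file.path(out, "unmatched_lesions.csv"),
                         row.names = FALSE)
        jsonlite::write_json(
          list(config = cfg[!vapply(cfg, is.null, logical(1))],
               lesion_count_r = rep$lesion_count_r),
          file.path(out, "validation.json"), auto_unbox = TRUE,
          digits = NA, pretty = TRUE)
        0L
      },
      sweep = {
        pet <- need("pet"); ct <- need("ct")
        ref <- need("ref"); out <- need("out")
        cfg <- cfg_from_flags()
        ths <- if (is.null(fl$thresholds)) c(2.0, 2.5, 3.0, 3.5, 4, 6)
               else as.numeric(strsplit(fl$thresholds, ",")[[1]])
        pl <- run_pipeline(pet, ct, config = cfg, quiet = isTRUE(fl$quiet))
        ref_labels <- rasterise_contours(read_rtstruct(ref), pl$suv)
        case <- list(suv = pl$suv, bone = pl$bone, ref_labels = ref_labels)
        sw <- sweep_thresholds(list(case), thresholds = ths,
                               domain = cfg$domain)
        opt <- select_optimum_threshold(sw)
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(sw$metrics, file.path(out, "sweep.csv"),
                         row.names = FALSE)
        utils::write.csv(opt$report, file.path(out, "roc_points.csv"),
                         row.names = FALSE)
        jsonlite::write_json(list(optimum_suv_th = opt$threshold),
                             file.path(out, "optimum.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      phantom = {
        out <- need("out")
        seed <- as.integer(fl$seed %||% 1L)
        preset <- fl$preset %||% "oligo"
        ph <- if (identical(preset, "widespread"))
          phantom_cohort(1, seed = seed, n_lesions = 6:8,
                         radii = c(4, 5, 6))[[1]]
        else generate_phantom(phantom_spec(seed = seed))
        write_phantom_dicom(ph, out)
        utils::write.csv(ph$truth_stats,
                         file.path(out, "truth_lesions.csv"),
                         row.names = FALSE)
        0L
      },
      stop("usage error: unknown command '", cmd, "'", call. = FALSE))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}
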
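# Volume I/O (NIfTI-1 via RNifti), YAML pipeline configuration, JSON
# provenance sidecars, and end-to-end pipeline orchestration. All
# randomness flows from a single root seed split per stage.

#' Read a 3D NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return List with `values` (3D array), `voxel_size_mm`, `affine`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI volume: ",
                                           path, " (", conditionMessage(e), ")"))
  if (length(dim(img)) != 3)
    stop("expected a 3D volume, got ", length(dim(img)), "D: ", path)
  vox <- RNifti::pixdim(img)[1:3]
  list(values = array(as.numeric(img), dim = dim(img)),
       voxel_size_mm = as.numeric(vox),
       affine = structure(RNifti::xform(img), class = NULL))
}

#' Write a 3D volume as NIfTI-1
#'
#' Writes float32 data (or uint8 for logical masks) with an RAS affine
#' built from the voxel size; round-trips losslessly through
#' [read_volume()] for these types.
#'
#' @param volume 3D numeric or logical array.
#' @param path output path.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size_mm = c(0.86, 0.86, 1.5)) {
  if (length(dim(volume)) != 3) stop("volume must be 3D")
  is_mask <- is.logical(volume)
  img <- RNifti::asNifti(array(if (is_mask) as.integer(volume)
                               else as.numeric(volume), dim = dim(volume)))
  img <- RNifti::`pixdim<-`(img, voxel_size_mm)
  RNifti::writeNifti(img, path,
                     datatype = if (is_mask) "uint8" else "float")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param stages character vector of enabled stages, in order, among
#'   `"simulate"`, `"reconstruct"`, `"roi"`, `"cohort"`, `"analyze"`.
#' @param phantom a [phantom_spec()] (default [default_phantom_spec()]).
#' @param acq an [acquisition_params()].
#' @param recon a [recon_params()].
#' @param cohort a [cohort_config()].
#' @param seed root seed; stage seeds are derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            stages = c("simulate", "reconstruct", "roi",
                                       "cohort", "analyze"),
                            phantom = default_phantom_spec(),
                            acq = acquisition_params(),
                            recon = recon_params(acq = acq),
                            cohort = cohort_config(),
                            seed = 1L) {
  known <- c("simulate", "reconstruct", "roi", "cohort", "analyze")
  if (!all(stages %in% known))
    stop("unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(out_dir = out_dir, stages = stages, phantom = phantom,
                 acq = acq, recon = recon, cohort = cohort,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# deterministic per-stage seed from the root seed (kept < 2^31)
stage_seed <- function(root, stage) {
  (as.integer(root) * 1000L +
     match(stage, c("simulate", "reconstruct", "roi", "cohort", "analyze"))) %%
    2147483647L
}

write_sidecar <- function(path, params, seed) {
  meta <- list(seed = seed, params = params,
               package = as.character(utils::packageVersion("swiqsm")),
               r_version = R.version.string)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order: phantom simulation (NIfTI
#' magnitude/phase/truth volumes), reconstruction (apparent susceptibility
#' map), ROI extraction (per-phantom subject record CSV), cohort simulation
#' (cohort CSV) and the statistical analysis (JSON summary + CSV tables).
#' Every artifact carries a JSON provenance sidecar with the stage seed and
#' parameters; a rerun with the same configuration reproduces all
#' stochastic stages bit-identically. Disabled stages leave their outputs
#' untouched.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(config$out_dir, ...)
  artifacts <- list()
  acq_sim <- NULL
  chi_map <- NULL

  if ("simulate" %in% config$stages) {
    acq <- config$acq
    acq$rng_seed <- stage_seed(config$seed, "simulate")
    acq_sim <- simulate_acquisition(config$phantom, acq)
    vox <- config$phantom$voxel_size_mm
    write_volume(acq_sim$magnitude, pth("magnitude.nii.gz"), vox)
    write_volume(acq_sim$phase_hpf, pth("phase_hpf.nii.gz"), vox)
    write_volume(acq_sim$truth$chi_true, pth("chi_true.nii.gz"), vox)
    write_volume(acq_sim$truth$brain_mask, pth("brain_mask.nii.gz"), vox)
    write_volume(array(as.numeric(acq_sim$truth$roi_atlas$labels),
                       dim = dim(acq_sim$magnitude)), pth("atlas.nii.gz"), vox)
    write_sidecar(pth("phase_hpf.nii.gz"),
                  list(B0_tesla = acq$B0_tesla, TE_s = acq$TE_s,
                       hpf_kernel = acq$hpf_kernel, snr = acq$snr),
                  acq$rng_seed)
    artifacts$simulate <- pth("phase_hpf.nii.gz")
  }

  if ("reconstruct" %in% config$stages) {
    if (is.null(acq_sim))
      stop("reconstruct stage requires the simulate stage (or loaded volumes)")
    chi_map <- qsm_reconstruct(acq_sim, config$recon)
    vox <- acq_sim$voxel_size_mm
    write_volume(chi_map$values, pth("chi_apparent.nii.gz"), vox)
    write_volume(chi_map$valid_mask, pth("valid_mask.nii.gz"), vox)
    write_sidecar(pth("chi_apparent.nii.gz"), chi_map$provenance,
                  stage_seed(config$seed, "reconstruct"))
    artifacts$reconstruct <- pth("chi_apparent.nii.gz")
  }

  if ("roi" %in% config$stages) {
    if (is.null(chi_map)) stop("roi stage requires the reconstruct stage")
    rec <- build_subject_record(chi_map, acq_sim$truth$roi_atlas,
                                list(subject_id = "phantom", group = "Phantom"))
    utils::write.csv(rec, pth("phantom_rois.csv"), row.names = FALSE)
    write_sidecar(pth("phantom_rois.csv"), list(), stage_seed(config$seed, "roi"))
    artifacts$roi <- pth("phantom_rois.csv")
  }

  if ("cohort" %in% config$stages) {
    cc <- config$cohort
    cc$seed <- stage_seed(config$seed, "cohort")
    cohort <- simulate_cohort(cc)
    write_cohort(cohort, pth("cohort.csv"))
    write_sidecar(pth("cohort.csv"),
                  list(group_sizes = as.list(cc$group_sizes),
                       rho_put = cc$rho_put), cc$seed)
    artifacts$cohort <- pth("cohort.csv")
  }

  if ("analyze" %in% config$stages) {
    if (!file.exists(pth("cohort.csv")))
      stop("analyze stage requires a cohort.csv in the output directory")
    cohort <- read_cohort(pth("cohort.csv"))
    res <- run_full_analysis(cohort)
    utils::write.csv(res$pairwise, pth("pairwise_tests.csv"), row.names = FALSE)
    utils::write.csv(res$roc, pth("roc_table.csv"), row.names = FALSE)
    lda_tab <- do.call(rbind, lapply(names(res$lda_pairs), function(nm) {
      d <- res$lda_pairs[[nm]]$loocv
      data.frame(pair = nm, loocv_sensitivity = d$sensitivity,
                 loocv_specificity = d$specificity, loocv_accuracy = d$accuracy,
                 loocv_ppv = d$ppv, loocv_npv = d$npv)
    }))
    utils::write.csv(lda_tab, pth("lda_loocv.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      alpha_corrected = res$alpha_corrected,
      ancova_F = lapply(res$ancova, function(a) a$F),
      ancova_p = lapply(res$ancova, function(a) a$p),
      four_group_loocv_accuracy = res$lda_all_groups$accuracy
    ), pth("analysis_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
    write_sidecar(pth("analysis_summary.json"), list(),
                  stage_seed(config$seed, "analyze"))
    artifacts$analyze <- pth("analysis_summary.json")
  }
  invisible(artifacts)
}

#' Read / write a cohort configuration as YAML
#'
#' Round-trips the scalar and tabular fields of a [cohort_config()].
#'
#' @param config a `cohort_config`.
#' @param path YAML file path.
#' @return `write_cohort_config` the path invisibly; `read_cohort_config`
#'   a `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$region_means <- as.list(as.data.frame(t(x$region_means)))
  # named atomic vectors serialize as YAML maps only via lists
  for (f in c("group_sizes", "female_fraction", "age_slope",
              "duration_slope_pd", "updrs_base", "updrs_sd"))
    x[[f]] <- as.list(x[[f]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  rm_ <- do.call(rbind, x$region_means)
  colnames(rm_) <- REGION_CODES
  args <- x
  args$region_means <- as.data.frame(rm_)
  for (f in c("group_sizes", "female_fraction", "age_slope",
              "duration_slope_pd", "updrs_base", "updrs_sd"))
    args[[f]] <- unlist(args[[f]])
  do.call(cohort_config, args)
}
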
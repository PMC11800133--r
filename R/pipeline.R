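#' Validate a pipeline configuration file
#'
#' Reads a single YAML file describing an end-to-end run. Recognised
#' top-level keys: `stages` (subset of `simulate_dwi`, `fit_tensor`, `alps`,
#' `volumes`, `simulate_cohort`, `stats`), `out_dir`, `phantom` (arguments
#' of [phantom_spec()] plus `n_directions`, `b`, `n_b0`), `cohort`
#' (arguments of [cohort_params()]), `rois` (path to a ROI JSON, or omitted
#' to use the phantom's ground-truth centers), `roi_diameter_mm`,
#' `lesion_side`, `seeds` (per-stage: `dwi`, `cohort`), `verbose`. Unknown
#' keys are rejected with the offending key path; omitted keys take
#' defaults.
#'
#' @param path YAML file path.
#' @return A validated configuration list of class `alps_run_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("stages", "out_dir", "phantom", "cohort", "rois",
             "roi_diameter_mm", "lesion_side", "seeds", "verbose")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  all_stages <- c("simulate_dwi", "fit_tensor", "alps", "volumes",
                  "simulate_cohort", "stats")
  cfg <- list(
    stages = if (is.null(raw$stages)) all_stages else unlist(raw$stages),
    out_dir = if (is.null(raw$out_dir)) "alps_run" else raw$out_dir,
    phantom = if (is.null(raw$phantom)) list() else raw$phantom,
    cohort = if (is.null(raw$cohort)) list() else raw$cohort,
    rois = raw$rois,
    roi_diameter_mm = if (is.null(raw$roi_diameter_mm)) 5
                      else raw$roi_diameter_mm,
    lesion_side = if (is.null(raw$lesion_side)) "none" else raw$lesion_side,
    seeds = utils::modifyList(list(dwi = 1L, cohort = 1L),
                              if (is.null(raw$seeds)) list() else raw$seeds),
    verbose = isTRUE(raw$verbose)
  )
  bad_st <- setdiff(cfg$stages, all_stages)
  if (length(bad_st)) stop("unknown stage: ", paste(bad_st, collapse = ", "))
  if (cfg$roi_diameter_mm <= 0) stop("roi_diameter_mm must be positive")
  cfg$lesion_side <- match.arg(cfg$lesion_side,
                               c("none", "left", "right", "subtentorial"))
  known_ph <- c("grid", "voxdim", "S0", "n_directions", "b", "n_b0",
                "noise_sigma", "lesion")
  bad_ph <- setdiff(names(cfg$phantom), known_ph)
  if (length(bad_ph)) stop("unknown config key: phantom.", bad_ph[1])
  known_co <- c("n_sich", "n_hc", "n_subtentorial", "or_per_0.1",
                "favorable_target", "beta_age", "beta_nihss")
  bad_co <- setdiff(names(cfg$cohort), known_co)
  if (length(bad_co)) stop("unknown config key: cohort.", bad_co[1])
  bad_seed <- setdiff(names(cfg$seeds), c("dwi", "cohort"))
  if (length(bad_seed)) stop("unknown config key: seeds.", bad_seed[1])
  class(cfg) <- "alps_run_config"
  cfg
}

config_phantom_spec <- function(cfg) {
  ph <- cfg$phantom
  scheme <- make_scheme(
    n_directions = if (is.null(ph$n_directions)) 30 else ph$n_directions,
    b = if (is.null(ph$b)) 1000 else ph$b,
    n_b0 = if (is.null(ph$n_b0)) 1 else ph$n_b0)
  lesion <- ph$lesion
  if (!is.null(lesion))
    lesion <- lapply(lesion, function(e)
      list(center = unlist(e$center), semiaxes = unlist(e$semiaxes)))
  phantom_spec(
    grid = if (is.null(ph$grid)) c(96, 96, 40) else unlist(ph$grid),
    voxdim = if (is.null(ph$voxdim)) c(1.7, 1.7, 2) else unlist(ph$voxdim),
    S0 = if (is.null(ph$S0)) 1000 else ph$S0,
    scheme = scheme,
    noise_sigma = if (is.null(ph$noise_sigma)) 0 else ph$noise_sigma,
    seed = cfg$seeds$dwi,
    lesion = lesion)
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the enabled stages in dependency order -- phantom simulation,
#' tensor fitting, ALPS computation, lesion volumetry, cohort simulation and
#' cohort statistics -- writing all outputs plus a machine-readable JSON
#' manifest (configuration, seeds, per-file MD5 checksums) into the output
#' directory. Identical configuration and seeds give identical outputs; a
#' stage whose outputs already exist with checksums matching the manifest is
#' skipped as a no-op.
#'
#' @param config An `alps_run_config` from [validate_config()], or a path to
#'   a YAML config file.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "alps_run_config"))
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message("[alps-glymph] ", ...)
  pth <- function(...) file.path(config$out_dir, ...)

  prev <- NULL
  mpath <- pth("manifest.json")
  if (file.exists(mpath))
    prev <- tryCatch(jsonlite::read_json(mpath), error = function(e) NULL)
  manifest <- list(package = "glymphalps",
                   version = as.character(utils::packageVersion("glymphalps")),
                   seeds = config$seeds, stages = list())

  stage_done <- function(name, outputs, params) {
    hash <- digest_params(params)
    rec <- prev$stages[[name]]
    if (!is.null(rec) && identical(rec$param_hash, hash) &&
        all(file.exists(outputs))) {
      sums <- as.vector(tools::md5sum(outputs))
      if (identical(unname(unlist(rec$checksums)), sums)) {
        say("stage ", name, ": outputs up to date, skipping")
        return(list(param_hash = hash,
                    checksums = stats::setNames(as.list(sums), basename(outputs)),
                    skipped = TRUE))
      }
    }
    NULL
  }
  record <- function(outputs, params) {
    sums <- as.vector(tools::md5sum(outputs))
    list(param_hash = digest_params(params),
         checksums = stats::setNames(as.list(sums), basename(outputs)),
         skipped = FALSE)
  }

  st <- config$stages
  phantom_built <- NULL

  if ("simulate_dwi" %in% st) {
    spec <- config_phantom_spec(config)
    outs <- c(pth("dwi.nii"), pth("dwi.bval"), pth("dwi.bvec"),
              pth("rois_truth.json"), pth("truth.json"))
    has_lesion <- !is.null(spec$lesion)
    if (has_lesion) outs <- c(outs, pth("hematoma.nii"), pth("total_lesion.nii"))
    done <- stage_done("simulate_dwi", outs, c(config$phantom,
                                               seed = config$seeds$dwi))
    if (is.null(done)) {
      say("stage simulate_dwi")
      phantom_built <- build_alps_phantom(spec)
      write_dwi(phantom_built$dwi, pth("dwi"))
      tr <- phantom_built$truth
      rois <- mapply(function(h, f, i, j, k)
        roi_spec(h, f, c(i, j, k), config$roi_diameter_mm),
        tr$roi_centers$hemisphere, tr$roi_centers$fiber_class,
        tr$roi_centers$i, tr$roi_centers$j, tr$roi_centers$k,
        SIMPLIFY = FALSE)
      write_rois(rois, pth("rois_truth.json"))
      jsonlite::write_json(list(alps_analytic = as.list(tr$alps_analytic),
                                dmv_slice = tr$dmv_slice),
                           pth("truth.json"), auto_unbox = TRUE, digits = NA)
      if (has_lesion) {
        lm <- tr$lesion_masks
        write_map(lm$hematoma, pth("hematoma.nii"), lm$voxdim, lm$affine)
        write_map(lm$total_lesion, pth("total_lesion.nii"), lm$voxdim,
                  lm$affine)
      }
      done <- record(outs, c(config$phantom, seed = config$seeds$dwi))
    }
    manifest$stages$simulate_dwi <- done
  }

  if ("fit_tensor" %in% st) {
    dep <- c(pth("dwi.nii"), pth("dwi.bval"), pth("dwi.bvec"))
    if (!all(file.exists(dep)))
      stop("stage 'fit_tensor': missing dependency output of 'simulate_dwi' (",
           paste(basename(dep[!file.exists(dep)]), collapse = ", "), ")")
    outs <- pth(c("Dxx.nii", "Dyy.nii", "Dzz.nii", "FA.nii", "colorFA.nii"))
    done <- stage_done("fit_tensor", outs, list(dep = as.vector(tools::md5sum(dep))))
    if (is.null(done)) {
      say("stage fit_tensor")
      dwi <- read_dwi(dep[1], dep[2], dep[3])
      field <- fit_tensor(dwi)
      maps <- axis_diffusivities(field)
      feats <- eigendecompose(field)
      ev <- feats$eigenvalues; g3 <- dim(ev)[1:3]
      fa <- fractional_anisotropy(pmax(array(ev[, , , 1], g3), 0),
                                  pmax(array(ev[, , , 2], g3), 0),
                                  pmax(array(ev[, , , 3], g3), 0))
      write_map(maps$Dxx, outs[1], dwi$voxdim, dwi$affine)
      write_map(maps$Dyy, outs[2], dwi$voxdim, dwi$affine)
      write_map(maps$Dzz, outs[3], dwi$voxdim, dwi$affine)
      write_map(fa, outs[4], dwi$voxdim, dwi$affine)
      write_map(color_fa(feats), outs[5], dwi$voxdim, dwi$affine)
      done <- record(outs, list(dep = as.vector(tools::md5sum(dep))))
    }
    manifest$stages$fit_tensor <- done
  }

  if ("alps" %in% st) {
    dep <- pth(c("Dxx.nii", "Dyy.nii", "Dzz.nii"))
    if (!all(file.exists(dep)))
      stop("stage 'alps': missing dependency output of 'fit_tensor' (",
           paste(basename(dep[!file.exists(dep)]), collapse = ", "), ")")
    roi_file <- if (is.null(config$rois)) pth("rois_truth.json") else config$rois
    if (!file.exists(roi_file))
      stop("stage 'alps': ROI file not found: ", roi_file)
    outs <- c(pth("alps.json"), pth("roi_means.csv"))
    params <- list(dep = as.vector(tools::md5sum(c(dep, roi_file))),
                   side = config$lesion_side)
    done <- stage_done("alps", outs, params)
    if (is.null(done)) {
      say("stage alps")
      maps <- list(Dxx = read_map(dep[1])$data, Dyy = read_map(dep[2])$data,
                   Dzz = read_map(dep[3])$data)
      vox <- read_map(dep[1])$voxdim
      rois <- read_rois(roi_file)
      res <- alps_from_maps(maps, rois, vox, config$lesion_side)
      jsonlite::write_json(unclass(res$result), outs[1], auto_unbox = TRUE,
                           digits = NA, na = "null")
      utils::write.csv(res$roi_means, outs[2], row.names = FALSE)
      done <- record(outs, params)
    }
    manifest$stages$alps <- done
  }

  if ("volumes" %in% st) {
    dep <- pth(c("hematoma.nii", "total_lesion.nii"))
    if (!all(file.exists(dep)))
      stop("stage 'volumes': missing dependency output of 'simulate_dwi' (",
           paste(basename(dep[!file.exists(dep)]), collapse = ", "), ")")
    outs <- pth("volumes.json")
    params <- list(dep = as.vector(tools::md5sum(dep)))
    done <- stage_done("volumes", outs, params)
    if (is.null(done)) {
      say("stage volumes")
      hem <- read_map(dep[1]); tot <- read_map(dep[2])
      rep_ <- volume_report(hem$data, tot$data, hem$voxdim, tot$voxdim)
      jsonlite::write_json(unclass(rep_), outs, auto_unbox = TRUE,
                           digits = NA, na = "null")
      done <- record(outs, params)
    }
    manifest$stages$volumes <- done
  }

  if ("simulate_cohort" %in% st) {
    outs <- pth("cohort.csv")
    params <- c(config$cohort, seed = config$seeds$cohort)
    done <- stage_done("simulate_cohort", outs, params)
    if (is.null(done)) {
      say("stage simulate_cohort")
      cp <- do.call(cohort_params, config$cohort)
      write_cohort(simulate_cohort(cp, seed = config$seeds$cohort), outs)
      done <- record(outs, params)
    }
    manifest$stages$simulate_cohort <- done
  }

  if ("stats" %in% st) {
    dep <- pth("cohort.csv")
    if (!file.exists(dep))
      stop("stage 'stats': missing dependency output of 'simulate_cohort' ",
           "(cohort.csv)")
    outs <- pth(c("group_comparison.csv", "outcome_determinants.csv",
                  "alps_correlations.csv", "outcome_model.csv"))
    params <- list(dep = as.vector(tools::md5sum(dep)))
    done <- stage_done("stats", outs, params)
    if (is.null(done)) {
      say("stage stats")
      cohort <- read_cohort(dep)
      utils::write.csv(analyze_group_comparison(cohort), outs[1],
                       row.names = FALSE)
      utils::write.csv(analyze_outcome_determinants(cohort), outs[2],
                       row.names = FALSE)
      utils::write.csv(analyze_alps_correlations(cohort), outs[3],
                       row.names = FALSE)
      utils::write.csv(analyze_outcome_model(cohort), outs[4],
                       row.names = FALSE)
      done <- record(outs, params)
    }
    manifest$stages$stats <- done
  }

  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Stable hash of stage parameters for the idempotency check.
digest_params <- function(params) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(params), collapse = ""), tf)
  unname(as.vector(tools::md5sum(tf)))
}
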
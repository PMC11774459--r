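#' Run the automatable landmark-pair workflow stages
#'
#' Executes the requested stage sequence of the landmark-pair pipeline
#' on files named in the configuration and writes a JSON manifest
#' recording inputs, a configuration hash, the seed and per-stage
#' outputs. Deterministic stages produce identical manifests for
#' identical config + seed.
#'
#' Supported stages and their config blocks:
#' \describe{
#'   \item{`overwrite`}{`volume`, `masks` (paths), `constants` (HU);
#'     writes `overwritten.nii.gz`. Flattens organ intensities under
#'     the masks.}
#'   \item{`project`}{`landmarks`, `dvf`; writes
#'     `projected_landmarks.csv`. Projects image-1 landmarks through a
#'     DVF.}
#'   \item{`refine`}{`volume` (or the overwrite output), `landmarks`,
#'     optional `manual_mask`; writes `refined_landmarks.csv` with
#'     substrate and divergence columns. Sphere-grows every type-1
#'     landmark.}
#'   \item{`evaluate`}{`landmarks1`, `landmarks2`, optional `dvf`,
#'     optional `cutoff` (mm); writes `tre_summary.json` and
#'     `tre_distances.csv`.}
#' }
#'
#' @param config Configuration list as returned by [read_run_config()],
#'   with a `stages` character vector and an `inputs` block of file
#'   paths as described above.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json` in `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0L)
    stop("config$stages must name at least one stage")
  known <- c("overwrite", "project", "refine", "evaluate")
  if (!all(stages %in% known))
    stop(sprintf("unknown stage(s): %s",
                 paste(setdiff(stages, known), collapse = ", ")))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- config$inputs %||% list()
  need <- function(field, stage) {
    p <- inputs[[field]]
    if (is.null(p)) stop(sprintf("stage '%s' needs inputs$%s", stage, field))
    p
  }
  need_file <- function(field, stage) {
    p <- need(field, stage)
    if (!file.exists(p))
      stop(sprintf("stage '%s': missing input file '%s'", stage, p))
    p
  }
  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)
  gcfg <- do.call(growth_config, config$growth %||% list())
  vcfg <- do.call(vesselness_config, config$vesselness %||% list())

  manifest <- list(package = "vesselmark",
                   version = as.character(utils::packageVersion("vesselmark")),
                   seed = seed, config_hash = config_hash(config),
                   stages = list())
  current_volume <- NULL

  for (stage in stages) {
    outputs <- character(0)
    if (stage == "overwrite") {
      vol <- read_volume(need_file("volume", stage))
      mask_paths <- need("masks", stage)
      masks <- lapply(mask_paths, function(p) {
        if (!file.exists(p)) stop(sprintf("missing mask file '%s'", p))
        read_volume(p)
      })
      vol <- overwrite_organ_intensities(vol, masks,
                                         as.numeric(need("constants", stage)))
      out <- file.path(out_dir, "overwritten.nii.gz")
      write_volume(vol, out)
      current_volume <- out
      outputs <- out
    } else if (stage == "project") {
      lms <- read_landmarks(need_file("landmarks", stage))
      dvf <- read_vector_field(need_file("dvf", stage))
      proj <- project_landmarks_through_dvf(lms, dvf)
      out <- file.path(out_dir, "projected_landmarks.csv")
      write_landmarks(proj, out)
      outputs <- out
    } else if (stage == "refine") {
      vol_path <- inputs$volume %||% current_volume
      if (is.null(vol_path) || !file.exists(vol_path))
        stop("stage 'refine': missing input volume")
      vol <- read_volume(vol_path)
      lms <- read_landmarks(need_file("landmarks", stage))
      mmask <- if (!is.null(inputs$manual_mask))
        read_volume(need_file("manual_mask", stage)) else NULL
      refined <- lms
      refined$diverged <- 0L
      for (i in seq_len(nrow(lms))) {
        if (lms$type[i] != "type1") next
        r <- refine_landmark(vol, lms[i, ], gcfg, manual_mask = mmask,
                             vconfig = vcfg)
        refined[i, names(lms)] <- r[1, names(lms)]
        refined$diverged[i] <- as.integer(r$substrate == "none")
      }
      out <- file.path(out_dir, "refined_landmarks.csv")
      write_landmarks(refined, out)
      outputs <- out
    } else if (stage == "evaluate") {
      lms1 <- read_landmarks(need_file("landmarks1", stage))
      lms2 <- read_landmarks(need_file("landmarks2", stage))
      dvf <- if (!is.null(inputs$dvf))
        read_vector_field(need_file("dvf", stage)) else NULL
      cutoff <- config$evaluate$cutoff %||% NULL
      proj <- if (is.null(dvf)) lms1
              else project_landmarks_through_dvf(lms1, dvf)
      d <- landmark_errors(proj, lms2)
      summ <- summarize_errors(d, cutoff = cutoff)
      out1 <- file.path(out_dir, "tre_summary.json")
      jsonlite::write_json(
        list(mean_mm = summ$mean, std_mm = summ$std, n_total = summ$n_total,
             n_excluded = summ$n_excluded,
             cutoff_mm = if (is.na(summ$cutoff)) NULL else summ$cutoff),
        out1, auto_unbox = TRUE, digits = NA, null = "null")
      out2 <- file.path(out_dir, "tre_distances.csv")
      writeLines(c("id,distance_mm",
                   paste(names(d), fmt_num(d), sep = ",")), out2)
      outputs <- c(out1, out2)
    }
    manifest$stages[[stage]] <- list(
      outputs = basename(outputs),
      md5 = unname(tools::md5sum(outputs)))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable md5 of a configuration list via its canonical JSON rendering.
# The output directory is not part of the scientific configuration.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  config$out_dir <- NULL
  keyed <- config[order(names(config))]
  jsonlite::write_json(keyed, tf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tf))
}
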
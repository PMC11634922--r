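# Pipeline orchestration: config handling and the convert / synth / analyze
# / validate / correlate stages, each a thin, reproducible wrapper over the
# analysis modules. Every output table carries the config hash so a run can
# be reproduced exactly.

default_config <- function() {
  list(
    inputs = character(0),     # JSON frame dirs and/or flattened CSVs
    scores_csv = NULL,         # quality-scores CSV (correlate stage)
    fps = 30,
    analysis = "both",         # cwt | gcwt | both
    keypoint_set = "all",      # all | reduced (GCWT component set)
    use_coi = TRUE,            # average inside the cone of influence
    band = NULL,               # optional period band in seconds
    normalize = TRUE,          # GCWT component-power normalization
    about_origin = TRUE,       # GCWT moments about the origin
    surrogate_seed = 1L,
    n_shuffles = 1L,
    out_dir = "dyadsync_out",
    synth = list(n_dyads = 10L, kappa_grid = c(0, 1, 3, 8), noise_sd = 0.5,
                 seed = 1L, duration_s = 180, fps = 30)
  )
}

#' Load a pipeline run configuration
#'
#' Merges, in increasing precedence: package defaults, an optional YAML
#' file, and explicit overrides. See [run_analyze()] for the meaning of the
#' fields.
#'
#' @param path optional YAML config path.
#' @param overrides named list of fields to override.
#' @return A `run_config` list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg <- utils::modifyList(cfg, overrides)
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  hashable <- unclass(cfg)
  hashable$out_dir <- NULL
  yaml::write_yaml(hashable, tf)
  unname(tools::md5sum(tf))
}

log_info <- function(cfg, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message("[dyadsync] ", msg)
  log_file <- file.path(cfg$out_dir, "run.log")
  if (dir.exists(cfg$out_dir)) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg, "\n",
        file = log_file, append = TRUE)
  }
  invisible(msg)
}

validate_config <- function(cfg, need_scores = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  for (p in cfg$inputs) {
    if (!file.exists(p) && !dir.exists(p)) stopf("input path does not exist: %s", p)
  }
  if (need_scores) {
    if (is.null(cfg$scores_csv)) stopf("correlate stage needs scores_csv")
    if (!file.exists(cfg$scores_csv)) {
      stopf("scores file does not exist: %s", cfg$scores_csv)
    }
  }
  if (!cfg$analysis %in% c("cwt", "gcwt", "both")) {
    stopf("analysis must be one of cwt, gcwt, both")
  }
  invisible(TRUE)
}

ensure_out_dir <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  invisible(cfg$out_dir)
}

write_metadata <- function(cfg, stage, extra = list()) {
  meta <- c(
    list(stage = stage, config = unclass(cfg), config_hash = config_hash(cfg),
         package_version = as.character(utils::packageVersion("dyadsync"))),
    extra
  )
  jsonlite::write_json(meta, file.path(cfg$out_dir, paste0("metadata_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(meta)
}

# Load every configured input into a list of dyad recordings. JSON
# directories go through identity assignment; CSVs are read directly.
load_dyads <- function(cfg) {
  dyads <- list()
  for (p in cfg$inputs) {
    if (dir.exists(p)) {
      frames <- load_openpose_frames(p)
      dyads[[length(dyads) + 1L]] <-
        assign_identities(frames, fps = cfg$fps, dyad_id = basename(p))
    } else {
      dyads[[length(dyads) + 1L]] <- read_dyad_csv(p, fps = cfg$fps)
    }
  }
  if (length(dyads) == 0L) stopf("no inputs configured")
  dyads
}

#' Convert OpenPose JSON frame directories to flattened dyad CSVs
#'
#' Each configured JSON directory is parsed, person identities are resolved
#' with [assign_identities()], and the recording is written as one
#' flattened CSV (`converted/<name>.csv` under the output directory).
#' Conversion is deterministic: re-running produces byte-identical CSVs.
#'
#' @param cfg a `run_config` from [load_run_config()].
#' @return Character vector of written CSV paths, invisibly.
#' @export
run_convert <- function(cfg) {
  validate_config(cfg)
  ensure_out_dir(cfg)
  dirs <- cfg$inputs[dir.exists(cfg$inputs)]
  if (length(dirs) == 0L) stopf("no JSON frame directories among inputs")
  out <- character(0)
  conv_dir <- file.path(cfg$out_dir, "converted")
  dir.create(conv_dir, showWarnings = FALSE, recursive = TRUE)
  for (p in dirs) {
    frames <- load_openpose_frames(p)
    dyad <- assign_identities(frames, fps = cfg$fps, dyad_id = basename(p))
    dest <- file.path(conv_dir, paste0(basename(p), ".csv"))
    write_dyad_csv(dyad, dest)
    log_info(cfg, "converted %s (%d frames) -> %s", basename(p),
             dyad$n_frames, dest)
    out <- c(out, dest)
  }
  write_metadata(cfg, "convert", list(n_recordings = length(out)))
  invisible(out)
}

#' Generate a synthetic cohort on disk
#'
#' Simulates `cfg$synth$n_dyads` coupled dyads with [generate_cohort()] and
#' writes each as a flattened CSV plus a shared quality-scores CSV, so the
#' downstream stages can be exercised without real recordings.
#'
#' @param cfg a `run_config`; the `synth` block carries `n_dyads`,
#'   `kappa_grid`, `noise_sd`, `seed`, `duration_s`, and `fps`.
#' @return The cohort, invisibly.
#' @export
run_synth <- function(cfg) {
  ensure_out_dir(cfg)
  s <- cfg$synth
  cohort <- generate_cohort(
    n_dyads = s$n_dyads, kappa_grid = s$kappa_grid, noise_sd = s$noise_sd,
    seed = s$seed,
    base_spec = coupling_spec(duration_s = s$duration_s, fps = s$fps)
  )
  synth_dir <- file.path(cfg$out_dir, "synth")
  dir.create(synth_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in cohort$dyads) {
    write_dyad_csv(d, file.path(synth_dir, paste0(d$dyad_id, ".csv")))
  }
  write_quality_csv(cohort$quality_scores, file.path(synth_dir, "quality_scores.csv"))
  truth <- data.frame(
    dyad_id = vapply(cohort$dyads, function(d) d$dyad_id, character(1)),
    kappa = cohort$true_coupling
  )
  utils::write.csv(truth, file.path(synth_dir, "true_coupling.csv"),
                   row.names = FALSE)
  log_info(cfg, "wrote %d synthetic dyads to %s", length(cohort$dyads), synth_dir)
  write_metadata(cfg, "synth", list(n_dyads = length(cohort$dyads)))
  invisible(cohort)
}

compute_summaries <- function(cfg, dyads) {
  rows <- list()
  for (d in dyads) {
    row <- tryCatch({
      t0 <- Sys.time()
      out <- data.frame(dyad_id = d$dyad_id,
                        mean_coherence = NA_real_, mean_magnitude = NA_real_)
      if (cfg$analysis %in% c("cwt", "both")) {
        coh <- dyad_head_coherence(d)
        out$mean_coherence <- mean_coherence(coh, band = cfg$band,
                                             use_coi = cfg$use_coi)
      }
      if (cfg$analysis %in% c("gcwt", "both")) {
        g <- gcwt_dyad(d, keypoint_set = cfg$keypoint_set,
                       normalize = cfg$normalize,
                       about_origin = cfg$about_origin)
        out$mean_magnitude <- mean_magnitude(g, band = cfg$band,
                                             use_coi = cfg$use_coi)
      }
      log_info(cfg, "analyzed %s in %.2f s", d$dyad_id,
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
      out
    }, error = function(e) {
      log_info(cfg, "FAILED %s: %s", d$dyad_id, conditionMessage(e))
      NULL
    })
    rows[[length(rows) + 1L]] <- row
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) stopf("all dyads failed to analyze")
  do.call(rbind, rows)
}

#' Per-dyad synchrony summary table
#'
#' Computes, for every configured input recording, the mean head-movement
#' wavelet coherence (`analysis = "cwt"`), the mean GCWT magnitude
#' (`"gcwt"`), or both. Per-dyad failures are logged and skipped; an error
#' is raised only if every dyad fails. The table is written to
#' `summaries.csv` together with a metadata JSON carrying all parameters
#' and the config hash.
#'
#' @param cfg a `run_config`.
#' @param dyads optional list of [dyad_recording()]s; defaults to loading
#'   `cfg$inputs`.
#' @return Data frame with `dyad_id`, `mean_coherence`, `mean_magnitude`,
#'   `band`, `coi_policy`, `keypoint_set`, `config_hash`.
#' @export
run_analyze <- function(cfg, dyads = NULL) {
  validate_config(cfg)
  ensure_out_dir(cfg)
  dyads <- dyads %||% load_dyads(cfg)
  out <- compute_summaries(cfg, dyads)
  out$band <- if (is.null(cfg$band)) "full" else paste(cfg$band, collapse = "-")
  out$coi_policy <- if (cfg$use_coi) "coi" else "all"
  out$keypoint_set <- if (is.numeric(cfg$keypoint_set)) "custom" else cfg$keypoint_set
  out$config_hash <- config_hash(cfg)
  utils::write.csv(out, file.path(cfg$out_dir, "summaries.csv"), row.names = FALSE)
  write_metadata(cfg, "analyze", list(n_dyads = nrow(out)))
  out
}

#' Surrogate (pseudo-dyad) validation report
#'
#' Compares real dyads against derangement pseudo-dyads on each requested
#' synchrony measure with a two-tailed paired t-test, writing a tidy
#' `validation.csv`.
#'
#' @inheritParams run_analyze
#' @return Data frame with one row per measure: `measure`, `n`,
#'   `mean_real`, `mean_pseudo`, `t`, `df`, `p`, `seed`, `config_hash`.
#' @export
run_validate <- function(cfg, dyads = NULL) {
  validate_config(cfg)
  ensure_out_dir(cfg)
  dyads <- dyads %||% load_dyads(cfg)
  measures <- switch(cfg$analysis, cwt = "cwt", gcwt = "gcwt",
                     both = c("cwt", "gcwt"))
  rows <- lapply(measures, function(m) {
    cmp <- surrogate_validation(
      dyads, measure = m, seed = cfg$surrogate_seed,
      n_shuffles = cfg$n_shuffles,
      keypoint_set = if (m == "gcwt") cfg$keypoint_set else "all"
    )
    log_info(cfg, "validate [%s]: t(%d) = %.3f, p = %.3g", m, cmp$df,
             cmp$t_stat, cmp$p_value)
    data.frame(
      measure = m, n = length(cmp$real_values),
      mean_real = mean(cmp$real_values),
      mean_pseudo = mean(cmp$pseudo_values),
      t = cmp$t_stat, df = cmp$df, p = cmp$p_value,
      seed = cfg$surrogate_seed
    )
  })
  out <- do.call(rbind, rows)
  out$config_hash <- config_hash(cfg)
  utils::write.csv(out, file.path(cfg$out_dir, "validation.csv"), row.names = FALSE)
  write_metadata(cfg, "validate", list(seed = cfg$surrogate_seed))
  out
}

#' Correlate synchrony summaries with interaction-quality subscales
#'
#' Computes per-dyad summaries (or reuses a supplied summary table), joins
#' them with the quality-scores CSV by `dyad_id`, and reports Spearman
#' correlations per subscale -- plus a CWT-vs-GCWT cross-method row when
#' both measures are available. Results go to `correlations.csv`.
#'
#' @inheritParams run_analyze
#' @param summaries optional precomputed output of [run_analyze()].
#' @return Tidy data frame: `measure`, `subscale`, `rho`, `p`, `n`,
#'   `config_hash`.
#' @export
run_correlate <- function(cfg, dyads = NULL, summaries = NULL) {
  validate_config(cfg, need_scores = TRUE)
  ensure_out_dir(cfg)
  scores <- read_quality_csv(cfg$scores_csv)
  if (is.null(summaries)) {
    dyads <- dyads %||% load_dyads(cfg)
    summaries <- run_analyze(cfg, dyads)
  }
  idx <- match(scores$dyad_id, summaries$dyad_id)
  if (anyNA(idx)) stopf("dyad ids in scores do not match analyzed dyads")
  summaries <- summaries[idx, ]

  out <- NULL
  if (cfg$analysis %in% c("cwt", "both")) {
    tab <- spearman_with_quality(
      summaries$mean_coherence, scores,
      other = if (cfg$analysis == "both") summaries$mean_magnitude else NULL
    )
    tab$measure[tab$measure == "summary"] <- "cwt"
    tab$measure[tab$measure == "cross_method"] <- "cwt_vs_gcwt"
    out <- rbind(out, tab)
  }
  if (cfg$analysis %in% c("gcwt", "both")) {
    tab <- spearman_with_quality(summaries$mean_magnitude, scores)
    tab$measure[tab$measure == "summary"] <- "gcwt"
    out <- rbind(out, tab)
  }
  out$config_hash <- config_hash(cfg)
  utils::write.csv(out, file.path(cfg$out_dir, "correlations.csv"), row.names = FALSE)
  write_metadata(cfg, "correlate", list(n_dyads = nrow(scores)))
  out
}
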
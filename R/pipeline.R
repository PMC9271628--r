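#' Default pipeline configuration
#'
#' A nested list of every stage's tunables with the standard resting-state
#' defaults: synthetic input, 125 Hz / 1-60 Hz / 50 Hz notch / 2,000-ms
#' epochs / first 20 preprocessing, 2-20 Hz microstate band with four
#' T-AAHC clusters, per-epoch-mean covariance omega, alpha 0.05.
#'
#' @param ... Named overrides merged over the defaults (nested lists are
#'   merged one level deep, e.g. `preprocess = list(n_epochs = 10)`).
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    input = "synthetic", # or "edf_dir"
    edf_dir = NULL,
    seed = 1,
    out_dir = NULL,
    synthetic = list(n_subjects_per_group = 20),
    preprocess = list(
      resample_hz = 125, bp_low = 1, bp_high = 60, notch_hz = 50,
      epoch_ms = 2000, n_epochs = 20
    ),
    microstate = list(
      ms_bp_low = 2, ms_bp_high = 20, n_clusters = 4, min_duration_ms = 0,
      shared_templates = FALSE
    ),
    omega = list(omega_mode = "per_epoch_mean", omega_matrix = "covariance"),
    stats = list(alpha = 0.05, gg_correction = FALSE)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [default_config()].
#' @return A `run_config` list (defaults filled in for absent keys).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(default_config, yaml::read_yaml(path))
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config") || is.list(cfg))
  if (!cfg$input %in% c("synthetic", "edf_dir")) {
    stop("input mode must be 'synthetic' or 'edf_dir'", call. = FALSE)
  }
  if (cfg$input == "edf_dir") {
    if (is.null(cfg$edf_dir) || !dir.exists(cfg$edf_dir)) {
      stop("edf_dir does not exist: ", cfg$edf_dir %||% "<missing>", call. = FALSE)
    }
    manifest <- file.path(cfg$edf_dir, "manifest.csv")
    if (!file.exists(manifest)) {
      stop("edf_dir must contain a manifest.csv (subject_id, group, age, edf)",
        call. = FALSE
      )
    }
  }
  if (is.null(cfg$out_dir)) stop("out_dir must be set", call. = FALSE)
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run: acquire input (synthetic cohort or a
#' directory of EDF recordings with a manifest), preprocess, run the
#' group-wise microstate analysis (2-20 Hz band, GFP peaks, T-AAHC,
#' canonical labeling, back-fit) and the omega complexity analysis
#' (broadband), then the group statistics. All stage outputs are written as
#' CSV under `out_dir`; the run is deterministic given (config, seed).
#'
#' @param cfg A `run_config` from [default_config()] or [read_config()].
#' @return A `run_manifest` tibble listing every output file with its MD5
#'   checksum; attributes `config_hash`, `seed`, `n_subjects`, `warnings`.
#' @export
run_pipeline <- function(cfg = default_config()) {
  validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  # --- input ---
  cohort <- stage("input", {
    if (cfg$input == "synthetic") {
      n <- cfg$synthetic$n_subjects_per_group
      nc <- nc_spec_default()
      lls <- lls_spec_default()
      nc$n_subjects_per_group <- n
      lls$n_subjects_per_group <- n
      nc$n_epochs <- cfg$preprocess$n_epochs
      lls$n_epochs <- cfg$preprocess$n_epochs
      generate_group_cohort(nc, lls, seed = cfg$seed)
    } else {
      manifest <- readr::read_csv(file.path(cfg$edf_dir, "manifest.csv"),
        show_col_types = FALSE
      )
      manifest$epochs <- lapply(seq_len(nrow(manifest)), function(i) {
        rec <- load_recording(file.path(cfg$edf_dir, manifest$edf[i]))
        pp <- cfg$preprocess
        preprocess_recording(rec,
          resample_hz = pp$resample_hz, bp_low = pp$bp_low,
          bp_high = pp$bp_high, notch_hz = pp$notch_hz,
          epoch_ms = pp$epoch_ms, n_epochs = pp$n_epochs
        )
      })
      manifest
    }
  })

  # --- microstate band + analysis per group ---
  ms_cfg <- cfg$microstate
  ms_cohort <- cohort
  ms_cohort$epochs <- lapply(
    cohort$epochs,
    function(ep) average_reference(eeg_bandpass(ep, ms_cfg$ms_bp_low, ms_cfg$ms_bp_high))
  )
  canon <- canonical_maps(montage_1020())
  groups <- unique(ms_cohort$group)
  ms_res <- stage("microstate", {
    if (isTRUE(ms_cfg$shared_templates)) {
      one <- run_group_microstate(ms_cohort,
        canon = canon,
        k = ms_cfg$n_clusters, min_duration_ms = ms_cfg$min_duration_ms
      )
      list(prototypes = stats::setNames(list(one$prototypes), "shared"),
           reports = one$reports)
    } else {
      per <- lapply(groups, function(g) {
        run_group_microstate(ms_cohort[ms_cohort$group == g, , drop = FALSE],
          canon = canon,
          k = ms_cfg$n_clusters, min_duration_ms = ms_cfg$min_duration_ms
        )
      })
      list(
        prototypes = stats::setNames(lapply(per, `[[`, "prototypes"), groups),
        reports = dplyr::bind_rows(lapply(per, `[[`, "reports"))
      )
    }
  })
  ms_outcomes <- cohort_outcomes(ms_res$reports)

  # --- omega on the broadband epochs ---
  om <- stage("omega", {
    cohort_omega(cohort,
      mode = cfg$omega$omega_mode, matrix_type = cfg$omega$omega_matrix
    )
  })
  om_long <- tidyr::pivot_longer(
    om,
    dplyr::all_of(c("omega_global", "omega_anterior", "omega_posterior")),
    names_to = "class", values_to = "value"
  )
  om_long$measure <- "omega"
  om_long$class <- sub("^omega_", "", om_long$class)
  outcomes <- dplyr::bind_rows(
    ms_outcomes,
    om_long[, c("subject_id", "group", "age", "measure", "class", "value")]
  )

  # --- statistics ---
  enough <- length(groups) >= 2 && min(table(cohort$group)) >= 2
  stats_res <- stage("stats", {
    if (enough) {
      run_group_stats(outcomes, gg_correction = cfg$stats$gg_correction)
    } else {
      warnings_log <<- c(warnings_log,
        "fewer than 2 subjects per group in 2 groups: statistics skipped")
      list(rm = tibble::tibble(), univariate = tibble::tibble())
    }
  })

  # --- write outputs ---
  files <- c(
    outcomes = "outcomes.csv",
    omega = "omega.csv",
    stats_rm = "stats_rm.csv",
    stats_univariate = "stats_univariate.csv"
  )
  readr::write_csv(outcomes, file.path(cfg$out_dir, files["outcomes"]))
  readr::write_csv(om, file.path(cfg$out_dir, files["omega"]))
  readr::write_csv(stats_res$rm, file.path(cfg$out_dir, files["stats_rm"]))
  readr::write_csv(stats_res$univariate,
    file.path(cfg$out_dir, files["stats_univariate"])
  )
  proto_files <- vapply(names(ms_res$prototypes), function(g) {
    f <- file.path(cfg$out_dir, paste0("prototypes_", g, ".tsv"))
    pm <- ms_res$prototypes[[g]]$maps
    utils::write.table(
      data.frame(channel = rownames(pm), pm, check.names = FALSE),
      f,
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    f
  }, "")
  out_files <- c(file.path(cfg$out_dir, files), proto_files)
  manifest <- tibble::tibble(
    file = basename(out_files),
    md5 = unname(tools::md5sum(out_files)),
    rows = vapply(out_files, function(f) length(readLines(f)) - 1L, 0L)
  )
  attr(manifest, "config_hash") <- rlang::hash(unclass(cfg))
  attr(manifest, "seed") <- cfg$seed
  attr(manifest, "n_subjects") <- nrow(cohort)
  attr(manifest, "warnings") <- warnings_log
  readr::write_csv(manifest, file.path(cfg$out_dir, "run_manifest.csv"))
  class(manifest) <- c("run_manifest", class(manifest))
  manifest
}
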
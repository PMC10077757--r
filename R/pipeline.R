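default_config <- function() {
  list(
    seed = 1L,
    out_dir = "synscreen_run",
    n_perm = 1000L,
    thresholds = list(
      fold_change = 5,
      bliss = 0,
      sensitivity_viability = 0.5,
      top_dose_nM = 10000,
      min_set_size = 5
    ),
    simulate = list(
      n_lines = 2L,
      n_mono_compounds = 6L,
      n_library_compounds = 24L,
      frac_synergistic = 1 / 6,
      delta = 0.2,
      sigma = 0.05,
      replicates = 2L,
      n_ped = 20L,
      n_adult = 60L,
      n_panel_compounds = 60L,
      n_pathways = 6L,
      shifted_pathway = "PATHWAY_01",
      shift = -0.15
    )
  )
}

#' Validate and complete a pipeline configuration
#'
#' Merges a raw configuration (a named list, or the path to a YAML file)
#' over the defaults, rejecting unknown keys and out-of-range values. The
#' default thresholds are the screen-analysis conventions used throughout
#' the package: fold-change 5 and Bliss 0 for hit selection, 50% viability
#' at a 10 uM top dose for the sensitivity classification, and a minimum
#' set size of 5 for enrichment.
#'
#' @param raw Named list or YAML file path; `NULL` or an empty list yields
#'   the full default configuration.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw) && length(raw) == 1) {
    raw <- yaml::read_yaml(raw)
  }
  raw <- raw %||% list()
  if (!is.list(raw)) abort("config must be a named list or a YAML file path")
  cfg <- merge_config(default_config(), raw, path = "config")

  if (!is_number(cfg$n_perm) || cfg$n_perm < 100) {
    abort("config error: n_perm must be a number >= 100")
  }
  thr <- cfg$thresholds
  for (key in names(thr)) {
    if (!is_number(thr[[key]])) {
      abort(paste0("config error: thresholds$", key, " must be a finite number"))
    }
  }
  if (thr$fold_change <= 0) abort("config error: thresholds$fold_change must be > 0")
  if (thr$min_set_size < 1) abort("config error: thresholds$min_set_size must be >= 1")
  if (thr$sensitivity_viability <= 0 || thr$sensitivity_viability >= 1) {
    abort("config error: thresholds$sensitivity_viability must be in (0, 1)")
  }
  if (!is_number(cfg$seed) || cfg$seed < 0 || cfg$seed > 2^31 - 1000) {
    abort("config error: seed must be an integer in [0, 2^31 - 1000]")
  }
  sim <- cfg$simulate
  if (sim$frac_synergistic < 0 || sim$frac_synergistic > 1) {
    abort("config error: simulate$frac_synergistic must be in [0, 1]")
  }
  if (sim$sigma < 0) abort("config error: simulate$sigma must be >= 0")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

merge_config <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("config error: unknown key(s) under ", path, ": ",
                 paste(unknown, collapse = ", ")))
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        abort(paste0("config error: ", path, "$", key, " must be a block"))
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(path, "$", key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the simulate / normalize / fit / synergy / enrich pipeline
#'
#' Executes the full analysis on a simulated design: generates a
#' monotherapy screen, an anchored combination library screen and a panel
#' sensitivity dataset; normalizes raw signals to viability; fits
#' dose-response curves; scores synergy and selects hits; and runs
#' compound-set enrichment. Every stage writes a TSV plus a JSON metadata
#' sidecar (config hash, seed, package version); filter counts are
#' appended to `pipeline.log`; and a manifest of output files with MD5
#' content hashes is written last. Re-running with an identical
#' configuration reproduces identical hashes.
#'
#' @param config A `run_config` from [validate_config()] (or anything it
#'   accepts).
#' @return The manifest tibble (`stage`, `file`, `md5`), invisibly.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  cat(sprintf("run_pipeline seed=%d config_hash=%s\n", cfg$seed,
              config_hash(cfg)), file = log_path)
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  manifest <- list()
  emit <- function(stage, file) {
    hash <- unname(tools::md5sum(file))
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, file = basename(file), md5 = hash
    )
    sidecar <- paste0(file, ".meta.json")
    jsonlite::write_json(
      list(stage = stage, config_hash = config_hash(cfg), seed = cfg$seed,
           package = "synscreen",
           version = as.character(utils::packageVersion("synscreen"))),
      sidecar, auto_unbox = TRUE
    )
  }
  sim <- cfg$simulate
  thr <- cfg$thresholds
  nm <- noise_model(sim$sigma, sim$replicates)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      logf("stage %s FAILED: %s", stage, conditionMessage(e))
      if (length(manifest) > 0) {
        readr::write_tsv(dplyr::bind_rows(manifest),
                         file.path(out, "manifest.tsv"))
      }
      abort(paste0("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # --- simulate ---------------------------------------------------------
  screen <- NULL
  panel <- NULL
  run_stage("simulate", {
    mono_sim <- gen_monotherapy_screen(
      n_lines = sim$n_lines, compounds = sim$n_mono_compounds,
      noise = nm, seed = cfg$seed + 11L
    )
    wells_path <- file.path(out, "mono_wells.csv")
    write_screen_table(mono_sim$wells, wells_path)
    readr::write_tsv(mono_sim$truth, file.path(out, "mono_truth.tsv"))
    emit("simulate", wells_path)
    emit("simulate", file.path(out, "mono_truth.tsv"))

    screen <- gen_anchored_library_screen(
      n_compounds = sim$n_library_compounds,
      frac_synergistic = sim$frac_synergistic, delta = sim$delta,
      noise = noise_model(sim$sigma, 1L), seed = cfg$seed + 23L
    )
    panel <- gen_sensitivity_dataset(
      n_ped = sim$n_ped, n_adult = sim$n_adult,
      n_compounds = sim$n_panel_compounds, n_pathways = sim$n_pathways,
      shifted_pathways = setNames(sim$shift, sim$shifted_pathway),
      seed = cfg$seed + 37L
    )
    write_sensitivity_dataset(panel$dataset, file.path(out, "panel"))
    for (f in c("panel_auc.tsv", "panel_cells.tsv", "panel_compounds.tsv")) {
      emit("simulate", file.path(out, f))
    }
    logf("simulate: %d mono wells; %d library compounds (%d synergistic); %d panel lines",
         nrow(mono_sim$wells), sim$n_library_compounds,
         sum(screen$truth$synergistic), sim$n_ped + sim$n_adult)
  })

  # --- normalize --------------------------------------------------------
  points <- run_stage("normalize", {
    wells <- read_screen_table(file.path(out, "mono_wells.csv"))
    pts <- normalize_viability(wells)
    path <- file.path(out, "viability_points.tsv")
    readr::write_tsv(pts, path)
    emit("normalize", path)
    logf("normalize: %d wells -> %d viability points", nrow(wells), nrow(pts))
    pts
  })

  # --- fit --------------------------------------------------------------
  fits <- run_stage("fit", {
    f <- fit_dose_response(points)
    f$sensitivity <- classify_sensitivity(
      fourpl(thr$top_dose_nM, f$e0, f$einf, f$ec50_nM, f$hill)
    )
    path <- file.path(out, "dose_response_fits.tsv")
    readr::write_tsv(f, path)
    emit("fit", path)
    logf("fit: %d curves; %d not converged; %d censored IC50",
         nrow(f), sum(!f$converged), sum(f$ic50_censored != "none"))
    f
  })

  # --- synergy ----------------------------------------------------------
  run_stage("synergy", {
    scored <- score_anchored_screen(screen, fc_threshold = thr$fold_change,
                                    bliss_threshold = thr$bliss)
    per_anchor <- tidyr::unnest(
      scored[c("cell_line", "compound", "per_anchor")], "per_anchor"
    )
    flat <- scored[setdiff(names(scored), "per_anchor")]
    path <- file.path(out, "synergy_metrics.tsv")
    readr::write_tsv(flat, path)
    readr::write_tsv(per_anchor, file.path(out, "synergy_per_anchor.tsv"))
    emit("synergy", path)
    emit("synergy", file.path(out, "synergy_per_anchor.tsv"))
    logf("synergy: %d combinations scored; %d hits (fc>%g or bliss>%g)",
         nrow(flat), sum(flat$is_hit), thr$fold_change, thr$bliss)
  })

  # --- enrich -----------------------------------------------------------
  run_stage("enrich", {
    msgs <- character()
    res <- withCallingHandlers(
      compound_set_enrichment(panel$dataset, n_perm = cfg$n_perm,
                              seed = cfg$seed + 53L,
                              min_size = thr$min_set_size),
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
      },
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      }
    )
    flat <- res
    flat$leading_edge <- vapply(flat$leading_edge, paste, "", collapse = ";")
    path <- file.path(out, "enrichment.tsv")
    readr::write_tsv(tibble::as_tibble(flat), path)
    emit("enrich", path)
    for (m in msgs) logf("enrich: %s", trimws(m))
    logf("enrich: %d sets tested; %d with padj < 0.05", nrow(res),
         sum(res$padj < 0.05))
  })

  manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest, file.path(out, "manifest.tsv"))
  logf("done: %d output files", nrow(manifest))
  invisible(manifest)
}
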
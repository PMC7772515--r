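# End-to-end orchestration: generate -> measure -> test -> simulate -> MI
# -> uncaging, with a single global seed, per-stage derived sub-seeds and
# deterministic plain-text outputs.

pipeline_stages <- c("generate", "morphometry", "stats", "simulate", "mi",
                     "uncage")

# Stable sub-seed from (global seed, stage name); inserting a stage does not
# reshuffle the seeds of the others.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 48611 * 32717 + h * 131) %% 2147483647L)
}

pipeline_defaults <- function() {
  list(
    stages = pipeline_stages,
    seed = 1L,
    out_dir = "spinesim_run",
    input_dir = NULL,
    regions = c("CA1_PSR", "CB"),
    n_dendrites = 25L,
    verbose = TRUE,
    sim = list(case = 1, freqs = seq(1, 10, by = 1), n_trials = 3,
               duration = 20000, sigma_e = 1),
    uncage = list(n_per_group = 35,
                  long = c(mean = 0.92, sd = 0.54),
                  short = c(mean = 1.66, sd = 0.94),
                  n_trials = 5, noise_sd = 0.1)
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path",
                             call. = FALSE)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  bad <- setdiff(cfg$stages, pipeline_stages)
  if (length(bad))
    stop("unknown pipeline stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg$stages <- pipeline_stages[pipeline_stages %in% cfg$stages]
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run: synthetic dataset generation per region,
#' morphometry summaries, the statistical comparisons and correlations,
#' a two-layer neuron simulation, the MI tuning curve and the uncaging
#' cohort comparison. Every stage derives its own sub-seed from the global
#' seed, so two runs with the same config produce identical output files.
#'
#' @param config Named list, or path to a YAML/JSON file. Recognised
#'   fields: `stages` (subset of generate, morphometry, stats, simulate,
#'   mi, uncage), `seed`, `out_dir`, `input_dir` (pre-existing dataset CSVs
#'   when the generate stage is omitted), `regions`, `n_dendrites`,
#'   `verbose`, `sim` (case, freqs, n_trials, duration, sigma_e) and
#'   `uncage` (n_per_group, long/short group mean and sd, n_trials,
#'   noise_sd). Unspecified fields fall back to defaults.
#' @return Invisibly, a list with the per-stage in-memory results and the
#'   paths of all files written under `out_dir`.
#' @examples
#' \donttest{
#' out <- run_pipeline(list(out_dir = tempfile(), seed = 7,
#'                          stages = c("generate", "morphometry"),
#'                          regions = "CA1_PSR", n_dendrites = 5,
#'                          verbose = FALSE))
#' names(out$results)
#' }
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(cfg$verbose)) message("[spinesim] ", ...)
  paths <- character()
  results <- list()

  jsonlite::write_json(cfg[setdiff(names(cfg), "verbose")],
                       file.path(cfg$out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  datasets <- NULL
  if ("generate" %in% cfg$stages) {
    say("generate: ", length(cfg$regions), " region(s), ",
        cfg$n_dendrites, " dendrites each")
    sseed <- stage_seed(cfg$seed, "generate")
    datasets <- lapply(seq_along(cfg$regions), function(i) {
      generate_region(region_presets(cfg$regions[i]), cfg$n_dendrites,
                      seed = sseed + i)
    })
    names(datasets) <- cfg$regions
    for (r in cfg$regions) {
      p <- write_spine_dataset(datasets[[r]],
                               file.path(cfg$out_dir, r))
      paths <- c(paths, p)
    }
    results$datasets <- datasets
  } else if (!is.null(cfg$input_dir)) {
    datasets <- lapply(cfg$regions, function(r)
      read_spine_dataset(file.path(cfg$input_dir, r)))
    names(datasets) <- cfg$regions
    results$datasets <- datasets
  }

  needs_data <- intersect(c("morphometry", "stats"), cfg$stages)
  if (length(needs_data) && is.null(datasets))
    stop(sprintf(
      "dependency error: stage '%s' requires outputs of stage 'generate' %s",
      needs_data[1], "(or an input_dir)"), call. = FALSE)

  if ("morphometry" %in% cfg$stages) {
    say("morphometry: per-dendrite and per-region summaries")
    summaries <- lapply(datasets, morphometry_summary)
    per_dend <- do.call(rbind, lapply(summaries, `[[`, "per_dendrite"))
    per_region <- do.call(rbind, lapply(summaries, `[[`, "per_region"))
    rownames(per_dend) <- rownames(per_region) <- NULL
    f1 <- file.path(cfg$out_dir, "per_dendrite.csv")
    f2 <- file.path(cfg$out_dir, "per_region.csv")
    utils::write.csv(per_dend, f1, row.names = FALSE)
    utils::write.csv(per_region, f2, row.names = FALSE)
    paths <- c(paths, f1, f2)
    results$morphometry <- list(per_dendrite = per_dend,
                                per_region = per_region)
  }

  if ("stats" %in% cfg$stages) {
    say("stats: correlations and region comparisons")
    res <- list()
    for (r in names(datasets)) {
      sp <- datasets[[r]]$spines
      sp <- sp[!sp$filopodium, , drop = FALSE]
      if (nrow(sp) >= 4)
        res[[paste0(r, ": head volume vs PSD area")]] <-
          choose_and_correlate(sp$head_volume_um3, sp$psd_area_um2)
      if ("morphometry" %in% cfg$stages) {
        pd <- results$morphometry$per_dendrite
        pd <- pd[pd$region == datasets[[r]]$config$region_label, ]
        if (nrow(pd) >= 4)
          res[[paste0(r, ": diameter vs PSD-area density")]] <-
            choose_and_correlate(pd$diameter_um, pd$psd_area_density)
      }
    }
    if (length(datasets) >= 2) {
      groups <- lapply(datasets, function(d)
        d$spines$head_volume_um3[!d$spines$filopodium])
      res[["head volume across regions"]] <- choose_and_compare(groups)
    }
    tab <- stat_results_table(res)
    f <- file.path(cfg$out_dir, "stat_results.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    paths <- c(paths, f)
    results$stats <- res
  }

  sim <- NULL
  if ("simulate" %in% cfg$stages) {
    say("simulate: two-layer neuron, case ", cfg$sim$case)
    params <- two_layer_neuron(sigma_e = cfg$sim$sigma_e,
                               duration = cfg$sim$duration)
    sim <- run_simulation(params, case = cfg$sim$case,
                          seed = stage_seed(cfg$seed, "simulate"))
    trains <- rbind(
      do.call(rbind, lapply(seq_along(sim$dendritic), function(j)
        if (length(sim$dendritic[[j]]))
          data.frame(train_id = sprintf("dend_%02d", j),
                     time_ms = as.numeric(sim$dendritic[[j]])))),
      if (length(sim$somatic))
        data.frame(train_id = "soma", time_ms = as.numeric(sim$somatic))
    )
    f <- file.path(cfg$out_dir, "spike_trains.csv")
    utils::write.csv(trains, f, row.names = FALSE)
    paths <- c(paths, f)
    results$simulation <- sim
  }

  if ("mi" %in% cfg$stages) {
    say("mi: tuning curve over ", length(cfg$sim$freqs), " frequencies")
    params <- two_layer_neuron(sigma_e = cfg$sim$sigma_e,
                               duration = cfg$sim$duration)
    curve <- tuning_curve(params, case = cfg$sim$case,
                          freqs = cfg$sim$freqs,
                          n_trials = cfg$sim$n_trials,
                          seed = stage_seed(cfg$seed, "mi"))
    f <- file.path(cfg$out_dir, "mi_curve.csv")
    utils::write.csv(as.data.frame(curve), f, row.names = FALSE)
    paths <- c(paths, f)
    results$mi_curve <- curve
  }

  if ("uncage" %in% cfg$stages) {
    say("uncage: long vs short neck cohorts, n = ",
        cfg$uncage$n_per_group, " each")
    results$uncaging <- with_seed(stage_seed(cfg$seed, "uncage"), {
      u <- cfg$uncage
      long <- measure_uncaging_cohort(u$n_per_group, u$long[["mean"]],
                                      u$long[["sd"]], n_trials = u$n_trials,
                                      noise_sd = u$noise_sd)
      short <- measure_uncaging_cohort(u$n_per_group, u$short[["mean"]],
                                       u$short[["sd"]], n_trials = u$n_trials,
                                       noise_sd = u$noise_sd)
      cmp <- choose_and_compare(list(long_neck = long$amplitude,
                                     short_neck = short$amplitude))
      tab <- rbind(data.frame(group = "long_neck", long),
                   data.frame(group = "short_neck", short))
      f <- file.path(cfg$out_dir, "uncaging_amplitudes.csv")
      utils::write.csv(tab, f, row.names = FALSE)
      list(amplitudes = tab, comparison = cmp, path = f)
    })
    paths <- c(paths, results$uncaging$path)
  }

  say("done: ", length(paths), " file(s) in ", cfg$out_dir)
  invisible(list(config = cfg, results = results, paths = unname(paths)))
}
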
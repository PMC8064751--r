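#' Pipeline configuration
#'
#' Bundles the stage configurations for [run_pipeline()]. The single seed
#' fans out to fixed per-stage child seeds, so any stage can be rerun in
#' isolation and reproduce its part of the bundle.
#'
#' @param generator A [generator_config()].
#' @param spectral A [spectral_config()].
#' @param locomotion A [locomotion_config()].
#' @param decoding List of decoding options (`n_neuron_grid`, `n_combos`,
#'   `min_bin_samples`, `locomotion`).
#' @param stats List of stats options (`n_perm`).
#' @param seed Master seed; overrides the generator seed.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            spectral = spectral_config(),
                            locomotion = locomotion_config(),
                            decoding = list(n_neuron_grid = NULL,
                                            n_combos = 25,
                                            min_bin_samples = 20,
                                            locomotion = NULL),
                            stats = list(n_perm = 2000),
                            seed = 1L) {
  generator$seed <- seed
  structure(list(generator = generator, spectral = spectral,
                 locomotion = locomotion, decoding = decoding,
                 stats = stats, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Generates a grating session and a gray-screen block, then runs the
#' analysis stages in order: condition-resolved band powers from the
#' gray-block LFP, trial assembly, per-unit rates and laser ratios with
#' waveform classification, per-unit mutual information by laser condition,
#' population decoding (LOOXV accuracy per laser condition plus the
#' count-matched curve), and group-level laser contrasts. Artifacts (trial
#' CSV, metrics CSV, MI CSV, decoding JSON, stats JSON, figures, and a
#' markdown report) are written under `out_dir`; all numeric outputs are
#' reproducible from the config seed.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing). `NULL` skips all
#'   file output and just returns the results list.
#' @param gray_block_duration Length of the gray-screen block used for the
#'   LFP stage, seconds.
#' @param include_lfp Set `FALSE` to skip the LFP stage entirely.
#' @return A list with elements `trials`, `band_powers`, `unit_metrics`,
#'   `mi`, `decoding`, `count_matched`, `stats`, and `paths` (written
#'   files), invisibly-ready for further analysis.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         gray_block_duration = 200, include_lfp = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  paths <- list()

  gen <- pipeline_stage("generate", generate_session(cfg$generator,
                                                     include_lfp = FALSE))
  sess <- gen$session

  band_powers <- NULL
  if (include_lfp) {
    gcfg <- cfg$generator
    gray <- pipeline_stage("gray_block",
                           generate_gray_block(gcfg,
                                               block_duration =
                                                 gray_block_duration))
    band_powers <- pipeline_stage("spectra", condition_band_power(
      gray$session, window_length = 4, cfg = cfg$spectral,
      lcfg = cfg$locomotion, band = "gamma"))
  }

  trials <- pipeline_stage("trials",
                           build_trials(sess, cfg = cfg$locomotion))

  unit_metrics <- pipeline_stage("unit_metrics", {
    feats <- session_waveform_features(sess)
    cls <- classify_ns_bs(feats)
    ratios_still <- laser_rate_ratios(trials, "still")
    cv_tbl <- purrr::map_dfr(attr(trials, "unit_ids"), function(id) {
      wl <- attr(trials, "window_length")
      tibble::tibble(
        unit_id = id,
        cv_off = coefficient_of_variation(
          trials[[id]][!trials$laser_on] / wl),
        cv_on = coefficient_of_variation(
          trials[[id]][trials$laser_on] / wl))
    })
    feats |>
      dplyr::left_join(cls$labels, by = "unit_id") |>
      dplyr::left_join(ratios_still, by = "unit_id") |>
      dplyr::left_join(cv_tbl, by = "unit_id")
  })

  mi <- pipeline_stage("mutual_information",
                       mi_by_condition(trials, split = "laser_on"))

  dec <- pipeline_stage("decoding", {
    per_cond <- purrr::map_dfr(c(FALSE, TRUE), function(on) {
      sub <- trials[trials$laser_on == on, , drop = FALSE]
      res <- looxv_accuracy(count_matrix(sub),
                            group_orientations(sub$direction))
      tibble::tibble(laser_on = on, accuracy = res$accuracy,
                     n_trials = res$n_trials)
    })
    cm <- count_matched_decoding(
      trials,
      n_neuron_grid = cfg$decoding$n_neuron_grid,
      n_combos = cfg$decoding$n_combos,
      min_bin_samples = cfg$decoding$min_bin_samples,
      locomotion = cfg$decoding$locomotion,
      seed = derive_seed(cfg$seed, 4L))
    list(accuracy = per_cond, count_matched = cm)
  })

  stats_res <- pipeline_stage("group_stats", {
    mi_wide <- mi |>
      dplyr::select("unit_id", "laser_on", "mi") |>
      tidyr::pivot_wider(names_from = "laser_on", values_from = "mi",
                         names_prefix = "laser_")
    mi_test <- rank_tests(mi_wide$laser_FALSE, mi_wide$laser_TRUE,
                          paired = TRUE)
    ratio_test <- rank_tests(unit_metrics$rate_off, unit_metrics$rate_on,
                             paired = TRUE)
    gamma_test <- NULL
    if (!is.null(band_powers)) {
      still <- band_powers[band_powers$locomotion == "still", ]
      if (sum(!still$laser_on) >= 2 && sum(still$laser_on) >= 2) {
        gamma_test <- rank_tests(still$power[!still$laser_on],
                                 still$power[still$laser_on])
      }
    }
    list(mi_laser = mi_test, rate_laser = ratio_test, gamma_laser = gamma_test)
  })

  if (!is.null(out_dir)) {
    paths$trials <- file.path(out_dir, "trials.csv")
    write_trials_csv(trials, paths$trials)
    paths$metrics <- file.path(out_dir, "unit_metrics.csv")
    write.csv(unit_metrics, paths$metrics, row.names = FALSE)
    paths$mi <- file.path(out_dir, "mi.csv")
    write.csv(mi, paths$mi, row.names = FALSE)
    paths$decoding <- file.path(out_dir, "decoding.json")
    jsonlite::write_json(list(accuracy = dec$accuracy,
                              count_matched = dec$count_matched),
                         paths$decoding, digits = NA, dataframe = "rows")
    paths$stats <- file.path(out_dir, "stats.json")
    jsonlite::write_json(
      list(mi_laser = stats_res$mi_laser,
           rate_laser = stats_res$rate_laser,
           gamma_laser = stats_res$gamma_laser,
           seed = cfg$seed),
      paths$stats, digits = NA, dataframe = "rows", null = "null")
    if (!is.null(band_powers)) {
      paths$band_powers <- file.path(out_dir, "band_powers.csv")
      write.csv(band_powers, paths$band_powers, row.names = FALSE)
    }

    figs <- list(
      rate_ratios = plot_rate_ratios(
        dplyr::rename(unit_metrics, cell_class = "cell_class")),
      mi_scatter = plot_mi_scatter(mi),
      count_matched = plot_count_matched(dec$count_matched))
    if (!is.null(band_powers)) {
      figs$power_bands <- plot_power_bands(band_powers)
    }
    for (nm in names(figs)) {
      paths[[paste0("fig_", nm)]] <- file.path(out_dir,
                                               paste0(nm, ".png"))
      suppressMessages(ggplot2::ggsave(paths[[paste0("fig_", nm)]],
                                       figs[[nm]], width = 5, height = 4,
                                       dpi = 120))
    }

    paths$report <- file.path(out_dir, "report.md")
    rep <- c(
      "# Synthetic-session analysis report",
      sprintf("seed: %d", cfg$seed), "",
      "## Decoding accuracy (orientation, LOOXV)",
      sprintf("- laser off: %.3f (%d trials)", dec$accuracy$accuracy[1],
              dec$accuracy$n_trials[1]),
      sprintf("- laser on:  %.3f (%d trials)", dec$accuracy$accuracy[2],
              dec$accuracy$n_trials[2]), "",
      "## Mutual information (bits, mean over units)",
      sprintf("- laser off: %.3f", mean(mi$mi[!mi$laser_on])),
      sprintf("- laser on:  %.3f", mean(mi$mi[mi$laser_on])),
      sprintf("- paired signed-rank p = %.3g", stats_res$mi_laser$p_value),
      "",
      "## Firing-rate laser contrast",
      sprintf("- median laser-on/off ratio (still): %.3f",
              median(unit_metrics$ratio, na.rm = TRUE)),
      sprintf("- paired signed-rank p = %.3g", stats_res$rate_laser$p_value))
    if (!is.null(band_powers) && !is.null(stats_res$gamma_laser)) {
      g_off <- mean(band_powers$power[band_powers$locomotion == "still" &
                                        !band_powers$laser_on])
      g_on <- mean(band_powers$power[band_powers$locomotion == "still" &
                                       band_powers$laser_on])
      rep <- c(rep, "",
               "## Gamma band power (still, uV^2/Hz)",
               sprintf("- laser off: %.2f", g_off),
               sprintf("- laser on:  %.2f", g_on),
               sprintf("- rank-sum p = %.3g",
                       stats_res$gamma_laser$p_value))
    }
    writeLines(rep, paths$report)
  }

  list(trials = trials, band_powers = band_powers,
       unit_metrics = unit_metrics, mi = mi,
       decoding = dec$accuracy, count_matched = dec$count_matched,
       stats = stats_res, paths = paths)
}
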
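#' Pipeline configuration
#'
#' Declarative description of an end-to-end run: synthetic cohort(s),
#' protocols, classifier thresholds, Ih windows and the seed. All
#' thresholds are validated against their admissible ranges; the seed is
#' recorded in every output. `read_pipeline_config()` loads the same
#' structure from a YAML file.
#'
#' @param n_control,n_ccd Cohort sizes (set `n_ccd = 0` to skip the
#'   second cohort).
#' @param control_props,ccd_props Subclass proportions for the two
#'   cohorts.
#' @param jitter Relative SD of parameter jitter in [generate_cohort()].
#' @param seed Integer seed for every stochastic stage.
#' @param step_amplitudes,step_duration Step protocol for the I-F family
#'   (pA, ms).
#' @param ramp_peak,ramp_duration Ramp protocol (pA, ms).
#' @param classifier Thresholds from [classifier_config()].
#' @param ih_window_initial,ih_window_steady Ih measurement windows, ms.
#' @param with_rheobase Run the bisection rheobase search per neuron.
#' @param noise_sd Recording-noise SD, mV.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_control = 40, n_ccd = 0,
                            control_props = control_proportions(),
                            ccd_props = ccd_proportions(),
                            jitter = 0.1, seed = 1L,
                            step_amplitudes = seq(100, 1000, by = 100),
                            step_duration = 500,
                            ramp_peak = 1000, ramp_duration = 1000,
                            classifier = classifier_config(),
                            ih_window_initial = c(12, 15),
                            ih_window_steady = 100,
                            with_rheobase = FALSE,
                            noise_sd = 0) {
  stopifnot(n_control > 0, n_ccd >= 0, jitter >= 0, noise_sd >= 0,
            step_duration > 0, ramp_duration > 0,
            ih_window_initial[1] >= 0, diff(ih_window_initial) > 0,
            ih_window_steady > 0)
  structure(list(n_control = n_control, n_ccd = n_ccd,
                 control_props = control_props, ccd_props = ccd_props,
                 jitter = jitter, seed = as.integer(seed),
                 step_amplitudes = step_amplitudes,
                 step_duration = step_duration,
                 ramp_peak = ramp_peak, ramp_duration = ramp_duration,
                 classifier = classifier,
                 ih_window_initial = ih_window_initial,
                 ih_window_steady = ih_window_steady,
                 with_rheobase = with_rheobase, noise_sd = noise_sd),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the `pipeline_config()`
#'   fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    rlang::abort(paste0("unknown config field(s): ",
                        paste(unknown, collapse = ", ")))
  if (!is.null(raw$classifier)) raw$classifier <- do.call(classifier_config, raw$classifier)
  do.call(pipeline_config, raw)
}

#' Run the full excitability-typing pipeline
#'
#' Generates the configured cohort(s) and, for every neuron: passive
#' properties and QC, the step family and ramp, feature extraction,
#' class assignment, and Ih quantification from the voltage-clamp
#' family. Aggregates class counts, Ih density comparison (with one-way
#' ANOVA and LSD comparisons), and - when a second cohort is configured -
#' the per-class proportion-shift chi-square report. Neurons failing QC
#' are excluded, with the exclusion and its reason recorded in the
#' result (never silently dropped). The run is fully reproducible from
#' the configuration and its seed; the summary embeds both the seed and
#' a configuration hash.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: per-neuron tables and the summary
#'   are written there as CSV/JSON.
#' @param quiet Suppress progress messages.
#' @return A `drg_pipeline` list: `neurons` (per-neuron feature + class
#'   + Ih table), `counts` (per cohort), `ih_comparison`, `ih_anova`,
#'   `shift_report` (or `NULL`), `exclusions`, `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  cohorts <- list(control = generate_cohort(config$n_control,
                                            config$control_props,
                                            config$jitter, config$seed))
  if (config$n_ccd > 0)
    cohorts$ccd <- generate_cohort(config$n_ccd, config$ccd_props,
                                   config$jitter, config$seed + 1L)

  process_cohort <- function(tbl, label) {
    say("pipeline: cohort '%s' (%d neurons)", label, nrow(tbl))
    rows <- purrr::map(seq_len(nrow(tbl)), function(i) {
      p <- tbl$params[[i]]
      rest <- simulate_current_clamp(
        p, step_protocol(0, duration = 300, onset = 50, tail = 0))
      small <- simulate_current_clamp(p, step_protocol(-20, duration = 400))
      props <- passive_properties(rest, small)
      feats <- simulate_features(
        p, step_amplitudes = config$step_amplitudes,
        step_duration = config$step_duration,
        ramp_peak = config$ramp_peak, ramp_duration = config$ramp_duration,
        with_rheobase = config$with_rheobase)
      top <- simulate_current_clamp(
        p, step_protocol(max(config$step_amplitudes),
                         duration = config$step_duration))
      qc <- qc_filter(props, detect_spikes(top))
      ih <- simulate_ih_measurement(
        p, window_initial = config$ih_window_initial,
        window_steady = config$ih_window_steady)
      dplyr::bind_cols(
        tibble::tibble(cohort = label, neuron_id = tbl$neuron_id[[i]],
                       true_class = as.character(tbl$true_class[[i]]),
                       qc_pass = qc),
        props, feats,
        tibble::tibble(ih_density = attr(ih, "current_density")))
    })
    dplyr::bind_rows(rows)
  }

  neurons <- purrr::imap(cohorts, process_cohort) |> dplyr::bind_rows()
  exclusions <- neurons |>
    dplyr::filter(!.data$qc_pass) |>
    dplyr::transmute(.data$cohort, .data$neuron_id,
                     reason = ifelse(.data$resting_potential >= -50,
                                     "RMP not below -50 mV",
                                     "no overshooting action potential"))
  if (nrow(exclusions) > 0)
    say("pipeline: excluded %d neuron(s) failing QC", nrow(exclusions))

  kept <- dplyr::filter(neurons, .data$qc_pass)
  if (nrow(kept) == 0L)
    rlang::abort("pipeline aborted at QC stage: no neuron passed.",
                 class = "drgexcite_stage_error")
  kept <- classify_cohort(kept, config$classifier)
  neurons <- dplyr::left_join(
    neurons, dplyr::select(kept, "cohort", "neuron_id", "class"),
    by = c("cohort", "neuron_id"))

  counts <- kept |>
    dplyr::group_by(.data$cohort) |>
    dplyr::group_modify(~ class_counts(.x$class)) |>
    dplyr::ungroup()

  # Ih comparison over replicated assigned classes of the control cohort
  # (UNCLASSIFIED cells and singleton groups carry no group mean)
  ih_tbl <- kept |>
    dplyr::filter(.data$cohort == "control",
                  as.character(.data$class) != "UNCLASSIFIED") |>
    dplyr::transmute(class = as.character(.data$class),
                     density = .data$ih_density) |>
    dplyr::group_by(.data$class) |>
    dplyr::filter(dplyr::n() >= 2L) |>
    dplyr::ungroup()
  ihc <- tryCatch(compare_ih_across_classes(ih_tbl),
                  error = function(e) NULL)
  ih_anova <- if (!is.null(ihc) && nrow(ihc$summary) >= 2L) {
    tryCatch(one_way_anova_lsd(ihc$anova_input, .data$density, .data$class),
             error = function(e) NULL)
  }

  shift <- NULL
  if (config$n_ccd > 0) {
    to3 <- function(lbl) {
      cc <- class_counts(dplyr::filter(kept, .data$cohort == lbl)$class)
      c(class1 = cc$n[cc$class == "CLASS1"],
        class2 = cc$n[cc$class == "CLASS2_1"] + cc$n[cc$class == "CLASS2_2"],
        class3 = cc$n[cc$class == "CLASS3"])
    }
    shift <- proportion_shift_report(to3("control"), to3("ccd"))
  }

  cfg_hash <- rlang::hash(unclass(config))
  summary <- list(
    seed = config$seed,
    config_hash = cfg_hash,
    n_neurons = nrow(neurons),
    n_excluded = nrow(exclusions),
    counts = counts,
    ih_class2_1_max = if (!is.null(ihc)) ihc$class2_1_max else NA,
    ih_anova = if (!is.null(ih_anova)) glance(ih_anova) else NULL,
    shift_report = shift)

  res <- structure(list(neurons = neurons, counts = counts,
                        ih_comparison = ihc, ih_anova = ih_anova,
                        shift_report = shift, exclusions = exclusions,
                        summary = summary, config = config),
                   class = "drg_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    # every result file carries its provenance (seed + config hash)
    stamp <- sprintf("# drgexcite run: seed %d, config %s", config$seed, cfg_hash)
    write_stamped <- function(df, name) {
      path <- file.path(out_dir, name)
      writeLines(stamp, path)
      readr::write_csv(df, path, append = TRUE, col_names = TRUE)
    }
    write_stamped(dplyr::select(neurons,
                                -dplyr::any_of(c("if_curve", "evidence"))),
                  "neurons.csv")
    write_stamped(counts, "class_counts.csv")
    if (!is.null(shift)) write_stamped(shift, "proportion_shift.csv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE, dataframe = "rows", force = TRUE)
  }
  res
}

#' @export
print.drg_pipeline <- function(x, ...) {
  cat(sprintf("<drg_pipeline> %d neurons (%d excluded by QC), seed %d\n",
              nrow(x$neurons), nrow(x$exclusions), x$config$seed))
  print(x$counts)
  if (!is.null(x$shift_report)) {
    cat("Proportion shift (control vs CCD):\n")
    print(x$shift_report)
  }
  invisible(x)
}
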
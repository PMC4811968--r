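#' Run configuration
#'
#' A run is fully determined by its configuration: master seed, cohort
#' sizes, task/noise/RT/preprocessing settings and the output directory.
#'
#' @param seed master seed.
#' @param n_young,n_middle,n_old cohort sizes.
#' @param task,templates,noise,rt,preproc configuration objects.
#' @param between_sd_scale subject-level parameter variation (see
#'   [generate_cohort()]).
#' @param latency_jitter_sd trial-level latency jitter SD, ms.
#' @param out_dir output directory.
#' @param make_plots write grand-average waveform figures (PNG).
#' @param filter apply the band-pass stage.
#' @return A list of class `erp_run_config`.
#' @export
run_config <- function(seed = 1, n_young = 18, n_middle = 20, n_old = 15,
                       task = task_config(), templates = component_templates(),
                       noise = noise_config(), rt = rt_model(),
                       preproc = preproc_config(), between_sd_scale = 1,
                       latency_jitter_sd = 0, out_dir = "erp_run",
                       make_plots = FALSE, filter = TRUE) {
  structure(as.list(environment()), class = "erp_run_config")
}

#' Run the full simulate -> preprocess -> measure -> map -> test pipeline
#'
#' Streams the cohort subject by subject (recordings are not retained),
#' producing: the trial/RT table, the per-subject component-measure table,
#' group-mean component summaries, grand-average difference waveforms,
#' voltage and CSD maps at the grand-average component peaks, ANOVA and
#' post-hoc tables for RT and every component parameter, optional
#' Figure-style waveform plots, and a JSON manifest. Identical
#' configurations yield identical CSV outputs.
#'
#' @param config an [run_config()].
#' @return Invisibly, a list with the main tables and output paths.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  montage <- standard_1010_montage()
  groups <- c("Young", "MiddleAged", "Old")
  ga_sum <- list()   # running sums for grand averages, per group x contrast
  ga_n <- list()
  waves <- list()
  trial_rows <- list()
  counts_rows <- list()
  process_one <- function(rec) {
    pp <- preprocess_subject(rec, config$preproc, filter = config$filter)
    list(NS = pp$NS, DS = pp$DS, counts = pp$counts,
         timeline = rec$timeline, group = rec$group)
  }
  res <- generate_cohort(
    n_young = config$n_young, n_middle = config$n_middle,
    n_old = config$n_old, master_seed = config$seed, task = config$task,
    templates = config$templates, noise = config$noise, rt = config$rt,
    montage = montage, between_sd_scale = config$between_sd_scale,
    latency_jitter_sd = config$latency_jitter_sd, process = process_one)
  subjects <- attr(res, "subjects")
  for (i in seq_along(res)) {
    r <- res[[i]]
    waves[[i]] <- list(subject = i, group = r$group, NS = r$NS, DS = r$DS)
    key <- r$group
    if (is.null(ga_sum[[key]])) {
      ga_sum[[key]] <- list(NS = r$NS$data, DS = r$DS$data)
      ga_n[[key]] <- 1
    } else {
      ga_sum[[key]]$NS <- ga_sum[[key]]$NS + r$NS$data
      ga_sum[[key]]$DS <- ga_sum[[key]]$DS + r$DS$data
      ga_n[[key]] <- ga_n[[key]] + 1
    }
    tl <- as.data.frame(r$timeline)
    tl$subject <- i
    tl$group <- r$group
    trial_rows[[i]] <- tl
    cts <- as.data.frame(r$counts, stringsAsFactors = FALSE)
    cts$subject <- i
    counts_rows[[i]] <- cts
  }
  times <- waves[[1]]$NS$times
  trials <- do.call(rbind, trial_rows)
  measures <- measure_cohort(waves)
  gmeans <- group_component_means(measures)
  rt_res <- rt_analysis(trials)
  anovas <- component_anovas(measures)

  # grand-average difference waves and peak-latency topographies
  maps <- list()
  for (g in names(ga_sum)) for (ct in c("NS", "DS")) {
    ga <- structure(list(data = ga_sum[[g]][[ct]] / ga_n[[g]], times = times,
                         contrast = ct, group = g,
                         sample_rate = waves[[1]]$NS$sample_rate),
                    class = "erp_difference_wave")
    mm <- measure_components(ga, subject = paste0("GA_", g))
    for (cp in c("eP3a", "lP3a", "RON")) {
      lat <- mm$latency[mm$component == cp][1]
      if (is.na(lat)) next
      vm <- voltage_map(ga, lat, montage)
      cm <- csd_map(ga, lat, montage = montage)
      maps[[length(maps) + 1]] <- data.frame(
        group = g, contrast = ct, component = cp, t_ms = attr(vm, "t_ms"),
        label = vm$label, voltage = vm$value, csd = cm$value,
        stringsAsFactors = FALSE)
    }
    if (config$make_plots)
      plot_difference_wave_png(ga, file.path(
        config$out_dir, sprintf("waveforms_%s_%s.png", g, ct)))
  }
  map_tab <- do.call(rbind, maps)

  out_csv <- function(x, name) {
    f <- file.path(config$out_dir, name)
    utils::write.csv(x, f, row.names = FALSE)
    f
  }
  paths <- c(
    out_csv(trials, "trials.csv"),
    out_csv(as.data.frame(measures), "component_measures.csv"),
    out_csv(gmeans, "component_group_means.csv"),
    out_csv(do.call(rbind, counts_rows), "epoch_counts.csv"),
    out_csv(map_tab, "topomaps.csv"),
    out_csv(anovas$anova, "anova_components.csv"),
    out_csv(anovas$posthoc, "posthoc_components.csv"),
    out_csv(rt_res$anova, "anova_rt.csv"),
    out_csv(rbind(cbind(family = "group", rt_res$posthoc_group),
                  cbind(family = "condition", rt_res$posthoc_condition)),
            "posthoc_rt.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("erpdistract")),
    seed = config$seed, subjects = subjects,
    n_pairs = config$task$n_pairs,
    noise_rms = config$noise$rms,
    filter = config$filter, outputs = basename(paths))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trials = trials, measures = measures, group_means = gmeans,
                 rt = rt_res, anovas = anovas, maps = map_tab,
                 subjects = subjects, out_dir = config$out_dir,
                 paths = paths))
}

#' Component parameter ANOVAs
#'
#' For each component: the amplitude ANOVA (Group x Difference x Electrode
#' for e-P3a/l-P3a/RON, Group x Difference for MMN, which is measured at a
#' single electrode) and the latency ANOVA (Group x Difference, at Cz),
#' each restricted to the subjects included for that component, plus
#' Bonferroni post-hoc comparisons for the Group factor.
#'
#' @param measures an [measure_cohort()] table.
#' @return A list: `anova` (one row per effect per analysis), `posthoc`.
#' @export
component_anovas <- function(measures) {
  an_rows <- list()
  ph_rows <- list()
  for (cp in unique(measures$component)) {
    m <- measures[measures$component == cp & measures$included, , drop = FALSE]
    if (!nrow(m)) next
    multi_el <- length(unique(m$electrode)) > 1
    amp <- tryCatch({
      if (multi_el)
        mixed_anova(m, "amplitude", "subject", "group",
                    within = c("contrast", "electrode"))
      else
        mixed_anova(m, "amplitude", "subject", "group", within = "contrast")
    }, error = function(e) NULL)
    lat_tab <- m[m$electrode == "Cz", , drop = FALSE]
    lat <- tryCatch(
      mixed_anova(lat_tab, "latency", "subject", "group",
                  within = "contrast"),
      error = function(e) NULL)
    if (!is.null(amp))
      an_rows[[paste0(cp, "_amp")]] <- cbind(component = cp,
                                             parameter = "amplitude", amp)
    if (!is.null(lat))
      an_rows[[paste0(cp, "_lat")]] <- cbind(component = cp,
                                             parameter = "latency", lat)
    subj_amp <- stats::aggregate(amplitude ~ subject + group, data = m,
                                 FUN = mean)
    ph <- tryCatch(bonferroni_posthoc(subj_amp, "amplitude", "subject",
                                      "group", design = "between"),
                   error = function(e) NULL)
    if (!is.null(ph))
      ph_rows[[cp]] <- cbind(component = cp, parameter = "amplitude", ph)
  }
  list(anova = do.call(rbind, an_rows), posthoc = do.call(rbind, ph_rows))
}
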
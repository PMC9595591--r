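# End-to-end orchestration: demo plate generation, staged pipeline run with
# provenance record.

DEMO_POPULATIONS <- c("SNc", "LC", "R", "DMV", "VTA", "XII", "STR")
DEMO_DOSES <- c(0, 100, 150, 200)

# Demo plate conditions (documented in the methods vignette): vulnerable
# populations get longer axons and a higher Syt-1-positive fraction, and lose
# more neurons per hydrogen-peroxide dose, than resilient ones.
demo_population_params <- function(population) {
  vulnerable <- vulnerability_classes()[population] == "vulnerable"
  list(
    class = unname(vulnerability_classes()[population]),
    n_neurons0 = 8L,
    length_per_neuron_um = if (vulnerable) 180 else 110,
    syt1_pos_fraction = if (vulnerable) 0.75 else 0.45,
    survival = if (vulnerable) c(`0` = 1, `100` = 0.65, `150` = 0.45,
                                 `200` = 0.30)
               else c(`0` = 1, `100` = 0.85, `150` = 0.70, `200` = 0.55),
    oxidation_mean = c(SNc = 0.45, LC = 0.42, R = 0.40, DMV = 0.30,
                       VTA = 0.35, XII = 0.32, STR = 0.33)[[population]])
}

#' Generate the bundled-style synthetic demo plate
#'
#' Writes a 7-population x 4-dose plate: per-well multichannel TIFFs with
#' ground-truth JSON sidecars, a well manifest (`wells.csv`), per-population
#' roGFP trace CSVs (including planted drifting and non-responding ROIs), and
#' a ready-to-run `config.yaml`. Vulnerable populations (SNc, LC, R, DMV) are
#' planted with longer, more varicosity-rich axons, higher Syt-1-positive
#' fractions, steeper dose-response and higher relative oxidation than
#' resilient ones (VTA, XII, STR), so the downstream class comparisons are
#' exercised in a known direction.
#'
#' @param out_dir output directory (created if missing)
#' @param seed master seed; every well and trace seed is derived from it
#' @param n_wells_dose0 wells per population at dose 0 (analysis wells)
#' @param n_wells_dose wells per population at each nonzero dose
#' @param n_traces_per_pop roGFP ROIs per population
#' @param width_px,height_px field size of the demo images
#' @return invisibly, the manifest data.frame
#' @export
make_demo_dataset <- function(out_dir, seed = 1L, n_wells_dose0 = 3L,
                              n_wells_dose = 2L, n_traces_per_pop = 12L,
                              width_px = 256L, height_px = 256L) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "traces"), showWarnings = FALSE)
  manifest <- list()
  for (pop in DEMO_POPULATIONS) {
    par <- demo_population_params(pop)
    for (dose in DEMO_DOSES) {
      n_wells <- if (dose == 0) n_wells_dose0 else n_wells_dose
      for (wi in seq_len(n_wells)) {
        well <- sprintf("%s_d%03d_w%d", pop, dose, wi)
        wseed <- derive_seed(seed, well)
        set.seed(wseed)
        n_neur <- max(1L, stats::rbinom(1, par$n_neurons0 * 2,
                                        par$survival[[as.character(dose)]] / 2))
        jitter <- stats::rlnorm(1, 0, 0.08)
        spec <- field_spec(
          width_px = width_px, height_px = height_px,
          n_neurons = n_neur, n_nuclei = 25L,
          neurite_total_length_um = n_neur * par$length_per_neuron_um * jitter,
          syt1_pos_fraction = par$syt1_pos_fraction,
          seed = derive_seed(seed, paste0(well, ":field")))
        fg <- generate_field(spec)
        img_path <- file.path("images", paste0(well, ".tif"))
        truth_path <- file.path("images", paste0(well, "_truth.json"))
        write_field_tiff(fg$field, file.path(out_dir, img_path))
        write_ground_truth(fg$truth, file.path(out_dir, truth_path))
        manifest[[length(manifest) + 1L]] <- data.frame(
          well = well, population = pop, dose = dose, class = par$class,
          image = img_path, truth = truth_path,
          analysis = dose == 0, excluded = FALSE)
      }
    }
    # roGFP traces: planted oxidation per population plus QC decoys
    traces <- lapply(seq_len(n_traces_per_pop), function(i) {
      tseed <- derive_seed(seed, sprintf("%s:trace%02d", pop, i))
      set.seed(tseed)
      ox <- min(0.95, max(0.05, stats::rnorm(1, par$oxidation_mean, 0.06)))
      fd <- 1000; fa <- 200
      fb <- fd - ox * (fd - fa)
      drift <- if (i == n_traces_per_pop) -0.2 else stats::runif(1, -0.04, 0.04)
      responder <- i != n_traces_per_pop - 1L
      generate_trace(trace_spec(f_baseline = if (responder) fb else fb,
                                f_dtt = fd, f_ald = fa,
                                drift_fraction = drift,
                                responder = responder, noise_sd = 8,
                                seed = tseed),
                     roi_id = sprintf("%s_%02d", pop, i))
    })
    write_traces_csv(traces, file.path(out_dir, "traces",
                                       paste0(pop, ".csv")))
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "wells.csv"),
                   row.names = FALSE)
  config <- list(seed = seed, pixel_size_um = 0.3,
                 paths = list(root = ".", out = "results"),
                 stages = list(census = TRUE, trace = TRUE,
                               varicosities = TRUE, redox = TRUE,
                               stats = TRUE),
                 census = list(min_soma_area_um2 = 30),
                 varicosities = list(strict_length_gate = FALSE),
                 redox = list(drift_limit = 0.10, response_k = 3),
                 stats = list(n_resamples = 2000L, control = "SNc"))
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

#' Load and validate a pipeline run configuration
#'
#' @param path YAML file, or a pre-built config list
#' @param root directory the config's relative paths resolve against
#' @return validated config list (class `run_config`)
#' @export
read_run_config <- function(path, root = NULL) {
  config <- if (is.character(path)) {
    if (is.null(root)) root <- dirname(normalizePath(path))
    yaml::read_yaml(path)
  } else path
  if (is.null(root)) root <- config$paths$root
  config$paths$root <- root
  defaults <- list(seed = 1L, pixel_size_um = 0.3,
                   stages = list(census = TRUE, trace = TRUE,
                                 varicosities = TRUE, redox = TRUE,
                                 stats = TRUE),
                   census = list(min_soma_area_um2 = 30),
                   varicosities = list(strict_length_gate = FALSE),
                   redox = list(drift_limit = 0.10, response_k = 3),
                   stats = list(n_resamples = 2000L, control = "SNc"))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]])) {
      missing <- setdiff(names(defaults[[nm]]), names(config[[nm]]))
      config[[nm]][missing] <- defaults[[nm]][missing]
    }
  }
  check_that(config$pixel_size_um > 0, "pixel_size_um must be positive")
  check_that(config$redox$drift_limit > 0, "drift_limit must be positive")
  class(config) <- "run_config"
  config
}

#' Run the full analysis pipeline on a plate
#'
#' Executes the enabled stages in order (census, neurite trace/morphometry,
#' varicosities, redox, stats) over the wells listed in the plate manifest,
#' writing one CSV per stage plus a JSON run record with per-stage row
#' counts, exclusion tallies and timings. All outputs are pure functions of
#' (inputs, config, seed); rerunning with the same config overwrites them
#' identically. Missing input files or an invalid configuration abort before
#' any computation.
#'
#' @param config path to a YAML config, or a config list ([read_run_config()])
#' @param root optional root directory overriding the config's
#' @return invisibly, the run record list
#' @export
run_pipeline <- function(config, root = NULL) {
  config <- read_run_config(config, root)
  root <- config$paths$root
  out_dir <- file.path(root, config$paths$out %||% "results")
  manifest_path <- file.path(root, "wells.csv")
  check_that(file.exists(manifest_path), "manifest not found: %s",
             manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  # pre-flight: every referenced image must exist before any computation
  missing <- manifest$image[!file.exists(file.path(root, manifest$image))]
  check_that(!length(missing), "missing image file(s): %s",
             paste(missing, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  record <- list(config = unclass(config),
                 package_version = as.character(utils::packageVersion("axovuln")),
                 stages = list())
  psz <- config$pixel_size_um
  active <- manifest[!manifest$excluded, ]

  counts <- NULL
  if (isTRUE(config$stages$census)) {
    t0 <- proc.time()[3]
    rows <- lapply(seq_len(nrow(active)), function(i) {
      field <- read_field_tiff(file.path(root, active$image[i]), psz)
      mask <- segment_somata(field,
                             min_soma_area = config$census$min_soma_area_um2)
      data.frame(well = active$well[i], population = active$population[i],
                 dose = active$dose[i], count = count_neurons(mask))
    })
    counts <- do.call(rbind, rows)
    survival <- normalize_survival(counts)
    utils::write.csv(counts, file.path(out_dir, "counts.csv"),
                     row.names = FALSE)
    utils::write.csv(survival, file.path(out_dir, "survival.csv"),
                     row.names = FALSE)
    record$stages$census <- list(wells = nrow(counts),
                                 excluded_wells = sum(manifest$excluded),
                                 seconds = round(proc.time()[3] - t0, 2))
  }

  morpho <- NULL; varic_all <- NULL; varic_metrics <- NULL
  if (isTRUE(config$stages$trace) || isTRUE(config$stages$varicosities)) {
    t0 <- proc.time()[3]
    awells <- active[active$analysis, ]
    morpho_rows <- list(); varic_rows <- list(); skeletons <- list()
    for (i in seq_len(nrow(awells))) {
      field <- read_field_tiff(file.path(root, awells$image[i]), psz)
      mask <- segment_somata(field,
                             min_soma_area = config$census$min_soma_area_um2)
      neurites <- segment_neurites(field, mask)
      sk <- skeletonize(neurites, psz)
      skeletons[[awells$well[i]]] <- sk
      morpho_rows[[i]] <- cbind(
        morphometry(sk, count_neurons(mask), awells$well[i]),
        population = awells$population[i])
      if (isTRUE(config$stages$varicosities)) {
        vv <- detect_varicosities(
          field, sk,
          strict_length_gate = isTRUE(config$varicosities$strict_length_gate))
        if (nrow(vv)) vv <- cbind(well = awells$well[i],
                                  population = awells$population[i], vv)
        varic_rows[[i]] <- vv
      }
    }
    morpho <- do.call(rbind, morpho_rows)
    if (isTRUE(config$stages$trace)) {
      utils::write.csv(morpho, file.path(out_dir, "morphometry.csv"),
                       row.names = FALSE)
      record$stages$trace <- list(
        wells = nrow(morpho),
        undefined_wells = sum(!morpho$defined),
        seconds = round(proc.time()[3] - t0, 2))
    }
    if (isTRUE(config$stages$varicosities)) {
      varic_all <- do.call(rbind, varic_rows[lengths(varic_rows) > 0])
      # plate-wide Syt-1 cutoff from all gate-failing candidates
      cutoff <- syt1_cutoff(varic_all[!varic_all$passes_gate, ],
                            background = c(100, 5))
      met_rows <- lapply(names(skeletons), function(wl) {
        vv <- varic_all[varic_all$well == wl, ]
        vm <- varicosity_metrics(vv, cutoff,
                                 skeletons[[wl]]$total_length_um, wl)
        cbind(vm$summary,
              population = awells$population[awells$well == wl][1])
      })
      varic_metrics <- do.call(rbind, met_rows)
      utils::write.csv(varic_all, file.path(out_dir, "varicosities.csv"),
                       row.names = FALSE)
      utils::write.csv(varic_metrics,
                       file.path(out_dir, "varicosity_metrics.csv"),
                       row.names = FALSE)
      record$stages$varicosities <- list(
        wells = length(skeletons), candidates = nrow(varic_all),
        passing = sum(varic_all$passes_gate),
        excluded_by_gate = sum(!varic_all$passes_gate),
        syt1_cutoff = cutoff$cutoff,
        seconds = round(proc.time()[3] - t0, 2))
    }
  }

  redox <- NULL
  if (isTRUE(config$stages$redox)) {
    t0 <- proc.time()[3]
    trace_files <- list.files(file.path(root, "traces"), "\\.csv$",
                              full.names = TRUE)
    rows <- lapply(trace_files, function(f) {
      traces <- read_traces_csv(f)
      pop <- sub("\\.csv$", "", basename(f))
      do.call(rbind, lapply(traces, function(tr)
        cbind(population = pop,
              oxidation_result(tr, config$redox$drift_limit,
                               config$redox$response_k))))
    })
    redox <- do.call(rbind, rows)
    if (!is.null(redox)) rownames(redox) <- NULL
    utils::write.csv(redox, file.path(out_dir, "redox.csv"),
                     row.names = FALSE)
    record$stages$redox <- list(
      rois = if (is.null(redox)) 0L else nrow(redox),
      included = if (is.null(redox)) 0L else sum(redox$included),
      excluded_drift = if (is.null(redox)) 0L else sum(redox$excluded_drift),
      excluded_nonresponder = if (is.null(redox)) 0L
                              else sum(redox$excluded_nonresponder),
      seconds = round(proc.time()[3] - t0, 2))
  }

  if (isTRUE(config$stages$stats)) {
    t0 <- proc.time()[3]
    B <- config$stats$n_resamples
    ctrl <- config$stats$control
    seed <- config$seed
    tests <- list(); estimates <- list()
    if (!is.null(morpho) && sum(morpho$defined) > 3) {
      md <- morpho[morpho$defined, ]
      if (all(table(md$population) >= 3)) {
        tests$morpho_omnibus <- cbind(metric = "mean_length_per_neuron_um",
          omnibus_and_posthoc(md$mean_length_per_neuron_um, md$population))
      }
      cc <- class_comparison(md$mean_length_per_neuron_um, md$population,
                             n_resamples = B,
                             seed = derive_seed(seed, "morpho:class"))
      tests$morpho_class <- cbind(metric = "mean_length_per_neuron_um",
                                  comparison = "vulnerable_vs_resilient",
                                  route = "class", adjustment = "none",
                                  test = cc$test$test,
                                  statistic = cc$test$statistic,
                                  p_raw = cc$test$p, p_adjusted = cc$test$p)
      estimates$morpho_class <- cbind(metric = "mean_length_per_neuron_um",
                                      cc$estimation)
      if (all(table(md$population) >= 3)) {
        estimates$morpho_shared <- cbind(
          metric = "mean_length_per_neuron_um",
          shared_control_design(md$mean_length_per_neuron_um, md$population,
                                ctrl, n_resamples = B,
                                seed = derive_seed(seed, "morpho:shared")))
      }
    }
    if (!is.null(varic_metrics) &&
        sum(!is.na(varic_metrics$syt1_positive_fraction)) > 3) {
      vm <- varic_metrics[!is.na(varic_metrics$syt1_positive_fraction), ]
      cc <- class_comparison(vm$syt1_positive_fraction, vm$population,
                             n_resamples = B,
                             seed = derive_seed(seed, "syt1:class"))
      tests$syt1_class <- cbind(metric = "syt1_positive_fraction",
                                comparison = "vulnerable_vs_resilient",
                                route = "class", adjustment = "none",
                                test = cc$test$test,
                                statistic = cc$test$statistic,
                                p_raw = cc$test$p, p_adjusted = cc$test$p)
      estimates$syt1_class <- cbind(metric = "syt1_positive_fraction",
                                    cc$estimation)
    }
    if (!is.null(redox) && sum(redox$included) > 3) {
      rd <- redox[redox$included, ]
      if (all(table(rd$population) >= 3)) {
        estimates$redox_shared <- cbind(
          metric = "relative_oxidation",
          shared_control_design(rd$relative_oxidation, rd$population, ctrl,
                                n_resamples = B,
                                seed = derive_seed(seed, "redox:shared")))
      }
    }
    test_df <- do.call(rbind, lapply(unname(tests), function(d) {
      d[, c("metric", "test", "comparison", "statistic", "p_raw",
            "p_adjusted", "adjustment", "route")]
    }))
    est_df <- do.call(rbind, unname(estimates))
    if (!is.null(test_df)) {
      utils::write.csv(test_df, file.path(out_dir, "stats_tests.csv"),
                       row.names = FALSE)
    }
    if (!is.null(est_df)) {
      utils::write.csv(est_df, file.path(out_dir, "stats_estimation.csv"),
                       row.names = FALSE)
    }
    record$stages$stats <- list(
      tests = if (is.null(test_df)) 0L else nrow(test_df),
      estimates = if (is.null(est_df)) 0L else nrow(est_df),
      n_resamples = B, seconds = round(proc.time()[3] - t0, 2))
  }

  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(record)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
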
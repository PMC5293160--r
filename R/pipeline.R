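#' Pipeline configuration
#'
#' All knobs of the end-to-end run in one validated list. Unknown keys
#' are rejected and `seed` is mandatory; every stochastic stage derives
#' its own seed from it, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param seed Master integer seed (mandatory).
#' @param experiments Character vector of history presets to simulate
#'   (>= 1; >= 2 enables the consistency map). Ignored when
#'   `tracks_path` is given.
#' @param tracks_path Optional named character vector of per-experiment
#'   track CSVs to analyse instead of simulating.
#' @param n_cells,duration Passed to [sim_config()].
#' @param sim_overrides Named list of further [sim_config()] arguments
#'   applied to every experiment.
#' @param min_controls Control cells a frame needs (see
#'   [baseline_by_controls()]).
#' @param min_track_frames Bright-field frames a cell needs (see
#'   [filter_short_tracks()]).
#' @param sigma,span_points Smoother parameters.
#' @param plateau_window Plateau period, minutes.
#' @param bin_width State-space bin width, %.
#' @param field_t_range Minutes entering the vector field.
#' @param consistency_min_n,consistency_B,consistency_m Consistency
#'   statistic parameters.
#' @param lag_threshold Lag crossing threshold, %.
#' @param ecdf_B,movement_B,vardecomp_B Bootstrap replicate counts.
#' @param out_dir Output directory for [run_pipeline()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            experiments = c("glycerol", "reinduction",
                                            "ltgr"),
                            tracks_path = NULL,
                            n_cells = 300,
                            duration = 1500,
                            sim_overrides = list(),
                            min_controls = 50,
                            min_track_frames = 5,
                            sigma = 1,
                            span_points = 5,
                            plateau_window = c(900, 1500),
                            bin_width = 6,
                            field_t_range = c(0, 900),
                            consistency_min_n = 10,
                            consistency_B = 500,
                            consistency_m = 10,
                            lag_threshold = 10,
                            ecdf_B = 1000,
                            movement_B = 100,
                            vardecomp_B = 200,
                            out_dir = "galfield_out") {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("pipeline_config(): `seed` is mandatory")
  }
  cfg <- list(seed = as.integer(seed), experiments = experiments,
              tracks_path = tracks_path, n_cells = n_cells,
              duration = duration, sim_overrides = sim_overrides,
              min_controls = min_controls,
              min_track_frames = min_track_frames, sigma = sigma,
              span_points = span_points, plateau_window = plateau_window,
              bin_width = bin_width, field_t_range = field_t_range,
              consistency_min_n = consistency_min_n,
              consistency_B = consistency_B, consistency_m = consistency_m,
              lag_threshold = lag_threshold, ecdf_B = ecdf_B,
              movement_B = movement_B, vardecomp_B = vardecomp_B,
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(master, k) (as.integer(master) * 101L + k * 7919L) %% 2000000011L

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> quantify -> trajectories ->
#' vector field -> consistency -> population statistics, writing every
#' table as CSV under `config$out_dir` together with a JSON run manifest
#' (config hash, seeds, package version, per-stage row counts and
#' exclusions). Any stage error aborts with the stage name; a
#' `STALE` marker is left so partial outputs are recognizable.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stale_flag <- file.path(out, "STALE")
  file.create(stale_flag)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(seed = config$seed, stages = list(),
                   package_version = as.character(
                     utils::packageVersion("galfield")))
  t_all <- Sys.time()
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    say(sprintf("[%s] done in %.1fs", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  # -- simulate ---------------------------------------------------------
  sims <- run_stage("simulate", function() {
    if (!is.null(config$tracks_path)) {
      lapply(config$tracks_path, function(p) {
        list(tracks = read_tracks(p), bf = NULL, truth = NULL,
             meta = list(warn_low_controls = NA))
      })
    } else {
      sims <- lapply(seq_along(config$experiments), function(i) {
        args <- c(list(seed = stage_seed(config$seed, i),
                       n_cells = config$n_cells,
                       history = config$experiments[i],
                       duration = config$duration),
                  config$sim_overrides)
        simulate_population(do.call(sim_config, args))
      })
      names(sims) <- config$experiments
      sims
    }
  })
  for (nm in names(sims)) {
    write_table(sims[[nm]]$tracks, file.path(out, paste0("tracks_", nm, ".csv")))
    if (!is.null(sims[[nm]]$truth)) {
      write_table(sims[[nm]]$truth, file.path(out, paste0("truth_", nm, ".csv")))
    }
  }
  manifest$stages$simulate <- list(
    experiments = names(sims),
    rows = vapply(sims, function(s) nrow(s$tracks), integer(1)),
    warn_low_controls = vapply(sims, function(s)
      isTRUE(s$meta$warn_low_controls), logical(1)))

  # -- quantify ---------------------------------------------------------
  quant <- run_stage("quantify", function() {
    lapply(sims, function(s) {
      tr <- filter_short_tracks(s$tracks, bf = s$bf,
                                min_frames = config$min_track_frames)
      bl <- baseline_by_controls(tr, min_controls = config$min_controls)
      bl$n_cells_removed <- attr(tr, "n_cells_removed")
      bl
    })
  })
  excl <- dplyr::bind_rows(lapply(names(quant), function(nm) {
    e <- quant[[nm]]$excluded
    if (nrow(e)) e$experiment <- nm
    e
  }))
  write_table(excl, file.path(out, "excluded_frames.csv"))
  manifest$stages$quantify <- list(
    rows = vapply(quant, function(q) nrow(q$data), integer(1)),
    frames_excluded = nrow(excl))

  # -- trajectories -----------------------------------------------------
  norm <- run_stage("trajectories", function() {
    lapply(quant, function(q) {
      normalize_experiment(q$data, sigma = config$sigma,
                           span_points = config$span_points,
                           plateau_window = config$plateau_window)
    })
  })
  norm_all <- dplyr::bind_rows(lapply(norm, function(x) x$data))
  write_table(norm_all, file.path(out, "normalized.csv"))
  manifest$stages$trajectories <- list(
    rows = nrow(norm_all),
    plateau3_au = vapply(norm, function(x) x$plateau3$plateau_au, numeric(1)),
    plateau1_au = vapply(norm, function(x) x$plateau1$plateau_au, numeric(1)))

  # -- vector field + consistency ---------------------------------------
  vf <- run_stage("vectorfield", function() {
    fields <- lapply(norm, function(x) {
      estimate_field(x$data, t_range = config$field_t_range,
                     width = config$bin_width)
    })
    cmap <- NULL
    if (length(fields) >= 2) {
      cut_fields <- lapply(norm, function(x) {
        co <- cutoff_frames(x$data)
        estimate_field(apply_cutoffs(x$data, co),
                       t_range = config$field_t_range,
                       width = config$bin_width)
      })
      cmap <- consistency_statistic(
        cut_fields, min_n = config$consistency_min_n,
        B = config$consistency_B, m = config$consistency_m,
        seed = stage_seed(config$seed, 97L))
    }
    list(fields = fields, cmap = cmap)
  })
  field_all <- dplyr::bind_rows(lapply(names(vf$fields), function(nm) {
    f <- vf$fields[[nm]]$field
    f$experiment <- nm
    f
  }))
  write_table(field_all, file.path(out, "vector_field.csv"))
  if (!is.null(vf$cmap)) {
    write_table(vf$cmap$map, file.path(out, "consistency.csv"))
  }
  manifest$stages$vectorfield <- list(
    bins = vapply(vf$fields, function(f) nrow(f$field), integer(1)),
    consistency_bins = if (is.null(vf$cmap)) 0L else nrow(vf$cmap$map))

  # -- population statistics -------------------------------------------
  pop <- run_stage("popstats", function() {
    lags <- lapply(norm, function(x)
      lag_table(x$data, channel = "pct3_raw",
                threshold = config$lag_threshold))
    bands <- lapply(seq_along(lags), function(i) {
      lt <- lags[[i]]
      if (sum(!lt$censored) >= 2) {
        ecdf_with_ci(lt, B = config$ecdf_B,
                     seed = stage_seed(config$seed, 200L + i))
      } else NULL
    })
    names(bands) <- names(lags)
    viab <- lapply(sims, function(s) viability_curve(s$tracks))
    mov <- lapply(seq_along(sims), function(i) {
      if (is.null(sims[[i]]$bf)) return(NULL)
      movement_median(sims[[i]]$bf, B = config$movement_B,
                      seed = stage_seed(config$seed, 300L + i), thin = 10)
    })
    names(mov) <- names(sims)
    vd <- tryCatch(
      variance_decomposition(norm_all, window = config$plateau_window,
                             B = config$vardecomp_B,
                             seed = stage_seed(config$seed, 400L)),
      error = function(e) NULL)
    list(lags = lags, bands = bands, viability = viab, movement = mov,
         vardecomp = vd)
  })
  lag_all <- dplyr::bind_rows(lapply(names(pop$lags), function(nm) {
    lt <- pop$lags[[nm]]
    if (nrow(lt)) lt$experiment <- nm
    lt
  }))
  write_table(lag_all, file.path(out, "lags.csv"))
  band_all <- dplyr::bind_rows(lapply(names(pop$bands), function(nm) {
    b <- pop$bands[[nm]]
    if (is.null(b)) return(NULL)
    bb <- b$band
    bb$experiment <- nm
    bb
  }))
  write_table(band_all, file.path(out, "ecdf_bands.csv"))
  viab_all <- dplyr::bind_rows(lapply(names(pop$viability), function(nm) {
    v <- pop$viability[[nm]]
    v$experiment <- nm
    v
  }))
  write_table(viab_all, file.path(out, "viability.csv"))
  mov_all <- dplyr::bind_rows(lapply(names(pop$movement), function(nm) {
    m <- pop$movement[[nm]]
    if (is.null(m)) return(NULL)
    m$experiment <- nm
    m
  }))
  write_table(mov_all, file.path(out, "movement.csv"))
  if (!is.null(pop$vardecomp)) {
    vd <- pop$vardecomp
    write_table(tibble::tibble(
      intercell_fraction = vd$intercell_fraction,
      ci_lo = vd$ci95[["lo"]], ci_hi = vd$ci95[["hi"]],
      sigma2_cell = vd$sigma2_cell, sigma2_resid = vd$sigma2_resid,
      n_cells = vd$n_cells),
      file.path(out, "variance_decomposition.csv"))
  }
  manifest$stages$popstats <- list(
    lags = nrow(lag_all),
    censored = sum(lag_all$censored),
    intercell_fraction = if (is.null(pop$vardecomp)) NA_real_ else
      pop$vardecomp$intercell_fraction)

  # -- manifest ---------------------------------------------------------
  cfg_path <- file.path(out, "config.yaml")
  cfg_list <- unclass(config)
  cfg_list$out_dir <- NULL  # output location is not analysis configuration
  yaml::write_yaml(cfg_list, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  unlink(stale_flag)
  say(sprintf("pipeline complete in %.1fs -> %s",
              as.numeric(difftime(Sys.time(), t_all, units = "secs")), out))
  invisible(list(sims = sims, quant = quant, norm = norm, vf = vf,
                 pop = pop, manifest = manifest))
}
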
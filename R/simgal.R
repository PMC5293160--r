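#' Deterministic drift of the two-transducer induction model
#'
#' Velocity of the positive-feedback dynamics at a point of the
#' (Gal3p%, Gal1p%) state space. Both transducers share the activation
#' signal `s = g3 + g1`; synthesis follows `beta * (basal + hill(s))` and
#' each protein decays at `delta` per minute. With calibrated defaults
#' (see [drift_params()]) the system has a stable fixed point at
#' (100, 100); with `basal = 0` the origin is a second (unstable) fixed
#' point.
#'
#' @param g3,g1 Expression levels in % of plateau (vectors allowed;
#'   recycled to a common length). Must be finite. Negative values (baseline
#'   noise) contribute zero activation.
#' @param params A [drift_params()] object.
#' @param boost Multiplier on the synthesis term (used for the transient
#'   resource boost in glucose-mix histories).
#' @return For scalar input, a named numeric `c(dg3, dg1)` in %/min;
#'   otherwise a two-column matrix.
#' @examples
#' induction_drift(100, 100, drift_params())   # ~ c(0, 0)
#' induction_drift(0, 0, drift_params(basal = 0))  # exactly c(0, 0)
#' @export
induction_drift <- function(g3, g1, params = drift_params(), boost = 1) {
  if (!all(is.finite(g3)) || !all(is.finite(g1))) {
    stop("induction_drift(): non-finite expression levels")
  }
  stopifnot(inherits(params, "drift_params"))
  n <- max(length(g3), length(g1))
  g3 <- rep_len(as.numeric(g3), n)
  g1 <- rep_len(as.numeric(g1), n)
  s <- pmax(g3 + g1, 0)
  act <- s^params$n_hill / (params$K^params$n_hill + s^params$n_hill)
  dg3 <- params$beta3 * (params$basal + act) * boost - params$delta * g3
  dg1 <- params$beta1 * (params$basal + act) * boost - params$delta * g1
  if (n == 1L) c(dg3 = dg3, dg1 = dg1) else cbind(dg3 = dg3, dg1 = dg1)
}

hist_is_mix <- function(history) history %in% c("mix015", "mix030")

#' Simulate a synthetic single-cell induction experiment
#'
#' Generates a population of cells following the bistable two-transducer
#' dynamics of [induction_drift()] by Euler-Maruyama integration at a 1-min
#' internal step, with history-dependent initial conditions, sticky-region
#' escape (LTGR), death before induction (LTGR), division with crowding
#' washout after induction, cell-specific lognormal plateau multipliers,
#' and a fluorescence measurement model
#' `au = gain * (true_pct * plateau_mult + noise) + baseline + autofluorescence`.
#' Control cells carry only baseline, autofluorescence, and noise.
#'
#' @param config A [sim_config()] object.
#' @param experiment Label written into the `experiment` column (defaults
#'   to the history name).
#' @param init Optional numeric matrix with columns (g3, g1): explicit
#'   initial states for the experimental cells (recycled), overriding the
#'   history preset's initial means. Intended for state-space coverage
#'   studies and tests.
#' @return A list of class `sim_result` with elements
#'   `tracks` (tibble, one row per present cell per fluorescence frame,
#'   columns `experiment, cell_id, parent_id, frame, t_min, au_yfp, au_cfp,
#'   x_um, y_um, area_px, class, alive`),
#'   `truth` (per-cell ground truth: escape/death/washout times, true
#'   plateaus, lineage parent, control flag),
#'   `bf` (bright-field positions: `cell_id, frame_bf, t_min, x_um, y_um`),
#'   and `meta` (config echo, demography counts, `warn_low_controls`).
#' @export
simulate_population <- function(config, experiment = config$history,
                                init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  dt <- 1

  n0 <- cfg$n_cells
  n_ctrl <- round(cfg$control_fraction * n0)
  n_bad <- round(cfg$bad_fraction * n0)
  n_exp <- n0 - n_ctrl - n_bad
  if (n_exp < 1) stop("simulate_population(): no experimental cells left ",
                      "after control/bad allocation")
  cap_exp <- ceiling(cfg$capacity_factor * n_exp)
  warn_low_controls <- n_ctrl < 50

  # growable state arrays -----------------------------------------------
  N <- n0 + 4L * cap_exp
  g3 <- g1 <- m3 <- m1 <- x <- y <- numeric(N)
  escape <- rep(Inf, N)
  birth <- death <- left <- rep(NA_real_, N)
  parent <- rep(NA_integer_, N)
  klass <- character(N)
  present <- alive <- logical(N)
  n_cells_total <- 0L

  grow <- function() {
    extra <- N
    g3 <<- c(g3, numeric(extra)); g1 <<- c(g1, numeric(extra))
    m3 <<- c(m3, numeric(extra)); m1 <<- c(m1, numeric(extra))
    x <<- c(x, numeric(extra)); y <<- c(y, numeric(extra))
    escape <<- c(escape, rep(Inf, extra))
    birth <<- c(birth, rep(NA_real_, extra))
    death <<- c(death, rep(NA_real_, extra))
    left <<- c(left, rep(NA_real_, extra))
    parent <<- c(parent, rep(NA_integer_, extra))
    klass <<- c(klass, character(extra))
    present <<- c(present, logical(extra))
    alive <<- c(alive, logical(extra))
    N <<- N + extra
  }

  # correlated lognormal plateau multipliers ----------------------------
  draw_mult <- function(n) {
    if (cfg$plateau_cv <= 0) return(cbind(rep(1, n), rep(1, n)))
    sdl <- sqrt(log(1 + cfg$plateau_cv^2))
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    za <- z1
    zb <- cfg$plateau_rho * z1 + sqrt(1 - cfg$plateau_rho^2) * z2
    cbind(exp(sdl * za - sdl^2 / 2), exp(sdl * zb - sdl^2 / 2))
  }

  # initial cells --------------------------------------------------------
  idx0 <- seq_len(n0)
  n_cells_total <- n0
  klass[idx0] <- c(rep("exp", n_exp), rep("control", n_ctrl),
                   rep("bad", n_bad))
  present[idx0] <- TRUE
  alive[idx0] <- TRUE
  birth[idx0] <- 0
  x[idx0] <- stats::runif(n0, 0, 100)
  y[idx0] <- stats::runif(n0, 0, 100)
  iexp <- idx0[klass[idx0] == "exp"]

  origin_start <- function(n) {
    cbind(pmin(abs(stats::rnorm(n, 0.3, 0.2)), cfg$sticky_radius * 0.45),
          pmin(abs(stats::rnorm(n, 0.3, 0.2)), cfg$sticky_radius * 0.45))
  }
  g0 <- switch(cfg$history,
    glycerol = cbind(pmax(stats::rnorm(n_exp, cfg$init_mean, cfg$init_sd), 0),
                     abs(stats::rnorm(n_exp, 0.2, 0.2))),
    reinduction = cbind(abs(stats::rnorm(n_exp, 0.2, 0.2)),
                        pmax(stats::rnorm(n_exp, cfg$init_mean, cfg$init_sd), 0)),
    origin_start(n_exp)  # ltgr and mixes
  )
  if (!is.null(init)) {
    init <- matrix(as.numeric(init), ncol = 2)
    g0 <- init[rep_len(seq_len(nrow(init)), n_exp), , drop = FALSE]
  }
  g3[iexp] <- g0[, 1]; g1[iexp] <- g0[, 2]
  mm <- draw_mult(n_exp)
  m3[iexp] <- mm[, 1]; m1[iexp] <- mm[, 2]
  m3[idx0[klass[idx0] != "exp"]] <- 1
  m1[idx0[klass[idx0] != "exp"]] <- 1

  if (cfg$history == "ltgr") {
    escape[iexp] <- if (cfg$escape_rate > 0) {
      stats::rexp(n_exp, cfg$escape_rate)
    } else rep(Inf, n_exp)
  } else {
    escape[iexp] <- 0  # no sticky phase outside LTGR
  }

  boost_at <- function(t) {
    if (hist_is_mix(cfg$history)) 1 + cfg$mix_boost * exp(-t / cfg$mix_boost_tau)
    else 1
  }

  # recording buffers ----------------------------------------------------
  n_fluor <- floor(cfg$duration / cfg$frame_interval_fluor) + 1L
  n_bf <- floor(cfg$duration / cfg$frame_interval_bf) + 1L
  fluor_rows <- vector("list", n_fluor)
  bf_rows <- vector("list", n_bf)
  i_fluor <- 0L; i_bf <- 0L
  n_div <- 0L; n_death <- 0L; n_wash <- 0L

  record_fluor <- function(t) {
    ids <- which(present[seq_len(n_cells_total)])
    k <- klass[ids]
    ne <- length(ids)
    eps3 <- stats::rnorm(ne, 0, cfg$meas_noise_sd)
    eps1 <- stats::rnorm(ne, 0, cfg$meas_noise_sd)
    base <- cfg$baseline_au + cfg$autofluor_au
    sig3 <- ifelse(k == "exp", g3[ids] * m3[ids], 0)
    sig1 <- ifelse(k == "exp", g1[ids] * m1[ids], 0)
    au_y <- base + cfg$gain3 * (sig3 + eps3)
    au_c <- base + cfg$gain1 * (sig1 + eps1)
    bad <- k == "bad"
    if (any(bad)) {  # intensely autofluorescent debris in both channels
      au_y[bad] <- cfg$baseline_au + 25 * cfg$autofluor_au +
        cfg$gain3 * abs(eps3[bad])
      au_c[bad] <- cfg$baseline_au + 25 * cfg$autofluor_au +
        cfg$gain1 * abs(eps1[bad])
    }
    list(cell_id = ids, parent_id = parent[ids],
         frame = rep(t %/% cfg$frame_interval_fluor + 1L, ne),
         t_min = rep(t, ne), au_yfp = au_y, au_cfp = au_c,
         x_um = x[ids], y_um = y[ids],
         area_px = pmax(stats::rnorm(ne, 120, 15), 30),
         class = k, alive = as.integer(alive[ids]))
  }

  induced <- function(ids) g3[ids] + g1[ids] >= 100

  for (t in seq(0, cfg$duration, by = dt)) {
    on_bf <- t %% cfg$frame_interval_bf == 0
    on_fl <- t %% cfg$frame_interval_fluor == 0

    if (on_bf) {
      ids <- which(present[seq_len(n_cells_total)])
      if (t > 0) {  # crowd mobility tracks the induced fraction
        ie <- ids[klass[ids] == "exp" & alive[ids]]
        frac_ind <- if (length(ie)) mean(induced(ie)) else 0
        mob <- cfg$movement_sd *
          (cfg$stasis_factor + (1 - cfg$stasis_factor) * frac_ind)
        x[ids] <- x[ids] + stats::rnorm(length(ids), 0, mob)
        y[ids] <- y[ids] + stats::rnorm(length(ids), 0, mob)
      }
      i_bf <- i_bf + 1L
      bf_rows[[i_bf]] <- list(
        cell_id = ids,
        frame_bf = rep(t %/% cfg$frame_interval_bf + 1L, length(ids)),
        t_min = rep(t, length(ids)), x_um = x[ids], y_um = y[ids])
    }
    if (on_fl) {
      i_fluor <- i_fluor + 1L
      fluor_rows[[i_fluor]] <- record_fluor(t)
    }
    if (t >= cfg$duration) break

    all_ids <- seq_len(n_cells_total)
    act <- all_ids[present[all_ids] & klass[all_ids] == "exp"]

    # drift + intrinsic noise for live, escaped cells
    mov <- act[alive[act] & t >= escape[act]]
    if (length(mov)) {
      d <- induction_drift(g3[mov], g1[mov], cfg$drift, boost = boost_at(t))
      d <- matrix(d, ncol = 2)
      g3[mov] <- g3[mov] + d[, 1] * dt
      g1[mov] <- g1[mov] + d[, 2] * dt
      if (cfg$intrinsic_noise_sd > 0) {
        sdn <- cfg$intrinsic_noise_sd * sqrt(dt)
        g3[mov] <- abs(g3[mov] + stats::rnorm(length(mov), 0, sdn))
        g1[mov] <- abs(g1[mov] + stats::rnorm(length(mov), 0, sdn))
      }
    }
    # dead cells: no synthesis, first-order decay
    dd <- act[!alive[act]]
    if (length(dd)) {
      g3[dd] <- g3[dd] * (1 - cfg$drift$delta * dt)
      g1[dd] <- g1[dd] * (1 - cfg$drift$delta * dt)
    }

    # death of uninduced LTGR cells
    if (cfg$history == "ltgr" && cfg$death_hazard_preinduction > 0) {
      vul <- act[alive[act] & !induced(act)]
      if (length(vul)) {
        dies <- vul[stats::runif(length(vul)) <
                      cfg$death_hazard_preinduction * dt]
        if (length(dies)) {
          alive[dies] <- FALSE
          death[dies] <- t + dt
          n_death <- n_death + length(dies)
        }
      }
    }

    # division of induced cells, with washout at carrying capacity
    if (cfg$division_rate_postinduction > 0) {
      fert <- act[alive[act] & induced(act)]
      if (length(fert)) {
        moms <- fert[stats::runif(length(fert)) <
                       cfg$division_rate_postinduction * dt]
        for (mom in moms) {
          while (n_cells_total + 1L > N) grow()
          kid <- n_cells_total + 1L
          n_cells_total <- kid
          g3[kid] <- g3[mom]; g1[kid] <- g1[mom]
          m3[kid] <- m3[mom]; m1[kid] <- m1[mom]
          parent[kid] <- mom; birth[kid] <- t + dt
          escape[kid] <- 0
          klass[kid] <- "exp"; present[kid] <- TRUE; alive[kid] <- TRUE
          x[kid] <- x[mom] + stats::rnorm(1, 0, 1)
          y[kid] <- y[mom] + stats::rnorm(1, 0, 1)
          n_div <- n_div + 1L
          pres_exp <- which(present[seq_len(n_cells_total)] &
                              klass[seq_len(n_cells_total)] == "exp")
          if (length(pres_exp) > cap_exp) {
            out <- sample(setdiff(pres_exp, kid), 1L)
            present[out] <- FALSE
            left[out] <- t + dt
            n_wash <- n_wash + 1L
          }
        }
      }
    }
  }

  ids_all <- seq_len(n_cells_total)
  tracks <- tibble::as_tibble(
    lapply(stats::setNames(names(fluor_rows[[1]]), names(fluor_rows[[1]])),
           function(nm) unlist(lapply(fluor_rows, `[[`, nm),
                               use.names = FALSE)))
  tracks$experiment <- experiment
  tracks <- tracks[, c("experiment", "cell_id", "parent_id", "frame",
                       "t_min", "au_yfp", "au_cfp", "x_um", "y_um",
                       "area_px", "class", "alive")]
  bf <- tibble::as_tibble(
    lapply(stats::setNames(names(bf_rows[[1]]), names(bf_rows[[1]])),
           function(nm) unlist(lapply(bf_rows, `[[`, nm),
                               use.names = FALSE)))
  truth <- tibble::tibble(
    cell_id = ids_all,
    is_control = klass[ids_all] == "control",
    class = klass[ids_all],
    escape_time = ifelse(cfg$history == "ltgr" & klass[ids_all] == "exp" &
                           is.na(parent[ids_all]),
                         escape[ids_all], NA_real_),
    true_plateau3 = ifelse(klass[ids_all] == "exp", 100 * m3[ids_all],
                           NA_real_),
    true_plateau1 = ifelse(klass[ids_all] == "exp", 100 * m1[ids_all],
                           NA_real_),
    lineage_parent = parent[ids_all],
    birth_time = birth[ids_all],
    death_time = death[ids_all],
    left_time = left[ids_all]
  )
  out <- list(tracks = tracks, truth = truth, bf = bf,
              meta = list(config = cfg, experiment = experiment,
                          warn_low_controls = warn_low_controls,
                          n_divisions = n_div, n_deaths = n_death,
                          n_washouts = n_wash))
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result>", x$meta$experiment, ":",
      length(unique(x$tracks$cell_id)), "cells,",
      nrow(x$tracks), "track rows,",
      x$meta$n_divisions, "divisions,",
      x$meta$n_deaths, "deaths\n")
  invisible(x)
}

#' Render a per-cell pixel-intensity sample
#'
#' Emulates the pixel values inside one segmented cell at one frame. Pixel
#' values scatter around the cell's raw intensity `au` with standard
#' deviation `gain * meas_noise_sd * sqrt(n_pixels)`, so that the pixel
#' mean reproduces the track-level measurement noise. With probability
#' `puncta_prob` (or when `punctum = TRUE`) a small subset of pixels
#' (5% or at least one) is replaced by a high-intensity punctum value of at
#' least ten times the cell's pixel median.
#'
#' @param au The cell's raw intensity (AU, background included).
#' @param config A [sim_config()] object (supplies noise, gain, puncta
#'   probability).
#' @param channel `"yfp"` or `"cfp"` (selects the gain).
#' @param n_pixels Number of pixels (>= 30).
#' @param punctum Force (`TRUE`) or suppress (`FALSE`) a punctum;
#'   `NULL` draws from `puncta_prob`.
#' @return Numeric vector of pixel values; attribute `"punctum"` records
#'   whether one was injected.
#' @export
render_pixels <- function(au, config, channel = c("yfp", "cfp"),
                          n_pixels = 36, punctum = NULL) {
  stopifnot(inherits(config, "sim_config"), n_pixels >= 30, is.finite(au))
  channel <- match.arg(channel)
  gain <- if (channel == "yfp") config$gain3 else config$gain1
  px_sd <- gain * config$meas_noise_sd * sqrt(n_pixels)
  px <- stats::rnorm(n_pixels, au, px_sd)
  if (is.null(punctum)) punctum <- stats::runif(1) < config$puncta_prob
  if (punctum) {
    k <- max(1L, floor(0.05 * n_pixels))
    hot <- sample.int(n_pixels, k)
    med <- stats::median(px)
    px[hot] <- 12 * max(med, 0) + 10 * max(px_sd, 1)
  }
  attr(px, "punctum") <- punctum
  px
}
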
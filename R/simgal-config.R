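#' Drift parameters for the two-transducer induction model
#'
#' The deterministic part of the simulated dynamics is a symmetric
#' positive-feedback model on the plateau-percent scale: each transducer is
#' synthesized at rate `beta * (basal + s^n / (K^n + s^n))` with shared
#' activation signal `s = g3 + g1`, and decays at rate `delta` per minute.
#' When `beta3`/`beta1` are `NULL` they are calibrated so that
#' (100%, 100%) is an exact fixed point:
#' `beta = delta * 100 / (basal + hill(200))`.
#'
#' @param beta3,beta1 Maximal synthesis rates (%/min). `NULL` (default)
#'   calibrates both so the stable fixed point sits at (100, 100).
#' @param K Half-activation of the shared signal, in % of plateau.
#' @param n_hill Hill exponent (>= 1).
#' @param basal Basal synthesis as a fraction of the maximal rate.
#' @param delta First-order decay/dilution rate per minute.
#' @return A named list of class `drift_params`.
#' @examples
#' p <- drift_params()
#' induction_drift(100, 100, p)  # c(0, 0) by calibration
#' @export
drift_params <- function(beta3 = NULL, beta1 = NULL, K = 30, n_hill = 2,
                         basal = 0.02, delta = 0.02) {
  stopifnot(K > 0, n_hill >= 1, basal >= 0, delta > 0)
  h200 <- 200^n_hill / (K^n_hill + 200^n_hill)
  beta_cal <- delta * 100 / (basal + h200)
  p <- list(
    beta3 = if (is.null(beta3)) beta_cal else beta3,
    beta1 = if (is.null(beta1)) beta_cal else beta1,
    K = K, n_hill = n_hill, basal = basal, delta = delta
  )
  stopifnot(p$beta3 >= 0, p$beta1 >= 0)
  class(p) <- "drift_params"
  p
}

#' Simulation configuration for synthetic GAL-like induction experiments
#'
#' Bundles every parameter of the synthetic single-cell generator: the
#' bistable drift, the history preset (which sets the initial transducer
#' levels and, for `ltgr`, the sticky-region escape process), demography
#' (death before induction, division and crowding washout after),
#' cell-specific plateau heterogeneity, and the measurement model
#' (gains, baseline, autofluorescence, noise, puncta, movement).
#'
#' History presets:
#' * `glycerol` - cells start with Gal3p around `init_mean`% and almost no
#'   Gal1p; they induce quickly and uniformly.
#' * `reinduction` - mirror image: residual Gal1p, almost no Gal3p.
#' * `ltgr` - long-term glucose repression: both transducers start near
#'   zero inside `sticky_radius`; the drift is suppressed until a
#'   per-cell exponential escape time with hazard `escape_rate`, and
#'   uninduced cells die with hazard `death_hazard_preinduction`.
#' * `mix015` / `mix030` - glucose-supplemented galactose after LTGR:
#'   cells start at the origin with no sticky phase, and synthesis is
#'   transiently boosted by `1 + mix_boost * exp(-t / mix_boost_tau)`,
#'   producing the characteristic plateau overshoot.
#'
#' @param seed Integer RNG seed (mandatory; identical seed + config gives
#'   byte-identical output).
#' @param n_cells Number of cells at time zero, controls included.
#' @param history One of `"glycerol"`, `"reinduction"`, `"ltgr"`,
#'   `"mix015"`, `"mix030"`.
#' @param frame_interval_fluor Minutes between fluorescence frames.
#' @param frame_interval_bf Minutes between bright-field frames.
#' @param duration Total simulated minutes after the medium switch (t = 0).
#' @param drift A [drift_params()] object.
#' @param escape_rate Per-minute hazard of leaving the sticky region
#'   (used for `ltgr` only). Default 0.0017, together with the
#'   demographic selection against late escapers, puts the observed
#'   median 10%-crossing lag of inducing cells in the 5-6.5 h range.
#' @param sticky_radius Radius (%) of the origin neighbourhood in which
#'   pre-escape cells are held.
#' @param init_mean,init_sd Mean and sd (%) of the non-zero initial
#'   transducer for glycerol/reinduction histories.
#' @param plateau_cv Coefficient of variation of the lognormal
#'   cell-specific plateau multipliers (applied to both channels).
#' @param plateau_rho Correlation of the two channels' log-multipliers.
#' @param intrinsic_noise_sd Sd of the additive Gaussian intrinsic noise on
#'   the Euler-Maruyama step, in % per sqrt(minute); applied after escape.
#' @param meas_noise_sd Measurement noise sd on the percent scale; the
#'   recorded intensity is `gain * (true_pct + noise) + baseline`.
#' @param gain3,gain1 AU per percent for the Gal3p (YFP) and Gal1p (CFP)
#'   channels; Gal1p is ~10x brighter.
#' @param baseline_au Background (non-cell) intensity level, AU.
#' @param autofluor_au Mean cellular autofluorescence above background, AU.
#' @param death_hazard_preinduction Per-minute death hazard for uninduced
#'   `ltgr` cells.
#' @param division_rate_postinduction Per-minute division hazard once a
#'   cell's summed transducer level exceeds 100%.
#' @param capacity_factor Field carrying capacity as a multiple of
#'   `n_cells`; at capacity each division washes a random non-control cell
#'   out of the field.
#' @param control_fraction Fraction of initial cells that are reporter-free
#'   controls. A configuration whose expected control count is < 50 is
#'   flagged in the output metadata.
#' @param puncta_prob Per cell per frame probability of a punctum in the
#'   rendered pixel sample.
#' @param movement_sd Random-walk displacement sd, um per bright-field
#'   frame, when the population is fully motile.
#' @param stasis_factor Multiplier on `movement_sd` when no cell has
#'   induced (crowded, non-growing field).
#' @param mix_boost,mix_boost_tau Amplitude and decay time (min) of the
#'   transient synthesis boost in the glucose-mix histories.
#' @param bad_fraction Fraction of cells emitted with class `"bad"`
#'   (autofluorescent debris that downstream stages must ignore).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_cells = 300,
                       history = c("glycerol", "reinduction", "ltgr",
                                   "mix015", "mix030"),
                       frame_interval_fluor = 20,
                       frame_interval_bf = 2,
                       duration = 1500,
                       drift = drift_params(),
                       escape_rate = 0.0017,
                       sticky_radius = 2,
                       init_mean = 3,
                       init_sd = 1,
                       plateau_cv = 0.15,
                       plateau_rho = 0.5,
                       intrinsic_noise_sd = 0.3,
                       meas_noise_sd = 1.5,
                       gain3 = 20,
                       gain1 = 200,
                       baseline_au = 100,
                       autofluor_au = 5,
                       death_hazard_preinduction = 1e-3,
                       division_rate_postinduction = 0.0029,
                       capacity_factor = 2,
                       control_fraction = 0.25,
                       puncta_prob = 0.05,
                       movement_sd = 0.5,
                       stasis_factor = 0.15,
                       mix_boost = 0.25,
                       mix_boost_tau = 250,
                       bad_fraction = 0.01) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("sim_config(): `seed` is mandatory")
  }
  history <- match.arg(history)
  stopifnot(inherits(drift, "drift_params"))
  num_nonneg <- c(
    frame_interval_fluor = frame_interval_fluor,
    frame_interval_bf = frame_interval_bf,
    escape_rate = escape_rate, sticky_radius = sticky_radius,
    init_mean = init_mean, init_sd = init_sd,
    plateau_cv = plateau_cv, intrinsic_noise_sd = intrinsic_noise_sd,
    meas_noise_sd = meas_noise_sd, gain3 = gain3, gain1 = gain1,
    baseline_au = baseline_au, autofluor_au = autofluor_au,
    death_hazard_preinduction = death_hazard_preinduction,
    division_rate_postinduction = division_rate_postinduction,
    movement_sd = movement_sd, stasis_factor = stasis_factor,
    mix_boost = mix_boost, mix_boost_tau = mix_boost_tau
  )
  if (any(!is.finite(num_nonneg)) || any(num_nonneg < 0)) {
    bad <- names(num_nonneg)[!is.finite(num_nonneg) | num_nonneg < 0]
    stop("sim_config(): negative or non-finite parameter(s): ",
         paste(bad, collapse = ", "))
  }
  probs <- c(control_fraction = control_fraction,
             puncta_prob = puncta_prob, bad_fraction = bad_fraction,
             plateau_rho = abs(plateau_rho))
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config(): probabilities must lie in [0, 1]")
  }
  if (n_cells < 1) stop("sim_config(): n_cells must be >= 1")
  if (duration <= 0) stop("sim_config(): duration must be > 0")
  if (capacity_factor < 1) stop("sim_config(): capacity_factor must be >= 1")
  cfg <- list(
    seed = as.integer(seed), n_cells = as.integer(n_cells), history = history,
    frame_interval_fluor = frame_interval_fluor,
    frame_interval_bf = frame_interval_bf, duration = duration,
    drift = drift, escape_rate = escape_rate, sticky_radius = sticky_radius,
    init_mean = init_mean, init_sd = init_sd,
    plateau_cv = plateau_cv, plateau_rho = plateau_rho,
    intrinsic_noise_sd = intrinsic_noise_sd, meas_noise_sd = meas_noise_sd,
    gain3 = gain3, gain1 = gain1, baseline_au = baseline_au,
    autofluor_au = autofluor_au,
    death_hazard_preinduction = death_hazard_preinduction,
    division_rate_postinduction = division_rate_postinduction,
    capacity_factor = capacity_factor, control_fraction = control_fraction,
    puncta_prob = puncta_prob, movement_sd = movement_sd,
    stasis_factor = stasis_factor,
    mix_boost = mix_boost, mix_boost_tau = mix_boost_tau,
    bad_fraction = bad_fraction
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> history:", x$history,
      " n_cells:", x$n_cells,
      " duration:", x$duration, "min",
      " seed:", x$seed, "\n")
  invisible(x)
}
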
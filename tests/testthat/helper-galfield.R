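# Shared fixture builders for the test suite. Everything is generated in
# code; no fixture files.

# minimal normalized-track tibble from per-cell (t, pct3, pct1) matrices
make_norm <- function(cells, experiment = "test", dt = 20) {
  dplyr::bind_rows(lapply(names(cells), function(id) {
    m <- cells[[id]]
    tibble::tibble(
      experiment = experiment, cell_id = id,
      frame = seq_len(nrow(m)), t_min = (seq_len(nrow(m)) - 1) * dt,
      pct3 = m[, 1], pct1 = m[, 2])
  }))
}

# a vector_field object holding hand-placed member directions in one bin
make_field_with_dirs <- function(theta, i3 = 5, i1 = 5, width = 6) {
  members <- tibble::tibble(
    i3 = i3, i1 = i1, cell_id = seq_along(theta),
    frame = 1L, theta = theta, speed = 1, v3 = cos(theta),
    v1 = sin(theta))
  field <- tibble::tibble(
    i3 = i3, i1 = i1, lo3 = i3 * width, lo1 = i1 * width,
    n = length(theta), v3 = mean(cos(theta)), v1 = mean(sin(theta)),
    circ_var = galfield::circular_variance(theta))
  structure(list(field = field, members = members, width = width,
                 t_range = c(0, 900)),
            class = "vector_field")
}

# small fully-quantified track table: ctrl controls at `ctrl_level`,
# experimental cells at given values, one frame
make_frame <- function(exp_values, ctrl_values, frame = 1) {
  tibble::tibble(
    frame = frame,
    cell_id = seq_len(length(exp_values) + length(ctrl_values)),
    class = c(rep("exp", length(exp_values)),
              rep("control", length(ctrl_values))),
    au_yfp = c(exp_values, ctrl_values),
    au_cfp = c(exp_values, ctrl_values))
}

# escape time of each cell's founder (root of the lineage)
root_escape <- function(truth) {
  esc <- truth$escape_time
  par <- truth$lineage_parent
  r <- seq_len(nrow(truth))
  for (i in r) {
    j <- i
    while (!is.na(par[j])) j <- par[j]
    r[i] <- j
  }
  esc[r]
}

# run simulate -> quantify -> normalize for one history
pipeline_normalize <- function(history, seed, n_cells = 250, ...) {
  sim <- galfield::simulate_population(
    galfield::sim_config(seed = seed, n_cells = n_cells,
                         history = history, ...))
  tr <- galfield::filter_short_tracks(sim$tracks, bf = sim$bf)
  bl <- galfield::baseline_by_controls(tr)
  list(sim = sim, norm = galfield::normalize_experiment(bl$data))
}

# angular difference in degrees, wrapped to [0, 180]
angle_diff_deg <- function(a, b) {
  abs((a - b + pi) %% (2 * pi) - pi) * 180 / pi
}
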
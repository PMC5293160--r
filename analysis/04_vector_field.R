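#!/usr/bin/env Rscript
# Vector-field stage: bin the (Gal3p%, Gal1p%) state space in 6% steps,
# estimate per-bin mean velocities and circular variances for each
# history, then compute the cross-experiment consistency statistic on
# cutoff-filtered data (500 resamples of 10 member directions per bin)
# for the three main histories, with a bilinear fine-grid interpolation.

library(galfield)
suppressMessages({library(readr); library(dplyr)})

out <- "results"
dir.create(file.path(out, "figures"), showWarnings = FALSE)
norm <- read_csv(file.path(out, "normalized.csv"), show_col_types = FALSE)

fields <- list()
for (h in unique(norm$experiment)) {
  d <- norm[norm$experiment == h, ]
  vf <- estimate_field(d, t_range = c(0, 900), width = 6)
  fields[[h]] <- vf
  f <- vf$field
  f$experiment <- h
  message(sprintf("%-11s %3d bins, %5d member velocities, median circ. var %.2f",
                  h, nrow(f), nrow(vf$members),
                  median(f$circ_var, na.rm = TRUE)))
  if (h == "ltgr") {
    ggplot2::ggsave(file.path(out, "figures", "vector_field_ltgr.png"),
                    plot_vector_field(vf), width = 6, height = 5, dpi = 150)
  }
}
write_table(bind_rows(lapply(names(fields), function(h) {
  f <- fields[[h]]$field
  f$experiment <- h
  f
})), file.path(out, "vector_field.csv"))

# consistency of the three main histories on cutoff-filtered tracks
main <- c("glycerol", "reinduction", "ltgr")
cut_fields <- lapply(main, function(h) {
  d <- norm[norm$experiment == h, ]
  co <- cutoff_frames(d)
  message(sprintf("%-11s 95%%-inducer frame F = %d", h, co$experiment_frame))
  estimate_field(apply_cutoffs(d, co), t_range = c(0, 900), width = 6)
})
names(cut_fields) <- main
cm <- consistency_statistic(cut_fields, min_n = 10, B = 500, m = 10,
                            seed = 20170104)
write_table(cm$map, file.path(out, "consistency.csv"))
write_table(interpolate_map(cm, factor = 4),
            file.path(out, "consistency_fine.csv"))
m <- cm$map
corner <- m$stat[m$i3 <= 1 & m$i1 <= 1]
midflow <- m$stat[m$i3 >= 2 & m$i1 >= 2 & m$i3 <= 12 & m$i1 <= 12]
nearfix <- m$stat[m$i3 > 12 | m$i1 > 12]
message(sprintf(
  "Findings: consistency statistic %.2f rad in the origin corner vs %.3f rad (max) in the mid-flow region:",
  max(corner), if (length(midflow)) max(midflow) else NA))
message("the three histories' flows disagree where LTGR cells wait to ",
        "escape, and agree through the induction front -- the cells have ",
        "lost their memory once they leave the corner.")
if (length(nearfix) && max(nearfix) > 0.2) {
  message(sprintf(
    "Note: %d bins adjacent to the (100%%, 100%%) fixed point reach %.2f rad -- drift speeds vanish there, so directions are noise-dominated (see the methods vignette).",
    sum(nearfix > 0.2), max(nearfix)))
}
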
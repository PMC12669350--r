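#!/usr/bin/env Rscript

# Step 4: Raman band-ratio metrics across tissue age and patient groups.
#
# Simulates osteonal ROI spectra at the five microanatomical positions
# (Os at the osteoid-forming front, TA1-TA3 between/around the tetracycline
# labels, In for older interstitial bone). Mineral content rises with tissue
# age (the v2PO4/v1PO4 amplitudes grow Os -> In); the affected group carries
# extra proteoglycan signal (higher GAG band). Spectra are trimmed,
# rubber-band corrected, reduced to the five metrics, averaged into one
# statistical unit per (subject, compartment, position), and compared by
# two-way ANOVA (group x position) with Holm-Sidak within-position contrasts.

suppressMessages(library(bonemat))
dir.create("results", showWarnings = FALSE)
set.seed(401)

positions <- c("Os", "TA1", "TA2", "TA3", "In")
mineral_scale <- c(Os = 0.15, TA1 = 0.55, TA2 = 0.75, TA3 = 0.9, In = 1.0)
groups <- rbind(data.frame(group = "GROUP-1", subject = 1:5, gag_scale = 1.35),
                data.frame(group = "GROUP-2", subject = 6:12, gag_scale = 1.0))

rows <- list()
for (i in seq_len(nrow(groups))) {
  for (pos in positions) {
    for (roi in 1:2) {
      b <- default_bone_bands()
      b$amplitude[b$name %in% c("v2PO4", "v1PO4")] <-
        b$amplitude[b$name %in% c("v2PO4", "v1PO4")] * mineral_scale[[pos]] *
        exp(rnorm(1, 0, 0.06))
      b$amplitude[b$name == "CH3"] <-
        b$amplitude[b$name == "CH3"] * groups$gag_scale[i] * exp(rnorm(1, 0, 0.06))
      rs <- render_spectrum(spectrum_spec(bands = b, noise_sd = 0.01))
      p <- process_spectrum(rs$spectrum)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(subject = groups$subject[i], group = groups$group[i],
                   compartment = "osteonal", position = pos, roi_id = roi,
                   label_quality = "two-labels"), p)
    }
  }
}
per_roi <- do.call(rbind, rows)
units <- aggregate_statistical_units(per_roi)
units <- merge(units, unique(per_roi[, c("subject", "group")]), by = "subject")
units$position <- factor(units$position, levels = positions)
write.csv(units, "results/raman_units.csv", row.names = FALSE)

cat("mean mineral/matrix ratio by tissue age (pooled groups):\n")
print(round(tapply(units$mm, units$position, mean), 3))

anova_rows <- list()
for (metric in c("mm", "gag", "nanoporosity", "pyd", "mmc")) {
  d <- data.frame(value = units[[metric]], group = units$group,
                  position = units$position)
  r <- two_way_anova(d)
  anova_rows[[length(anova_rows) + 1]] <- data.frame(
    metric = metric,
    p_group = r$anova_table["group", "Pr(>F)"],
    p_position = r$anova_table["position", "Pr(>F)"],
    p_interaction = r$anova_table["group:position", "Pr(>F)"],
    min_posthoc_p = min(r$post_hoc$p_adjusted))
}
anova_tab <- do.call(rbind, anova_rows)
write.csv(anova_tab, "results/raman_anova.csv", row.names = FALSE)
cat("\ntwo-way ANOVA (group x position), type-II p-values:\n")
print(anova_tab, row.names = FALSE, digits = 3)
cat("wrote results/raman_units.csv, raman_anova.csv\n")
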
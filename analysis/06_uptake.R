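#!/usr/bin/env Rscript
# Stage 6 — renal uptake quantification and agreement analysis.
#
# Uptake (U - B) / D * (1/k) * 100 is computed on the full-time, short-time
# and predicted full-time image of every test case with the ground-truth
# ROIs and dose counts (k = 1: the phantom has no attenuating tissue), and
# compared to the full-time reference with scatter + Bland-Altman analyses.

library(fastdmsa)
out <- "results/analysis"
cohort <- readRDS(file.path(out, "cohort.rds"))
ds <- readRDS(file.path(out, "dataset.rds"))
models <- sapply(c("dncnn", "win5rb", "resunet"), function(a)
  load_model(file.path(out, sprintf("model_%s.rds", a))), simplify = FALSE)

rows <- list()
for (id in ds$split$test) {
  case <- cohort[[id]]
  rois <- roi_set(case$truth$kidney_masks, case$truth$background_mask)
  D <- case$truth$total_dose_counts
  full <- sum_frames(case$series)
  short <- sum_frames(case$series, 1:2)
  imgs <- c(list(`full-time` = full, `short-time` = short),
            lapply(models, function(m) predict_counts(m, short)))
  Ds <- c(D, D * 0.2, rep(D, length(models)))
  for (i in seq_along(imgs)) {
    u <- image_uptake(imgs[[i]], rois, D = Ds[i], k = 1)
    u$case_id <- id; u$image_type <- names(imgs)[i]
    rows[[length(rows) + 1L]] <- u
  }
}
upt <- do.call(rbind, rows)
write.csv(upt, file.path(out, "uptake.csv"), row.names = FALSE)

ref <- upt[upt$image_type == "full-time", ]
for (ty in c("short-time", names(models))) {
  cmp <- upt[upt$image_type == ty, ]
  cmp <- cmp[match(paste(ref$case_id, ref$kidney),
                   paste(cmp$case_id, cmp$kidney)), ]
  ag <- agreement_analysis(ref$uptake_percent, cmp$uptake_percent)
  message(sprintf("%s vs full-time: R^2 %.4f, bias %.3f, limits (%.3f, %.3f)",
                  ty, ag$r2, ag$bias, ag$lower, ag$upper))
  ggplot2::ggsave(file.path(out, sprintf("bland_altman_%s.png", ty)),
                  bland_altman_plot(ref$uptake_percent, cmp$uptake_percent,
                                    sprintf("Renal uptake: %s vs full-time", ty)),
                  width = 5, height = 4, dpi = 120)
  ggplot2::ggsave(file.path(out, sprintf("scatter_%s.png", ty)),
                  uptake_scatter_plot(ref$uptake_percent, cmp$uptake_percent,
                                      sprintf("%s vs full-time", ty)),
                  width = 5, height = 4, dpi = 120)
}
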
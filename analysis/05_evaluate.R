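#!/usr/bin/env Rscript
# Stage 5 — image-quality evaluation on the held-out test pairs.
#
# NMSE / PSNR / SSIM of the short-time inputs and of each model's predicted
# full-time images against the 10-frame references, aggregated as
# mean (SD) and median (Q1, Q3), plus joint voxel-wise histograms with
# Pearson correlation.

library(fastdmsa)
out <- "results/analysis"
ds <- readRDS(file.path(out, "dataset.rds"))
models <- sapply(c("dncnn", "win5rb", "resunet"), function(a)
  load_model(file.path(out, sprintf("model_%s.rds", a))), simplify = FALSE)

shorts <- lapply(ds$test, `[[`, "short_time")
refs <- lapply(ds$test, `[[`, "full_time")
preds <- lapply(models, function(m)
  lapply(ds$test, function(p) predict_counts(m, p$short_time, p$params)))

ev <- evaluate_split(preds, shorts, refs)
write.csv(ev$summary, file.path(out, "metrics_summary.csv"), row.names = FALSE)
write.csv(ev$per_image, file.path(out, "metrics_per_image.csv"), row.names = FALSE)

for (m in names(preds)) {
  jh <- joint_histogram(preds[[m]], refs)
  write.csv(jh$histogram, file.path(out, sprintf("joint_histogram_%s.csv", m)),
            row.names = FALSE)
  message(sprintf("joint-histogram R^2 (%s vs full-time): %.4f", m, jh$r2))
}
jh0 <- joint_histogram(shorts, refs)
message(sprintf("joint-histogram R^2 (short-time vs full-time): %.4f", jh0$r2))
print(reshape(ev$summary[, c("method", "metric", "mean")],
              idvar = "metric", timevar = "method", direction = "wide"))
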
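#!/usr/bin/env Rscript
# Stage 3 — build the short-time / full-time training pairs.
#
# Every case yields C(10, 2) = 45 two-frame sums paired with its 10-frame
# sum; cases are split 12/4/4 (train/validation/test) and pairs are
# standardized with the input image's mean and standard deviation.

library(fastdmsa)
out <- "results/analysis"
cohort <- readRDS(file.path(out, "cohort.rds"))

split <- split_cases(names(cohort), fractions = c(0.6, 0.2, 0.2), seed = 5L)
take <- function(pl, k, seed) { set.seed(seed); pl[sort(sample(length(pl), k))] }
pairs_of <- function(ids, k) {
  out <- list()
  for (id in ids)
    out <- c(out, lapply(take(build_pairs(cohort[[id]]$series, id), k, 3L),
                         standardize_pair))
  out
}
ds <- list(split = split,
           train = pairs_of(split$train, 15L),
           validation = pairs_of(split$validation, 10L),
           test = pairs_of(split$test, 10L))
saveRDS(ds, file.path(out, "dataset.rds"))

manifest <- do.call(rbind, lapply(c("train", "validation", "test"), function(s)
  data.frame(split = s,
             case_id = vapply(ds[[s]], `[[`, character(1), "case_id"),
             frame_a = vapply(ds[[s]], function(p) p$frame_indices[1], integer(1)),
             frame_b = vapply(ds[[s]], function(p) p$frame_indices[2], integer(1)))))
write.csv(manifest, file.path(out, "dataset_manifest.csv"), row.names = FALSE)
message(sprintf("dataset: %d train / %d validation / %d test pairs from %d/%d/%d cases",
                length(ds$train), length(ds$validation), length(ds$test),
                length(split$train), length(split$validation), length(split$test)))
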
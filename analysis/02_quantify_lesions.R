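#!/usr/bin/env Rscript
# Stage 2 — EZ-loss quantification.
#
# For every visit of the simulated cohort, derives the EZ-loss mask from
# the OS map (absence = zero thickness), applies the peri-papillary and
# validity exclusions, and computes the lesion area by both routes: pixel
# counting on the en face mask and the B-scan-wise Riemann sum with the
# 250/200 um break-forgiveness rules. Writes results/lesions.csv.

library(ezprog)

cohort <- read_cohort("results/cohort")
rows <- lapply(cohort$visits, function(m) {
  rec <- quantify_lesion(m)
  data.frame(patient_id = m$meta$patient_id, eye = m$meta$eye,
             eye_id = paste(m$meta$patient_id, m$meta$eye, sep = ":"),
             age = m$meta$age, area_mm2 = rec$area_mm2,
             sqrt_area_mm = sqrt(rec$area_mm2),
             riemann_area_mm2 = rec$riemann_area_mm2)
})
lesions <- do.call(rbind, rows)
lesions <- lesions[order(lesions$eye_id, lesions$age), ]
first <- ave(lesions$age, lesions$eye_id, FUN = min)
lesions$time <- lesions$age - first

write.csv(lesions, "results/lesions.csv", row.names = FALSE)
agree <- with(lesions, max(abs(area_mm2 - riemann_area_mm2)))
message(sprintf("quantified %d visits; median area %.2f mm^2; max |map - Riemann| %.3f mm^2",
                nrow(lesions), median(lesions$area_mm2), agree))
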
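#!/usr/bin/env Rscript
# Generate the synthetic survey data the downstream analyses run on:
# a Danish-style survey (4 undiluted qPCR replicates per filter, 100 uL
# eluate, 5 uL template, ~1 L filtered) and a Norwegian-style survey
# (2 undiluted + 2 ten-fold diluted replicates, 200 uL eluate, 2 uL
# template, 5 L filtered, with PCR inhibition in two samples). Site truth
# spans no eDNA, trace level, and three quantifiable tenfold levels.

library(ednaqpcr)
dir.create("results", showWarnings = FALSE)

dk_sites <- data.frame(
  sample_id = c("DK_A", "DK_B", "DK_C", "DK_D", "DK_E"),
  true_copies_per_l = c(0, 2e2, 1e3, 1e4, 1e5),
  V_w = 1, V_e = 100, V_r = 5)
dk <- simulate_survey(dk_sites, simulation_config(template_volume = 5),
                      scheme = "danish", assay_id = "Astast", seed = 11)
write_plate(dk$plate, "results/plate_danish.csv")
write.csv(dk$truth, "results/truth_danish.csv", row.names = FALSE)

no_sites <- data.frame(
  sample_id = c("NO_A", "NO_B", "NO_C", "NO_D", "NO_E"),
  true_copies_per_l = c(0, 4e2, 2e3, 2e4, 2e4),
  V_w = 5, V_e = 200, V_r = 2,
  inhibition_shift = c(0, 0, 0, 2.0, 0))
no <- simulate_survey(no_sites, simulation_config(template_volume = 2),
                      scheme = "norwegian", assay_id = "Paclen", seed = 12)
write_plate(no$plate, "results/plate_norwegian.csv")
write.csv(no$truth, "results/truth_norwegian.csv", row.names = FALSE)

cat("Danish plate:", nrow(dk$plate), "wells;",
    sum(is.na(dk$plate$ct)), "non-detects\n")
cat("Norwegian plate:", nrow(no$plate), "wells;",
    sum(is.na(no$plate$ct)), "non-detects\n")
cat("all control wells negative:",
    all(is.na(dk$plate$ct[dk$plate$role != "unknown"])) &&
      all(is.na(no$plate$ct[no$plate$role != "unknown"])), "\n")
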
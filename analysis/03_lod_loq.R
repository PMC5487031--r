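#!/usr/bin/env Rscript
# Establish limits of detection and quantification under both schemes.
#
# Replicate rule (purified-amplicon standards, 3 replicates per tenfold
# step): LOD = lowest step with >= 1 positive, LOQ = lowest step with all
# positives. Statistical rule: LOD* = ln(1/alpha) caps the false-negative
# probability; the repeatability rule sets the LOQ at the lowest standard
# with replicate Ct SD < 0.5. Both are converted to copies per litre.

library(ednaqpcr)
dir.create("results", showWarnings = FALSE)

# Danish-style tenfold series down to 0.5 copies/reaction
cfg_dk <- simulation_config(true_concentration = 1e5, template_volume = 5,
                            curve_slope = -3.427, curve_intercept = 39.34)
dk_series <- simulate_dilution_series(cfg_dk, fold = 10, n_steps = 7,
                                      reps_per_step = 3, seed = 31)
dk <- lod_loq_danish(dk_series)
print(dk)

# Norwegian-style statistical LOD and repeatability LOQ
lod_stat <- lod_statistical(0.05)
cat("statistical LOD (false negatives < 5%):", round(lod_stat, 3),
    "copies/reaction\n")
cat("false-negative rate at the 5-copy working LOD:",
    signif(false_negative_rate(5), 2), "\n")
cfg_no <- simulation_config(true_concentration = 39321.6 / 2,
                            template_volume = 2,
                            curve_slope = -3.39, curve_intercept = 40.26)
no_series <- simulate_dilution_series(cfg_no, fold = 4, n_steps = 12,
                                      reps_per_step = 10, seed = 32)
loq_no <- loq_norwegian(no_series, sd_limit = 0.5)
cat("repeatability LOQ (Ct SD < 0.5):", signif(loq_no, 4),
    "copies/reaction\n")

# per-litre limits in each workflow's volume context
ctx_dk <- quantification_context(V_e = 100, V_r = 5, V_w = 1,
                                 scheme = "danish")
ctx_no <- quantification_context(V_e = 200, V_r = 2, V_w = 5,
                                 scheme = "norwegian")
tab <- data.frame(
  scheme = c("danish", "danish", "norwegian", "norwegian"),
  quantity = c("LOD", "LOQ", "LOD", "LOQ"),
  copies_per_reaction = c(dk$lod, dk$loq, 5, 10),
  copies_per_l = c(copies_per_liter(dk$lod, ctx_dk),
                   copies_per_liter(dk$loq, ctx_dk),
                   copies_per_liter(5, ctx_no),
                   copies_per_liter(10, ctx_no)))
write.csv(tab, "results/lod_loq.csv", row.names = FALSE)
cat("\nper-litre limits:\n")
print(tab, row.names = FALSE)
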
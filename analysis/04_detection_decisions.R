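#!/usr/bin/env Rscript
# Apply the per-sample detection and quantification rules to the simulated
# surveys (01) using the fitted standard curves (02) and the established
# limits (03), and compare the estimates with the simulation truth.

library(ednaqpcr)
dir.create("results", showWarnings = FALSE)

curves <- read.csv("results/standard_curves.csv")
row_dk <- curves[curves$scheme == "danish", ]
row_no <- curves[curves$scheme == "norwegian", ]
cv_dk <- standard_curve(row_dk$slope, row_dk$intercept, row_dk$assay_id)
cv_no <- standard_curve(row_no$slope, row_no$intercept, row_no$assay_id)
limits <- read.csv("results/lod_loq.csv")
lim <- function(scheme, q)
  limits$copies_per_reaction[limits$scheme == scheme & limits$quantity == q]

# -- Danish survey ---------------------------------------------------------
plate_dk <- read_plate("results/plate_danish.csv")
ctx_dk <- quantification_context(V_e = 100, V_r = 5, V_w = 1,
                                 scheme = "danish")
field <- plate_dk[plate_dk$role == "unknown", ]
res_dk <- do.call(rbind, lapply(split(field, field$sample_id), function(r)
  detect_danish(r, cv_dk, lod = lim("danish", "LOD"),
                loq = lim("danish", "LOQ"), ctx = ctx_dk)))
write_results(res_dk, "results/detections_danish.csv")

truth_dk <- read.csv("results/truth_danish.csv")
cmp_dk <- merge(res_dk, truth_dk[, c("sample_id", "true_copies_per_l")])
cat("Danish survey verdicts:\n")
print(cmp_dk[, c("sample_id", "positive_replicates", "status",
                 "copies_per_L", "true_copies_per_l")], row.names = FALSE)

# -- Norwegian survey ------------------------------------------------------
plate_no <- read_plate("results/plate_norwegian.csv")
ctx_no <- quantification_context(V_e = 200, V_r = 2, V_w = 5,
                                 scheme = "norwegian")
field_no <- plate_no[plate_no$role == "unknown", ]
res_no <- do.call(rbind, lapply(split(field_no, field_no$sample_id),
                                function(r)
  quantify_norwegian(r, cv_no, loq = lim("norwegian", "LOQ"), ctx = ctx_no)))
write_results(res_no, "results/detections_norwegian.csv")

truth_no <- read.csv("results/truth_norwegian.csv")
cmp_no <- merge(res_no, truth_no[, c("sample_id", "true_copies_per_l")])
cat("\nNorwegian survey verdicts (note the inhibition flags):\n")
print(cmp_no[, c("sample_id", "positive_replicates", "status",
                 "inhibition_flag", "copies_per_L", "true_copies_per_l")],
      row.names = FALSE)

# control wells must stay negative after censoring
ctrl <- rbind(plate_dk, plate_no)
ctrl <- ctrl[ctrl$role %in% c("ntc", "extraction_blank"), ]
cat("\ncontrols clean:", all(is.na(censor_cutoff(ctrl, 41)$ct)), "\n")

# recovery of quantified sites
q <- rbind(cmp_dk[, c("copies_per_L", "true_copies_per_l", "status")],
           cmp_no[, c("copies_per_L", "true_copies_per_l", "status")])
q <- q[q$status == "quantified", ]
err <- (q$copies_per_L - q$true_copies_per_l) / q$true_copies_per_l
cat("quantified sites:", nrow(q), "; median |relative error|:",
    signif(stats::median(abs(err)), 2), "\n")
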
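curve_nor <- standard_curve(-3.32, 40, "Astast")
ctx_nor <- quantification_context(V_e = 200, V_r = 2, V_w = 5,
                                  scheme = "norwegian")
ctx_dan <- quantification_context(V_e = 100, V_r = 5, V_w = 1,
                                  scheme = "danish")

test_that("Ct cutoff censoring keeps sub-cutoff signals and audits the rest", {
  reps <- make_sample_reps(c(40.7, 41.0, 42.3, NA))
  out <- censor_cutoff(reps, 41)
  expect_equal(out$ct, c(40.7, NA, NA, NA))
  expect_equal(out$ct_raw, c(40.7, 41.0, 42.3, NA))
  nd <- make_sample_reps(c(NA, NA))
  expect_equal(censor_cutoff(nd, 41)$ct, c(NA_real_, NA_real_))
})

test_that("delta-Ct is the mean dilution shift and errors when unassessable", {
  expect_equal(delta_ct(c(33.0, 33.0), c(36.32, 36.32)), 3.32)
  expect_equal(delta_ct(c(30, 31), c(30, 31)), 0)
  expect_equal(delta_ct(c(33.0, NA), c(36.0, 36.6)), 3.3)
  expect_error(delta_ct(c(33, 33), c(NA_real_, NA_real_)), "not assessable")
})

test_that("inhibition classification partitions the delta-Ct line", {
  expect_equal(classify_inhibition(3.32, ctx_nor), "none")
  expect_equal(classify_inhibition(2.82, ctx_nor), "none")   # inclusive
  expect_equal(classify_inhibition(3.82, ctx_nor), "none")   # inclusive
  expect_equal(classify_inhibition(2.81, ctx_nor), "inhibited")
  expect_equal(classify_inhibition(3.83, ctx_nor), "dilution_out_of_range")
  # exactly one label for any finite value
  for (d in seq(-2, 8, by = 0.37)) {
    expect_true(classify_inhibition(d, ctx_nor) %in%
                  c("none", "inhibited", "dilution_out_of_range"))
  }
})

test_that("copies-per-litre formula and its scaling laws hold", {
  expect_equal(copies_per_liter(5, ctx_nor), 100)
  expect_equal(copies_per_liter(10, ctx_nor), 200)
  ident <- quantification_context(V_e = 10, V_r = 10, V_w = 1)
  expect_equal(copies_per_liter(7.3, ident), 7.3)
  expect_equal(copies_per_liter(0, ctx_nor), 0)
  expect_error(quantification_context(V_e = 200, V_r = 2, V_w = 0),
               "positive")
  # linear in C_r and V_e, inverse in V_r and V_w
  set.seed(11)
  for (i in 1:20) {
    vr <- runif(1, 1, 10); ve <- vr * runif(1, 1, 50); vw <- runif(1, 0.5, 15)
    cr <- runif(1, 0, 1e4); a <- runif(1, 1, 5)
    c1 <- copies_per_liter(cr, quantification_context(ve, vr, vw))
    expect_equal(copies_per_liter(a * cr, quantification_context(ve, vr, vw)),
                 a * c1)
    expect_equal(copies_per_liter(cr, quantification_context(a * ve, vr, vw)),
                 a * c1)
    expect_equal(copies_per_liter(cr, quantification_context(ve, vr, a * vw)),
                 c1 / a)
  }
})

test_that("Danish rule: replicate counts map to the reported verdicts", {
  lod <- 5; loq <- 5
  cv <- standard_curve(-3.32, 39, "Paclen")
  # 1/4 positive -> not detected, reported 0
  r1 <- detect_danish(make_sample_reps(c(36, NA, NA, NA)), cv, lod, loq,
                      ctx_dan)
  expect_equal(r1$status, "not_detected")
  expect_equal(r1$positive_replicates, "1/4")
  expect_equal(render_verdict(r1), "0")
  # 2/4 positive but below LOQ -> <LOQ
  ct_low <- ct_for_copies(2, cv)  # 2 copies: above detection, below LOQ of 5
  r2 <- detect_danish(make_sample_reps(c(ct_low, ct_low, NA, NA)), cv,
                      lod = 1, loq = 5, ctx = ctx_dan)
  expect_equal(r2$status, "detected_below_LOQ")
  expect_equal(render_verdict(r2), "<LOQ")
  # 4/4 above LOQ -> quantified, copies/L via the C_L formula
  ct_hi <- ct_for_copies(50, cv)
  r3 <- detect_danish(make_sample_reps(rep(ct_hi, 4)), cv, lod, loq, ctx_dan)
  expect_equal(r3$status, "quantified")
  expect_equal(r3$copies_per_L, copies_per_liter(50, ctx_dan))
  expect_equal(r3$sd_copies_per_L, 0)
  # non-detects enter the mean as zero when quantifying
  r4 <- detect_danish(make_sample_reps(c(ct_hi, ct_hi, ct_hi, NA)), cv,
                      lod, loq, ctx_dan)
  expect_equal(r4$status, "quantified")
  expect_equal(r4$copies_per_L, copies_per_liter(50, ctx_dan) * 3 / 4)
  expect_error(detect_danish(make_sample_reps(c(36, 36)), cv, lod, loq,
                             ctx_dan), "expected 4 replicates")
})

test_that("Norwegian rule branches on inhibition and the LOQ gate", {
  loq <- 10
  mk <- function(und_copies, dil_copies) {
    rbind(make_sample_reps(ct_for_copies(und_copies, curve_nor), dilution = 1L),
          make_sample_reps(ct_for_copies(dil_copies, curve_nor), dilution = 10L))
  }
  # clean sample at 50 copies/reaction: delta-Ct = 3.32 exactly, all four used
  r <- quantify_norwegian(mk(c(50, 50), c(5, 5)), curve_nor, loq, ctx_nor)
  expect_equal(r$status, "quantified")
  expect_equal(r$inhibition_flag, "none")
  expect_equal(r$copies_per_L, copies_per_liter(50, ctx_nor))
  # noiseless branch consistency: all three branches agree
  expect_equal(r$copies_per_L,
               copies_per_liter(mean(c(5, 5) * 10), ctx_nor))
  # inhibited sample (undiluted shifted +2 cycles): diluted-only estimate
  shifted <- mk(c(50, 50), c(5, 5))
  shifted$ct[1:2] <- shifted$ct[1:2] + 2
  ri <- quantify_norwegian(shifted, curve_nor, loq = 2, ctx = ctx_nor)
  expect_equal(ri$inhibition_flag, "inhibited")
  expect_equal(ri$copies_per_L, copies_per_liter(50, ctx_nor))
  # dilution out of range: undiluted-only estimate
  over <- mk(c(50, 50), c(2, 2))  # delta-Ct = 3.32 + log10(2.5)*3.32 > 3.82
  ro <- quantify_norwegian(over, curve_nor, loq = 1, ctx = ctx_nor)
  expect_equal(ro$inhibition_flag, "dilution_out_of_range")
  expect_equal(ro$copies_per_L, copies_per_liter(50, ctx_nor))
  # 1/4 positives -> not detected, reported 0 (and likewise 0/4)
  r1 <- quantify_norwegian(rbind(make_sample_reps(c(38, NA), dilution = 1L),
                                 make_sample_reps(c(NA, NA), dilution = 10L)),
                           curve_nor, loq, ctx_nor)
  expect_equal(r1$status, "not_detected")
  expect_equal(render_verdict(r1), "0")
  r0 <- quantify_norwegian(rbind(make_sample_reps(c(NA, NA), dilution = 1L),
                                 make_sample_reps(c(NA, NA), dilution = 10L)),
                           curve_nor, loq, ctx_nor)
  expect_equal(r0$status, "not_detected")
  expect_equal(render_verdict(r0), "0")
  # 4/4 positives all below LOQ -> <LOQ
  rb <- quantify_norwegian(mk(c(4, 4), c(0.4, 0.4)), curve_nor, loq, ctx_nor)
  expect_equal(rb$status, "detected_below_LOQ")
  expect_error(quantify_norwegian(make_sample_reps(c(36, 36, 36, 36)),
                                  curve_nor, loq, ctx_nor),
               "2 undiluted")
})

test_that("site summaries combine filters per the zero rule", {
  one <- data.frame(sample_id = "F1", assay_id = "A", status = "quantified",
                    positive_replicates = "4/4", copies_per_L = 203,
                    sd_copies_per_L = 73, inhibition_flag = "none")
  s1 <- summarize_site(one)
  expect_equal(s1$mean_copies_per_L, 203)
  expect_equal(s1$sd_copies_per_L, 73)
  expect_equal(s1$level_grade, 1L)  # first band above the 100 copies/L base

  nd <- one; nd$status <- "not_detected"; nd$copies_per_L <- NA
  allnd <- rbind(nd, nd, nd)
  s2 <- summarize_site(allnd)
  expect_equal(s2$mean_copies_per_L, 0)
  expect_equal(s2$status, "not_detected")
  expect_equal(s2$level_grade, 0L)

  blq <- one; blq$status <- "detected_below_LOQ"; blq$copies_per_L <- NA
  s3 <- summarize_site(rbind(one, blq))
  expect_equal(s3$mean_copies_per_L, 203)  # <LOQ never imputed
  expect_equal(s3$n_below_loq, 1L)
  expect_equal(s3$status, "quantified")
})
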
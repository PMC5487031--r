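#' Quantification context: volumes and decision thresholds
#'
#' Bundles the sample-processing volumes and the decision thresholds used by
#' the per-sample detection and quantification rules.
#'
#' @param V_e Elution volume of the DNA extract, in microlitres.
#' @param V_r Template volume per qPCR reaction, in microlitres
#'   (\eqn{\le V_e}).
#' @param V_w Filtered water volume, in litres.
#' @param ct_cutoff Ct at or above which positive signals are regarded
#'   unreliable and counted as not detected (default 41).
#' @param delta_ct_center Expected Ct difference between undiluted and
#'   10-fold-diluted template in the absence of inhibition:
#'   \eqn{\log_2 10 \approx 3.32} cycles.
#' @param delta_ct_halfwidth Accepted deviation around the centre (default
#'   0.5 cycles, i.e. the window 2.82-3.82).
#' @param min_positive_replicates Minimum positive replicates for a reliable
#'   detection (default 2 of 4).
#' @param scheme \code{"danish"} (4 undiluted replicates, purified-amplicon
#'   standards) or \code{"norwegian"} (2 undiluted + 2 diluted replicates,
#'   MPN-anchored genomic standards).
#' @return An object of class \code{quant_context}.
#' @export
quantification_context <- function(V_e, V_r, V_w, ct_cutoff = 41,
                                   delta_ct_center = 3.32,
                                   delta_ct_halfwidth = 0.5,
                                   min_positive_replicates = 2L,
                                   scheme = c("danish", "norwegian")) {
  scheme <- match.arg(scheme)
  if (V_e <= 0 || V_r <= 0 || V_w <= 0) stop("all volumes must be positive")
  if (V_r > V_e) stop("template volume V_r cannot exceed elution volume V_e")
  if (delta_ct_halfwidth <= 0) stop("delta_ct_halfwidth must be positive")
  structure(list(V_e = V_e, V_r = V_r, V_w = V_w, ct_cutoff = ct_cutoff,
                 delta_ct_center = delta_ct_center,
                 delta_ct_halfwidth = delta_ct_halfwidth,
                 min_positive_replicates = as.integer(min_positive_replicates),
                 scheme = scheme),
            class = "quant_context")
}

#' Censor unreliable late-Ct signals
#'
#' Replicates with Ct at or above the cutoff become non-detects. The original
#' value is retained in a \code{ct_raw} audit column.
#'
#' @param reps Plate data frame (or any data frame with a \code{ct} column).
#' @param cutoff Ct cutoff in cycles (default 41).
#' @return The data frame with censored \code{ct} and added \code{ct_raw}.
#' @export
censor_cutoff <- function(reps, cutoff = 41) {
  if (cutoff <= 0) stop("cutoff must be positive")
  reps$ct_raw <- reps$ct
  reps$ct[!is.na(reps$ct) & reps$ct >= cutoff] <- NA_real_
  reps
}

#' Ct difference between diluted and undiluted template
#'
#' \eqn{\Delta Ct = \overline{Ct}_{diluted} - \overline{Ct}_{undiluted}},
#' means taken over detected replicates only. For a 10-fold dilution and
#' perfect doubling the theoretical value is \eqn{\log_2 10 = 3.32} cycles;
#' smaller values indicate PCR inhibition in the undiluted extract.
#'
#' @param undiluted_cts,diluted_cts Numeric Ct vectors (\code{NA} =
#'   non-detect); each must contain at least one detected value.
#' @return \eqn{\Delta Ct} in cycles.
#' @export
delta_ct <- function(undiluted_cts, diluted_cts) {
  if (all(is.na(undiluted_cts)) || all(is.na(diluted_cts)))
    stop("delta-Ct not assessable: one dilution level has no detected replicate")
  mean(diluted_cts, na.rm = TRUE) - mean(undiluted_cts, na.rm = TRUE)
}

#' Classify PCR inhibition from a delta-Ct value
#'
#' Partitions the real line into three states around the accepted window
#' \eqn{[center - halfwidth,\; center + halfwidth]} (inclusive boundaries;
#' default 2.82-3.82): below the window the undiluted extract is inhibited,
#' above it the 10-fold dilution is out of range.
#'
#' @param dct Finite delta-Ct in cycles.
#' @param ctx A \code{quant_context}.
#' @return One of \code{"none"}, \code{"inhibited"},
#'   \code{"dilution_out_of_range"}.
#' @export
classify_inhibition <- function(dct, ctx) {
  stopifnot(inherits(ctx, "quant_context"), is.finite(dct))
  lo <- ctx$delta_ct_center - ctx$delta_ct_halfwidth
  hi <- ctx$delta_ct_center + ctx$delta_ct_halfwidth
  if (dct < lo) "inhibited"
  else if (dct > hi) "dilution_out_of_range"
  else "none"
}

#' Copies per litre of filtered water
#'
#' \deqn{C_L = C_r \cdot (V_e / V_r) / V_w}
#' where \eqn{C_r} is copies per reaction, \eqn{V_e} the elution volume,
#' \eqn{V_r} the template volume per reaction and \eqn{V_w} the filtered
#' water volume. Linear in \eqn{C_r} and \eqn{V_e}, inverse in \eqn{V_r}
#' and \eqn{V_w}.
#'
#' @param C_r Copies per reaction (\eqn{\ge 0}; vectorized).
#' @param ctx A \code{quant_context} carrying the volumes.
#' @return Copies per litre.
#' @examples
#' ctx <- quantification_context(V_e = 200, V_r = 2, V_w = 5,
#'                               scheme = "norwegian")
#' copies_per_liter(5, ctx)   # 100
#' copies_per_liter(10, ctx)  # 200
#' @export
copies_per_liter <- function(C_r, ctx) {
  stopifnot(inherits(ctx, "quant_context"))
  if (any(C_r < 0)) stop("copies per reaction must be non-negative")
  C_r * (ctx$V_e / ctx$V_r) / ctx$V_w
}

.detection_result <- function(sample_id, assay_id, status, k, n,
                              copies_per_L = NA_real_,
                              sd_copies_per_L = NA_real_,
                              inhibition_flag = "not_assessed") {
  data.frame(sample_id = sample_id, assay_id = assay_id, status = status,
             positive_replicates = paste0(k, "/", n),
             copies_per_L = copies_per_L, sd_copies_per_L = sd_copies_per_L,
             inhibition_flag = inhibition_flag, stringsAsFactors = FALSE)
}

#' Danish-style detection and quantification for one sample
#'
#' Decision rule for the four-undiluted-replicate design: detection is
#' reliable only if at least \code{min_positive_replicates} (default 2 of 4)
#' replicates amplify at or above the LOD; otherwise the sample is reported
#' as 0. A reliable detection is quantified if at least that many positive
#' replicates are at or above the LOQ — non-detect replicates then enter the
#' mean as zero copies — and is otherwise reported as below LOQ.
#'
#' @param reps Plate rows for one sample/assay: all \code{dilution_factor}
#'   1, default 4 replicates.
#' @param curve A \code{standard_curve} for the assay.
#' @param lod,loq Limits of detection and quantification in copies/reaction.
#' @param ctx A \code{quant_context} with \code{scheme = "danish"}.
#' @param n_replicates Expected replicate count (default 4).
#' @return One-row detection-result data frame with \code{status}
#'   (\code{not_detected}, \code{detected_below_LOQ} or \code{quantified}),
#'   \code{positive_replicates} ("k/n"), and copies/L with SD across the
#'   per-replicate estimates when quantified.
#' @export
detect_danish <- function(reps, curve, lod, loq, ctx, n_replicates = 4L) {
  stopifnot(inherits(ctx, "quant_context"), inherits(curve, "standard_curve"))
  if (nrow(reps) != n_replicates)
    stop("expected ", n_replicates, " replicates for sample ",
         reps$sample_id[1], ", got ", nrow(reps))
  reps <- censor_cutoff(reps, ctx$ct_cutoff)
  copies <- rep(0, nrow(reps))
  det <- !is.na(reps$ct)
  copies[det] <- copies_from_ct(reps$ct[det], curve)
  k_lod <- sum(det & copies >= lod)
  k <- sum(det)
  sid <- reps$sample_id[1]; aid <- reps$assay_id[1]
  if (k_lod < ctx$min_positive_replicates)
    return(.detection_result(sid, aid, "not_detected", k, nrow(reps)))
  if (sum(det & copies >= loq) >= ctx$min_positive_replicates) {
    per_rep_cl <- copies_per_liter(copies, ctx)  # non-detects contribute 0
    return(.detection_result(sid, aid, "quantified", k, nrow(reps),
                             copies_per_L = mean(per_rep_cl),
                             sd_copies_per_L = stats::sd(per_rep_cl)))
  }
  .detection_result(sid, aid, "detected_below_LOQ", k, nrow(reps))
}

#' Norwegian-style detection and quantification for one sample
#'
#' Decision rule for the 2 undiluted + 2 ten-fold-diluted replicate design.
#' After censoring at the Ct cutoff, the delta-Ct inhibition state selects
#' which replicates carry quantitative information:
#' \itemize{
#'   \item no inhibition — all four replicates (diluted estimates multiplied
#'     by 10 to the extract scale);
#'   \item inhibited (\eqn{\Delta Ct} below the window) — the two diluted
#'     replicates only;
#'   \item dilution out of range (\eqn{\Delta Ct} above the window) — the two
#'     undiluted replicates only.
#' }
#' Detection requires at least \code{min_positive_replicates} positive
#' replicates (default 2 of 4); below that the sample is reported as 0. A
#' detected sample is quantified only if at least that many relevant
#' replicates measured at or above the LOQ in their own reaction, and is
#' otherwise reported as below LOQ. When the delta-Ct is not assessable
#' (one dilution level entirely negative) quantification is not attempted.
#'
#' @param reps Plate rows for one sample/assay: exactly 2 rows with
#'   \code{dilution_factor} 1 and 2 with \code{dilution_factor} 10.
#' @inheritParams detect_danish
#' @param loq Limit of quantification in copies/reaction.
#' @return One-row detection-result data frame; \code{copies_per_L} is the
#'   mean over relevant replicates of the extract-scale copy estimate pushed
#'   through the copies-per-litre formula, with the SD over the same
#'   replicates.
#' @export
quantify_norwegian <- function(reps, curve, loq, ctx) {
  stopifnot(inherits(ctx, "quant_context"), inherits(curve, "standard_curve"))
  und <- reps[reps$dilution_factor == 1L, , drop = FALSE]
  dil <- reps[reps$dilution_factor == 10L, , drop = FALSE]
  if (nrow(und) != 2L || nrow(dil) != 2L)
    stop("expected 2 undiluted + 2 ten-fold diluted replicates for sample ",
         reps$sample_id[1])
  und <- censor_cutoff(und, ctx$ct_cutoff)
  dil <- censor_cutoff(dil, ctx$ct_cutoff)
  sid <- reps$sample_id[1]; aid <- reps$assay_id[1]
  k <- sum(!is.na(und$ct)) + sum(!is.na(dil$ct))
  n <- nrow(und) + nrow(dil)
  if (k < ctx$min_positive_replicates)
    return(.detection_result(sid, aid, "not_detected", k, n))

  if (all(is.na(und$ct)) || all(is.na(dil$ct))) {
    # delta-Ct not assessable at trace level; no quantification attempted
    return(.detection_result(sid, aid, "detected_below_LOQ", k, n,
                             inhibition_flag = "not_assessed"))
  }
  state <- classify_inhibition(delta_ct(und$ct, dil$ct), ctx)
  # in-reaction copy estimates (LOQ comparisons) and extract-scale estimates
  und_rxn <- ifelse(is.na(und$ct), NA_real_,
                    copies_from_ct(ifelse(is.na(und$ct), 1, und$ct), curve))
  dil_rxn <- ifelse(is.na(dil$ct), NA_real_,
                    copies_from_ct(ifelse(is.na(dil$ct), 1, dil$ct), curve))
  relevant_rxn <- switch(state,
    none = c(und_rxn, dil_rxn),
    inhibited = dil_rxn,
    dilution_out_of_range = und_rxn)
  relevant_extract <- switch(state,
    none = c(und_rxn, dil_rxn * 10),
    inhibited = dil_rxn * 10,
    dilution_out_of_range = und_rxn)
  flag <- if (state == "none") "none" else state
  n_quant <- sum(!is.na(relevant_rxn) & relevant_rxn >= loq)
  if (n_quant < ctx$min_positive_replicates)
    return(.detection_result(sid, aid, "detected_below_LOQ", k, n,
                             inhibition_flag = flag))
  vals <- relevant_extract[!is.na(relevant_extract)]
  cl <- copies_per_liter(vals, ctx)
  .detection_result(sid, aid, "quantified", k, n,
                    copies_per_L = mean(cl),
                    sd_copies_per_L = if (length(cl) >= 2L) stats::sd(cl)
                                      else NA_real_,
                    inhibition_flag = flag)
}

#' Summarize detection results across the filters of one site
#'
#' Mean and SD of copies/L across a site's filter samples, with not-detected
#' filters entering as zero and below-LOQ filters flagged but never imputed.
#' When a single filter was quantified its within-filter replicate SD is
#' carried through. A log10-binned level grade (0 = no detection, then one
#' grade per tenfold step above \code{grade_base}, capped at 5) supports
#' coarse mapping of eDNA levels.
#'
#' @param results Detection-result data frame (one row per filter) for one
#'   site/assay.
#' @param grade_base Copies/L at the bottom of grade 1 (default 100, a
#'   typical per-litre LOD at 5 L filtered).
#' @return One-row data frame with \code{n_filters}, \code{n_quantified},
#'   \code{n_below_loq}, \code{mean_copies_per_L}, \code{sd_copies_per_L},
#'   \code{level_grade} and \code{status}.
#' @export
summarize_site <- function(results, grade_base = 100) {
  stopifnot(nrow(results) >= 1L)
  q <- results$status == "quantified"
  b <- results$status == "detected_below_LOQ"
  vals <- c(results$copies_per_L[q], rep(0, sum(results$status == "not_detected")))
  m <- if (length(vals) > 0L) mean(vals) else 0
  s <- if (sum(q) == 1L && length(vals) <= 1L) results$sd_copies_per_L[q]
       else if (length(vals) >= 2L) stats::sd(vals) else NA_real_
  status <- if (any(q)) "quantified" else if (any(b)) "detected_below_LOQ"
            else "not_detected"
  grade <- if (status == "not_detected" || m <= 0) 0L
           else max(1L, min(5L, 1L + floor(log10(m / grade_base))))
  data.frame(n_filters = nrow(results), n_quantified = sum(q),
             n_below_loq = sum(b), mean_copies_per_L = m,
             sd_copies_per_L = s, level_grade = as.integer(grade),
             status = status, stringsAsFactors = FALSE)
}
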
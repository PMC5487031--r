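#' Probability a reaction receives at least one template copy
#'
#' Under Poisson partitioning of template molecules into reactions with mean
#' \eqn{\lambda} copies per reaction, the detection probability is
#' \eqn{p = 1 - e^{-\lambda}}. At \eqn{\lambda \approx 1.2} this gives the
#' classic 7:3 positive:negative ratio (70\% detection) used to anchor
#' single-molecule quantification.
#'
#' @param lambda_copies Mean copies per reaction (\eqn{\ge 0}; vectorized).
#' @return Detection probability in \[0, 1\].
#' @export
detection_probability <- function(lambda_copies) {
  if (any(lambda_copies < 0)) stop("lambda must be non-negative")
  1 - exp(-lambda_copies)
}

#' Most-probable-number estimate of copies per reaction
#'
#' Single-dilution MPN under the Poisson occupancy model: with
#' \eqn{k} positive reactions out of \eqn{n},
#' \deqn{\hat\lambda = -\ln\left(\frac{n - k}{n}\right).}
#' An optional Clopper-Pearson confidence interval on the positive fraction
#' is transformed through \eqn{-\ln(1 - p)}.
#'
#' @param n_positive Number of positive reactions.
#' @param n_total Total number of reactions (\eqn{\ge 1}).
#' @param conf_level Confidence level for the interval, or \code{NULL} to
#'   skip it.
#' @return List with \code{lambda} (copies/reaction), \code{n_positive},
#'   \code{n_total}, and \code{ci} (length-2 vector or \code{NULL}).
#' @examples
#' mpn_estimate(7, 10)$lambda   # -log(0.3) = 1.204
#' @export
mpn_estimate <- function(n_positive, n_total, conf_level = NULL) {
  if (n_total < 1L || n_positive < 0L || n_positive > n_total)
    stop("need 0 <= n_positive <= n_total with n_total >= 1")
  if (n_positive == n_total)
    stop("saturated: MPN undefined with zero negative reactions; ",
         "run more replicates at this dilution")
  lambda <- -log((n_total - n_positive) / n_total)
  ci <- NULL
  if (!is.null(conf_level)) {
    bt <- stats::binom.test(n_positive, n_total, conf.level = conf_level)
    ci <- -log(1 - bt$conf.int)
    # upper limit of p = 1 would map to Inf; cap stays honest
    attributes(ci) <- NULL
  }
  list(lambda = lambda, n_positive = n_positive, n_total = n_total, ci = ci)
}

#' Propagate an MPN-anchored copy number across a dilution series
#'
#' One standard near the 70\% detection rate is quantified by MPN; copy
#' numbers of the other (more concentrated) standards follow from the
#' dilution fold: copies at step \eqn{i} equal
#' \eqn{\hat\lambda \cdot fold^{\,anchor - i}} (lower step index = more
#' concentrated).
#'
#' @param lambda Anchor copy number (copies/reaction).
#' @param anchor_index Step index of the anchored standard.
#' @param indices Step indices at which to compute copy numbers.
#' @param fold Dilution factor between consecutive steps (> 1).
#' @return Named numeric vector of copies/reaction, one per index.
#' @examples
#' propagate_standard_copies(2.4, 7, 0:7, 4)  # top standard 39321.6
#' @export
propagate_standard_copies <- function(lambda, anchor_index, indices, fold) {
  if (fold <= 1) stop("fold must be > 1")
  if (lambda < 0) stop("lambda must be non-negative")
  out <- lambda * fold^(anchor_index - indices)
  names(out) <- as.character(indices)
  out
}

#' Statistically defined limit of detection
#'
#' The smallest mean copy number \eqn{\lambda} at which the false-negative
#' probability \eqn{e^{-\lambda}} does not exceed \code{alpha}:
#' \eqn{\lambda^* = \ln(1/\alpha)}. With the conventional
#' \eqn{\alpha = 0.05} this is \eqn{\ln 20 \approx 3.0} copies/reaction.
#'
#' @param alpha Accepted false-negative probability, in (0, 1).
#' @return Copies per reaction.
#' @seealso [false_negative_rate()] to check a candidate LOD.
#' @export
lod_statistical <- function(alpha = 0.05) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  log(1 / alpha)
}

#' False-negative rate at a candidate limit of detection
#'
#' @param lambda_copies Candidate LOD in copies/reaction (\eqn{\ge 0}).
#' @return Probability that a reaction receives zero copies,
#'   \eqn{e^{-\lambda}}.
#' @examples
#' false_negative_rate(5)  # 0.0067 — well under the 5% criterion
#' @export
false_negative_rate <- function(lambda_copies) {
  if (any(lambda_copies < 0)) stop("lambda must be non-negative")
  exp(-lambda_copies)
}

# positives per concentration after the Ct cutoff; shared by the LOD/LOQ rules
.per_concentration <- function(points, ct_cutoff) {
  stopifnot(is.data.frame(points),
            all(c("copies_per_reaction", "ct") %in% names(points)))
  ct <- points$ct
  ct[!is.na(ct) & ct >= ct_cutoff] <- NA_real_
  concs <- sort(unique(points$copies_per_reaction))
  do.call(rbind, lapply(concs, function(cc) {
    v <- ct[points$copies_per_reaction == cc]
    data.frame(copies_per_reaction = cc, n = length(v),
               n_detected = sum(!is.na(v)),
               ct_sd = if (sum(!is.na(v)) >= 2L) stats::sd(v[!is.na(v)])
                       else NA_real_)
  }))
}

#' Replicate-based LOD and LOQ from a dilution-standard series
#'
#' The replicate rule used with purified-amplicon standards: LOD is the
#' lowest concentration at which at least one of the replicates amplified;
#' LOQ is the lowest concentration at which every replicate amplified. A
#' replicate counts as positive only if its Ct is detected and below the
#' reliability cutoff.
#'
#' @param points Long-format standard table (columns
#'   \code{copies_per_reaction}, \code{ct}; one row per replicate well).
#' @param min_replicates Minimum replicates required per concentration
#'   (default 3, the design the rule was stated for).
#' @param ct_cutoff Ct at or above which a signal is regarded unreliable.
#' @return An object of class \code{lod_loq}: list with \code{scheme},
#'   \code{lod}, \code{loq} (copies/reaction) and per-concentration
#'   \code{evidence}.
#' @export
lod_loq_danish <- function(points, min_replicates = 3L, ct_cutoff = 41) {
  tab <- .per_concentration(points, ct_cutoff)
  if (any(tab$n < min_replicates))
    stop("every concentration needs at least ", min_replicates, " replicates")
  any_pos <- tab$copies_per_reaction[tab$n_detected >= 1L]
  if (length(any_pos) == 0L)
    stop("LOD undefined: no concentration produced a detection")
  lod <- min(any_pos)
  all_pos <- tab$copies_per_reaction[tab$n_detected == tab$n]
  loq <- if (length(all_pos) > 0L) min(all_pos) else NA_real_
  structure(list(scheme = "danish_replicate", lod = lod, loq = loq,
                 evidence = tab),
            class = "lod_loq")
}

#' Repeatability-based LOQ (Ct standard deviation rule)
#'
#' LOQ is the lowest concentration at which every replicate amplified and the
#' replicate Ct standard deviation is below \code{sd_limit} cycles — the
#' acceptance level used for diagnostic qPCR quantification.
#'
#' @inheritParams lod_loq_danish
#' @param sd_limit Maximum acceptable replicate Ct SD in cycles.
#' @return Copies per reaction.
#' @export
loq_norwegian <- function(points, sd_limit = 0.5, ct_cutoff = 41) {
  tab <- .per_concentration(points, ct_cutoff)
  ok <- tab$n_detected == tab$n & !is.na(tab$ct_sd) & tab$ct_sd < sd_limit
  if (!any(ok))
    stop("LOQ undefined: no concentration meets the SD < ", sd_limit,
         " repeatability criterion")
  min(tab$copies_per_reaction[ok])
}

#' @export
print.lod_loq <- function(x, ...) {
  cat("LOD/LOQ (", x$scheme, ")\n", sep = "")
  cat("  LOD:", format(x$lod, digits = 4), "copies/reaction\n")
  cat("  LOQ:", format(x$loq, digits = 4), "copies/reaction\n")
  invisible(x)
}
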
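#' Molecular weight of a DNA oligonucleotide
#'
#' Single-strand weight follows the convention used by web
#' oligo-property calculators for synthesized (5'-OH) DNA:
#' \deqn{MW = n_A \cdot 313.21 + n_T \cdot 304.2 + n_C \cdot 289.18 +
#'   n_G \cdot 329.21 - 61.96}
#' i.e. per-nucleotide monophosphate masses minus the terminal phosphate.
#' The double-strand weight is the sum of the weights of the sequence and of
#' its reverse complement. Used to convert a fluorometric dsDNA mass
#' concentration of a purified amplicon into a copy concentration for
#' quantification standards.
#'
#' @param sequence DNA string over \{A, C, G, T\}. Ambiguity codes are
#'   rejected: quantification standards are exact sequences.
#' @param strands \code{"one"} or \code{"two"}.
#' @return Molecular weight in g/mol.
#' @examples
#' oligo_molecular_weight("AT")          # 555.45
#' oligo_molecular_weight("AT", "two")   # 1110.90 (AT is self-complementary)
#' @export
oligo_molecular_weight <- function(sequence, strands = c("one", "two")) {
  strands <- match.arg(strands)
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a non-empty DNA string")
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("sequence contains characters outside {A,C,G,T}: ",
         paste(unique(setdiff(chars, c("A", "C", "G", "T"))), collapse = ", "))
  w <- c(A = 313.21, T = 304.2, C = 289.18, G = 329.21)
  ss <- function(ch) sum(w[ch]) - 61.96
  if (strands == "one") return(ss(chars))
  rc <- rev(c(A = "T", T = "A", C = "G", G = "C")[chars])
  ss(chars) + ss(rc)
}

#' Copy concentration from a dsDNA mass concentration
#'
#' \eqn{copies/\mu L = c \cdot 10^{-9} \cdot N_A / MW} where \eqn{c} is the
#' mass concentration in ng/\eqn{\mu}L, \eqn{N_A} is Avogadro's number and
#' \eqn{MW} the molecular weight of the (double-stranded) molecule in g/mol.
#'
#' @param conc_ng_per_ul Mass concentration in ng/\eqn{\mu}L (\eqn{\ge 0}).
#' @param mw_g_per_mol Molecular weight in g/mol (> 0).
#' @return Copies per microlitre.
#' @export
copies_per_ul_from_mass <- function(conc_ng_per_ul, mw_g_per_mol) {
  if (any(mw_g_per_mol <= 0)) stop("molecular weight must be positive")
  if (any(conc_ng_per_ul < 0)) stop("concentration must be non-negative")
  conc_ng_per_ul * 1e-9 * 6.02214076e23 / mw_g_per_mol
}

#' Nominal concentrations of a serial dilution series
#'
#' @param stock_copies_per_ul Stock concentration in copies/\eqn{\mu}L.
#' @param fold Dilution factor between consecutive steps (> 1); 10 for a
#'   tenfold series, 4 for a four-fold series.
#' @param n_steps Number of dilution steps (step 0 is the stock).
#' @param template_volume Template volume per reaction in \eqn{\mu}L, used to
#'   express each step as copies per reaction.
#' @return Data frame with columns \code{step}, \code{copies_per_ul},
#'   \code{copies_per_reaction}; concentrations strictly decreasing.
#' @export
dilution_series <- function(stock_copies_per_ul, fold, n_steps,
                            template_volume) {
  if (fold <= 1) stop("fold must be > 1")
  if (stock_copies_per_ul <= 0) stop("stock concentration must be positive")
  step <- seq_len(n_steps) - 1L
  conc <- stock_copies_per_ul / fold^step
  data.frame(step = step, copies_per_ul = conc,
             copies_per_reaction = conc * template_volume)
}

#' Construct a standard-curve object from known coefficients
#'
#' For curves taken from instrument software or publications, where only the
#' fitted slope and intercept are available.
#'
#' @param slope Cycles per log10(copies/reaction); must be negative.
#' @param intercept Ct at 1 copy/reaction.
#' @param assay_id Assay label.
#' @param r_squared,n_points,dynamic_range Optional fit metadata.
#' @return An object of class \code{standard_curve}.
#' @export
standard_curve <- function(slope, intercept, assay_id = NA_character_,
                           r_squared = NA_real_, n_points = NA_integer_,
                           dynamic_range = c(NA_real_, NA_real_)) {
  if (!is.finite(slope) || slope >= 0) stop("slope must be finite and negative")
  structure(list(assay_id = assay_id, slope = slope, intercept = intercept,
                 efficiency_pct = efficiency_from_slope(slope),
                 r_squared = r_squared, n_points = n_points,
                 dynamic_range = dynamic_range),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve", if (!is.na(x$assay_id)) paste0("[", x$assay_id, "]"),
      "\n  Ct =", format(x$intercept, digits = 4), "+",
      format(x$slope, digits = 4), "* log10(copies/reaction)\n")
  cat("  efficiency:", formatC(x$efficiency_pct, format = "f", digits = 1),
      "%   R-squared:",
      if (is.na(x$r_squared)) "NA" else format(x$r_squared, digits = 3), "\n")
  if (!all(is.na(x$dynamic_range)))
    cat("  dynamic range:", format(x$dynamic_range[1], digits = 4), "-",
        format(x$dynamic_range[2], digits = 4), "copies/reaction\n")
  invisible(x)
}

#' Fit a log-linear Ct standard curve
#'
#' Ordinary least squares of Ct on log10(copies/reaction) over the detected
#' replicates of a dilution-standard series:
#' \deqn{Ct = intercept + slope \cdot \log_{10}(copies)}
#' Non-detect replicates are excluded from the fit (not imputed); a
#' concentration at which every replicate failed is dropped with a warning.
#'
#' @param points Long-format standard table: data frame with columns
#'   \code{copies_per_reaction} (> 0) and \code{ct} (\code{NA} = non-detect),
#'   one row per replicate well; an optional \code{assay_id} column labels
#'   the result.
#' @return A \code{standard_curve} object with slope, intercept, percentage
#'   amplification efficiency, \eqn{R^2}, number of fitted wells and the
#'   dynamic range spanned by the fitted concentrations.
#' @examples
#' pts <- data.frame(copies_per_reaction = rep(10^(1:5), each = 3))
#' pts$ct <- 39 - 3.3219 * log10(pts$copies_per_reaction)
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("copies_per_reaction", "ct") %in% names(points)))
  if (any(points$copies_per_reaction <= 0))
    stop("copies_per_reaction must be positive")
  dead <- tapply(points$ct, points$copies_per_reaction,
                 function(v) all(is.na(v)))
  if (any(dead)) {
    warning("excluding concentration(s) with no detected replicate: ",
            paste(names(dead)[dead], collapse = ", "))
  }
  use <- points[!is.na(points$ct), , drop = FALSE]
  concs <- unique(use$copies_per_reaction)
  if (length(concs) < 2L)
    stop("need at least 2 concentrations with detected replicates to fit a curve")
  fit <- stats::lm(ct ~ log10(copies_per_reaction), data = use)
  co <- stats::coef(fit)
  slope <- unname(co[2])
  if (slope >= 0)
    stop("fitted slope is non-negative; standards do not show a dilution response")
  # R^2 computed directly; summary.lm() warns on noiseless standards
  sst <- sum((use$ct - mean(use$ct))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  standard_curve(slope = slope, intercept = unname(co[1]),
                 assay_id = if ("assay_id" %in% names(use))
                   as.character(use$assay_id[1]) else NA_character_,
                 r_squared = r2,
                 n_points = nrow(use),
                 dynamic_range = range(concs))
}

#' Amplification efficiency from a standard-curve slope
#'
#' \eqn{E = (10^{-1/slope} - 1) \cdot 100}. A slope of \eqn{-3.3219}
#' (\eqn{-1/\log_{10}2}) corresponds to perfect per-cycle doubling (100\%).
#'
#' @param slope Cycles per log10(copies); must be negative.
#' @return Efficiency in percent.
#' @examples
#' efficiency_from_slope(-3.3219)  # 100.0
#' efficiency_from_slope(-3.427)   # 95.8
#' @export
efficiency_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0))
    stop("slope must be finite and negative")
  (10^(-1 / slope) - 1) * 100
}

#' Invert a standard curve: copies per reaction from Ct
#'
#' \eqn{copies = 10^{(Ct - intercept)/slope}}; strictly decreasing in Ct.
#' Non-detects carry no copy estimate, so callers must branch on detection
#' before inverting.
#'
#' @param ct Finite Ct value(s).
#' @param curve A \code{standard_curve}.
#' @return Copies per reaction (vectorized over \code{ct}).
#' @export
copies_from_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(!is.finite(ct)))
    stop("ct must be finite; non-detects have no copy estimate")
  10^((ct - curve$intercept) / curve$slope)
}
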
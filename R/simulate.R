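#' Configuration of the synthetic qPCR reaction generator
#'
#' The generator reproduces the statistical structure the analysis assumes:
#' template molecules partition into reactions as Poisson counts, detected
#' wells respond log-linearly in the realized copy number with Gaussian Ct
#' noise, zero-copy wells are non-detects, runs stop at a finite cycle
#' budget, and PCR inhibition adds a constant Ct shift to undiluted wells
#' only (fully removed by 10-fold dilution).
#'
#' @param true_concentration True template concentration of the extract in
#'   copies/\eqn{\mu}L.
#' @param curve_slope Cycles per log10(copies); default \eqn{-3.32}
#'   (near-perfect doubling).
#' @param curve_intercept Ct at 1 copy/reaction; default 40.
#' @param ct_noise_sd Gaussian Ct noise SD in cycles; default 0.3, chosen so
#'   that replicate repeatability approaches the SD < 0.5 boundary near the
#'   limit of quantification.
#' @param inhibition_shift Additive Ct shift applied to undiluted wells
#'   (cycles); default 0.
#' @param template_volume Template volume per reaction in \eqn{\mu}L.
#' @param n_replicates Default replicates per sample.
#' @param max_cycles Cycle budget of the run; Cts beyond it are non-detects.
#' @return An object of class \code{sim_config}.
#' @export
simulation_config <- function(true_concentration = 1,
                              curve_slope = -3.32, curve_intercept = 40,
                              ct_noise_sd = 0.3, inhibition_shift = 0,
                              template_volume = 5, n_replicates = 4L,
                              max_cycles = 50) {
  stopifnot(true_concentration >= 0, ct_noise_sd >= 0, max_cycles > 0,
            template_volume > 0, curve_slope < 0)
  structure(list(true_concentration = true_concentration,
                 curve_slope = curve_slope,
                 curve_intercept = curve_intercept,
                 ct_noise_sd = ct_noise_sd,
                 inhibition_shift = inhibition_shift,
                 template_volume = template_volume,
                 n_replicates = as.integer(n_replicates),
                 max_cycles = max_cycles),
            class = "sim_config")
}

#' Simulate Ct values for replicate qPCR reactions
#'
#' Each reaction draws \eqn{k \sim Poisson(\lambda)} with
#' \eqn{\lambda = concentration \cdot V_{template} / dilution}. Wells with
#' \eqn{k = 0} are non-detects (\code{NA}); otherwise
#' \eqn{Ct = intercept + slope \cdot \log_{10} k + N(0, sd)} plus the
#' inhibition shift for undiluted wells, censored to non-detect beyond the
#' cycle budget. Ct is generated from the realized copy count, which is what
#' produces the stochastic sub-LOQ scatter seen at trace concentrations.
#'
#' @param cfg A \code{sim_config}.
#' @param n Number of reactions.
#' @param dilution_factor Template dilution factor (1 = undiluted).
#' @param seed Optional integer seed.
#' @return Numeric vector of Ct values with \code{NA} for non-detects.
#' @export
simulate_reactions <- function(cfg, n, dilution_factor = 1L, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), n >= 1, dilution_factor >= 1)
  if (!is.null(seed)) set.seed(seed)
  lambda <- cfg$true_concentration * cfg$template_volume / dilution_factor
  k <- stats::rpois(n, lambda)
  ct <- rep(NA_real_, n)
  pos <- k > 0
  if (any(pos)) {
    ct[pos] <- cfg$curve_intercept + cfg$curve_slope * log10(k[pos]) +
      stats::rnorm(sum(pos), 0, cfg$ct_noise_sd) +
      if (dilution_factor == 1L) cfg$inhibition_shift else 0
    ct[!is.na(ct) & ct > cfg$max_cycles] <- NA_real_
  }
  ct
}

#' Simulate one qPCR reaction
#'
#' Convenience wrapper around [simulate_reactions()] for a single well.
#'
#' @inheritParams simulate_reactions
#' @return A single Ct value or \code{NA} (non-detect).
#' @export
simulate_reaction <- function(cfg, dilution_factor = 1L, seed = NULL) {
  simulate_reactions(cfg, 1L, dilution_factor, seed)
}

#' Simulate a dilution-standard series
#'
#' Generates replicate Ct values for a serial dilution of the configured
#' extract: step \eqn{i} has true concentration \eqn{stock / fold^i}.
#'
#' @param cfg A \code{sim_config}; \code{cfg$true_concentration} is the
#'   stock concentration in copies/\eqn{\mu}L.
#' @param fold Dilution factor between steps (> 1).
#' @param n_steps Number of steps (step 0 = stock).
#' @param reps_per_step Replicates per step.
#' @param seed Optional integer seed.
#' @return Long-format standard table (columns \code{step},
#'   \code{copies_per_reaction} — the nominal, not realized, copy number —
#'   and \code{ct}), suitable for [fit_standard_curve()], [lod_loq_danish()]
#'   and [loq_norwegian()].
#' @export
simulate_dilution_series <- function(cfg, fold, n_steps, reps_per_step = 3L,
                                     seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), fold > 1, n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n_steps) - 1L, function(i) {
    conc <- cfg$true_concentration / fold^i
    step_cfg <- cfg
    step_cfg$true_concentration <- conc
    data.frame(step = i,
               copies_per_reaction = conc * cfg$template_volume,
               ct = simulate_reactions(step_cfg, reps_per_step))
  })
  do.call(rbind, out)
}

#' Simulate a multi-site eDNA survey as a qPCR plate
#'
#' Generates field wells for each site/filter sample from its true eDNA
#' concentration in copies per litre of water, together with clean (or, at a
#' configurable rate, contaminated) no-template and extraction-blank
#' controls, and the ground-truth table needed for recovery tests. The
#' extract concentration implied by a site is
#' \eqn{C_L \cdot V_w / V_e} copies/\eqn{\mu}L.
#'
#' @param sites Data frame with one row per filter sample: columns
#'   \code{sample_id}, \code{true_copies_per_l}, \code{V_w} (litres),
#'   \code{V_e}, \code{V_r} (\eqn{\mu}L), and optional
#'   \code{inhibition_shift} (cycles, default 0).
#' @param cfg A \code{sim_config}; its concentration field is overridden per
#'   site and \code{template_volume} by each site's \code{V_r}.
#' @param scheme \code{"danish"} (\code{n_replicates} undiluted wells per
#'   sample) or \code{"norwegian"} (2 undiluted + 2 ten-fold diluted wells).
#' @param assay_id Assay label written to the plate.
#' @param n_ntc,n_blanks Number of no-template-control and extraction-blank
#'   wells appended.
#' @param contamination_rate Probability that a control well shows a weak
#'   late signal (default 0).
#' @param seed Optional integer seed.
#' @return List with \code{plate} (a plate data frame accepted by
#'   [read_plate()]/[write_plate()] and the decision rules) and \code{truth}
#'   (the input \code{sites} table).
#' @export
simulate_survey <- function(sites, cfg, scheme = c("danish", "norwegian"),
                            assay_id = "assay1", n_ntc = 4L, n_blanks = 2L,
                            contamination_rate = 0, seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(cfg, "sim_config"),
            all(c("sample_id", "true_copies_per_l", "V_w", "V_e", "V_r")
                %in% names(sites)))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sites$inhibition_shift)) sites$inhibition_shift <- 0
  wells <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    site_cfg <- cfg
    site_cfg$true_concentration <- s$true_copies_per_l * s$V_w / s$V_e
    site_cfg$template_volume <- s$V_r
    site_cfg$inhibition_shift <- s$inhibition_shift
    dils <- if (scheme == "danish") rep(1L, cfg$n_replicates)
            else c(1L, 1L, 10L, 10L)
    cts <- vapply(dils, function(d) simulate_reactions(site_cfg, 1L, d),
                  numeric(1))
    wells[[i]] <- data.frame(sample_id = s$sample_id, assay_id = assay_id,
                             dilution_factor = dils, ct = cts,
                             role = "unknown", stringsAsFactors = FALSE)
  }
  ctrl_ct <- function(n, role) {
    hit <- stats::runif(n) < contamination_rate
    ct <- rep(NA_real_, n)
    # contamination shows as a weak signal in the last cycles of the run
    ct[hit] <- stats::runif(sum(hit), cfg$max_cycles - 8, cfg$max_cycles - 1)
    data.frame(sample_id = paste0(role, "_", seq_len(n)), assay_id = assay_id,
               dilution_factor = 1L, ct = ct, role = role,
               stringsAsFactors = FALSE)
  }
  plate <- do.call(rbind, c(wells,
                            list(ctrl_ct(n_ntc, "ntc"),
                                 ctrl_ct(n_blanks, "extraction_blank"))))
  rownames(plate) <- NULL
  list(plate = plate, truth = sites)
}
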
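#' Read a qPCR plate-result table
#'
#' Reads a CSV file in which each row is one qPCR well. Required columns are
#' \code{sample_id}, \code{assay_id}, \code{dilution_factor}, \code{ct} and
#' \code{role}. The \code{ct} column holds the cycle-threshold value of the
#' well, or a non-detect token (default \code{"ND"}) for wells in which no
#' fluorescence crossed the threshold within the run's cycle budget.
#' Non-detects are represented in memory as \code{NA}; they are a distinct
#' state and are never coerced to a numeric Ct.
#'
#' @param path Path to the CSV file.
#' @param nd_token Character token(s) in the \code{ct} column denoting a
#'   non-detect. Instruments vary ("Undetermined", blank, "N/A"), so several
#'   tokens may be given; all map to \code{NA}.
#' @return A plate data frame with columns \code{sample_id}, \code{assay_id},
#'   \code{dilution_factor} (positive integer), \code{ct} (numeric, \code{NA}
#'   for non-detect) and \code{role} (one of \code{unknown}, \code{standard},
#'   \code{ntc}, \code{extraction_blank}, \code{positive_control}). Row order
#'   follows the file.
#' @seealso [write_plate()], [write_results()]
#' @examples
#' plate <- read_plate(system.file("extdata", "example_plate_synthetic.csv",
#'                                 package = "ednaqpcr"))
#' table(plate$role, is.na(plate$ct))
#' @export
read_plate <- function(path, nd_token = c("ND", "", "NA", "Undetermined")) {
  if (!file.exists(path)) stop("plate file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                         strip.white = TRUE)
  required <- c("sample_id", "assay_id", "dilution_factor", "ct", "role")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("plate file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(data.frame(sample_id = character(), assay_id = character(),
                      dilution_factor = integer(), ct = numeric(),
                      role = character(), stringsAsFactors = FALSE))
  }
  ct_chr <- raw$ct
  is_nd <- ct_chr %in% nd_token | is.na(ct_chr)
  ct <- rep(NA_real_, length(ct_chr))
  parsed <- suppressWarnings(as.numeric(ct_chr[!is_nd]))
  bad <- which(!is_nd)[is.na(parsed)]
  if (length(bad) > 0L) {
    # +1 for the header line so the number matches the file
    stop("unparseable ct value ", dQuote(ct_chr[bad[1]]),
         " on line ", bad[1] + 1L, " of ", path)
  }
  ct[!is_nd] <- parsed
  if (any(!is.na(ct) & ct <= 0)) {
    stop("detected Ct values must be positive; offending row(s): ",
         paste(which(!is.na(ct) & ct <= 0), collapse = ", "))
  }
  dil <- suppressWarnings(as.numeric(raw$dilution_factor))
  if (any(is.na(dil) | dil < 1 | dil != round(dil))) {
    stop("dilution_factor must be a positive integer (1 = undiluted)")
  }
  roles <- c("unknown", "standard", "ntc", "extraction_blank",
             "positive_control")
  if (!all(raw$role %in% roles)) {
    stop("unknown role value(s): ",
         paste(unique(setdiff(raw$role, roles)), collapse = ", "))
  }
  data.frame(sample_id = raw$sample_id, assay_id = raw$assay_id,
             dilution_factor = as.integer(dil), ct = ct, role = raw$role,
             stringsAsFactors = FALSE)
}

#' Write a plate data frame back to CSV
#'
#' Inverse of [read_plate()]: non-detect wells (\code{NA} Ct) are written as
#' the non-detect token so that a read/write round trip is lossless.
#'
#' @param plate A plate data frame as returned by [read_plate()] or
#'   [simulate_survey()].
#' @param path Output CSV path.
#' @param nd_token Token written for non-detect wells.
#' @return The path, invisibly.
#' @export
write_plate <- function(plate, path, nd_token = "ND") {
  out <- plate
  out$ct <- ifelse(is.na(plate$ct), nd_token,
                   formatC(plate$ct, format = "fg", digits = 15))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased; alignment gap characters (\code{-}) are retained
#' so that pre-aligned input can be used downstream (the specificity scanner
#' removes gaps itself). Characters outside the IUPAC nucleotide alphabet
#' plus gap are rejected with an error naming the record.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  allowed <- c(names(Biostrings::IUPAC_CODE_MAP), "-")
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0L) {
      stop("record ", dQuote(names(seqs)[i]),
           " contains non-IUPAC character(s): ", paste(bad, collapse = ", "))
    }
  }
  seqs
}

#' Render a detection verdict the way survey tables report it
#'
#' Not-detected samples print as \code{"0"}, positive detections below the
#' limit of quantification as \code{"<LOQ"}, and quantified samples as
#' \code{"mean (SD)"} in copies per litre.
#'
#' @param results A detection-result data frame (rows from [detect_danish()]
#'   or [quantify_norwegian()], or [summarize_site()] output).
#' @return Character vector of rendered verdicts, one per row.
#' @export
render_verdict <- function(results) {
  vapply(seq_len(nrow(results)), function(i) {
    st <- results$status[i]
    if (st == "not_detected") return("0")
    if (st == "detected_below_LOQ") return("<LOQ")
    mean_s <- formatC(results$copies_per_L[i], format = "f", digits = 0)
    sd_s <- formatC(results$sd_copies_per_L[i], format = "f", digits = 0)
    paste0(mean_s, " (", sd_s, ")")
  }, character(1))
}

#' Write detection results to CSV
#'
#' One row per sample/assay, with the verdict rendered by [render_verdict()]
#' in a \code{reported} column alongside the numeric fields.
#'
#' @inheritParams render_verdict
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  out <- results
  out$reported <- if (nrow(results) > 0L) render_verdict(results) else character()
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
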
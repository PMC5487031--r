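#' Built-in species-specific crayfish CO1 assays
#'
#' The four published TaqMan primer/probe sets targeting a 65-bp fragment of
#' mitochondrial CO1 in European freshwater crayfish: noble crayfish
#' (\emph{Astacus astacus}, assay \code{Astast}), signal crayfish
#' (\emph{Pacifastacus leniusculus}, \code{Paclen}) and narrow-clawed
#' crayfish (\emph{Astacus leptodactylus}) clades I and III
#' (\code{AstlepI}, \code{AstlepIII}). Sequences are written 5'\eqn{\to}3';
#' forward primer and probe bind the sense strand, the reverse primer the
#' antisense strand.
#'
#' @return Data frame with columns \code{assay_id}, \code{forward},
#'   \code{probe}, \code{reverse}.
#' @export
crayfish_assays <- function() {
  data.frame(
    assay_id = c("Astast", "Paclen", "AstlepI", "AstlepIII"),
    forward = c("GATTAGAGGAATAGTAGAGAG", "AACTAGAGGAATAGTTGAAAG",
                "AACTAGGGGTATAGTAGAGAG", "AACTAGAGGTATAGTAGAGGG"),
    probe = c("AGGAGTAGGGACAGGATGAACT", "AGGAGTGGGTACTGGATGAACT",
              "AGGAGTAGGGACCGGATGAACT", "GGGTGTAGGAACTGGATGAACC"),
    reverse = c("CTGATGCTAAAGGGGGATAA", "CCGCTGCTAGAGGAGGATAA",
                "CTGATGCTAAAGGGGGATAA", "CTGATGCTAGGGGAGGATAA"),
    stringsAsFactors = FALSE)
}

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param x DNA string (IUPAC codes allowed).
#' @return The reverse complement, as a character string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# IUPAC code -> set of plain bases
.iupac_sets <- function() {
  strsplit(Biostrings::IUPAC_CODE_MAP, "")
}

# match matrix m[oligo_char, record_char]: TRUE if base sets intersect
# (oligo ambiguity codes match any base in their set; record ambiguity codes
# count as a match iff the sets intersect — conservative for specificity)
.iupac_match_matrix <- function() {
  sets <- .iupac_sets()
  codes <- names(sets)
  m <- matrix(FALSE, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) for (b in codes)
    m[a, b] <- length(intersect(sets[[a]], sets[[b]])) > 0L
  m
}

#' Best-matching binding window of an oligo on a sequence record
#'
#' Slides the oligo (reverse-complemented for antisense orientation) along
#' the gap-stripped record and returns the minimum Hamming mismatch count
#' over all placements, with ties broken by the leftmost position. IUPAC
#' ambiguity codes in the oligo match any base in their set; ambiguity codes
#' in the record count as a match iff the base sets intersect.
#'
#' @param oligo Oligo sequence, 5'\eqn{\to}3' (IUPAC codes allowed).
#' @param record Subject sequence; gaps (\code{-}) are removed before
#'   scanning.
#' @param orientation \code{"sense"} to scan the oligo as given,
#'   \code{"antisense"} to scan its reverse complement (for reverse
#'   primers written 5'\eqn{\to}3' on the opposite strand).
#' @return List with \code{mismatches} and \code{position} (0-based start of
#'   the window on the forward strand of the degapped record).
#' @export
best_window_mismatches <- function(oligo, record,
                                   orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  record <- gsub("-", "", toupper(record), fixed = TRUE)
  oligo <- toupper(oligo)
  if (orientation == "antisense") oligo <- reverse_complement(oligo)
  L <- nchar(oligo); n <- nchar(record)
  if (L > n) stop("oligo (", L, " nt) longer than degapped record (", n, " nt)")
  m <- .iupac_match_matrix()
  oc <- strsplit(oligo, "")[[1]]
  rc <- strsplit(record, "")[[1]]
  match_mat <- m[oc, rc, drop = FALSE]  # L x n logical
  counts <- vapply(0:(n - L), function(off) {
    L - sum(match_mat[cbind(seq_len(L), off + seq_len(L))])
  }, numeric(1))
  best <- which.min(counts)  # which.min is leftmost on ties
  list(mismatches = as.integer(counts[best]), position = as.integer(best - 1L))
}

#' In-silico specificity screen of assays against a sequence collection
#'
#' For every assay/record pair, finds the best binding window of the forward
#' primer and probe (sense) and of the reverse primer (antisense) and tallies
#' mismatches. Totals of zero identify the assay's own target; the smallest
#' non-target total measures the theoretical risk of cross-species
#' amplification.
#'
#' @param assays Data frame with columns \code{assay_id}, \code{forward},
#'   \code{probe}, \code{reverse} (e.g. [crayfish_assays()]).
#' @param records Named character vector of sequences (e.g. from
#'   [read_fasta()]); records shorter than the longest oligo are skipped
#'   with a warning.
#' @return Data frame with one row per assay/record: per-oligo mismatch
#'   counts and window start positions, and \code{total}; sorted by
#'   \code{total} ascending.
#' @export
specificity_table <- function(assays, records) {
  stopifnot(is.data.frame(assays), nrow(assays) >= 1L, length(records) >= 1L)
  if (is.null(names(records)) || any(names(records) == ""))
    stop("records must be named")
  rows <- list()
  for (i in seq_len(nrow(assays))) {
    longest <- max(nchar(c(assays$forward[i], assays$probe[i],
                           assays$reverse[i])))
    for (j in seq_along(records)) {
      degapped <- gsub("-", "", records[[j]], fixed = TRUE)
      if (nchar(degapped) < longest) {
        warning("record ", dQuote(names(records)[j]),
                " shorter than the longest oligo; skipped")
        next
      }
      fw <- best_window_mismatches(assays$forward[i], records[[j]], "sense")
      pr <- best_window_mismatches(assays$probe[i], records[[j]], "sense")
      rv <- best_window_mismatches(assays$reverse[i], records[[j]], "antisense")
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = assays$assay_id[i], record_id = names(records)[j],
        forward_mm = fw$mismatches, probe_mm = pr$mismatches,
        reverse_mm = rv$mismatches,
        total = fw$mismatches + pr$mismatches + rv$mismatches,
        forward_pos = fw$position, probe_pos = pr$position,
        reverse_pos = rv$position, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(assay_id = character(), record_id = character(),
                      forward_mm = integer(), probe_mm = integer(),
                      reverse_mm = integer(), total = integer(),
                      forward_pos = integer(), probe_pos = integer(),
                      reverse_pos = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$total, out$assay_id, out$record_id), , drop = FALSE]
}

#' Flag potential cross-reactivity
#'
#' Decision aid: a record is flagged when its total mismatch count against
#' an assay does not exceed the threshold.
#'
#' @param total Total mismatch count(s), e.g. the \code{total} column of
#'   [specificity_table()] output.
#' @param threshold Maximum total mismatches still considered risky
#'   (\eqn{\ge 0}).
#' @return Logical vector.
#' @export
flag_cross_reactivity <- function(total, threshold) {
  if (threshold < 0) stop("threshold must be non-negative")
  total <= threshold
}

#' Synthetic design amplicon for an assay
#'
#' Reconstructs the 65-bp amplicon an assay was designed against from its
#' own oligos: forward primer, probe, a 2-nt spacer and the reverse
#' complement of the reverse primer. The spacer is unconstrained by the
#' oligos and is written as \code{NN}. This is a synthetic stand-in for the
#' species' true CO1 fragment, sufficient for self-match checks.
#'
#' @param assay One row of an assay data frame (see [crayfish_assays()]).
#' @return Character string of length 65.
#' @export
design_amplicon <- function(assay) {
  paste0(assay$forward, assay$probe, "NN", reverse_complement(assay$reverse))
}

#' Synthetic non-target CO1 records for specificity testing
#'
#' Builds a small synthetic alignment emulating a collection of non-target
#' crayfish CO1 fragments: each record starts from a consensus of the four
#' assay design amplicons and is mutated, at a fixed number of columns in
#' each oligo region, to a base carried by none of the assays at that
#' column. Every record is therefore guaranteed at least
#' \code{3 * mutations_per_region} total mismatches against every assay —
#' mimicking the mismatch separation real non-target species show, without
#' shipping third-party sequence data.
#'
#' @param n_records Number of synthetic non-target records.
#' @param mutations_per_region Mutated columns in each of the forward,
#'   probe and reverse regions (default 2).
#' @param seed Integer seed for reproducible column choice.
#' @return Named character vector of 65-nt sequences; names are
#'   \code{synthetic_nontarget_1} etc.
#' @export
synthetic_nontarget_records <- function(n_records = 6L,
                                        mutations_per_region = 2L,
                                        seed = 1L) {
  assays <- crayfish_assays()
  amps <- vapply(seq_len(nrow(assays)),
                 function(i) design_amplicon(assays[i, ]), character(1))
  mat <- do.call(rbind, strsplit(amps, ""))
  regions <- list(forward = 1:21, probe = 22:43, reverse = 46:65)
  # columns where the assays collectively use <= 3 plain bases, so a base
  # foreign to all of them exists
  candidates <- lapply(regions, function(idx) {
    idx[vapply(idx, function(col)
      length(setdiff(c("A", "C", "G", "T"), mat[, col])) > 0L, logical(1))]
  })
  consensus <- apply(mat, 2, function(col) names(sort(table(col),
                                                     decreasing = TRUE))[1])
  consensus[44:45] <- c("A", "A")  # spacer: arbitrary plain bases
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old())
  out <- vapply(seq_len(n_records), function(r) {
    rec <- consensus
    for (reg in candidates) {
      cols <- sample(reg, mutations_per_region)
      for (col in cols) {
        foreign <- setdiff(c("A", "C", "G", "T"), mat[, col])
        rec[col] <- foreign[1]
      }
    }
    paste(rec, collapse = "")
  }, character(1))
  names(out) <- paste0("synthetic_nontarget_", seq_len(n_records))
  out
}

# save/restore the RNG state so fixture builders do not disturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() invisible(NULL)
  }
}
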
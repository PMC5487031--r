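# fixtures and independent oracles shared across the suite

# naive all-positions Hamming scan with its own IUPAC handling,
# independent of the package's vectorized scanner
oracle_best_window <- function(oligo, record, antisense = FALSE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  record <- gsub("-", "", toupper(record))
  oligo <- toupper(oligo)
  if (antisense) {
    oligo <- paste(rev(comp[strsplit(oligo, "")[[1]]]), collapse = "")
  }
  oc <- strsplit(oligo, "")[[1]]
  rc <- strsplit(record, "")[[1]]
  best_n <- Inf; best_pos <- NA_integer_
  for (off in 0:(length(rc) - length(oc))) {
    mm <- 0L
    for (i in seq_along(oc)) {
      if (length(intersect(sets[[oc[i]]], sets[[rc[off + i]]])) == 0L)
        mm <- mm + 1L
    }
    if (mm < best_n) { best_n <- mm; best_pos <- off }
  }
  list(mismatches = best_n, position = best_pos)
}

# noiseless standard table on a given curve
make_standard_points <- function(concs, reps = 3L, slope = -3.3219,
                                 intercept = 39, detected = NULL) {
  pts <- data.frame(copies_per_reaction = rep(concs, each = reps))
  pts$ct <- intercept + slope * log10(pts$copies_per_reaction)
  if (!is.null(detected)) {
    # detected: named vector concentration -> number of detected replicates
    for (cc in names(detected)) {
      idx <- which(pts$copies_per_reaction == as.numeric(cc))
      nd <- idx[seq_len(reps - detected[[cc]])]
      if (length(nd) > 0) pts$ct[nd] <- NA_real_
    }
  }
  pts
}

# plate rows for one sample with given Ct values
make_sample_reps <- function(cts, dilution = 1L, sample_id = "S1",
                             assay_id = "assayX") {
  data.frame(sample_id = sample_id, assay_id = assay_id,
             dilution_factor = rep(dilution, length.out = length(cts)),
             ct = cts, role = "unknown", stringsAsFactors = FALSE)
}

# Ct values that map to the requested copies/reaction on a curve
ct_for_copies <- function(copies, curve) {
  curve$intercept + curve$slope * log10(copies)
}
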
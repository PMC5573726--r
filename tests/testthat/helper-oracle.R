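# Brute-force mapping oracle, written independently of the package mapper:
# enumerate every (precursor, start, prefix/suffix split), apply the score and
# tie-break definitions literally, and pick the winner by sorting.
oracle_map <- function(read, refset, max_mismatches = 1, max_nta = 3,
                       min_templated = 16) {
  rch <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(rch)
  prec <- refset$precursors[order(refset$precursors$precursor_id), ]
  cands <- list()
  for (pi in seq_len(nrow(prec))) {
    pch <- strsplit(prec$sequence[pi], "", fixed = TRUE)[[1]]
    L <- length(pch)
    for (s in 0:max(0, L - min_templated)) {
      for (k in min_templated:n) {
        if (s + k > L) next          # templated part must fit the precursor
        if (n - k > max_nta) next    # suffix too long to be an NTA
        mm <- sum(rch[1:k] != pch[(s + 1):(s + k)])
        if (mm > max_mismatches) next
        cands[[length(cands) + 1]] <- data.frame(
          precursor_id = prec$precursor_id[pi], pi = pi, start = s, k = k,
          mm = mm, score = k - 2 * mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cands) == 0) return(NULL)
  cands <- do.call(rbind, cands)
  ord <- order(-cands$score, n - cands$k, cands$mm, cands$pi, cands$start)
  best <- cands[ord[1], ]
  ambiguous <- any(cands$score == best$score & cands$pi != best$pi)
  list(
    precursor_id = best$precursor_id,
    tstart = best$start,
    tend = best$start + best$k,
    n_mismatch = best$mm,
    nta = if (best$k < n) substr(read, best$k + 1, n) else "",
    score = best$score,
    ambiguous = ambiguous
  )
}

# Brute-force seed-site scan: slide a window over the UTR and compare against
# the reverse complement computed with Biostrings (independent of the package
# helpers).
oracle_scan <- function(utr, mature, site_type) {
  span <- switch(site_type,
    site_5mer_2_6 = c(2, 6, FALSE), site_6mer_2_7 = c(2, 7, FALSE),
    site_7mer_m8 = c(2, 8, FALSE), site_7mer_A1 = c(2, 7, TRUE),
    site_8mer = c(2, 8, TRUE))
  seed <- substr(mature, span[1], span[2])
  motif <- as.character(Biostrings::reverseComplement(Biostrings::RNAString(seed)))
  if (span[3]) motif <- paste0(motif, "A")
  w <- nchar(motif)
  starts <- integer(0)
  for (i in seq_len(max(0, nchar(utr) - w + 1))) {
    if (substr(utr, i, i + w - 1) == motif) starts <- c(starts, i - 1L)
  }
  starts
}
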
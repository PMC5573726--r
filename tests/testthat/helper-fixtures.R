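# Fixtures are built in code; no binary data.

# Two synthetic hairpins, each housing one embedded 22-nt mature, with
# distinct flanks so reads are uniquely placeable.
toy_reference <- function() {
  m1 <- "ACGUACGUACGUACGUACGUAC"   # 22 nt
  m2 <- "GGAUCCGGAUCCGGAUCCGGAU"   # 22 nt
  p1 <- paste0("GGGGGCCCCC", m1, "CAAAAGGGGGCCCCCAAAAA")
  p2 <- paste0("UUUUUAAAAA", m2, "CUUUUGGGGGAAAAACCCCC")
  mir_reference(c(hpA = p1, hpB = p2), c(matA = m1, matB = m2))
}

# Random reference set for oracle comparisons: n_prec precursors of given
# length with no constraints beyond the alphabet.
random_reference <- function(n_prec = 2, len = 60, seed = 1) {
  withr::with_seed(seed, {
    prec <- vapply(seq_len(n_prec), function(i) {
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
    }, character(1))
    names(prec) <- sprintf("p%02d", seq_len(n_prec))
    mats <- vapply(prec, function(p) substr(p, 11, 32), character(1))
    names(mats) <- sprintf("m%02d", seq_len(n_prec))
    mir_reference(prec, mats)
  })
}

# Random reads for mapper stress tests: a mix of perturbed precursor
# substrings and fully random sequences, lengths 16-30.
random_reads <- function(refset, n = 50, seed = 1) {
  withr::with_seed(seed, {
    prec <- refset$precursors$sequence
    vapply(seq_len(n), function(i) {
      if (runif(1) < 0.75) {
        p <- sample(prec, 1)
        len <- sample(16:min(30, nchar(p)), 1)
        s <- sample.int(nchar(p) - len + 1L, 1)
        read <- substr(p, s, s + len - 1L)
        ch <- strsplit(read, "", fixed = TRUE)[[1]]
        # up to 2 random substitutions and up to 3 appended tail bases
        for (k in seq_len(sample(0:2, 1))) {
          j <- sample.int(len, 1)
          ch[j] <- sample(setdiff(c("A", "C", "G", "U"), ch[j]), 1)
        }
        tail_n <- sample(0:3, 1)
        paste0(paste(ch, collapse = ""),
               paste(sample(c("A", "C", "G", "U"), tail_n, replace = TRUE),
                     collapse = ""))
      } else {
        paste(sample(c("A", "C", "G", "U"), sample(16:30, 1), replace = TRUE),
              collapse = "")
      }
    }, character(1))
  })
}
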
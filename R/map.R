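# Precursor-space read mapping.
#
# A read is aligned ungapped to every precursor at every start position, and
# at every prefix/suffix split: the first k bases are templated (aligned to
# the precursor, mismatches allowed), the remaining bases are a candidate
# non-templated 3' addition (NTA). A candidate is valid when
#   k >= min_templated, mismatches(k) <= max_mismatches, n - k <= max_nta,
# and is scored
#   score = k - 2 * mismatches(k),
# so a terminal base that disagrees with the template is reported as a 1-nt
# NTA (score k-1+... ) rather than as a templated mismatch (score k+1-2):
# uridylation beats a forced mismatch. The maximum-score candidate wins; ties
# are broken by fewer NTA bases, then fewer mismatches, then lexicographically
# smallest precursor id, then smallest start. Equal-score survivors on a
# DIFFERENT precursor leave the winner flagged ambiguous.

# Pre-split precursors, ordered by id so the tie-break order is positional.
compile_reference <- function(refset) {
  ord <- order(refset$precursors$precursor_id, method = "radix")
  prec <- refset$precursors[ord, ]
  list(ids = prec$precursor_id,
       seqs = prec$sequence,
       chars = seq_chars(prec$sequence),
       lens = prec$length)
}

# Best alignment of one read sequence; returns a one-row data.frame or NULL.
map_one <- function(read_chars, ref, max_mismatches, max_nta, min_templated) {
  n <- length(read_chars)
  if (n < min_templated) return(NULL)
  kmin <- max(min_templated, n - max_nta)
  best <- NULL
  best_key <- NULL
  ambiguous <- FALSE
  for (pi in seq_along(ref$ids)) {
    P <- ref$chars[[pi]]
    L <- ref$lens[pi]
    if (L < min_templated) next
    for (s in 0:(L - min_templated)) {
      m <- min(n, L - s)
      if (m < kmin) next
      mm <- cumsum(read_chars[1:m] != P[(s + 1):(s + m)])
      ks <- kmin:m
      valid <- mm[ks] <= max_mismatches
      if (!any(valid)) next
      ks <- ks[valid]
      scores <- ks - 2L * mm[ks]
      j <- which.max(scores)  # ties within a start: larger k has larger score
      # among equal scores at one (precursor, start), prefer fewer NTA bases
      # (larger k) then fewer mismatches: k - 2mm equal & k larger => mm larger,
      # so the fewer-NTA rule decides; scan explicitly to apply the chain.
      cand_idx <- which(scores == scores[j])
      kbest <- max(ks[cand_idx])
      cand <- list(score = scores[j], k = kbest, mm = mm[kbest],
                   pi = pi, s = s)
      key <- c(-cand$score, n - cand$k, cand$mm, cand$pi, cand$s)
      if (is.null(best)) {
        best <- cand; best_key <- key; ambiguous <- FALSE
      } else {
        cmp <- compare_keys(key, best_key)
        if (cmp < 0) {
          # a strictly better score supersedes any earlier tie
          ambiguous <- if (cand$score > best$score) FALSE
                       else ambiguous || cand$pi != best$pi
          best <- cand; best_key <- key
        } else if (cand$score == best$score && cand$pi != best$pi) {
          ambiguous <- TRUE
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  P <- ref$chars[[best$pi]]
  mism <- which(read_chars[1:best$k] != P[(best$s + 1):(best$s + best$k)])
  data.frame(
    precursor_id = ref$ids[best$pi],
    tstart = best$s,
    tend = best$s + best$k,
    n_mismatch = best$mm,
    mismatch_positions = paste(best$s + mism - 1L, collapse = ","),
    nta = if (best$k < n) paste(read_chars[(best$k + 1):n], collapse = "") else "",
    score = best$score,
    ambiguous = ambiguous,
    stringsAsFactors = FALSE
  )
}

compare_keys <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  0L
}

#' Map reads onto hairpin precursors with templated-prefix alignment
#'
#' Aligns each read ungapped to the precursors of a reference set. The longest
#' scoring split of the read into a templated prefix (up to `max_mismatches`
#' substitutions) and a non-templated 3' suffix (up to `max_nta` bases) is
#' chosen by `score = templated_length - 2 * mismatches`, with deterministic
#' tie-breaking (fewer NTA bases, fewer mismatches, smallest precursor id,
#' smallest start). A read whose best score is matched on another precursor is
#' counted once, at the winner, with `ambiguous = TRUE`.
#'
#' @param reads Tibble with columns `read_id`, `sequence`; or a named/unnamed
#'   character vector of sequences; or the path of a FASTA/FASTQ file.
#' @param refset A [mir_reference()].
#' @param max_mismatches Maximum substitutions in the templated prefix
#'   (default 1).
#' @param max_nta Maximum non-templated 3' bases (default 3).
#' @param min_templated Minimum templated prefix length (default 16); reads
#'   shorter than this are dropped before mapping and reported as `filtered`.
#' @return Tibble with one row per surviving read: `read_id`, `sequence`,
#'   `mapped`, `precursor_id`, `tstart`, `tend` (0-based half-open templated
#'   interval), `n_mismatch`, `mismatch_positions` (0-based precursor
#'   positions, comma-joined), `nta`, `score`, `ambiguous`. The number of
#'   length-filtered reads is attached as attribute `"n_filtered"`.
#' @examples
#' rs <- mir34_reference()
#' map_reads(c(r1 = "UAGGCAGUGUCAUUAGCUGAUUG"), rs)
#' @export
map_reads <- function(reads, refset, max_mismatches = 1L, max_nta = 3L,
                      min_templated = 16L) {
  stopifnot(inherits(refset, "mir_reference"))
  reads <- as_read_tibble(reads)
  if (nrow(reads) == 0) abort("no reads supplied")
  reads$sequence <- as_rna(reads$sequence)

  keep <- nchar(reads$sequence) >= min_templated
  n_filtered <- sum(!keep)
  if (n_filtered > 0) {
    inform(sprintf("dropped %d read(s) shorter than %d nt",
                   n_filtered, min_templated))
  }
  reads <- reads[keep, ]
  if (nrow(reads) == 0) abort("all reads shorter than min_templated")

  ref <- compile_reference(refset)
  uniq <- unique(reads$sequence)
  hits <- purrr::map(seq_chars(uniq), map_one, ref = ref,
                     max_mismatches = max_mismatches, max_nta = max_nta,
                     min_templated = min_templated)
  aln <- purrr::map2(uniq, hits, function(s, h) {
    if (is.null(h)) {
      data.frame(sequence = s, mapped = FALSE, precursor_id = NA_character_,
                 tstart = NA_integer_, tend = NA_integer_,
                 n_mismatch = NA_integer_, mismatch_positions = NA_character_,
                 nta = NA_character_, score = NA_integer_, ambiguous = NA,
                 stringsAsFactors = FALSE)
    } else {
      cbind(data.frame(sequence = s, mapped = TRUE, stringsAsFactors = FALSE), h)
    }
  }) |> bind_rows() |> as_tibble()

  out <- left_join(reads, aln, by = "sequence")
  out <- out[, c("read_id", "sequence", "mapped", "precursor_id", "tstart",
                 "tend", "n_mismatch", "mismatch_positions", "nta", "score",
                 "ambiguous")]
  attr(out, "n_filtered") <- n_filtered
  out
}

as_read_tibble <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "sequence") %in% names(reads)))
    return(as_tibble(reads[, c("read_id", "sequence")]))
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    seqs <- read_seq_file(reads)
    return(tibble(read_id = names(seqs), sequence = unname(seqs)))
  }
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
    return(tibble(read_id = ids, sequence = unname(reads)))
  }
  abort("reads must be a tibble, a character vector, or a file path")
}

#' Classify mapped reads as isomiR calls
#'
#' Assigns each mapped read to the mature annotation whose interval overlaps
#' its templated interval most (ties go to the 5p arm), and expresses the
#' alignment as template offsets relative to that annotation: `offset5 =
#' templated_start - annotated_start`, `offset3 = templated_end -
#' annotated_end` (positive = downstream). Reads overlapping no annotation get
#' `mature_id = "unassigned"`.
#'
#' @param alignments Output of [map_reads()].
#' @param refset The [mir_reference()] used for mapping.
#' @return The alignment tibble with columns `mature_id`, `arm`, `offset5`,
#'   `offset3`, `n_subs` appended (NA for unmapped reads).
#' @export
classify_isomirs <- function(alignments, refset) {
  mats <- refset$matures
  key <- paste(alignments$precursor_id, alignments$tstart, alignments$tend)
  uk <- !duplicated(key) & alignments$mapped
  assign_one <- function(pid, ts, te) {
    cand <- mats[mats$precursor_id == pid, ]
    if (nrow(cand) == 0) return(c(NA_character_, NA_character_))
    ov <- pmin(cand$end, te) - pmax(cand$start, ts)
    if (max(ov) <= 0) return(c("unassigned", NA_character_))
    top <- cand[ov == max(ov), ]
    top <- top[order(top$arm, top$mature_id), ]  # "3p" < "5p"; prefer 5p
    top <- top[top$arm == top$arm[nrow(top)], ][1, ]
    c(top$mature_id, top$arm)
  }
  lut <- new.env(parent = emptyenv())
  for (i in which(uk)) {
    assign(key[i], assign_one(alignments$precursor_id[i],
                              alignments$tstart[i], alignments$tend[i]),
           envir = lut)
  }
  res <- t(vapply(seq_len(nrow(alignments)), function(i) {
    if (!isTRUE(alignments$mapped[i])) return(c(NA_character_, NA_character_))
    get(key[i], envir = lut)
  }, character(2)))

  out <- alignments
  out$mature_id <- res[, 1]
  out$arm <- res[, 2]
  ann <- mats[match(out$mature_id, mats$mature_id), ]
  out$offset5 <- as.integer(out$tstart - ann$start)
  out$offset3 <- as.integer(out$tend - ann$end)
  out$n_subs <- out$n_mismatch
  out
}
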
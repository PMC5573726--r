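# Seed-match target-site scanning in 3'UTR sequences.
#
# A seed site is the UTR substring exactly reverse-complementary (Watson-Crick
# only; G:U wobble is deliberately not counted) to a span of the mature
# miRNA. Site types follow the standard nomenclature: the span is nt 2-6
# (5mer, the RISC-exposed nucleotides), 2-7 (6mer, the common seed) or 2-8
# (7mer-m8); the A1 variants additionally require an adenine opposite mature
# position 1, i.e. an A immediately 3' of the complementary stretch on the
# mRNA.

SITE_TYPES <- c("site_5mer_2_6", "site_6mer_2_7", "site_7mer_m8",
                "site_7mer_A1", "site_8mer")

site_span <- function(site_type) {
  switch(site_type,
    site_5mer_2_6 = list(start = 2L, end = 6L, a1 = FALSE),
    site_6mer_2_7 = list(start = 2L, end = 7L, a1 = FALSE),
    site_7mer_m8  = list(start = 2L, end = 8L, a1 = FALSE),
    site_7mer_A1  = list(start = 2L, end = 7L, a1 = TRUE),
    site_8mer     = list(start = 2L, end = 8L, a1 = TRUE),
    abort(sprintf("unknown site type '%s'", site_type))
  )
}

#' Target-site motif for a mature miRNA and site type
#'
#' Returns the mRNA-side motif of a seed site: the reverse complement of the
#' designated seed span, with an `A` appended (opposite mature position 1) for
#' the `7mer_A1` and `8mer` types.
#'
#' @param mature_seq Mature miRNA sequence (RNA; T accepted).
#' @param site_type One of `"site_5mer_2_6"`, `"site_6mer_2_7"`,
#'   `"site_7mer_m8"`, `"site_7mer_A1"`, `"site_8mer"`.
#' @return The motif string (RNA alphabet, 5'->3' on the mRNA).
#' @examples
#' seed_site("UAGGCAGUGUCAUUAGCUGAUUG", "site_5mer_2_6") # "UGCCU"
#' seed_site("UGGCAGUGUCUUAGCUGGUUGU", "site_8mer")      # "CACUGCCA"
#' @export
seed_site <- function(mature_seq, site_type = "site_6mer_2_7") {
  span <- site_span(site_type)
  seed <- extract_seed(mature_seq,
                       seed_spec("custom", span$start, span$end))
  motif <- rna_revcomp(seed)
  if (span$a1) motif <- paste0(motif, "A")
  motif
}

#' Scan 3'UTR sequences for seed-match sites of a mature miRNA
#'
#' Exhaustive exact-match scan: every occurrence of each requested site motif
#' is reported, including overlapping ones, ordered by UTR and position.
#'
#' @param utrs UTR sequences: a named character vector, an `XStringSet`, a
#'   single string, or the path of a FASTA file. `T` is converted to `U`;
#'   any other non-`ACGU` character is an error.
#' @param mature_seq Mature miRNA sequence.
#' @param site_types Site types to scan for (default: all five).
#' @return Tibble `utr_id`, `start`, `end` (0-based half-open on the UTR),
#'   `site_type`, `motif`, `matched_seed` (the mature-side seed span).
#' @examples
#' scan_utr(c(u1 = "AAACACUGCCAAA"), "UGGCAGUGUCUUAGCUGGUUGU")
#' @export
scan_utr <- function(utrs, mature_seq, site_types = SITE_TYPES) {
  utrs <- as_utr_set(utrs)
  if (length(utrs) == 0) abort("empty UTR set")
  if (!all(site_types %in% SITE_TYPES)) {
    abort(sprintf("unknown site type(s): %s",
                  paste(setdiff(site_types, SITE_TYPES), collapse = ", ")))
  }
  subject <- Biostrings::BStringSet(utrs)
  out <- purrr::map(site_types, function(st) {
    span <- site_span(st)
    motif <- seed_site(mature_seq, st)
    hits <- Biostrings::vmatchPattern(motif, subject)
    starts <- Biostrings::startIndex(hits)
    purrr::imap(setNames(starts, names(utrs)), function(s, uid) {
      if (is.null(s) || length(s) == 0) return(NULL)
      tibble(utr_id = uid,
             start = as.integer(s) - 1L,
             end = as.integer(s) - 1L + nchar(motif),
             site_type = st,
             motif = motif,
             matched_seed = extract_seed(
               mature_seq, seed_spec("custom", span$start, span$end)))
    }) |> purrr::compact() |> bind_rows()
  }) |> bind_rows()
  if (nrow(out) == 0) {
    return(tibble(utr_id = character(), start = integer(), end = integer(),
                  site_type = character(), motif = character(),
                  matched_seed = character()))
  }
  arrange(out, .data$utr_id, .data$start, .data$site_type)
}

as_utr_set <- function(utrs) {
  if (methods::is(utrs, "XStringSet")) {
    utrs <- setNames(as.character(utrs), names(utrs))
  }
  if (is.character(utrs) && length(utrs) == 1 && !is.null(utrs) &&
      file.exists(utrs) && !grepl("^[ACGTUacgtu]+$", utrs)) {
    utrs <- read_seq_file(utrs)
  }
  if (!is.character(utrs)) abort("utrs must be sequences or a FASTA path")
  ids <- names(utrs) %||% sprintf("utr_%04d", seq_along(utrs))
  ids <- sub("\\s.*$", "", ids)
  setNames(as_rna(utrs), ids)
}

#' Target-repertoire overlap between two miRNA isoforms
#'
#' Scans a UTR set with both isoforms for one site type and quantifies how
#' much of the first isoform's site repertoire survives as sites of the
#' second. Sites are "shared" when they lie on the same UTR and their
#' intervals overlap by at least one position, which is exactly the situation
#' created by a 1-nt seed shift whose flanking base happens to complete the
#' shifted site. `n_shared` is the smaller of (a-sites overlapped by b,
#' b-sites overlapped by a), so it never exceeds either repertoire size.
#'
#' @param utrs UTR sequences (as in [scan_utr()]).
#' @param mature_a,mature_b The two isoform sequences; `retention_a_in_b` is
#'   the fraction of a's sites with an overlapping b site.
#' @param site_type Site type to compare (default the 6mer nt 2-7 seed site).
#' @return One-row tibble: `site_type`, `n_sites_a`, `n_sites_b`, `n_shared`,
#'   `jaccard`, `retention_a_in_b`. The two site tables are attached as
#'   attributes `"sites_a"` and `"sites_b"`.
#' @examples
#' utrs <- simulate_utrs(n = 20, length = 500, seed = 42)
#' isoform_target_overlap(utrs, "UAGGCAGUGUCAUUAGCUGAUUG",
#'                        "AGGCAGUGUCAUUAGCUGAUUGU")
#' @export
isoform_target_overlap <- function(utrs, mature_a, mature_b,
                                   site_type = "site_6mer_2_7") {
  utrs <- as_utr_set(utrs)
  if (length(utrs) == 0) abort("empty UTR set")
  sites_a <- scan_utr(utrs, mature_a, site_types = site_type)
  sites_b <- scan_utr(utrs, mature_b, site_types = site_type)

  n_a <- nrow(sites_a)
  n_b <- nrow(sites_b)
  if (n_a == 0 || n_b == 0) {
    a_hit <- b_hit <- 0L
  } else {
    levels <- names(utrs)
    gr <- function(s) GenomicRanges::GRanges(
      seqnames = factor(s$utr_id, levels = levels),
      ranges = IRanges::IRanges(start = s$start + 1L, end = s$end))
    ov <- GenomicRanges::findOverlaps(gr(sites_a), gr(sites_b),
                                      minoverlap = 1L)
    a_hit <- length(unique(S4Vectors::queryHits(ov)))
    b_hit <- length(unique(S4Vectors::subjectHits(ov)))
  }
  n_shared <- min(a_hit, b_hit)
  out <- tibble(
    site_type = site_type,
    n_sites_a = n_a,
    n_sites_b = n_b,
    n_shared = n_shared,
    jaccard = if (n_a + n_b - n_shared > 0) {
      n_shared / (n_a + n_b - n_shared)
    } else NA_real_,
    retention_a_in_b = if (n_a > 0) a_hit / n_a else NA_real_
  )
  attr(out, "sites_a") <- sites_a
  attr(out, "sites_b") <- sites_b
  out
}
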
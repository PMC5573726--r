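# IsomiR profiles: per-class and per-sequence tallies with RPM normalization.

#' Profile a read library into isomiR classes
#'
#' Maps every read ([map_reads()]), classifies it against the annotations
#' ([classify_isomirs()]), and aggregates: per-class counts keyed by
#' `(mature_id, offset5, offset3, nta, n_subs)` and per-sequence counts keyed
#' by `(mature_id, sequence)`, both with reads-per-million (RPM) computed on
#' the number of reads mapped to any precursor of the reference set.
#'
#' @inheritParams map_reads
#' @param library_id Label stored with the profile (default `"library"`).
#' @return An `isomir_profile` object: list with `library_id`, `classes`
#'   (tibble `mature_id`, `arm`, `offset5`, `offset3`, `nta`, `n_subs`,
#'   `count`, `rpm`), `sequences` (tibble `mature_id`, `sequence`, `count`,
#'   `rpm`), `calls` (per unique read sequence, with alignment coordinates and
#'   a `count` column), `total_mapped`, `n_unmapped`, `n_filtered`,
#'   `ambiguous_fraction`, `params`.
#' @examples
#' rs <- mir34_reference()
#' sim <- simulate_reads(rs, sim_config(c(`hsa-miR-34b-5p` = 100), seed = 1))
#' profile_reads(sim$reads, rs, library_id = "demo")
#' @export
profile_reads <- function(reads, refset, max_mismatches = 1L, max_nta = 3L,
                          min_templated = 16L, library_id = "library") {
  aln <- map_reads(reads, refset, max_mismatches = max_mismatches,
                   max_nta = max_nta, min_templated = min_templated)
  calls_full <- classify_isomirs(aln, refset)

  mapped <- filter(calls_full, .data$mapped)
  total_mapped <- nrow(mapped)
  n_unmapped <- sum(!calls_full$mapped)
  if (total_mapped == 0) abort("no reads mapped to the reference set")

  classes <- mapped |>
    count(.data$mature_id, .data$arm, .data$offset5, .data$offset3,
          .data$nta, .data$n_subs, name = "count") |>
    mutate(rpm = .data$count / total_mapped * 1e6) |>
    arrange(.data$mature_id, desc(.data$count))

  sequences <- mapped |>
    count(.data$mature_id, .data$sequence, name = "count") |>
    mutate(rpm = .data$count / total_mapped * 1e6) |>
    arrange(.data$mature_id, desc(.data$count))

  calls <- mapped |>
    group_by(across(c("sequence", "mapped", "precursor_id", "tstart", "tend",
                      "n_mismatch", "mismatch_positions", "nta", "score",
                      "ambiguous", "mature_id", "arm", "offset5", "offset3",
                      "n_subs"))) |>
    summarise(count = n(), .groups = "drop")

  structure(list(
    library_id = library_id,
    classes = classes,
    sequences = sequences,
    calls = calls,
    total_mapped = total_mapped,
    n_unmapped = n_unmapped,
    n_filtered = attr(aln, "n_filtered"),
    ambiguous_fraction = sum(mapped$ambiguous) / total_mapped,
    params = list(max_mismatches = max_mismatches, max_nta = max_nta,
                  min_templated = min_templated)
  ), class = "isomir_profile")
}

#' @export
print.isomir_profile <- function(x, ...) {
  cat(sprintf(
    "<isomir_profile '%s'> %d mapped, %d unmapped, %d filtered; %.2f%% ambiguous\n",
    x$library_id, x$total_mapped, x$n_unmapped, x$n_filtered,
    100 * x$ambiguous_fraction))
  print(x$classes, ...)
  invisible(x)
}

mature_depth <- function(profile, mature_id) {
  sum(profile$classes$count[profile$classes$mature_id == mature_id])
}

#' Fraction of a precursor's reads assigned to the 5p arm
#'
#' @param profile An [profile_reads()] result.
#' @param refset The [mir_reference()] used to build it.
#' @param precursor_id One or more precursor ids (default: all).
#' @return Tibble `precursor_id`, `n_5p`, `n_3p`, `arm5p_fraction`
#'   (`NA` when the precursor has no assigned reads).
#' @export
arm_fraction <- function(profile, refset, precursor_id = NULL) {
  mats <- select(refset$matures, "mature_id", "precursor_id")
  ids <- precursor_id %||% refset$precursors$precursor_id
  per <- profile$classes |>
    dplyr::inner_join(mats, by = "mature_id") |>
    group_by(.data$precursor_id) |>
    summarise(n_5p = sum(.data$count[.data$arm == "5p"]),
              n_3p = sum(.data$count[.data$arm == "3p"]),
              .groups = "drop")
  out <- tibble(precursor_id = ids) |>
    left_join(per, by = "precursor_id") |>
    mutate(n_5p = dplyr::coalesce(.data$n_5p, 0L),
           n_3p = dplyr::coalesce(.data$n_3p, 0L),
           arm5p_fraction = ifelse(.data$n_5p + .data$n_3p > 0,
                                   .data$n_5p / (.data$n_5p + .data$n_3p),
                                   NA_real_))
  if (anyNA(out$arm5p_fraction)) {
    warn(sprintf("no assigned reads for precursor(s): %s",
                 paste(out$precursor_id[is.na(out$arm5p_fraction)],
                       collapse = ", ")))
  }
  out
}

#' Fold change of a miRNA between two libraries
#'
#' Compares the total abundance of a mature (summed over all its isomiR
#' classes) between two profiles. The primary ratio is on RPM
#' (library-size-normalized); the raw-count ratio is also reported since the
#' two differ only by the library-size ratio.
#'
#' @param profile_a,profile_b Two [profile_reads()] results (numerator a).
#' @param mature_id Mature to compare.
#' @param pseudocount Add 0.5 to both raw counts before normalizing
#'   (default `FALSE`: no pseudocount, and a zero denominator yields `Inf`
#'   with `infinite = TRUE`).
#' @return One-row tibble: `mature_id`, `count_a`, `count_b`, `rpm_a`,
#'   `rpm_b`, `fold_change_rpm`, `fold_change_count`, `infinite`.
#' @export
fold_change <- function(profile_a, profile_b, mature_id, pseudocount = FALSE) {
  ca <- mature_depth(profile_a, mature_id)
  cb <- mature_depth(profile_b, mature_id)
  if (ca == 0 && cb == 0) {
    abort(sprintf("mature '%s' absent from both profiles", mature_id))
  }
  adj <- if (pseudocount) 0.5 else 0
  rpm_a <- (ca + adj) / profile_a$total_mapped * 1e6
  rpm_b <- (cb + adj) / profile_b$total_mapped * 1e6
  tibble(
    mature_id = mature_id,
    count_a = ca, count_b = cb,
    rpm_a = rpm_a, rpm_b = rpm_b,
    fold_change_rpm = rpm_a / rpm_b,
    fold_change_count = (ca + adj) / (cb + adj),
    infinite = rpm_b == 0
  )
}

#' Position probability matrix of the reads assigned to a mature
#'
#' Stacks every read assigned to a mature at its precursor coordinates over
#' the window `[annotated_start - flank, annotated_end + flank)`; non-templated
#' 3' bases occupy the positions immediately past the templated end. Column
#' probabilities are read-count weighted and normalized by the total read
#' depth of the mature, so a column sums to the fraction of reads covering
#' that position (1 for positions covered by every read); a depleted
#' annotated 5' end is therefore directly visible. This is the matrix behind
#' a sequence-logo rendering of the library.
#'
#' @param profile An [profile_reads()] result.
#' @param refset The matching [mir_reference()].
#' @param mature_id Mature whose window to profile.
#' @param flank Extra positions on each side of the annotation (default 2).
#' @return A `logo_matrix` object: list with `mature_id`, `precursor_id`,
#'   `window` (`start`, `end`, 0-based half-open), `matrix` (4 x width,
#'   rows A/C/G/U), `support` (reads covering each column).
#' @examples
#' rs <- mir34_reference()
#' sim <- simulate_reads(rs, sim_config(c(`hsa-miR-34b-5p` = 200), seed = 1))
#' lm <- logo_matrix(profile_reads(sim$reads, rs), rs, "hsa-miR-34b-5p")
#' round(lm$matrix[, 1:6], 2)
#' @export
logo_matrix <- function(profile, refset, mature_id, flank = 2L) {
  ann <- filter(refset$matures, .data$mature_id == !!mature_id)
  if (nrow(ann) == 0) abort(sprintf("unknown mature id '%s'", mature_id))
  ann <- ann[1, ]
  calls <- filter(profile$calls, .data$mature_id == !!mature_id)
  if (nrow(calls) == 0) {
    abort(sprintf("no reads assigned to '%s'", mature_id))
  }
  w_start <- max(0L, ann$start - as.integer(flank))
  w_end <- ann$end + as.integer(flank)
  width <- w_end - w_start
  mat <- matrix(0, nrow = 4, ncol = width,
                dimnames = list(RNA_BASES, as.character(w_start:(w_end - 1L))))
  for (i in seq_len(nrow(calls))) {
    ch <- strsplit(calls$sequence[i], "", fixed = TRUE)[[1]]
    pos <- calls$tstart[i] + seq_along(ch) - 1L  # NTA continues past tend
    keep <- pos >= w_start & pos < w_end
    if (!any(keep)) next
    idx <- cbind(match(ch[keep], RNA_BASES), pos[keep] - w_start + 1L)
    for (j in seq_len(nrow(idx))) {
      mat[idx[j, 1], idx[j, 2]] <- mat[idx[j, 1], idx[j, 2]] + calls$count[i]
    }
  }
  depth <- sum(calls$count)
  support <- colSums(mat)
  # Normalize by total read depth, not per-column coverage: a position covered
  # by few reads shows small letters (its column sums to support/depth), which
  # is what makes a depleted annotated 5' end visible in the logo. Columns
  # covered by every read sum to 1.
  probs <- mat / depth
  structure(list(
    mature_id = mature_id,
    precursor_id = ann$precursor_id,
    window = c(start = w_start, end = w_end),
    matrix = probs,
    support = support
  ), class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("<logo_matrix '%s'> window [%d,%d) on %s\n",
              x$mature_id, x$window["start"], x$window["end"],
              x$precursor_id))
  print(round(x$matrix, 3), ...)
  invisible(x)
}

#' Write an isomiR profile as TSV
#'
#' Columns: `library_id`, `mature_id`, `arm`, `offset5`, `offset3`, `nta`,
#' `n_subs`, `count`, `rpm`.
#'
#' @param profile An [profile_reads()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  out <- mutate(profile$classes, library_id = profile$library_id,
                .before = 1)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a logo matrix as TSV (positions x A/C/G/U)
#'
#' @param logo A [logo_matrix()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_logo <- function(logo, path) {
  out <- as_tibble(t(logo$matrix))
  out <- mutate(out, position = as.integer(colnames(logo$matrix)),
                support = as.integer(logo$support), .before = 1)
  readr::write_tsv(out, path)
  invisible(path)
}
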
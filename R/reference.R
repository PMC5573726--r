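# Reference model: hairpin precursors plus mature annotations placed on them.
#
# Coordinate conventions (used everywhere in the package):
#   * intervals on precursors are 0-based, half-open [start, end)
#   * positions on a mature miRNA are 1-based and inclusive (so "nucleotides
#     2-7" means the usual seed definition)

#' Build a reference set of hairpin precursors and mature miRNAs
#'
#' Constructs the central container used by the profiler, audit and simulator:
#' a set of precursor (hairpin) sequences together with mature annotations
#' located on them. When no placement table is given, each mature is located on
#' the precursors by exact substring search ([locate_mature()]); a mature that
#' occurs on several precursors is placed on all of them (each placement gets a
#' distinct row), and a mature that occurs more than once within one precursor
#' is placed at its first occurrence and flagged ambiguous.
#'
#' @param precursors Named character vector of precursor sequences, or a
#'   data frame with columns `precursor_id`, `sequence`. `T` is converted to
#'   `U` on input.
#' @param matures Named character vector of mature sequences, or a data frame
#'   with columns `mature_id`, `sequence` and optionally `precursor_id`,
#'   `start`, `end`, `arm` (0-based half-open coordinates on the precursor).
#' @param placements Optional data frame with columns `mature_id`,
#'   `precursor_id`, `start`, `end` and optionally `arm`, overriding substring
#'   search (used by the GFF3 reader).
#' @return A `mir_reference` object: a list with tibbles `precursors`
#'   (`precursor_id`, `sequence`, `length`) and `matures` (`mature_id`,
#'   `precursor_id`, `start`, `end`, `arm`, `sequence`, `ambiguous`).
#' @details The arm (`5p`/`3p`) is taken from the input when provided and
#'   otherwise inferred from the position of the mature's midpoint relative to
#'   the precursor midpoint. Precursors shorter than 40 nt or matures outside
#'   16-30 nt are rejected, as are duplicate ids and matures that cannot be
#'   placed on any precursor.
#' @examples
#' rs <- mir_reference(
#'   c(hp = paste0(strrep("ACGU", 12), "GGAC")),
#'   c(m1 = strrep("ACGU", 5))
#' )
#' rs$matures
#' @seealso [read_references()] to build a reference set from FASTA files,
#'   [mir34_reference()] for the bundled miR-34 family set.
#' @export
mir_reference <- function(precursors, matures, placements = NULL) {
  prec <- if (is.data.frame(precursors)) {
    tibble(precursor_id = as.character(precursors$precursor_id),
           sequence = as_rna(precursors$sequence))
  } else {
    if (is.null(names(precursors))) abort("precursors must be named")
    tibble(precursor_id = names(precursors), sequence = as_rna(precursors))
  }
  if (anyDuplicated(prec$precursor_id)) {
    abort(sprintf("duplicate precursor id: %s",
                  prec$precursor_id[duplicated(prec$precursor_id)][1]))
  }
  short <- nchar(prec$sequence) < 40L
  if (any(short)) {
    abort(sprintf("precursor '%s' is shorter than 40 nt",
                  prec$precursor_id[short][1]))
  }
  prec$length <- nchar(prec$sequence)

  if (is.data.frame(matures)) {
    mat <- as_tibble(matures)
    mat$mature_id <- as.character(mat$mature_id)
    mat$sequence <- as_rna(mat$sequence)
  } else {
    if (is.null(names(matures))) abort("matures must be named")
    mat <- tibble(mature_id = names(matures), sequence = as_rna(matures))
  }
  if (anyDuplicated(mat$mature_id)) {
    abort(sprintf("duplicate mature id: %s",
                  mat$mature_id[duplicated(mat$mature_id)][1]))
  }
  len <- nchar(mat$sequence)
  if (any(len < 16L | len > 30L)) {
    abort(sprintf("mature '%s' has length %d; expected 16-30 nt",
                  mat$mature_id[len < 16L | len > 30L][1],
                  len[len < 16L | len > 30L][1]))
  }

  if (!is.null(placements)) {
    mat <- place_by_table(prec, mat, as_tibble(placements))
  } else if (all(c("precursor_id", "start", "end") %in% names(mat)) &&
             !anyNA(mat$start)) {
    if (!"ambiguous" %in% names(mat)) mat$ambiguous <- FALSE
  } else {
    mat <- place_by_search(prec, mat)
  }

  if (!"arm" %in% names(mat)) mat$arm <- NA_character_
  mat <- mat |>
    left_join(select(prec, "precursor_id", prec_len = "length"),
              by = "precursor_id") |>
    mutate(arm = ifelse(is.na(.data$arm),
                        ifelse((.data$start + .data$end) / 2 <= .data$prec_len / 2,
                               "5p", "3p"),
                        .data$arm)) |>
    select(-"prec_len")
  if (!all(mat$arm %in% c("5p", "3p"))) abort("arm must be '5p' or '3p'")

  out <- structure(
    list(precursors = prec,
         matures = mat[, c("mature_id", "precursor_id", "start", "end",
                           "arm", "sequence", "ambiguous")]),
    class = "mir_reference"
  )
  validate_reference(out)
  out
}

place_by_search <- function(prec, mat) {
  rows <- purrr::pmap(mat, function(mature_id, sequence, ...) {
    hits <- purrr::imap(setNames(prec$sequence, prec$precursor_id),
                        function(ps, pid) {
      loc <- locate_mature(ps, sequence, quiet = TRUE)
      if (is.null(loc)) return(NULL)
      tibble(mature_id = mature_id, precursor_id = pid,
             start = loc$start, end = loc$end, sequence = sequence,
             ambiguous = loc$ambiguous)
    })
    hits <- purrr::compact(hits)
    if (length(hits) == 0) {
      abort(sprintf("mature '%s' could not be located on any precursor",
                    mature_id))
    }
    bind_rows(hits)
  })
  out <- bind_rows(rows)
  if (any(out$ambiguous)) {
    warn(sprintf("ambiguous placement (multiple occurrences) for: %s",
                 paste(unique(out$mature_id[out$ambiguous]), collapse = ", ")))
  }
  out
}

place_by_table <- function(prec, mat, placements) {
  need <- c("mature_id", "precursor_id", "start", "end")
  if (!all(need %in% names(placements))) {
    abort("placements must have columns mature_id, precursor_id, start, end")
  }
  out <- mat |>
    select(-dplyr::any_of(c("precursor_id", "start", "end"))) |>
    dplyr::inner_join(placements, by = "mature_id")
  if (nrow(out) < nrow(mat)) {
    missing <- setdiff(mat$mature_id, out$mature_id)
    abort(sprintf("no placement given for mature '%s'", missing[1]))
  }
  out$ambiguous <- FALSE
  out
}

validate_reference <- function(rs) {
  mat <- rs$matures
  prec <- setNames(rs$precursors$sequence, rs$precursors$precursor_id)
  bad <- !mat$precursor_id %in% names(prec)
  if (any(bad)) {
    abort(sprintf("mature '%s' references unknown precursor '%s'",
                  mat$mature_id[bad][1], mat$precursor_id[bad][1]))
  }
  got <- substr(prec[mat$precursor_id], mat$start + 1L, mat$end)
  off <- got != mat$sequence
  if (any(off)) {
    abort(sprintf(
      "mature '%s' does not match precursor '%s' at [%d,%d)",
      mat$mature_id[off][1], mat$precursor_id[off][1],
      mat$start[off][1], mat$end[off][1]))
  }
  invisible(rs)
}

#' @export
print.mir_reference <- function(x, ...) {
  cat(sprintf("<mir_reference> %d precursor(s), %d mature annotation(s)\n",
              nrow(x$precursors), nrow(x$matures)))
  print(x$matures, ...)
  invisible(x)
}

#' Load a reference set from miRBase-style FASTA (and optional GFF3) files
#'
#' Reads hairpin and mature FASTA files (id = first whitespace-delimited header
#' token; `T` accepted and converted to `U`) and places each mature on its
#' precursor by exact substring search, or by coordinates from an optional
#' GFF3 file.
#'
#' @param hairpin_path Path to the precursor (hairpin) FASTA.
#' @param mature_path Path to the mature FASTA.
#' @param gff_path Optional GFF3 whose `seqid` is the precursor id and whose
#'   coordinates are 1-based closed intervals on the precursor; mature ids are
#'   taken from the `Name` (or `ID`) attribute, miRBase attribute style.
#' @return A [mir_reference()] object.
#' @examples
#' hp <- system.file("extdata", "mir34_hairpins.fa", package = "seedshift")
#' mt <- system.file("extdata", "mir34_mature.fa", package = "seedshift")
#' read_references(hp, mt)
#' @export
read_references <- function(hairpin_path, mature_path, gff_path = NULL) {
  prec <- read_seq_file(hairpin_path)
  mat <- read_seq_file(mature_path)
  placements <- NULL
  if (!is.null(gff_path)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 placements requires the rtracklayer package")
    }
    gr <- rtracklayer::import(gff_path)
    ids <- as.character(gr$Name %||% gr$ID)
    placements <- tibble(
      mature_id = ids,
      precursor_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # GFF is 1-based closed
      end = GenomicRanges::end(gr)
    )
    placements <- filter(placements, .data$mature_id %in% names(mat))
  }
  mir_reference(prec, mat, placements = placements)
}

#' The bundled miR-34 family reference set
#'
#' Hairpins and annotated matures for hsa-mir-34a, hsa-mir-34b and hsa-mir-34c
#' (miRBase sequences shipped with the package as plain FASTA). This is the
#' worked example used throughout: the endogenously dominant miR-34b-5p is a
#' 1-nt 5'-shifted, 3'-extended variant of the annotated mature.
#'
#' @return A [mir_reference()] object with 3 precursors and 6 matures.
#' @examples
#' mir34_reference()
#' @export
mir34_reference <- function() {
  read_references(
    system.file("extdata", "mir34_hairpins.fa", package = "seedshift"),
    system.file("extdata", "mir34_mature.fa", package = "seedshift")
  )
}

#' Locate a mature sequence on a precursor by exact substring search
#'
#' @param precursor_seq,mature_seq RNA strings (T accepted).
#' @param quiet Return `NULL` instead of erroring when there is no occurrence.
#' @return A list with `start`, `end` (0-based half-open) and `ambiguous`
#'   (`TRUE` when the mature occurs more than once; the first occurrence is
#'   returned).
#' @examples
#' locate_mature("AAGGCC", "GGC") # [2, 5)
#' @export
locate_mature <- function(precursor_seq, mature_seq, quiet = FALSE) {
  p <- as_rna(precursor_seq)
  m <- as_rna(mature_seq)
  if (nchar(p) == 0 || nchar(m) == 0) abort("empty sequence")
  hits <- gregexpr(m, p, fixed = TRUE)[[1]]
  if (hits[1] == -1L) {
    if (quiet) return(NULL)
    abort(sprintf("mature sequence '%s' not found on precursor", m))
  }
  ambiguous <- length(hits) > 1L
  if (ambiguous && !quiet) {
    warn("mature occurs more than once on the precursor; using the first occurrence")
  }
  list(start = hits[1] - 1L, end = hits[1] - 1L + nchar(m),
       ambiguous = ambiguous)
}

#' Seed span specifications
#'
#' A seed specification names a 1-based inclusive span of mature-miRNA
#' positions: `seed_2_7` (the common seed definition, nucleotides 2-7),
#' `seed_2_8` (the extended 7-nt seed) and `exposed_2_6` (the nucleotides
#' exposed for initial target pairing in the RISC).
#'
#' @param label One of `"seed_2_7"`, `"seed_2_8"`, `"exposed_2_6"`, or
#'   `"custom"` with explicit `start_pos`/`end_pos`.
#' @param start_pos,end_pos 1-based inclusive positions on the mature; must
#'   satisfy `1 < start_pos <= end_pos <= 10`.
#' @return A `seed_spec` list with `start_pos`, `end_pos`, `label`.
#' @examples
#' seed_spec("seed_2_7")
#' @export
seed_spec <- function(label = c("seed_2_7", "seed_2_8", "exposed_2_6", "custom"),
                      start_pos = NULL, end_pos = NULL) {
  label <- match.arg(label)
  span <- switch(label,
    seed_2_7 = c(2L, 7L),
    seed_2_8 = c(2L, 8L),
    exposed_2_6 = c(2L, 6L),
    custom = c(as.integer(start_pos), as.integer(end_pos))
  )
  if (anyNA(span)) abort("custom seed_spec needs start_pos and end_pos")
  if (!(1L < span[1] && span[1] <= span[2] && span[2] <= 10L)) {
    abort("seed span must satisfy 1 < start_pos <= end_pos <= 10")
  }
  structure(list(start_pos = span[1], end_pos = span[2], label = label),
            class = "seed_spec")
}

as_seed_spec <- function(spec) {
  if (inherits(spec, "seed_spec")) spec else seed_spec(spec)
}

#' Extract a seed span from a mature sequence
#'
#' @param mature_seq RNA string (T accepted).
#' @param spec A [seed_spec()] or its label (default the common nt 2-7 seed).
#' @return The seed substring (RNA alphabet).
#' @examples
#' extract_seed("UAGGCAGUGUCAUUAGCUGAUUG", "exposed_2_6") # "AGGCA"
#' extract_seed("UGGCAGUGUCUUAGCUGGUUGU", "exposed_2_6")  # "GGCAG"
#' @export
extract_seed <- function(mature_seq, spec = "seed_2_7") {
  spec <- as_seed_spec(spec)
  s <- as_rna(mature_seq)
  short <- nchar(s) < spec$end_pos
  if (any(short)) {
    abort(sprintf("sequence of length %d too short for %s (needs >= %d nt)",
                  nchar(s)[short][1], spec$label, spec$end_pos))
  }
  substr(s, spec$start_pos, spec$end_pos)
}

#' Build a templated 5'/3'-shifted variant of an annotated mature
#'
#' Moves the annotated interval by `delta5` at the 5' end and `delta3` at the
#' 3' end (positive = downstream on the precursor) and reads the variant
#' sequence off the precursor, so the result is templated by construction.
#' `shift_mature(rs, id, +1, +1)` is the transformation behind a 1-nt 5'
#' seed shift with preserved length.
#'
#' @param refset A [mir_reference()].
#' @param mature_id Id of the annotated mature to shift.
#' @param delta5,delta3 Integer offsets applied to the annotated start and end.
#' @param new_id Id for the variant; default `"<mature_id>_5p<+d>_3p<+d>"`.
#' @return A one-row tibble shaped like `refset$matures`.
#' @examples
#' rs <- mir34_reference()
#' shift_mature(rs, "hsa-miR-34b-5p", 1, 1)
#' @export
shift_mature <- function(refset, mature_id, delta5, delta3,
                         new_id = NULL) {
  stopifnot(inherits(refset, "mir_reference"))
  ann <- filter(refset$matures, .data$mature_id == !!mature_id)
  if (nrow(ann) == 0) abort(sprintf("unknown mature id '%s'", mature_id))
  ann <- ann[1, ]
  prec <- filter(refset$precursors, .data$precursor_id == ann$precursor_id)
  start <- ann$start + as.integer(delta5)
  end <- ann$end + as.integer(delta3)
  if (start < 0L || end > prec$length || start >= end) {
    abort(sprintf(
      "shifted interval [%d,%d) escapes precursor '%s' (length %d)",
      start, end, prec$precursor_id, prec$length))
  }
  tibble(
    mature_id = new_id %||%
      sprintf("%s_5p%+d_3p%+d", mature_id, delta5, delta3),
    precursor_id = ann$precursor_id,
    start = start, end = end, arm = ann$arm,
    sequence = substr(prec$sequence, start + 1L, end),
    ambiguous = FALSE
  )
}

#' Add mature annotations to a reference set
#'
#' Convenience for inserting rows such as the output of [shift_mature()].
#'
#' @param refset A [mir_reference()].
#' @param matures Tibble shaped like `refset$matures`.
#' @return A new `mir_reference`.
#' @export
add_matures <- function(refset, matures) {
  stopifnot(inherits(refset, "mir_reference"))
  mir_reference(refset$precursors,
                bind_rows(refset$matures, as_tibble(matures)))
}
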
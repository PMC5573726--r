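# Synthetic small-RNA read generator with exact ground-truth manifests.
#
# Reads are built mature by mature: sample a (offset5, offset3) pair, read the
# templated core off the precursor, append a sampled non-templated 3' suffix
# (NTA), then apply iid substitutions. Offsets, NTA and substitutions are
# sampled independently of each other; real libraries are likely to couple
# them (e.g. trimming and tailing by the same exonuclease/TUTase machinery),
# but independence keeps the ground truth exact and is sufficient for the
# class structures profiled here.

#' Describe an isomiR distribution for the read generator
#'
#' @param offset5_probs,offset3_probs Named numeric vectors mapping integer
#'   template offsets (names, e.g. `"-1"`, `"0"`, `"1"`) to probabilities;
#'   each must sum to 1. Positive offsets move downstream on the precursor, so
#'   `offset5 = +1` drops the annotated first nucleotide and `offset3 = +1`
#'   extends the 3' end by one templated nucleotide.
#' @param nta_probs Named numeric vector mapping non-templated 3' suffixes to
#'   probabilities; the empty suffix `""` must be included. The default puts
#'   most tailing mass on mono-uridylation, the dominant 3' addition in small
#'   RNA libraries.
#' @param substitution_rate Per-nucleotide substitution probability, in
#'   `[0, 0.05]`.
#' @param arm5p_fraction Probability that a read drawn for a precursor-keyed
#'   count comes from the 5p arm (ignored for mature-keyed counts).
#' @param protect_5p Substitutions are never placed in the first `protect_5p`
#'   read positions (default 8), keeping 5' ends and seeds exact; set to 0 to
#'   allow them anywhere.
#' @return An `isomir_distribution` list.
#' @examples
#' isomir_distribution(offset5_probs = c(`0` = 0.9, `1` = 0.1))
#' @export
isomir_distribution <- function(offset5_probs = c(`0` = 1),
                                offset3_probs = c(`0` = 1),
                                nta_probs = setNames(c(0.80, 0.15, 0.03, 0.02),
                                                     c("", "U", "UU", "A")),
                                substitution_rate = 0,
                                arm5p_fraction = 0.5,
                                protect_5p = 8L) {
  check_probs <- function(p, what) {
    if (is.null(names(p))) abort(sprintf("%s must be named", what))
    if (any(p < 0)) abort(sprintf("%s has negative probability", what))
    if (abs(sum(p) - 1) > 1e-9) {
      abort(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)))
    }
    p
  }
  offset5_probs <- check_probs(offset5_probs, "offset5_probs")
  offset3_probs <- check_probs(offset3_probs, "offset3_probs")
  nta_probs <- check_probs(nta_probs, "nta_probs")
  if (anyNA(suppressWarnings(as.integer(names(offset5_probs)))) ||
      anyNA(suppressWarnings(as.integer(names(offset3_probs))))) {
    abort("offset probability names must be integers")
  }
  nta_names <- names(nta_probs)[nchar(names(nta_probs)) > 0]
  if (length(nta_names) > 0 && any(grepl("[^ACGU]", chartr("T", "U", toupper(nta_names))))) {
    abort("nta suffixes must be RNA strings")
  }
  if (substitution_rate < 0 || substitution_rate > 0.05) {
    abort("substitution_rate must be in [0, 0.05]")
  }
  if (arm5p_fraction < 0 || arm5p_fraction > 1) {
    abort("arm5p_fraction must be in [0, 1]")
  }
  structure(list(
    offset5_probs = offset5_probs,
    offset3_probs = offset3_probs,
    nta_probs = nta_probs,
    substitution_rate = substitution_rate,
    arm5p_fraction = arm5p_fraction,
    protect_5p = as.integer(protect_5p)
  ), class = "isomir_distribution")
}

#' Configure a simulated small-RNA library
#'
#' @param counts Named integer vector of expected read counts. Names may be
#'   mature ids, or precursor ids, in which case the reads are split between
#'   that precursor's 5p and 3p matures with probability `arm5p_fraction`.
#' @param distribution An [isomir_distribution()], or a named list of them for
#'   per-miRNA overrides plus an optional `".default"` entry.
#' @param seed Integer seed; the whole simulation is a deterministic function
#'   of `(refset, config)`.
#' @param read_count_model `"exact"` (each entry of `counts` is hit exactly)
#'   or `"multinomial"` (the total is redistributed multinomially with
#'   `counts` as weights).
#' @param min_len Reads shorter than this are resampled (size selection);
#'   default 16 nt, matching the profiler's floor.
#' @return A `sim_config` list.
#' @export
sim_config <- function(counts,
                       distribution = isomir_distribution(),
                       seed = 1L,
                       read_count_model = c("exact", "multinomial"),
                       min_len = 16L) {
  if (is.null(names(counts)) || any(counts < 0) || sum(counts) <= 0) {
    abort("counts must be a named vector with non-negative values summing > 0")
  }
  read_count_model <- match.arg(read_count_model)
  if (inherits(distribution, "isomir_distribution")) {
    distribution <- list(.default = distribution)
  }
  if (!all(vapply(distribution, inherits, TRUE, "isomir_distribution"))) {
    abort("distribution must be one or more isomir_distribution objects")
  }
  structure(list(
    counts = counts,
    distribution = distribution,
    seed = as.integer(seed),
    read_count_model = read_count_model,
    min_len = as.integer(min_len)
  ), class = "sim_config")
}

dist_for <- function(config, mature_id) {
  config$distribution[[mature_id]] %||% config$distribution[[".default"]] %||%
    abort(sprintf("no distribution for mature '%s' and no .default", mature_id))
}

sample_named <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# Expand counts keyed by precursor id into per-mature counts via the arm
# fraction; mature-keyed entries pass through.
expand_counts <- function(refset, config) {
  counts <- config$counts
  out <- integer(0)
  bump <- function(tab, id, n) {
    tab[id] <- (if (id %in% names(tab)) tab[[id]] else 0L) + n
    tab
  }
  for (id in names(counts)) {
    n <- as.integer(counts[[id]])
    if (id %in% refset$matures$mature_id) {
      out <- bump(out, id, n)
    } else if (id %in% refset$precursors$precursor_id) {
      mats <- filter(refset$matures, .data$precursor_id == id)
      m5 <- filter(mats, .data$arm == "5p")
      m3 <- filter(mats, .data$arm == "3p")
      if (nrow(m5) == 0 || nrow(m3) == 0) {
        only <- if (nrow(m5) > 0) m5 else m3
        if (nrow(only) == 0) abort(sprintf("precursor '%s' has no matures", id))
        out <- bump(out, only$mature_id[1], n)
      } else {
        p5 <- dist_for(config, m5$mature_id[1])$arm5p_fraction
        n5 <- rbinom(1L, n, p5)
        out <- bump(out, m5$mature_id[1], n5)
        out <- bump(out, m3$mature_id[1], n - n5)
      }
    } else {
      abort(sprintf("count key '%s' is neither a mature nor a precursor id", id))
    }
  }
  if (config$read_count_model == "multinomial") {
    total <- sum(out)
    out <- setNames(as.integer(stats::rmultinom(1L, total, out)), names(out))
  }
  out[out > 0L]
}

#' Generate a synthetic read library with a ground-truth manifest
#'
#' Draws reads mature by mature: sample `(offset5, offset3)` from the
#' distribution, take the templated core `[start+offset5, end+offset3)` off
#' the precursor, append a sampled non-templated suffix, apply iid
#' substitutions outside the protected 5' window. Intervals that escape the
#' precursor (or fall below `min_len`) are resampled up to 100 times, then the
#' generator errors. The manifest records, per read, everything needed to
#' rebuild it exactly, in canonical maximally-templated coordinates: a
#' sampled tail base identical to the next templated base is recorded as a
#' templated 3' extension, since no read-based classifier can distinguish
#' the two.
#'
#' @param refset A [mir_reference()].
#' @param config A [sim_config()].
#' @return A list with `reads` (tibble `read_id`, `sequence`) and `manifest`
#'   (tibble `read_id`, `mature_id`, `arm`, `offset5`, `offset3`, `nta`,
#'   `sub_positions` (comma-joined 1-based read positions), `sequence`).
#' @examples
#' rs <- mir34_reference()
#' cfg <- sim_config(c(`hsa-miR-34b-5p` = 50), seed = 7)
#' sim <- simulate_reads(rs, cfg)
#' head(sim$manifest)
#' @export
simulate_reads <- function(refset, config) {
  stopifnot(inherits(refset, "mir_reference"), inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    per_mature <- expand_counts(refset, config)
    chunks <- purrr::imap(per_mature, function(n, mid) {
      simulate_for_mature(refset, config, mid, n)
    })
    manifest <- bind_rows(chunks)
    if (nrow(manifest) == 0) abort("configuration produced no reads")
    # stable read ids over the whole library
    manifest$read_id <- sprintf("read_%06d", seq_len(nrow(manifest)))
    list(
      reads = tibble(read_id = manifest$read_id,
                     sequence = manifest$sequence),
      manifest = manifest[, c("read_id", "mature_id", "arm", "offset5",
                              "offset3", "nta", "sub_positions", "sequence")]
    )
  })
}

simulate_for_mature <- function(refset, config, mature_id, n) {
  ann <- filter(refset$matures, .data$mature_id == !!mature_id)[1, ]
  prec <- filter(refset$precursors, .data$precursor_id == ann$precursor_id)
  dist <- dist_for(config, mature_id)
  L <- prec$length

  o5 <- as.integer(sample_named(n, dist$offset5_probs))
  o3 <- as.integer(sample_named(n, dist$offset3_probs))
  ok <- function(a, b) ann$start + a >= 0L & ann$end + b <= L &
    (ann$end + b) - (ann$start + a) >= config$min_len
  tries <- 0L
  bad <- !ok(o5, o3)
  while (any(bad) && tries < 100L) {
    o5[bad] <- as.integer(sample_named(sum(bad), dist$offset5_probs))
    o3[bad] <- as.integer(sample_named(sum(bad), dist$offset3_probs))
    bad <- !ok(o5, o3)
    tries <- tries + 1L
  }
  if (any(bad)) {
    abort(sprintf(
      "offsets for '%s' kept escaping precursor bounds after 100 resamples",
      mature_id))
  }

  core <- substr(rep(prec$sequence, n), ann$start + o5 + 1L, ann$end + o3)
  nta <- sample_named(n, dist$nta_probs)
  seqs <- paste0(core, nta)

  # Canonicalize: a sampled tail prefix that aligns to the template at least
  # as well as it scores as an NTA is indistinguishable from a templated 3'
  # extension, so the manifest records the maximally-templated coordinates
  # (what any read-based classifier scoring templated_len - 2*mismatches,
  # with NTA minimized on ties, must report). A tail base absorbed over a
  # template mismatch is recorded as a substitution.
  pchars <- seq_chars(prec$sequence)[[1]]
  sub_positions <- character(n)
  for (i in seq_len(n)) {
    t <- nta[i]
    if (nchar(t) == 0L) next
    end0 <- ann$end + o3[i]  # 0-based exclusive end = next template index
    emax <- min(nchar(t), L - end0)
    if (emax <= 0L) next
    tch <- strsplit(t, "", fixed = TRUE)[[1]]
    mm <- 0L
    mism <- integer(0)
    best_e <- 0L
    best_sc <- 0L
    best_mism <- integer(0)
    for (e in seq_len(emax)) {
      if (tch[e] != pchars[end0 + e]) {
        mm <- mm + 1L
        mism <- c(mism, e)
      }
      sc <- e - 2L * mm
      if (sc >= best_sc) {  # ties resolve to the longer templated form
        best_sc <- sc
        best_e <- e
        best_mism <- mism
      }
    }
    if (best_e > 0L) {
      core_len <- end0 - (ann$start + o5[i])
      if (length(best_mism) > 0L) {
        sub_positions[i] <- paste(core_len + best_mism, collapse = ",")
      }
      o3[i] <- o3[i] + best_e
      nta[i] <- substr(t, best_e + 1L, nchar(t))
    }
  }

  if (dist$substitution_rate > 0) {
    for (i in seq_len(n)) {
      k <- nchar(core[i])
      eligible <- seq_len(k)
      eligible <- eligible[eligible > dist$protect_5p]
      if (length(eligible) == 0) next
      hit <- eligible[runif(length(eligible)) < dist$substitution_rate]
      if (length(hit) == 0) next
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      for (p in hit) ch[p] <- sample(setdiff(RNA_BASES, ch[p]), 1L)
      seqs[i] <- paste(ch, collapse = "")
      prior <- if (sub_positions[i] == "") integer(0) else
        as.integer(strsplit(sub_positions[i], ",", fixed = TRUE)[[1]])
      sub_positions[i] <- paste(sort(c(prior, hit)), collapse = ",")
    }
  }

  tibble(mature_id = mature_id, arm = ann$arm,
         offset5 = o5, offset3 = o3, nta = nta,
         sub_positions = sub_positions, sequence = seqs)
}

#' Exact isomiR class tallies of a truth manifest
#'
#' Aggregates a generator manifest by `(mature_id, offset5, offset3, nta)`,
#' the oracle against which profiler output is compared in substitution-free
#' recovery tests.
#'
#' @param manifest The `manifest` tibble from [simulate_reads()].
#' @return Tibble `mature_id`, `arm`, `offset5`, `offset3`, `nta`, `count`,
#'   sorted by decreasing count within mature.
#' @export
truth_summary <- function(manifest) {
  if (is.null(manifest) || nrow(manifest) == 0) abort("empty manifest")
  manifest |>
    count(.data$mature_id, .data$arm, .data$offset5, .data$offset3,
          .data$nta, name = "count") |>
    arrange(.data$mature_id, desc(.data$count))
}

#' Simulate iid uniform random 3'UTR sequences
#'
#' @param n Number of UTRs.
#' @param length UTR length in nt.
#' @param seed Integer seed.
#' @return Named character vector (`utr_0001`, ...) of RNA sequences with
#'   iid uniform nucleotides.
#' @export
simulate_utrs <- function(n = 500L, length = 1000L, seed = 1L) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(RNA_BASES, length, replace = TRUE), collapse = "")
    }, character(1))
    setNames(seqs, sprintf("utr_%04d", seq_len(n)))
  })
}

#' Write simulated reads to FASTA or FASTQ
#'
#' @param reads Tibble with `read_id`, `sequence` (e.g. from
#'   [simulate_reads()]).
#' @param path Output file.
#' @param format `"fasta"` (default) or `"fastq"` (constant quality `I`).
#' @param alphabet `"rna"` (U, default) or `"dna"` (T).
#' @return The path, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq"),
                        alphabet = c("rna", "dna")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  seqs <- setNames(reads$sequence, reads$read_id)
  if (format == "fasta") write_fasta(seqs, path, alphabet)
  else write_fastq(seqs, path, alphabet)
  invisible(path)
}

#' Write a truth manifest as TSV
#'
#' @param manifest Manifest tibble from [simulate_reads()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(path)
}
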
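# End-to-end pipeline wrappers: simulate -> profile -> audit -> targets, each
# writing its outputs under a run directory. These functions back the
# `inst/cli/seedshift` command-line wrapper; all logic lives here.

run_metadata <- function(out_dir, params) {
  meta <- list(
    package = "seedshift",
    version = as.character(packageVersion("seedshift")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(meta)
}

#' Simulate one or more read libraries and write them to disk
#'
#' @param refset A [mir_reference()].
#' @param configs A [sim_config()] or a named list of them (names become
#'   library ids).
#' @param out_dir Output directory (created if needed).
#' @param format `"fasta"` or `"fastq"`.
#' @return Invisibly, a tibble with `library_id`, `reads_path`,
#'   `manifest_path`, `n_reads`.
#' @export
run_simulate <- function(refset, configs, out_dir, format = "fasta") {
  if (inherits(configs, "sim_config")) configs <- list(library = configs)
  if (is.null(names(configs))) abort("configs must be a named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "fasta") "fa" else "fq"
  rows <- purrr::imap(configs, function(cfg, id) {
    sim <- simulate_reads(refset, cfg)
    reads_path <- file.path(out_dir, sprintf("%s.%s", id, ext))
    manifest_path <- file.path(out_dir, sprintf("%s.manifest.tsv", id))
    write_reads(sim$reads, reads_path, format = format)
    write_manifest(sim$manifest, manifest_path)
    inform(sprintf("[simulate] %s: %d reads -> %s", id, nrow(sim$reads),
                   reads_path))
    tibble(library_id = id, reads_path = reads_path,
           manifest_path = manifest_path, n_reads = nrow(sim$reads))
  }) |> bind_rows()
  run_metadata(out_dir, list(
    step = "simulate", format = format,
    libraries = purrr::map(configs, function(cfg) {
      list(seed = cfg$seed, read_count_model = cfg$read_count_model,
           total_reads = sum(cfg$counts))
    })
  ))
  invisible(rows)
}

#' Profile and audit one or more read libraries
#'
#' For each library: map and classify the reads, write the class-level profile
#' TSV and a logo matrix per audited mature, audit every annotation, and write
#' the combined audit report (JSON + TSV + markdown). Read counts, unmapped
#' and ambiguous fractions are logged.
#'
#' @param refset A [mir_reference()] (or pass `hairpin_path`/`mature_path`).
#' @param reads Named list/vector of read inputs (paths or tibbles); names
#'   become library ids.
#' @param out_dir Output directory.
#' @param hairpin_path,mature_path,gff_path Alternative to `refset`: build the
#'   reference from files.
#' @param mature_ids Matures to audit and render logos for (default: all).
#' @param ... Passed to [profile_reads()] and [audit_library()]
#'   (`max_mismatches`, `max_nta`, `min_templated`, `min_depth`,
#'   `dominance_threshold`, `spec`).
#' @return Invisibly, a named list of `mir_audit` objects.
#' @export
run_audit <- function(refset = NULL, reads, out_dir,
                      hairpin_path = NULL, mature_path = NULL,
                      gff_path = NULL, mature_ids = NULL, ...) {
  if (is.null(refset)) {
    if (is.null(hairpin_path) || is.null(mature_path)) {
      abort("supply refset, or hairpin_path and mature_path")
    }
    refset <- read_references(hairpin_path, mature_path, gff_path)
  }
  if (is.null(names(reads))) abort("reads must be named by library id")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dots <- list(...)
  prof_args <- dots[names(dots) %in% c("max_mismatches", "max_nta",
                                       "min_templated")]
  audit_args <- dots[names(dots) %in% c("min_depth", "dominance_threshold",
                                        "spec")]
  ids <- mature_ids %||% refset$matures$mature_id

  audits <- purrr::imap(as.list(reads), function(rd, lib) {
    prof <- do.call(profile_reads,
                    c(list(reads = rd, refset = refset, library_id = lib),
                      prof_args))
    inform(sprintf(
      "[audit] %s: %d mapped, %d unmapped, %d filtered, %.2f%% ambiguous",
      lib, prof$total_mapped, prof$n_unmapped, prof$n_filtered,
      100 * prof$ambiguous_fraction))
    write_profile(prof, file.path(out_dir, sprintf("%s.profile.tsv", lib)))
    for (mid in ids) {
      if (mature_depth(prof, mid) > 0) {
        write_logo(logo_matrix(prof, refset, mid),
                   file.path(out_dir, sprintf("%s.%s.logo.tsv", lib,
                                              gsub("[^A-Za-z0-9._-]", "_", mid))))
      }
    }
    do.call(audit_library,
            c(list(profile = prof, refset = refset, mature_ids = ids),
              audit_args))
  })
  files <- audit_report(audits, out_dir)
  if (attr(files, "any_seed_shifted")) {
    inform("[audit] seed-shifted annotation(s) detected")
  }
  run_metadata(out_dir, c(list(step = "audit", libraries = names(reads)),
                          dots))
  invisible(audits)
}

#' Scan UTRs and compare two isoform target repertoires
#'
#' Writes a BED-like site TSV (`utr_id`, `start`, `end`, `site_type`,
#' `isoform`) and an overlap-statistics JSON.
#'
#' @param utrs UTR sequences or FASTA path.
#' @param mature_a,mature_b The two isoform sequences.
#' @param out_dir Output directory.
#' @param site_type Site type for the overlap comparison.
#' @return Invisibly, the overlap tibble.
#' @export
run_targets <- function(utrs, mature_a, mature_b, out_dir,
                        site_type = "site_6mer_2_7") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ov <- isoform_target_overlap(utrs, mature_a, mature_b,
                               site_type = site_type)
  sites <- bind_rows(
    mutate(attr(ov, "sites_a"), isoform = "a"),
    mutate(attr(ov, "sites_b"), isoform = "b")
  )
  readr::write_tsv(
    select(sites, "utr_id", "start", "end", "site_type", "isoform"),
    file.path(out_dir, "sites.tsv"))
  jsonlite::write_json(
    c(list(schema = "seedshift-overlap/1",
           mature_a = as_rna(mature_a), mature_b = as_rna(mature_b)),
      as.list(ov)),
    file.path(out_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
  inform(sprintf(
    "[targets] %d vs %d sites; retention_a_in_b = %.3f",
    ov$n_sites_a, ov$n_sites_b, ov$retention_a_in_b))
  run_metadata(out_dir, list(step = "targets", site_type = site_type))
  invisible(ov)
}
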
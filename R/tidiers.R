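# broom-style tidiers so profiles, audits and logos drop into dplyr chains.

#' Tidy an isomiR profile into its class table
#'
#' @param x An [profile_reads()] result.
#' @param ... Unused.
#' @return Tibble of isomiR classes with `library_id` prepended.
#' @export
tidy.isomir_profile <- function(x, ...) {
  mutate(x$classes, library_id = x$library_id, .before = 1)
}

#' One-row summary of an isomiR profile
#'
#' @param x An [profile_reads()] result.
#' @param ... Unused.
#' @return Tibble with mapping totals and the ambiguous fraction.
#' @export
glance.isomir_profile <- function(x, ...) {
  tibble(
    library_id = x$library_id,
    total_mapped = x$total_mapped,
    n_unmapped = x$n_unmapped,
    n_filtered = x$n_filtered,
    ambiguous_fraction = x$ambiguous_fraction,
    n_matures = dplyr::n_distinct(x$classes$mature_id),
    n_classes = nrow(x$classes)
  )
}

#' Tidy an annotation audit into its verdict table
#'
#' @param x An [audit_library()] result.
#' @param ... Unused.
#' @return The verdict tibble with `library_id` prepended.
#' @export
tidy.mir_audit <- function(x, ...) {
  mutate(x$verdicts, library_id = x$library_id, .before = 1)
}

#' One-row summary of an annotation audit
#'
#' @param x An [audit_library()] result.
#' @param ... Unused.
#' @return Tibble counting verdicts by category.
#' @export
glance.mir_audit <- function(x, ...) {
  v <- x$verdicts$verdict
  tibble(
    library_id = x$library_id,
    n_audited = length(v),
    n_concordant = sum(v == "concordant"),
    n_seed_shifted = sum(v == "seed_shifted"),
    n_three_prime_variant_only = sum(v == "three_prime_variant_only"),
    n_low_coverage = sum(v == "low_coverage")
  )
}

#' Tidy a logo matrix into long position-probability form
#'
#' @param x A [logo_matrix()] result.
#' @param ... Unused.
#' @return Tibble `position` (0-based precursor coordinate), `base`,
#'   `probability`, `support`.
#' @export
tidy.logo_matrix <- function(x, ...) {
  pos <- as.integer(colnames(x$matrix))
  tidyr::expand_grid(position = pos, base = rownames(x$matrix)) |>
    mutate(probability = purrr::map2_dbl(
      .data$base, match(.data$position, pos),
      function(b, j) x$matrix[b, j]),
      support = x$support[match(.data$position, pos)])
}
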
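# Preset simulation conditions.
#
# These encode, as generator parameters, the measured structure of the small
# RNA libraries the package's worked example is about (miR-34 family in
# MDA-MB-231 and related cell lines):
#
# * mimic library: miR-34b-mimic-transfected cells. Of the miR-34b-5p reads,
#   22.4% are identical to the mimic, 17.9% carry a +U tail and 19.4% lack
#   four 3' nucleotides; the rest lack 1-3 nt and/or combine truncation with
#   tailing. Under the generator's independence of offset3 and NTA, the
#   marginals below reproduce those joint fractions analytically:
#   P(offset3 = 0) = 0.403 and P(nta = "U") = 0.4442 give
#   0.403 x 0.5558 = 0.224, 0.403 x 0.4442 = 0.179, and with
#   P(offset3 = -4) = 0.349, 0.349 x 0.5558 = 0.194.
#   The transfection itself is represented by flooding the library with
#   miR-34b-5p at a level 830-fold (in RPM) over the control.
#
# * control library: endogenous expression, with miR-34c at 342 reads vs
#   miR-34b at 19, split 5p/3p as observed (99.7% and ~76% 5p).
#
# * endogenous miR-34b condition: the dominant endogenous form carries a
#   +1/+1 template shift (the 5'-shifted isoform); ~97% of reads share its 5'
#   start, under 2% start at the annotated position, and 3' ends are
#   heterogeneous.

#' Preset isomiR distribution of a miR-34b mimic-transfected library
#'
#' @return An [isomir_distribution()] with canonical 5' ends, the measured
#'   3'-truncation spectrum, and a uridylation-dominated tail table (see the
#'   source for the analytic derivation of the marginals).
#' @export
mimic_34b_distribution <- function() {
  isomir_distribution(
    offset5_probs = c(`0` = 1),
    offset3_probs = c(`0` = 0.403, `-1` = 0.0827, `-2` = 0.0827,
                      `-3` = 0.0826, `-4` = 0.349),
    nta_probs = setNames(c(0.5558, 0.4442), c("", "U")),
    substitution_rate = 0,
    arm5p_fraction = 1
  )
}

#' Preset isomiR distribution of the endogenous shifted miR-34b-5p form
#'
#' Reads start one nucleotide downstream of the annotated 5' end (the
#' seed-shifting +1 offset) with ~97% dominance, extend one templated
#' nucleotide at the 3' end as the modal form, and show heterogeneous 3'
#' termini with mostly-U tails.
#'
#' @return An [isomir_distribution()].
#' @export
endogenous_34b_distribution <- function() {
  isomir_distribution(
    offset5_probs = c(`1` = 0.97, `0` = 0.015, `2` = 0.015),
    offset3_probs = c(`1` = 0.80, `0` = 0.10, `-1` = 0.05, `-2` = 0.05),
    nta_probs = setNames(c(0.85, 0.12, 0.02, 0.01), c("", "U", "UU", "A")),
    substitution_rate = 0,
    arm5p_fraction = 0.76
  )
}

#' Preset library configurations for the miR-34 worked example
#'
#' Two deterministic-count library configurations over [mir34_reference()]:
#'
#' * `control`: endogenous levels - 342 miR-34c reads (341 on the 5p arm,
#'   99.7%) vs 19 miR-34b reads (14 on the 5p arm, the closest realizable
#'   split to the observed 76% at this depth), topped up with canonical
#'   miR-34a-5p reads to 20,000. The miR-34b-5p reads follow
#'   [endogenous_34b_distribution()], i.e. the 5'-shifted form.
#' * `mimic`: miR-34b-5p flooded to 11,620 of 20,000 reads, exactly 830-fold
#'   the control's 14/20,000 in RPM, with the mimic class structure from
#'   [mimic_34b_distribution()].
#'
#' @param seed Integer seed (the two libraries use `seed` and `seed + 1`).
#' @return Named list of two [sim_config()] objects (`control`, `mimic`).
#' @export
mir34_study_configs <- function(seed = 1L) {
  canonical <- isomir_distribution()  # default: mild 3' tailing only
  control <- sim_config(
    counts = c(`hsa-miR-34a-5p` = 19639L,
               `hsa-miR-34b-5p` = 14L, `hsa-miR-34b-3p` = 5L,
               `hsa-miR-34c-5p` = 341L, `hsa-miR-34c-3p` = 1L),
    distribution = list(.default = canonical,
                        `hsa-miR-34b-5p` = endogenous_34b_distribution()),
    seed = seed,
    read_count_model = "exact"
  )
  mimic <- sim_config(
    counts = c(`hsa-miR-34a-5p` = 8380L, `hsa-miR-34b-5p` = 11620L),
    distribution = list(.default = canonical,
                        `hsa-miR-34b-5p` = mimic_34b_distribution()),
    seed = seed + 1L,
    read_count_model = "exact"
  )
  list(control = control, mimic = mimic)
}
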
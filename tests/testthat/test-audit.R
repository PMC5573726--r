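no_tail <- function() setNames(1, "")

shifted_dist <- function(p) {
  # mixture of the +1/+1-shifted form (probability p) and the canonical form
  isomir_distribution(
    offset5_probs = c(`1` = p, `0` = 1 - p),
    offset3_probs = c(`1` = p, `0` = 1 - p),
    nta_probs = no_tail())
}

test_that("dominant calls report support fractions and modal offsets", {
  rs <- mir34_reference()
  ann <- dplyr::filter(rs$matures, mature_id == "hsa-miR-34b-5p")
  shifted <- shift_mature(rs, "hsa-miR-34b-5p", 1, 1)$sequence
  reads <- c(rep(ann$sequence, 5), rep(shifted, 95))
  p <- profile_reads(setNames(reads, sprintf("r%03d", seq_along(reads))), rs)
  dom <- dominant_sequence(p, "hsa-miR-34b-5p")
  expect_equal(dom$dominant_sequence, shifted)
  expect_equal(dom$support_fraction_full, 0.95)
  expect_equal(dom$support_fraction_5p_end, 0.95)
  expect_gte(dom$support_fraction_5p_end, dom$support_fraction_full)
  expect_equal(dom$modal_offset5, 1)
  expect_equal(dom$modal_offset3, 1)
  expect_equal(dom$read_depth, 100)

  # exact tie: lexicographically smallest sequence wins
  reads2 <- c(rep(ann$sequence, 5), rep(shifted, 5))
  p2 <- profile_reads(setNames(reads2, sprintf("r%03d", seq_along(reads2))), rs)
  dom2 <- dominant_sequence(p2, "hsa-miR-34b-5p")
  expect_equal(dom2$dominant_sequence,
               sort(c(ann$sequence, shifted))[1])
  expect_error(dominant_sequence(p2, "hsa-miR-34a-5p"), "no reads")
})

test_that("audits separate concordant, shifted and low-coverage annotations", {
  rs <- mir34_reference()
  ann <- dplyr::filter(rs$matures, mature_id == "hsa-miR-34b-5p")

  # all-canonical library
  reads <- setNames(rep(ann$sequence, 50), sprintf("r%03d", 1:50))
  v <- audit_mature(profile_reads(reads, rs), rs, "hsa-miR-34b-5p")
  expect_equal(v$verdict, "concordant")
  expect_equal(v$shift5, 0)
  expect_equal(v$fraction_matching_annotation, 1.0)
  expect_equal(v$observed_seed, v$annotated_seed)

  # library dominated by the +1/+1 variant
  sim <- simulate_reads(rs, sim_config(c(`hsa-miR-34b-5p` = 500),
                                       distribution = shifted_dist(0.9),
                                       seed = 61))
  v2 <- audit_mature(profile_reads(sim$reads, rs), rs, "hsa-miR-34b-5p")
  expect_equal(v2$verdict, "seed_shifted")
  expect_equal(v2$shift5, 1)
  expect_false(v2$observed_seed == v2$annotated_seed)
  expect_equal(v2$observed_seed_2_8,
               extract_seed(dplyr::filter(rs$matures,
                 mature_id == "hsa-miR-34a-5p")$sequence, "seed_2_8"))

  # depth below min_depth
  few <- setNames(rep(ann$sequence, 5), paste0("r", 1:5))
  v3 <- audit_mature(profile_reads(few, rs), rs, "hsa-miR-34b-5p",
                     min_depth = 10)
  expect_equal(v3$verdict, "low_coverage")

  # zero depth
  v4 <- audit_mature(profile_reads(few, rs), rs, "hsa-miR-34c-5p")
  expect_equal(v4$verdict, "low_coverage")
  expect_equal(v4$observed_seed, "")
  expect_equal(v4$read_depth, 0)
})

test_that("3'-only variation is not called a seed shift", {
  rs <- mir34_reference()
  dist <- isomir_distribution(offset3_probs = c(`-2` = 0.7, `0` = 0.3),
                              nta_probs = no_tail())
  sim <- simulate_reads(rs, sim_config(c(`hsa-miR-34b-5p` = 300),
                                       distribution = dist, seed = 62))
  v <- audit_mature(profile_reads(sim$reads, rs), rs, "hsa-miR-34b-5p")
  expect_equal(v$verdict, "three_prime_variant_only")
  expect_equal(v$shift5, 0)
})

test_that("audit verdict tracks the shifted-fraction mixture", {
  rs <- mir34_reference()
  for (seed in c(71, 72)) {
    for (p in c(0.2, 0.95)) {
      sim <- simulate_reads(rs, sim_config(c(`hsa-miR-34b-5p` = 400),
                                           distribution = shifted_dist(p),
                                           seed = seed))
      v <- audit_mature(profile_reads(sim$reads, rs), rs, "hsa-miR-34b-5p")
      if (p > 0.5) expect_equal(v$verdict, "seed_shifted")
      else expect_equal(v$verdict, "concordant")
    }
  }
})

test_that("verdicts are invariant under read order permutation", {
  rs <- mir34_reference()
  sim <- simulate_reads(rs, sim_config(c(`hsa-miR-34b-5p` = 200),
                                       distribution = shifted_dist(0.8),
                                       seed = 63))
  v1 <- audit_mature(profile_reads(sim$reads, rs), rs, "hsa-miR-34b-5p")
  shuffled <- sim$reads[withr::with_seed(1, sample(nrow(sim$reads))), ]
  v2 <- audit_mature(profile_reads(shuffled, rs), rs, "hsa-miR-34b-5p")
  expect_equal(v1, v2)
})

test_that("family seed checks compare against the modal annotated seed", {
  rs <- mir34_reference()
  sim <- simulate_reads(rs, sim_config(c(`hsa-miR-34b-5p` = 200),
                                       distribution = shifted_dist(0.97),
                                       seed = 64))
  audit <- audit_library(profile_reads(sim$reads, rs), rs,
                         mature_ids = "hsa-miR-34b-5p")
  fam <- dplyr::filter(rs$matures,
                       mature_id %in% c("hsa-miR-34a-5p", "hsa-miR-34b-5p",
                                        "hsa-miR-34c-5p"))
  checked <- family_seed_check(audit, fam)
  # the shifted miR-34b-5p seed equals the modal (miR-34a/c) family seed
  expect_true(checked$verdicts$family_seed_match)

  # a family whose members all disagree never matches
  fake <- rs$matures[1:2, ]
  fake$sequence <- c("UUUUUUUUUUUUUUUUUUUUUU", "ACACACACACACACACACACAC")
  checked2 <- family_seed_check(audit, fake)
  expect_false(checked2$verdicts$family_seed_match)

  # single-member family: undefined
  expect_warning(checked3 <- family_seed_check(audit, fam[1, ]), "fewer than 2")
  expect_true(is.na(checked3$verdicts$family_seed_match))
})

test_that("concordance fractions distinguish full and 5'-end matching", {
  rs <- mir34_reference()
  ann <- dplyr::filter(rs$matures, mature_id == "hsa-miR-34b-5p")
  cand <- ann$sequence
  # 95 exact + 5 shifted
  reads <- c(rep(cand, 95), rep(shift_mature(rs, "hsa-miR-34b-5p", 1, 1)$sequence, 5))
  p <- profile_reads(setNames(reads, sprintf("r%03d", seq_along(reads))), rs)
  expect_equal(concordance_fraction(p, rs, "hsa-miR-34b-5p", cand,
                                    "full_sequence"), 0.95)

  # all reads shifted: nothing matches the annotation
  p2 <- profile_reads(setNames(rep(reads[100], 20), paste0("r", 1:20)), rs)
  expect_equal(concordance_fraction(p2, rs, "hsa-miR-34b-5p", cand,
                                    "full_sequence"), 0)

  # mixed 3' ends sharing the candidate's 5' start
  reads3 <- c(rep(cand, 6), rep(substr(cand, 1, 19), 4))
  p3 <- profile_reads(setNames(reads3, paste0("r", 1:10)), rs)
  expect_equal(concordance_fraction(p3, rs, "hsa-miR-34b-5p", cand,
                                    "five_prime_end"), 1.0)
  expect_lt(concordance_fraction(p3, rs, "hsa-miR-34b-5p", cand,
                                 "full_sequence"), 1.0)
  expect_error(concordance_fraction(p3, rs, "hsa-miR-34b-5p",
                                    strrep("A", 20)), "placed")
})

test_that("audit reports serialize verdicts to JSON, TSV and markdown", {
  rs <- mir34_reference()
  sim <- simulate_reads(rs, sim_config(c(`hsa-miR-34b-5p` = 100),
                                       distribution = shifted_dist(0.97),
                                       seed = 65))
  audit <- audit_library(profile_reads(sim$reads, rs), rs)
  out <- withr::local_tempdir()
  files <- audit_report(audit, out)
  expect_true(all(file.exists(files)))
  expect_true(attr(files, "any_seed_shifted"))
  js <- jsonlite::read_json(files[["json"]])
  verdicts <- vapply(js$verdicts, function(v) v$verdict, character(1))
  expect_true("seed_shifted" %in% verdicts)
  expect_equal(js$match_modes$fraction_matching_annotation, "five_prime_end")
  md <- readLines(files[["md"]])
  expect_true(any(grepl("seed shift", md)))
  expect_error(audit_report(list(), out), "mir_audit")

  gl <- glance(audit)
  expect_equal(gl$n_seed_shifted, 1)
  expect_equal(gl$n_audited, 6)
  expect_equal(nrow(tidy(audit)), 6)
})
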
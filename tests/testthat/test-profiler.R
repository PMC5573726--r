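no_tail <- function() setNames(1, "")

test_that("exact substrings map ungapped with no mismatches or NTA", {
  rs <- toy_reference()
  read <- substr(rs$precursors$sequence[1], 11, 32)
  aln <- map_reads(c(r1 = read), rs)
  expect_true(aln$mapped)
  expect_equal(aln$precursor_id, "hpA")
  expect_equal(aln$tstart, 10)
  expect_equal(aln$tend, 32)
  expect_equal(aln$n_mismatch, 0)
  expect_equal(aln$nta, "")
  expect_false(aln$ambiguous)
})

test_that("a 3' U over a templated C is reported as NTA, not a mismatch", {
  rs <- toy_reference()  # base after matA on hpA is C
  read <- paste0(rs$matures$sequence[1], "U")
  aln <- map_reads(setNames(read, "r1"), rs)
  expect_equal(aln$tstart, 10)
  expect_equal(aln$tend, 32)   # templated interval unchanged
  expect_equal(aln$nta, "U")
  expect_equal(aln$n_mismatch, 0)
})

test_that("mapper agrees with the exhaustive enumeration oracle", {
  rs <- random_reference(n_prec = 2, len = 60, seed = 11)
  reads <- random_reads(rs, n = 50, seed = 12)
  aln <- map_reads(reads, rs)
  for (i in seq_along(reads)) {
    oracle <- oracle_map(reads[i], rs)
    row <- aln[i, ]
    if (is.null(oracle)) {
      expect_false(row$mapped)
    } else {
      expect_true(row$mapped)
      expect_equal(row$precursor_id, oracle$precursor_id)
      expect_equal(row$tstart, oracle$tstart)
      expect_equal(row$tend, oracle$tend)
      expect_equal(row$n_mismatch, oracle$n_mismatch)
      expect_equal(row$nta, oracle$nta)
      expect_equal(row$score, oracle$score)
      expect_equal(row$ambiguous, oracle$ambiguous)
    }
  }
})

test_that("identical precursors yield ambiguous assignments, counted once", {
  m <- "ACGUACGUACGUACGUACGUAC"
  p <- paste0("GGGGGCCCCC", m, "CAAAAGGGGGCCCCCAAAAA")
  rs <- mir_reference(c(hpA = p, hpB = p), data.frame(
    mature_id = c("mA", "mB"), sequence = c(m, m),
    precursor_id = c("hpA", "hpB"), start = 10L, end = 32L,
    arm = "5p"))
  aln <- map_reads(c(r1 = m), rs)
  expect_equal(nrow(aln), 1)        # counted once
  expect_equal(aln$precursor_id, "hpA")  # lexicographically smallest wins
  expect_true(aln$ambiguous)
})

test_that("the reconstruction rule holds for every mapped read", {
  rs <- mir34_reference()
  dist <- isomir_distribution(offset5_probs = c(`0` = 0.6, `1` = 0.4),
                              substitution_rate = 0.02)
  sim <- simulate_reads(rs, sim_config(c(`hsa-miR-34b-5p` = 150,
                                         `hsa-miR-34a-3p` = 150),
                                       distribution = dist, seed = 21))
  aln <- map_reads(sim$reads, rs)
  prec <- setNames(rs$precursors$sequence, rs$precursors$precursor_id)
  mapped <- aln[aln$mapped, ]
  for (i in seq_len(nrow(mapped))) {
    r <- mapped[i, ]
    templ <- strsplit(substr(prec[r$precursor_id], r$tstart + 1, r$tend),
                      "")[[1]]
    rch <- strsplit(r$sequence, "")[[1]]
    k <- r$tend - r$tstart
    if (r$mismatch_positions != "") {
      mpos <- as.integer(strsplit(r$mismatch_positions, ",")[[1]])
      templ[mpos - r$tstart + 1] <- rch[mpos - r$tstart + 1]
    }
    expect_equal(paste0(paste(templ, collapse = ""), r$nta), r$sequence)
    expect_lte(nchar(r$nta), 3)
    expect_gte(k, 16)
  }
})

test_that("classification recovers canonical, shifted and truncated reads", {
  rs <- mir34_reference()
  ann <- dplyr::filter(rs$matures, mature_id == "hsa-miR-34b-5p")
  reads <- c(
    canonical = ann$sequence,
    shifted = shift_mature(rs, "hsa-miR-34b-5p", 1, 1)$sequence,
    trunc4 = substr(ann$sequence, 1, nchar(ann$sequence) - 4)
  )
  calls <- classify_isomirs(map_reads(reads, rs), rs)
  expect_equal(calls$mature_id, rep("hsa-miR-34b-5p", 3))
  expect_equal(calls$offset5, c(0, 1, 0))
  expect_equal(calls$offset3, c(0, 1, -4))
  expect_equal(calls$nta, c("", "", ""))
  expect_equal(calls$arm, rep("5p", 3))
})

test_that("profiles count, normalize and conserve reads", {
  rs <- toy_reference()
  reads <- c(r1 = rs$matures$sequence[1], r2 = rs$matures$sequence[1],
             r3 = rs$matures$sequence[2], r4 = rs$matures$sequence[2])
  p <- profile_reads(reads, rs)
  expect_equal(p$total_mapped, 4)
  expect_equal(sort(p$classes$count), c(2, 2))
  expect_equal(unique(p$classes$rpm), 500000)
  expect_equal(sum(p$classes$rpm), 1e6)

  # one unmappable read among mapped ones is tallied, not dropped silently
  reads2 <- c(reads, bad = strrep("A", 20))
  p2 <- profile_reads(reads2, rs)
  expect_equal(p2$total_mapped, 4)
  expect_equal(p2$n_unmapped, 1)
  expect_equal(sum(p2$classes$count), p2$total_mapped)

  # reads below the length floor are filtered before mapping
  expect_message(p3 <- profile_reads(c(reads, tiny = "ACGUACGU"), rs),
                 "shorter")
  expect_equal(p3$n_filtered, 1)
  expect_error(profile_reads(character(0), rs), "no reads")
})

test_that("profiler output equals the truth manifest on clean simulations", {
  rs <- mir34_reference()
  for (seed in c(31, 32)) {
    dist <- isomir_distribution(
      offset5_probs = c(`0` = 0.5, `1` = 0.4, `-1` = 0.1),
      offset3_probs = c(`0` = 0.5, `1` = 0.2, `-2` = 0.2, `-4` = 0.1),
      substitution_rate = 0)
    sim <- simulate_reads(rs, sim_config(
      c(`hsa-miR-34b-5p` = 400, `hsa-miR-34c-5p` = 300,
        `hsa-miR-34a-3p` = 200), distribution = dist, seed = seed))
    prof <- profile_reads(sim$reads, rs)
    got <- dplyr::count(prof$classes, mature_id, offset5, offset3, nta,
                        wt = count, name = "count")
    want <- dplyr::select(truth_summary(sim$manifest), -arm)
    joined <- dplyr::full_join(got, want,
                               by = c("mature_id", "offset5", "offset3", "nta"),
                               suffix = c("_prof", "_truth"))
    expect_false(anyNA(joined))
    expect_equal(joined$count_prof, joined$count_truth)
  }
})

test_that("substitutions perturb class counts by at most the substituted reads", {
  rs <- mir34_reference()
  dist <- isomir_distribution(substitution_rate = 0.01, nta_probs = no_tail())
  sim <- simulate_reads(rs, sim_config(c(`hsa-miR-34b-5p` = 1000),
                                       distribution = dist, seed = 33))
  n_sub <- sum(sim$manifest$sub_positions != "")
  prof <- profile_reads(sim$reads, rs)
  got <- dplyr::count(prof$classes, mature_id, offset5, offset3, nta,
                      wt = count, name = "count")
  want <- dplyr::select(truth_summary(sim$manifest), -arm)
  joined <- dplyr::full_join(got, want,
                             by = c("mature_id", "offset5", "offset3", "nta"),
                             suffix = c("_prof", "_truth"))
  dev <- abs(tidyr::replace_na(joined$count_prof, 0) -
               tidyr::replace_na(joined$count_truth, 0))
  expect_true(all(dev <= n_sub))
})

test_that("arm fractions and fold changes follow the class counts", {
  rs <- mir34_reference()
  sim <- simulate_reads(rs, sim_config(
    c(`hsa-miR-34b-5p` = 76, `hsa-miR-34b-3p` = 24), seed = 41))
  p <- profile_reads(sim$reads, rs)
  af <- suppressWarnings(arm_fraction(p, rs))
  expect_equal(af$arm5p_fraction[af$precursor_id == "hsa-mir-34b"], 0.76)
  expect_true(is.na(af$arm5p_fraction[af$precursor_id == "hsa-mir-34a"]))
  expect_warning(arm_fraction(p, rs), "no assigned reads")

  expect_equal(fold_change(p, p, "hsa-miR-34b-5p")$fold_change_rpm, 1.0)
  sim2 <- simulate_reads(rs, sim_config(c(`hsa-miR-34c-5p` = 50), seed = 42))
  p2 <- profile_reads(sim2$reads, rs)
  fc <- fold_change(p, p2, "hsa-miR-34b-5p")
  expect_true(fc$infinite)
  expect_equal(fc$fold_change_rpm, Inf)
  expect_error(fold_change(p2, p2, "hsa-miR-34a-5p"), "absent")
})

test_that("logo matrices are depth-normalized position probabilities", {
  rs <- toy_reference()
  m <- rs$matures$sequence[1]
  # all reads identical: fully covered columns are single-nucleotide at 1.0
  p <- profile_reads(setNames(rep(m, 5), paste0("r", 1:5)), rs)
  lg <- logo_matrix(p, rs, "matA")
  inside <- as.integer(colnames(lg$matrix)) >= 10 &
    as.integer(colnames(lg$matrix)) < 32
  expect_true(all(colSums(lg$matrix)[inside] == 1))
  expect_true(all(apply(lg$matrix[, inside], 2, max) == 1))
  # flanking columns carry no reads
  expect_true(all(lg$support[!inside] == 0))

  # two equally frequent variants differing at one position give a 0.5/0.5
  # column; all columns sum to coverage/depth
  variant <- paste0(substr(m, 1, 10), "A", substr(m, 12, 22))  # pos 11 G->A
  stopifnot(substr(m, 11, 11) != "A")
  p2 <- profile_reads(c(r1 = m, r2 = m, r3 = variant, r4 = variant), rs)
  lg2 <- logo_matrix(p2, rs, "matA")
  col <- lg2$matrix[, as.character(10 + 10)]  # precursor position of read pos 11
  expect_equal(sort(col[col > 0]), c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(colSums(lg2$matrix), lg2$support / 4, ignore_attr = TRUE)
  expect_error(logo_matrix(p2, rs, "matB"), "no reads")
})

test_that("a dominant +1 start depletes the annotated first position", {
  rs <- mir34_reference()
  n <- 1000
  dist <- isomir_distribution(offset5_probs = c(`1` = 0.95, `0` = 0.05),
                              offset3_probs = c(`1` = 1),
                              nta_probs = setNames(1, ""))
  sim <- simulate_reads(rs, sim_config(c(`hsa-miR-34b-5p` = n),
                                       distribution = dist, seed = 55))
  p <- profile_reads(sim$reads, rs)
  lg <- logo_matrix(p, rs, "hsa-miR-34b-5p")
  ann <- dplyr::filter(rs$matures, mature_id == "hsa-miR-34b-5p")
  first_nt <- substr(ann$sequence, 1, 1)
  prob <- lg$matrix[first_nt, as.character(ann$start)]
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(prob - 0.05), 3 * se)
})

test_that("tidiers and plots summarize profiles consistently", {
  rs <- toy_reference()
  p <- profile_reads(setNames(rep(rs$matures$sequence[1], 4),
                              paste0("r", 1:4)), rs, library_id = "lib1")
  td <- tidy(p)
  expect_equal(td$library_id[1], "lib1")
  gl <- glance(p)
  expect_equal(gl$total_mapped, 4)
  expect_equal(gl$n_unmapped, 0)
  lg <- logo_matrix(p, rs, "matA")
  expect_s3_class(autoplot(lg, refset = rs), "ggplot")
  expect_s3_class(autoplot(p), "ggplot")
  lt <- tidy(lg)
  expect_equal(nrow(lt), 4 * ncol(lg$matrix))
})
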
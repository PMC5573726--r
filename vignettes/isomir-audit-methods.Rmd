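---
title: "Auditing miRNA annotations with isomiR profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing miRNA annotations with isomiR profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedshift)
library(dplyr)
```

## The problem

A mature miRNA is deposited in reference databases as a single sequence, but a
sequencing library contains a population of end-variants (isomiRs): reads that
start or end a few nucleotides up- or downstream of the annotation on the
hairpin precursor, or that carry non-templated 3' additions (NTA, most often
uridines). Most of this variation is 3'-end noise with little functional
consequence. A **5' offset is different**: because target recognition is
driven by the seed (mature nucleotides 2–7, with nucleotides 2–6 exposed for
initial pairing in the RISC), shifting the 5' end by one nucleotide shifts
the seed and therefore redirects the miRNA to a different target repertoire.
If the *dominant* form in real cells is 5'-shifted relative to the
annotation, then the annotation is effectively wrong for any downstream use
(mimic design, target prediction, qPCR assays).

`seedshift` implements the computation needed to detect and quantify exactly
this situation, end to end: map reads onto hairpins, classify isomiRs,
call the dominant form per arm, compare it with the annotation, and measure
how much of the target repertoire a seed shift preserves. The worked example
throughout is the human miR-34 family, where the endogenously dominant
miR-34b-5p is a +1/+1 variant of the annotation: still 23 nt, but with the
seed shifted onto nucleotides 2–8, where it coincides with the seed annotated
for miR-34a and miR-34c.

## Coordinates and reference model

Two conventions are used consistently:

* intervals on precursors are 0-based half-open `[start, end)`;
* positions on a mature are 1-based inclusive, matching the "nucleotides 2–7"
  phrasing used for seeds.

A `mir_reference` couples precursor sequences with mature annotations. When
no placement table (GFF3) is given, each mature is located by exact substring
search; a mature occurring twice on one precursor is placed at its first
occurrence and flagged ambiguous (deterministic and visible, rather than an
error). The internal alphabet is RNA; `T` is converted on input. Arms are
taken from input where provided and otherwise inferred from the position of
the mature's midpoint relative to the hairpin midpoint.

`shift_mature(refset, id, delta5, delta3)` constructs templated variants by
moving the annotated interval and re-reading the precursor, so a "shifted
isoform" is by construction a sequence the hairpin can actually produce:

```{r shift}
rs <- mir34_reference()
shift_mature(rs, "hsa-miR-34b-5p", 1, 1)
```

## Read mapping and isomiR classification

Mapping is performed in **precursor space**, not genome space. Every quantity
of interest (offsets, NTA, arm ratios, RPM, logos) is defined relative to the
hairpin, so aligning to the precursor set directly preserves all of them
while removing any genome dependency.

A read is aligned ungapped at every precursor position and at every split of
the read into a templated prefix and a 3' NTA suffix. A candidate is valid
when the templated part is at least `min_templated` (16) nt with at most
`max_mismatches` (1) substitutions, and the suffix is at most `max_nta` (3)
nt. Candidates are scored

$$\mathrm{score} = \text{templated length} - 2 \times \text{mismatches},$$

and ties are broken by fewer NTA bases, fewer mismatches, lexicographically
smallest precursor id, then smallest start. The scoring has two consequences
worth stating explicitly:

* a terminal base that disagrees with the template is reported as a 1-nt NTA
  (uridylation) rather than as a templated mismatch, because the NTA split
  scores one point higher;
* conversely, a 2-nt tail whose second base matches the template ties in
  score with the pure-NTA split, and the fewer-NTA tie-break resolves it to a
  templated extension carrying one substitution.

A read whose best score is achieved on more than one precursor is counted
once, at the deterministic winner, and flagged ambiguous; profiles report the
ambiguous fraction rather than splitting counts fractionally.

Classification assigns each mapped read to the mature whose interval overlaps
its templated interval most (ties to the 5p arm) and expresses it as
`offset5 = templated start − annotated start` and
`offset3 = templated end − annotated end` (positive = downstream). Only 3'
NTA is modelled; an untemplated 5' base is counted as a mismatch. RPM uses
the number of reads mapped to any precursor of the reference set as the
denominator — the choice is stated here because published RPM values rarely
state theirs; all concordance *fractions* are denominator-free.

## Dominant-form calling and the audit verdict

For each mature, the dominant form is the most frequent full read string
(ties to the lexicographically smallest). Two support fractions are kept:
exact-sequence support, and the never-smaller fraction of reads sharing the
dominant 5' start. The audit verdict is:

* `low_coverage` below `min_depth` (default 10 reads);
* `seed_shifted` when the dominant 5' start is offset (`shift5 != 0`) and at
  least `dominance_threshold` (default 0.5, per the meaning of
  "predominant") of reads share that start;
* `three_prime_variant_only` when the 5' end is concordant but the modal 3'
  end is offset or most reads carry an NTA;
* `concordant` otherwise.

Because published "X% matched the sequence" statements often leave the match
criterion implicit, the audit reports *both* the full-sequence and the
5'-start fractions, against both the annotation and the dominant form, and
the JSON report names the mode of each field. The default seed definition
for verdicts is nt 2–7; the nt 2–8 and nt 2–6 seeds of the dominant form are
always emitted alongside. `family_seed_check()` flags whether the observed
seed equals the modal annotated seed of a miRNA family — the configuration
that turns a "misannotation" call from a curiosity into a concrete
correction (the shifted miR-34b-5p seed is exactly the miR-34a/c seed).

## Position probability matrices (logos)

`logo_matrix()` stacks reads at their precursor coordinates over the
annotated window (± `flank`, default 2) and reports count-weighted nucleotide
probabilities per position, with NTA bases occupying positions past the
templated end. Columns are normalized by the **total read depth of the
mature**, not per-column coverage: a column covered by every read sums to 1,
and a position covered by few reads shows proportionally small letters. This
choice is deliberate — it is precisely what makes a depleted annotated 5'
position visible in the rendering (if 95% of reads start one nucleotide
downstream, the annotated first position shows its nucleotide at probability
about 0.05, not 1.0 among the 5% of reads that cover it).

## The synthetic read generator

The generator draws, per read: a source mature (per configured counts, which
may also be keyed by precursor id and split 5p/3p by `arm5p_fraction`), a
`(offset5, offset3)` pair, an NTA suffix from an explicit table, and iid
substitutions. Defaults encode what small-RNA libraries typically show:
U-dominated tail tables, and substitutions kept out of the first 8 read
positions so 5' ends and seeds stay exact (overridable). Offsets whose
interval escapes the precursor or produces a read under 16 nt (the size
floor of a typical small-RNA library prep, matching the profiler's filter)
are resampled with bounded retries. Everything is a deterministic function
of `(refset, config)` including the seed, and every read is emitted with a
manifest row recording its source, offsets, NTA and substitution positions.

Two deliberate simplifications, and one subtlety:

* offsets, NTA and substitutions are sampled **independently**; real
  libraries likely couple them (trimming and tailing arise from shared
  machinery). Class structures that depend only on the marginals are
  unaffected; joint-class realism is out of scope.
* qualities carry no information here, so FASTQ output uses constant quality.
* the manifest records each read in **canonical maximally-templated
  coordinates**: a sampled tail prefix that the template can explain at
  equal or better alignment score is recorded as a templated extension (with
  any absorbed mismatch recorded as a substitution). Without this, no
  read-based classifier could reproduce the manifest exactly — e.g. a +U
  tail on miR-34b-5p is indistinguishable from the templated +1 extension,
  because the next hairpin base *is* U. This is an identifiability limit of
  the data, not of the implementation, and it is worth remembering when
  interpreting published "+U" fractions: relative to a mimic or annotation,
  a trailing U may be templated on the precursor.

`truth_summary()` tallies the manifest exactly and is the oracle for the
profiler's recovery tests: on substitution-free simulations the profile
equals the truth tallies class by class, and with substitution rate 0.01
class deviations are bounded by the number of substituted reads.

### Preset study conditions

`mir34_study_configs()` encodes the measured structure of the libraries in
the worked example as generator parameters, derived analytically, not
fitted: the mimic-transfected library's three headline classes (22.4%
identical to the mimic, 17.9% with an additional 3' U, 19.4% lacking four 3'
nucleotides) are reproduced by marginals solving those products under
independence (P(offset3 = 0) = 0.403, P(nta = U) = 0.4442,
P(offset3 = −4) = 0.349); the control library fixes miR-34c at 342 reads vs
miR-34b at 19, split 341:1 (99.7% 5p) and 14:5 (the closest realizable split
to the observed 76% at depth 19); and the mimic library floods miR-34b-5p at
11,620 of 20,000 reads against the control's 14 of 20,000, an exactly
830-fold RPM increase. The endogenous condition places 97% of miR-34b-5p
5' ends at the +1 position with heterogeneous 3' ends, so that over 95% of
reads share the shifted form's 5' start and under 2% start at the annotated
position. Acceptance tests in `tests/testthat/test-acceptance.R` re-derive
all of these numbers from the raw simulated reads via the profiler and
audit; the concordance checks use 5000-read libraries, a depth at which a
true 1.5% annotated-start rate stays below the 2% bound with comfortable
margin under binomial noise.

## Seed-site scanning and repertoire overlap

A seed site is the UTR substring exactly reverse-complementary to a seed
span, in RNA space, Watson–Crick only — G:U wobble is not counted, because
the repertoire-shift argument rests on exact complementarity (non-canonical
pairing is acknowledged as real but out of scope). Site types follow the
standard nomenclature (5mer nt 2–6, 6mer nt 2–7, 7mer-m8 nt 2–8, and the
7mer-A1/8mer variants requiring an A opposite mature position 1). Scans are
exhaustive and report overlapping matches.

`isoform_target_overlap()` quantifies what a 1-nt 5' shift does to the
repertoire. Sites of the two isoforms are "shared" when their intervals
overlap by at least one position on the same UTR — a deliberately permissive
criterion, because the interesting case *is* the 1-nt-shifted site pair, in
which an annotated-isoform site happens to be flanked by the base that
completes the shifted isoform's site. On iid uniform sequence that flanking
base matches with probability 1/4, so the retention of the annotated
repertoire by the shifted isoform converges to 25%: the null expectation
against which any observed repertoire conservation must be judged.
`n_shared` is defined as the smaller of (a-sites overlapped by b, b-sites
overlapped by a), which keeps `n_shared <= min(n_a, n_b)` even when several
sites on one side overlap a single site on the other; the Jaccard index is
`n_shared / (n_a + n_b - n_shared)`.

```{r overlap}
rs <- mir34_reference()
shifted <- shift_mature(rs, "hsa-miR-34b-5p", 1, 1)
isoform_target_overlap(simulate_utrs(n = 100, length = 1000, seed = 1),
                       "UAGGCAGUGUCAUUAGCUGAUUG", shifted$sequence)
```

## Numerical and design choices

* **Degenerate inputs**: empty read sets, unmappable candidates, zero-depth
  matures and empty UTR sets are hard errors or explicit `NA`s (arm fraction
  of a read-free precursor), never silent zeros.
* **Ties** are always broken deterministically and documented per function
  (lexicographic for sequences and precursor ids, smaller absolute offset
  for modal offsets, 5p for equal-overlap assignment).
* **Problem sizes** used by the test-suite simulations (hundreds to a few
  thousand reads per library, 500 × 1 kb random UTRs, 3-precursor oracle
  instances) were chosen so that every stochastic assertion has
  three-binomial-SE margins; they are stated in the tests themselves.
* **Fold change** is reported on RPM by default with the raw-count ratio
  alongside (published fold changes rarely state which was used; with equal
  library sizes they coincide). No pseudocount by default; a zero
  denominator yields `Inf` with an explicit flag.

## What passing tests do and do not show

The generator emulates end-variant structure, tailing, substitutions and arm
usage, and the suite demonstrates exact bookkeeping, mapper optimality
against brute-force enumeration, and recovery of configured truths. It does
**not** emulate adapter artefacts, per-cycle error profiles, PCR
duplication, ligation bias, or coupled offset/NTA distributions, so passing
tests certify the analysis given reasonably clean trimmed reads — not
robustness to upstream library-prep pathology. Cross-mapping between near-
identical paralogous hairpins is handled by deterministic tie-breaking and
an ambiguity flag, not by fractional assignment; on reference sets with many
near-duplicate precursors the ambiguous fraction should be inspected before
interpreting per-arm counts.
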
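---
title: "introscan: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{introscan: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models behind `introscan`, the parameters that
matter, and the design choices made where several formalizations were
defensible. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. Diagnostic-SNP classification

The panel has three roles: donor-candidate accessions (the suspected wild
source species), polyploid reference accessions (ordinary tetraploid and
hexaploid wheat), and one query line (the suspected introgression carrier).
Each biallelic SNP receives exactly one category:

* **DONOR_DIAGNOSTIC** — the alternate allele is present in *every*
  non-missing donor candidate and absent from *every* non-missing
  reference, with the missing fraction within the policy limit in both
  groups. Such alleles mark donor chromatin.
* **QUERY_RARE** — the query carries the alternate allele, no reference
  does, but the donor condition fails. These are the "rare polymorphisms"
  that first suggest an alien origin without pinning the donor.
* **SHARED_WHEAT** — the alternate allele occurs in at least one
  reference: ordinary wheat polymorphism.
* **UNINFORMATIVE** — everything else.

Two policy knobs (`classification_policy()`):

* `het_carries` (default `TRUE`). A heterozygous call counts as carrying
  the alternate allele. The genotypes typically come from RNA-seq of a
  polyploid, where allele dosage at a single locus is confounded by
  homoeologous expression; presence of the allele is the robust signal.
  Set to `FALSE` for DNA-based panels with reliable dosage.
* `max_missing_frac` (default `0`). Complete panels are assumed; raise it
  (e.g. to `0.25`) when calls are missing so that a site is not disqualified
  from `DONOR_DIAGNOSTIC` by a single dropped call. The acceptance suite
  shows ≥ 95% agreement with generator truth at 5% missingness under a
  `0.25` tolerance.

"Absent" is interpreted per allele, not per genotype: absence means no
non-missing reference carries the alternate allele under the het policy.

## 2. Segment detection and the breakpoint bracket

Supporting SNPs are the query-shared donor-diagnostic sites. Detection has
three stages, governed by `detection_params()`:

1. **Density filter.** The chromosome is tiled into `window_bp` windows
   (default 1 Mb, anchored at position 1). In windows where supporting
   SNPs make up less than `min_window_fraction` (default 0.5) of the
   classified SNPs, the supporting SNPs are discarded. This is a filter,
   not a veto: an isolated noisy window loses its handful of supporting
   SNPs instead of splitting an otherwise contiguous multi-hundred-Mb run.
   At realistic densities (~13 classified SNPs per window, ~85% of them
   diagnostic inside a segment) a window fails the fraction test with
   probability ≈ 1.4 × 10⁻³ by binomial sampling alone, so over several
   hundred windows a hard per-window veto would fragment about half of all
   true segments — the filter formalization is the one that makes the
   ≥ 95% bracket-coverage guarantee attainable. The filter is monotone:
   raising `min_window_fraction` can only shrink or split runs, never
   lengthen the reported segment.
2. **Run formation.** Surviving supporting SNPs are grouped into runs in
   which consecutive SNPs are at most `max_gap_bp` apart (default 10 Mb, a
   generous bound for transcriptome-derived SNP panels whose gene deserts
   create multi-Mb gaps). The physically longest run with at least
   `min_support` SNPs (default 20) is reported; ties go to the larger
   support count, then to the more distal start (determinism).
3. **Breakpoint bracket.** `breakpoint_lo` is the last supporting SNP.
   `breakpoint_hi` is the first SNP beyond the run that evidences
   recipient chromatin: primarily the first donor-diagnostic SNP the query
   does *not* carry. Shared-wheat polymorphism also occurs *inside* donor
   chromatin (the introgression line participates in ordinary wheat
   polymorphism), so a shared SNP cannot by itself bound the boundary; it
   is used as a fallback when no discordant diagnostic site follows, and
   the chromosome-end sentinel (`chrom_length`, else `Inf`) covers
   whole-arm segments.

The defaults were chosen once for robustness on synthetic truth at the
study's SNP density and are exposed in the run configuration; they are not
estimates of any published threshold (the source analyses located the
boundary visually on density plots).

## 3. Donor assignment by neighbor joining

Distances are genotype p-distances: the weighted mismatch fraction over
sites called in both accessions, with heterozygous-vs-homozygous
mismatches weighted 0.5 by default (`het_weight`) under an allele-sharing
interpretation, and homozygous-opposite mismatches weighted 1. Because the
input is a SNP table rather than aligned sequences, this is the standard
surrogate for a substitution distance; no realignment is performed.
`min_overlap` (default 50 co-called sites) guards against unstable
distances on sparse pairs and is irrelevant for complete matrices.

The tree is Saitou–Nei neighbor joining with the usual Q-criterion.
Numerical choices: ties in Q break deterministically toward the
lowest-index pair; negative branch lengths are clamped to zero with the
deficit transferred to the sister branch (at the final trifurcation,
clamping only). On additive matrices the algorithm reproduces all
path-length distances to 1e-9, which the suite checks, along with
topology agreement with an independent NJ implementation on noisy
matrices. Distances for donor assignment are computed on the genotypes
restricted to the detected segment, where the query's chromatin is
donor-derived; whole-genome distances would dilute the signal with the
recipient background. Placement is summarized as whether the query plus
the donor candidates form a monophyletic group. Bootstrap support is out
of scope.

## 4. Segregation tests, gamete counting and the genetic map

Infection types use the Stakman 0–4 scale. The parser takes the largest
numeral in the string (so the range "3-4" reads as 4), ignores the
modifiers `;`, `+`, `-`, maps pure fleck reactions (";", "0;") to class 0,
and refuses anything unparseable rather than silently scoring susceptible.
`binary = R` when the class is at most `resistance_threshold` (default 2:
classes 0–2 are resistant-type reactions, 3–4 susceptible).

The segregation test is the Pearson goodness-of-fit chi-square with one
degree of freedom and **no** Yates continuity correction — the convention
under which published segregation statistics for two-class ratios are
computed (the correction would roughly halve the printed values).

Recombinant gametes between a marker and the dominant gene (coupling
phase) are counted minimally: over all gamete-pair assignments consistent
with the two-locus genotype, the minimum number of recombinant gametes,
which equals the absolute difference of donor-allele doses at the two
loci. Phase-ambiguous double heterozygotes therefore resolve to zero. At
the recombination fractions involved (r ≪ 0.5) the neglected
double-recombinant pairs occur at rate r²/2 per plant, giving the
estimator a downward bias of 100·r²/2 cM — about 0.00004 cM at r = 0.003
and 0.125 cM at r = 0.05, i.e. negligible relative to a single
2,000-gamete estimate's binomial standard error. The acceptance suite
verifies recovery at r ∈ {0.005, 0.01, 0.05} with 100 replicates of 2,000
gametes each, within twice that standard error.

Map distances are plain recombination percentages (`cM = 100·n_rec /
n_total`, rounded to two decimals half away from zero, matching printed
precision); no Haldane/Kosambi mapping function is applied because all
distances of interest are far below the range where the correction
exceeds rounding error. Loci are ordered by physical anchor positions
(reference-genome coordinates replace multipoint ordering), and loci
joined by zero-recombinant intervals collapse into co-segregation groups.
Progeny tests resolve gene genotypes (all resistant → RR, all susceptible
→ rr, mixed → Rr) with a minimum family size of 12, below which the call
is UNKNOWN: a 12-plant all-resistant family from a heterozygote occurs
with probability 0.75¹² ≈ 0.03, so smaller families cannot exclude Rr at
conventional confidence.

## 5. CAPS and InDel markers

Recognition sites are matched as IUPAC patterns on the top strand
(`Biostrings::matchPattern(fixed = FALSE)`, overlaps allowed); patterns
that are not palindromic under IUPAC are additionally matched against
their reverse complement with positions mapped to top-strand coordinates.
Digestion is linear (PCR amplicons): the cut falls after base
`site_start + cut_offset − 1` on the top strand (for bottom-strand sites,
after `site_start + L − cut_offset − 1`), duplicate cut positions are
merged, and fragment lengths always sum to the amplicon length (a
property the suite checks on 1,000 random digests).

The diagnostic verdict models an agarose gel: fragments shorter than
`min_resolvable_diff` (default 20 bp, a conservative stand-in for gel
resolution) are invisible, and two banding patterns are distinguishable
when the visible band counts differ or some sorted-pairwise band
difference reaches the threshold. This resolves the tension between
"count differences are diagnostic" and the observation that a SNP
creating a second cut a few bp away from an existing one (one band
shifted by a few bp plus one invisible sliver) is not scorable on a gel.
Enzyme proposal ranks diagnostic enzymes whose recognition window
overlaps the SNP by their discrimination margin — the best distinguishing
band's distance to the nearest band of the other pattern. Methylation
sensitivity, star activity and partial digestion are out of scope; the
shipped enzyme table (`inst/extdata/enzymes.tsv`) is a small editable TSV
seeded with AvaI and other common six- and four-cutters, not a REBASE
mirror.

## 6. What the simulators emulate — and what they do not

`simulate_species_panel()` emulates the SNP panel behind an
origin analysis: 4 donor accessions (two per candidate donor species), 17
polyploid references (2 tetraploid + 15 hexaploid), one query, 9,294 SNPs
on a 721-Mb chromosome with the donor segment spanning positions
1–687,016,683 by default, mirroring the study design this package
addresses. Site-type proportions (85% donor-diagnostic, 12% shared
polymorphism, the remainder donor-private rare variants and monomorphic
sites) were fixed once to echo the reported ratio of species-specific to
total segment SNPs. Donor-diagnostic alleles are fixed in the donor
group; the query carries them exactly inside the configured segment.
Ground truth is recomputed from the clean genotypes by direct rule
application, so stored truth is self-consistent by construction, and all
generators are pure functions of their configuration (seed included).

Deliberate simplifications: species histories are not coalescent-real
(donor accessions are exchangeable; there is no intra-donor phylogenetic
structure), the query is not modeled as a recombinant mosaic at
shared-polymorphism sites, missingness is uniform rather than
coverage-driven, and there is no genotyping error beyond missingness.
Passing tests therefore demonstrate correctness of the classification,
detection and bracketing logic under the stated statistical model — not
robustness to reference bias, paralogous mapping or allele-specific
expression, which real RNA-seq panels add on top.

`simulate_mapping_population()` uses a no-interference meiosis model (each
interval recombines independently with probability rᵢ in each gamete);
interference is unobservable at the sub-cM distances of interest. A
deterministic forced-placement mode exists solely to reconstruct printed
worked examples (e.g. one recombinant among 376 gametes → 0.27 cM).
`simulate_amplicon_pair()` rejection-samples a site-free background (cap:
10,000 attempts, then an error) and plants one concrete expansion of the
recognition site, so assay geometry such as 1,118 → 418 + 700 bp is exact
by construction.

## 7. Problem sizes and determinism

The test suite runs panels of 500–9,294 sites, 50-panel bracket-coverage
sweeps, 100-replicate × 2,000-gamete recombination recoveries, and
1,000-digest conservation sweeps — sizes chosen so the full suite
completes in about a minute while keeping every statistical check at the
study's own scale where it matters (the bracket property uses the
full-density default panel). Every stochastic stage takes an explicit
seed; pipeline reruns with the same configuration are byte-identical, and
the resolved configuration is written alongside every output set for
auditability.

## 8. Known limitations

* Origin analysis handles one query line and one chromosome per call;
  multi-query joint analysis and ancestral-state polarization are out of
  scope.
* The breakpoint bracket is bounded by SNP density: the true boundary is
  only localized between the last concordant and first discordant
  informative site, and the bracket width is the local inter-SNP spacing.
* `QUERY_RARE` counts depend strongly on panel composition and the het
  policy; published counts of that kind are not reproducible without the
  underlying genotype tables and are not targeted.
* The chi-square segregation test is asymptotic; with expected class
  counts below ~5 an exact binomial test would be preferable, but such
  populations do not occur in this workflow.
* The gel model reduces resolvability to a single bp threshold;
  co-migrating fragments of similar-but-distinct sizes and smears from
  partial digestion are not modeled.
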
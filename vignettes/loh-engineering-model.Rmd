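---
title: "Modelling targeted LOH engineering by mitotic crossover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling targeted LOH engineering by mitotic crossover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohsim)
```

## The system being modelled

Copy-neutral loss of heterozygosity (LOH) can be engineered in cultured
diploid cells by combining three elements: an invertible dual-resistance
selection cassette (neomycin/puromycin, "cNP") knocked into one
haplotype of a chromosome arm; an allele-specific CRISPR/Cas9
double-strand break (DSB) placed centromeric to the cassette, targeted
to one haplotype through a heterozygous SNP that disrupts the PAM on the
other; and suppression of the BLM helicase (Tet-Off knockdown or the
inhibitor ML216), which raises the mitotic crossover rate. A crossover
between homologous non-sister chromatids in G2 (the 4N stage), followed
by the right segregation, duplicates the cassette-bearing distal segment
in one daughter: all heterozygous sites distal to the crossover become
homozygous while copy number stays at two. Cre-mediated inversion
converts some cassette copies from the G418-resistant N orientation to
the puromycin-resistant P orientation, so a cassette-duplicated daughter
with one copy of each orientation survives double drug selection
(N^R P^R). `lohsim` implements this whole chain — and the read-outs used
to verify it — as an explicit chromatid-level simulation over synthetic
phased genomes.

## The 4N model

`replicate_to_4n()` builds four chromatids per chromosome: sister pairs
derived from the hapA and hapB homologs, with the cassette on the two
carrier sisters. Stages act in the order iCre inversion, DSB and repair,
rare events, segregation:

* **iCre** (`apply_icre()`): each cassette copy inverts independently
  with probability `q_inversion`. Inversion acts after replication
  because Cre and Cas9 are delivered together in G2-arrested cultures;
  acting before replication would make sister cassettes identical, and a
  single crossover could then never produce the N^R P^R state. The
  default 0.25 encodes the observed 20–30% inversion efficiency.
* **DSB and repair** (`induce_dsb_and_repair()`): each target-haplotype
  chromatid is cut with probability `p_cut`. A cut resolves as a
  crossover with a non-sister with probability
  `crossover_prob_given_cut_suppressed` when BLM is suppressed and
  `crossover_prob_given_cut_unsuppressed = 0` otherwise — the
  experimental observation is that positive clones arise only when
  suppression and the DSB are combined, so the unsuppressed crossover
  rate and the spontaneous (no-DSB) crossover rate are both zero by
  default. The crossover breakpoint is the DSB position plus an
  exponential offset: centromeric with probability
  `p_centromeric_side = 0.7`, with side-specific scales of 20 kb
  (centromeric) and 300 kb (telomeric). The exponential is the minimal
  one-parameter positive law consistent with the reported characteristic
  magnitudes; the side bias is configurable and not asserted by any
  test. Cuts that do not cross over resolve as a distal deletion
  (exponential length, 10 kb scale), a short gene-conversion tract
  copied from a non-sister (1 kb scale, never moving the cassette), or
  no scored change. Absolute rates (`p_cut = 0.8`, crossover fraction
  0.05 per cut under suppression) are order-of-magnitude placeholders:
  the source experiments report efficiencies only graphically, and no
  acceptance property depends on their absolute values.
* **Rare events** (`apply_rare_events()`): with probability
  `p_amplification` (default 1e-5) a cassette copy is duplicated in
  place — the duplicate re-draws its orientation with the Cre inversion
  probability, since Cre is still active — producing the
  aberrant-duplication clones that keep the wildtype allele; with
  probability `p_upd` (default 1e-6) the chromosome undergoes
  whole-homolog replacement at segregation (uniparental disomy). Both
  defaults are literature-plausible per-division orders of magnitude for
  cultured pluripotent cells; neither is derivable from the source data.
* **Segregation** (`segregate()`): sisters go to opposite poles, the two
  pole assignments independent and uniform. With a single crossover,
  exhaustive enumeration of the four assignments shows the X-type
  configuration (recombinant distal segments co-segregating, one
  daughter homozygous distal to the breakpoint) in exactly half — the
  Monte Carlo path is tested against this enumeration. In an X-type
  division the dual-cassette daughter carries the two former sister
  cassettes, which inverted independently, so its survival probability
  under double selection is 2q(1−q) = 0.375 at q = 0.25.

`simulate_experiment()` runs `n_cells` cells through these stages. All
randomness derives from a single root seed through named stage
substreams (hashed child seeds drive per-stage pre-drawn variates), so
cohorts are reproducible component-wise, and cells whose pre-drawn
events cannot yield a cassette-duplicated daughter are counted and
skipped without building chromatid structures — this is what makes
10^5-cell negative arms cheap.

## Screening and mapping

`competitive_pcr()` reproduces the three-band screen: wildtype band if
any chromatid carries the unmodified allele at the cassette site, N and
P bands for the two cassette orientations. Crossover-duplicated clones
lose the wildtype band; amplification clones keep it, which is why the
positive pattern {N, P} excludes them (recall on simulated
amplifications is exactly 1 because the wildtype chromatid is retained
deterministically).

`genotype_panel()` calls each marker het or hom from the daughter's two
chromatids, flipping calls with probability `genotype_error`
(default 0.002, a typical array-genotyping error rate).
`smooth_panel()` applies a single-pass run-length rule: a run of
discordant calls shorter than `k` (default 3) flanked on both sides by
at least `k` concordant calls is flipped. `infer_crossover_point()`
then requires exactly one het-to-hom transition with homozygosity
extending to the telomere-most marker and places the crossover point
equidistant from the last heterozygous and first LOH marker. Ties round
half toward the centromere (the estimator is otherwise symmetric, so
the choice is inconsequential; it is fixed for determinism).

Two design choices deserve note:

* **Side calls below marker resolution.** When the bounding marker
  interval straddles the DSB, the crossover demonstrably happened but
  its side relative to the DSB is not identifiable; such clones are
  reported as `spanning` and excluded from per-side distance summaries.
  With this rule every assigned side agrees with simulation truth at
  zero genotyping error. The corollary is a truncation effect: on
  sparse or irregular panels, small-offset clones are preferentially
  unsidable, and the kept-clone mean distance is inflated by roughly
  the local marker gap at the DSB. The distance-recovery analyses
  therefore use regular marker panels (one marker per 2 kb for the
  centromeric side, per 10 kb for the telomeric side) that place a
  marker at the DSB position, which makes side assignment exact and the
  per-side means unbiased estimates of the generating scales.
* **Whole-chromosome LOH is one class.** An all-homozygous panel may be
  uniparental disomy or a crossover centromeric of the most centromeric
  marker; the assay cannot distinguish them, so `classify_clone()`
  merges both into `whole_chromosome_loh`.

## Array simulation and segmentation

`simulate_baf_lrr()` emits ideal B-allele frequencies (0.5 het; 0/1 in
LOH) and log R ratios (log2 of copy number over 2) with truncated
Gaussian noise. `segment_loh()` is deliberately rule-based rather than
an HMM: a running median of the mirrored BAF deviation (threshold 0.35)
marks LOH, and within LOH the running median LRR (threshold −0.5)
separates hemizygous deletion (−1) from copy-neutral LOH (0). The
vendor pipeline this emulates was used qualitatively; the minimal
method that provably recovers synthetic truth (exact on noiseless
input, within two probe spacings in ≥95% of clones at BAF sd 0.05 /
LRR sd 0.15, window 25) is preferred for testability. Raw intensity
normalisation, GC waves and subclonal mixtures are out of scope.

## Synthetic genomes

`make_genome()` draws het SNP positions as a Poisson process (default
one per 5 kb, adequate for midpoint-error bounds of half the marker
spacing) outside the centromere, with random distinct alleles. The
`chr19_aavs1` preset (58.6 Mb, centromere 24.5–27.0 Mb, cassette at
55.1 Mb, DSBs 9/14/19 Mb telomeric of the centromere edge on the q arm)
and the `chr6p_hla` preset (170.8 Mb, cassette at 0.2 Mb near the p
telomere, DSB at 31.4 Mb between the class I and class III blocks, HLA
loci ordered A, C, B, class III, DRB1, DQB1 from the telomere) encode
the two experimental designs; coordinates approximate the human
reference but only relative geometry matters. The cassette carrier is
fixed to hapA (the source data do not say which haplotype carried it)
and the A-locus labels default to A2 on hapA and A32 on hapB, so that a
mapped class-I–III crossover clone reports the A2/A2 genotype of the
verified clone while DRB1 stays heterozygous.

What the generator does *not* emulate: linkage disequilibrium and
realistic allele frequencies, reference-genome sequence (guide design
runs on supplied backbone windows), pre-existing karyotype
abnormalities, and cell-fitness effects of BLM loss. Passing tests
therefore demonstrate the correctness of the genetic logic and the
estimators under the stated noise models, not performance on real
arrays.

## Problem sizes and numerics

The test suite and the acceptance analyses use cohorts of 3,000–40,000
cells (up to 100,000 for the negative arm, where the fast path makes
the run cheap), 500-clone distance recoveries, 200-clone array
recoveries and 1,000-sequence scanner cross-checks; these sizes give
3–4σ resolution on every asserted frequency while keeping any single
analysis under a couple of minutes on one core. Breakpoints whose
resampling guard fires (outside the centromere–cassette interval) are
counted in the run log; with the default scales the guard is never
exercised in practice. All interval logic is 1-based and closed
internally; BED output converts to 0-based half-open on write only.

## A worked example

```{r example, eval = FALSE}
genome <- make_genome("chr19_aavs1", snp_density = 1 / 5000, seed = 1)
cfg <- make_cohort_config(overrides = list(n_cells = 20000, seed = 2))
cohort <- simulate_experiment(genome, "9M", cfg)
mapped <- map_cohort(cohort, panel_positions(genome, "chr19"))
summarize_cohort(mapped, n_screened = cfg$n_cells)
```

The pipeline wrapper `run_pipeline()` chains all stages and writes
clone tables, the het/LOH panel matrix, crossover points, array
segments and a manifest with per-stage counters and file digests;
`replay_report()` renders the human-readable summary, including the
per-locus HLA table for the chr6p design.
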
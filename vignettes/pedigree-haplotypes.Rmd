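---
title: "Pedigree haplotype blocks, graphical genotypes and diversity in inbred panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree haplotype blocks, graphical genotypes and diversity in inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`pedhap` analyzes SNP-array genotypes of panels of closely related inbred
crop cultivars — the situation of a national breeding program, where a few
dozen landraces were recombined over a century of documented crosses into
modern elite lines. This vignette explains the model behind each step, the
parameters that matter, what the simulator does and does not emulate, and
the design decisions taken where the procedure was genuinely open.

## The data model

Everything is anchored on a **SNP map**: ordered biallelic loci with
1-based bp positions and per-chromosome lengths. Genotypes are unordered
allele pairs (`"A/G"`, missing `"./."`). After quality control, calls are
**coded** against two reference cultivars — the donor-parent reference
(state `P1`) and the sequenced reference (`P2`), with `HET` and `MISSING`
— because in a near-homozygous panel those two references span the allele
space of every retained SNP. The coded matrix, not the raw calls, is the
substrate of all downstream comparisons.

Array QC applies five discard rules: (1) no signal in any sample, (2) no
signal in either reference, (3) missing in more than 10% of samples, (4)
no polymorphism, (5) heterozygous in more than 10% of signals. Two rules
needed interpretation:

* *Rule 4.* "No polymorphism" is read as *either* all non-missing calls
  identical *or* the two references carrying the same genotype. The second
  clause makes the rule also remove SNPs that cannot be coded against the
  references, which is what an array designed on reference-vs-reference
  polymorphisms screens out in practice.
* *Rule 5 denominator.* The fraction of heterozygous signals is computed
  over non-missing calls by default (a "signal" is a call that produced
  one); `het_over_nonmissing = FALSE` switches to all samples. Both
  thresholds are strict (`> 0.10`), following the wording "more than 10%".

Group labels stratify cultivars by development era; the defaults cut at
1930 and 1974 (landraces/early cultivars, mid-century high-yield breeding,
modern quality breeding), both configurable in `assign_groups()`.

## Identity blocks and ancestral attribution

Two cultivars are *identical* over a stretch of SNPs when every compared
SNP carries the same homozygous state. A differing homozygous state or a
heterozygous call at either cultivar terminates a run; a missing call is
**bridged** — it neither matches nor breaks. Bridging (rather than
breaking) was chosen because array dropout is random with respect to
haplotype structure; `max_gap` bounds the number of consecutive bridged
SNPs for users worried about long uninformative stretches (default:
unlimited). Runs become physical intervals bounded by the **midpoints**
between adjacent SNPs — the same convention the graphical genotypes use
for cell borders, so block geometry and figures agree — rounded toward the
lower coordinate so that intervals tile exactly; runs touching a
chromosome's first or last SNP extend to the termini. Blocks shorter than
`min_length` (default 500 kb) are dropped; density is reported as matching
SNPs per 100 kb, and `flag_dense_long_blocks()` marks blocks strictly
longer than 2 Mb and denser than 1 SNP/100 kb as the best-supported ones.

**Attribution** walks each block up the pedigree. The unique-parent test
operates at block granularity: a block goes to a parent when that parent
is identical over the *whole* block and the other parent is not; when both
parents are identical over the whole block the origin is "unidentified"
(it may have come through either lineage — the gray class of a graphical
pedigree figure). When *neither* parent spans the block the block is a
mosaic, and it is re-segmented by the maximal identity runs against each
parent before recursing. Two numerical choices govern that re-segmentation:

* A stretch covered by both parents' runs counts as *genuine* shared
  ancestry only when it spans at least `min_length` **and** contains at
  least 10 supporting SNPs. Two unrelated inbred lines share a homozygous
  genotype at roughly half of all biallelic loci, so chance identity
  halves per SNP; ten SNPs bound the false-ambiguity rate near 0.1% per
  position, while a bp-only threshold would let 2–3 coincidentally
  matching SNPs masquerade as ambiguity at 200-kb marker spacing.
* Shorter contested stretches are boundary noise and are split at their
  midpoint between the flanking single-parent assignments. Within such a
  zone the data are genuinely uninformative about the true breakpoint
  (the posterior over its position is uniform), so the midpoint minimizes
  the worst-case error.

Attribution recurses to the deepest uniquely consistent ancestor; a
lineage whose genotypes are absent from the matrix closes at its last
genotyped member. `donor_fraction()` sums a recipient's donor-identity
blocks over the genome length (the full map length, not the covered
length); `consensus_blocks()` intersects several recipients' donor blocks
and labels intersections of at least 1 Mb with the donor's own ancestral
origin.

### How well can boundaries be localized?

A block recovered around a true recombination breakpoint extends past it
by however many SNPs the neighboring lineage happens to match — a
geometric number with mean about one at the ~50% per-SNP sharing rate of
biallelic markers. The contested zone this creates is irreducible: no
identity-by-state method can place the boundary more precisely than the
zone itself. In simulations at the default study scale (12 chromosomes,
382 Mb, ~1900 retained SNPs, six founders), `segment_recovery()` shows the
consequence: essentially every truth segment with at least 5 SNPs and
500 kb is attributed to the *correct founder*, but only ~75–80% also have
both boundaries within one inter-SNP interval of the truth; nearly all
remaining misses are off by two or more intervals at one boundary, exactly
the zones where the neighboring founder matched by chance. Users should
treat block boundaries as accurate to one or two marker intervals, never
to base pairs.

## LD calibration and the haplotype diversity index

Lewontin's D′ is computed directly from homozygous two-locus states
(haplotypes are observed in an inbred panel, not phased); cultivars
heterozygous or missing at either SNP are excluded, and pairs monomorphic
after exclusion are undefined. The profile bins pairwise D′ by physical
distance (200-kb bins to 5 Mb, the bin width following the panel's mean
SNP spacing of `mean_spacing(382150945, 1917)` ≈ 200 kb) and takes the
median per bin to damp outliers. Internally the sign of D is retained;
profiles report |D′|.

The sliding-window size is the candidate (2, 5, 10, 15 SNPs) closest to
the LD decay distance divided by the mean spacing. The decay criterion had
to be made explicit: the decay distance is the left edge of the first bin
whose median D′ falls below `theta = 0.5` of the first bin's median. On
profiles that decay near 2 Mb this recovers the 10-SNP window; on profiles
that never decay the largest candidate is returned with a warning, which
is the honest answer when LD extends beyond the profiled range.

The diversity index of a k-SNP window is the number of distinct k-state
haplotype strings divided by the **full group size**; cultivars with a
heterozygous or missing call anywhere in the window are excluded from the
count (consistent with restricting LD to homozygous calls) but the
denominator stays the group size, so missingness can only lower the index.
Chromosomes whose mean k-SNP window exceeds 10 Mb are skipped with a
warning — at that sparsity a "window" spans half a chromosome arm and the
index stops being local. Group comparison uses the Friedman rank test with
windows as blocks (`stats::friedman.test`; windows with an undefined index
in any group are dropped, and fully tied data return statistic 0). Both a
genome-wide and a per-chromosome mode are provided, since either reading
of "for each chromosome" is defensible.

## Graphical genotypes

`segment_row()` merges consecutive equal states into segments with
midpoint borders and full-terminus extension (a chromosome's first and
last SNP states run to the ends, matching the full-length bars of
published panels); a chromosome with no retained SNPs renders as a single
MISSING segment. `render_graphical()` writes a deterministic SVG at 13
pixels per Mb with a 1-pixel floor — so segments below about 77 kb
(1 Mb/13) collapse to a single pixel — using blue/yellow/dark-green/gray
for P1/P2/HET/MISSING.

## SNP effect classification

CDS models come from GFF3 (grouped by `Parent`), the reference from FASTA.
The affected codon is rebuilt on the coding strand (reverse complement for
minus-strand genes), the reference allele is validated against the genome,
and both codons are translated under the standard nuclear code:
synonymous, nonsynonymous, stop-gained, stop-lost, or noncoding outside
every CDS. Substitutions destroying the initiator ATG are reported as
nonsynonymous with a `start_lost` note. Models whose CDS length is not a
multiple of three are flagged and their SNPs classed `unknown`. A SNP
hitting several gene models gets one row per (SNP, gene) pair; per-SNP
summaries use the most severe class (stop > nonsynonymous > synonymous),
and per-gene tallies count a gene in the "both" category when it carries
both a synonymous and a nonsynonymous change.

## The simulator and what passing tests mean

The generator produces the statistical structure the analysis assumes,
with complete truth:

* **Genome.** 12 chromosomes with rice pseudomolecule lengths (382.2 Mb
  total), SNPs placed uniformly at random (or at fixed spacing). The
  default panel simulates 3834 designed SNPs so that roughly half —
  ~1900, at ~200-kb mean spacing — survive QC rule 4, emulating array
  ascertainment where only reference-vs-reference polymorphisms are
  informative.
* **Founders.** Fully homozygous landraces with alleles drawn
  independently at `maf = 0.5` per SNP. The real landraces' allele
  frequencies and relatedness are unknown, so the simplest exchangeable
  choice was made; 0.5 also minimizes chance identity between founders,
  which is the regime most favorable to block attribution.
* **Meiosis.** Haldane model (no crossover interference): crossover
  counts per chromosome are Poisson with mean equal to the map length in
  Morgans at `cM_per_Mb = 4` (≈1530 cM / 382 Mb for rice), positions
  uniform. The implied recombination fraction between points d Morgans
  apart is (1 − e^(−2d))/2, which the tests verify by Monte Carlo.
* **Breeding.** Each cross is advanced by `g = 6` generations of
  single-seed-descent selfing (residual heterozygosity (1/2)^g), then
  forced to fixation. Fixation operates per ancestry segment — wherever
  the two homologues descend from different founders, one is copied over
  the other with probability 1/2 — which resolves every residual
  heterozygous call and leaves a single founder mosaic per cultivar, so
  the truth tiling is exact. Assay noise (missing and heterozygous
  mis-calls) is applied per call at configurable rates.
* **Panels.** `simulate_panel()` builds the pedigree-analysis
  constellation (six landrace founders in a three-tier pedigree, a target
  cultivar, three target-derived recipients, one unrelated reference
  founder); `simulate_diversity_panel()` builds the three-group diversity
  panel (38 landraces, 49 mid-era crosses of random landraces, 64 modern
  cultivars bred from six elite parents — the bottleneck that depresses
  modern diversity).

What the simulator does **not** emulate: relatedness among landraces
(real landraces share ancestry, so empirical panels show higher baseline
LD and much lower Group-1 diversity indices than simulated ones),
selection, mutation, genotyping batch effects, and non-random missingness.
Passing tests therefore demonstrate that the algorithms are correct under
the stated genetic model, not that any particular empirical panel's
numbers will be reproduced.

## Problem sizes and determinism

The test suite runs the full 12-chromosome, ~1900-retained-SNP panel for
the acceptance-level checks and 4-chromosome, few-hundred-SNP panels for
module tests; the acceptance script additionally breeds the 151-cultivar
diversity panel. All generators are driven by a single integer seed, and
identical configuration plus seed reproduces outputs bit for bit,
including written files.

## Known limitations

* Boundary localization is limited to the contested-zone width (above);
  per-founder genome fractions inherit that uncertainty.
* Attribution is deterministic identity-by-state with a length threshold —
  no probabilistic IBD model, no genotyping-error tolerance inside runs
  beyond missing-call bridging.
* D′ and the diversity index assume essentially homozygous material;
  panels with substantial residual heterozygosity lose many calls to the
  homozygosity filters.
* The effect classifier handles single-nucleotide substitutions in
  annotated CDS only: no splice sites, UTRs, or regulatory annotation.
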
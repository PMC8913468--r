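---
title: "Methods: high-confidence variant-site filtering and strain divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: high-confidence variant-site filtering and strain divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainvar)
```

# The problem

Wild-derived inbred mouse strains drawn from the *Mus musculus* subspecies
(*domesticus*, *musculus*, *castaneus*, and the hybrid *molossinus*) are
near-fully homozygous and diverge from one another at roughly 0.15–0.33% of
sites within a subspecies complex and 0.71–0.88% between subspecies. Calling
variants in such panels from short-read resequencing is dominated not by
genotype uncertainty (sites are essentially haploid) but by *where* calls can
be trusted: repeats collapse into depth spikes, alignment artifacts pile up
at read ends, and mapping errors produce alleles supported by one strand
only. strainvar implements a filtering stack built around that observation:
it first defines **target regions** — the genomic territory where calls are
high-confidence — and only then emits calls, so that every downstream
statistic (pairwise divergence, allele-sharing distance, dendrograms,
pseudo-sequences) can be computed against an explicit callable denominator.

# Read QC

A base is marked low-quality when the arithmetic mean Phred quality over the
base and its adjacent neighbour on each side falls below 20. At read
termini the window is clipped to the existing bases, so a terminal base is
judged by the mean of two values; inventing phantom qualities beyond the read
end seemed worse than shortening the window. Marking is computed once on the
original read; the maximal marked runs at the 5' and 3' ends are then
trimmed in a single pass, and interior marked bases are retained. After
trimming, a pair survives only if both mates keep at least 20 nt.

One consequence of single-pass trimming with clipped windows is worth
stating: trimming is *not* exactly idempotent. A base that was unmarked on
the full read (its window reached a neighbour that is subsequently trimmed
away) can fall below threshold when the window is re-clipped on the trimmed
read. Re-running the trimmer therefore occasionally shaves another base or
two. We deliberately do not iterate to a fixed point: the procedure is
defined as mark-then-trim, its brute-force oracle is single-pass, and the
tests check that property rather than idempotence.

# The five exclusion criteria

Per individual, with defaults as in `filter_config()`:

1. **Depth.** Genome-wide mean and population standard deviation of depth
   are computed over covered positions (depth ≥ 1); positions with depth
   below 10 or above mean + 2.5 SD are excluded. Both boundaries are
   inclusive on the passing side; the upper boundary being inclusive is our
   choice where the rule's wording does not decide it. Restricting the
   statistics to covered positions treats depth as a property of mapped
   coverage rather than of the genome; including the zeros would drag the
   mean down with unmappable territory.
2. **Strand coverage.** A position must be covered by at least one forward
   and one reverse read, summed over alleles.
3. **Indel adjacency.** Each indel's reference footprint, padded by 10 bp on
   each side, is excluded from SNP target regions. The indel calls
   themselves are never removed by this criterion, and the callable mask
   used to retain indel calls is computed *without* this exclusion. Indel
   calls are consumed as an upstream list (the product of a dedicated indel
   caller); this package does not re-implement indel discovery.
4. **Strand balance.** At a candidate variant site, every allele that is
   part of the genotype must be supported by at least one read on each
   strand. "Part of the genotype" means its allele fraction reaches the
   heterozygous lower band (`het_low`, default 0.25): for a balanced
   heterozygous-looking site both reference and alternative alleles must be
   two-stranded (ref A 20F/12R with alt G 15F/18R is retained; ref A 18F/0R
   with alt G 19F/22R is biased), while a clean homozygous site — whose
   reference allele is absent — is judged on the alternative allele alone.
   Reading the rule as "all four counts ≥ 1" unconditionally would discard
   every homozygous SNP in an inbred strain, which is plainly not intended;
   the genotype-allele reading reproduces the worked examples and preserves
   homozygous calls. Biased sites and 10 bp on each side are excluded.
5. **Read-end artifacts.** A candidate site whose alt-supporting reads lie,
   on average, within 10 bp (inclusive) of their read's nearest end is
   excluded with the same 10 bp pad. We average over the *alt-supporting*
   reads and measure to the *nearest* end: the filter targets alignment
   artifacts at read termini, and those manifest in the reads that carry the
   alternative allele. When end distances are unavailable (pileups parsed
   from mpileup-dialect text, which does not carry them), the check passes.

Criteria 4 and 5 are evaluated at **candidate sites**: positions whose top
alternative allele reaches the genotype fraction (`het_low`). Evaluating
them at every position with any mismatching read would let isolated
sequencing errors (fraction ~1/depth) carve 21-bp exclusion windows across
the genome, destroying callable territory for no gain; candidacy mirrors
the fact that the original filters were applied to called variant sites.

The target is then `(depth ∩ strand-coverage) − (indel ∪ bias ∪ end)`
as interval algebra over 0-based half-open intervals (IRanges underneath);
a per-position brute-force evaluator is kept in the test suite and the
acceptance script as an independent oracle, and the two agree exactly on
randomized instances.

## Genotype classes

Zygosity is assigned from the alt-allele fraction of depth: homozygous at
≥ 0.8, heterozygous in [0.25, 0.75], no call in between. These bands are
configuration, not doctrine — the upstream genotyper they stand in for is a
black box — and they matter mainly in that `het_low` doubles as the
genotype-allele threshold of criterion 4. Multi-allelic columns are reduced
to their most frequent non-reference allele; additional alleles are ignored
rather than guessed at.

# Comparative statistics

**Percent divergence** between two strains is 100 × (jointly callable,
homozygous sites with different alleles) / (effective length), where the
effective length is the total length of the intersection of the two strains'
callable masks. Using the callable intersection as denominator is what makes
the statistic comparable across strain pairs with different coverage.
Heterozygous and missing sites are dropped pairwise; rounding (two decimals
in the conventional table layout) happens only at presentation.

**ASD** (allele sharing distance) for fully homozygous inbred lines
collapses to the mismatch proportion over jointly callable sites, which is
what `asd_matrix()` computes; the general two-allele form (0/0.5/1 per
site) is inert for inbred inputs and heterozygous codes are simply dropped
pairwise.

**UPGMA** is implemented directly (size-weighted average linkage, node
height = merge distance / 2) rather than through a library call, because
determinism under ties is part of the contract: ties are broken towards the
pair whose members come first in the input label order. `stats::hclust`
(average linkage) and ape's cophenetic distances serve as independent
cross-checks in the tests. On ultrametric inputs the output's cophenetic
matrix reproduces the input exactly (to floating precision; branch lengths
are serialized at full `%.17g` precision).

**Subspecies-specific sites** require the site to be callable in every
strain of the table, the same non-reference allele in every in-group
strain, and that allele absent outside the group — the conservative reading
of "specific"; a site missing in one in-group strain is not counted.

**Novelty counting** against an external catalog matches `(chrom, pos,
alt)` against at most the first three alternative alleles recorded per
catalog site. "Up to the third candidates" is ambiguous; we read it as the
third-ranked alternative allele and document that choice here. Totals are
conserved: novel + known equals the input size.

# Pseudo-sequences

`cut_sequence()` applies a strain's calls to the reference over a 1-based
inclusive region (the coordinate idiom of genome-browser position
intervals; 0-based half-open internally). In `snp_only` mode the output
length equals the region length; homozygous SNPs substitute, heterozygous
SNPs emit IUPAC ambiguity codes (A/G → R) because picking an arbitrary
allele would discard information. In `with_indels` mode insertions and
deletions splice the sequence right-to-left so earlier coordinates stay
valid; overlapping variant footprints are an error naming the collision,
and an indel straddling the region boundary asks for a larger region rather
than guessing. The default no-data policy emits the reference base
(consensus-from-pileup behaviour); `n_fill` writes `N` at reference
positions outside the callable mask, evaluated in reference coordinates
before indels are applied. The default region ceiling is 300 kb, matching
the broad map-view range of the associated browsers.

# Phenotype statistics

Derived traits: adiposity index `AI = (SFAT + VFAT + DBAT)/BW × 100`;
`BMI = BW/BL² × 100` with BW in g and BL (nose-to-anus) in **mm**, which
lands mouse BMI on the conventional ~0.2–0.4 g/cm² scale; organ weights are
re-expressed as percent of body weight. Zero or missing denominators
produce `NA` with a warning rather than infinities.

Pairwise comparisons use the two-sided Welch (unequal-variance) t-test —
the default of the statistical environment the analysis convention comes
from — with Bonferroni correction `min(1, p × m)` where the family `m` is
all testable strain pairs *for one trait within one sex*; sexes are always
analysed separately. Classes: highly significant below 0.001, significant
below 0.05, on the corrected p-value. A strain-sex cell with fewer than two
usable animals renders its pairs untestable (`nd`) and shrinks the family.
Values at or above a configured instrument ceiling are censored before
testing. Boxplot summaries follow the default convention: hinges at the
quartiles, whiskers at the most extreme points within 1.5 × IQR.

# The synthetic-data generator

The generator exists so that every module is testable against known truth
without downloads, and its defaults encode the study conditions the
package targets.

* **Strain genomes.** An ancestral (reference) genome with uniform base
  composition evolves down a rooted strain tree whose branch lengths are
  per-site substitution probabilities; substitutions per branch are
  Binomial(L, p) at uniformly chosen sites, to a uniformly chosen other
  base. The default ten-strain tree is ultrametric with two
  domesticus-like, five musculus-like, one castaneus-like and two
  molossinus-like strains, the molossinus pair nested inside the musculus
  clade's divergence band; its heights place every within-complex pair in
  0.15–0.33% and every between-lineage pair in 0.71–0.88%. Within those
  bands the internal heights were spaced (minimum gap 2.5 × 10⁻⁴
  substitutions/site) so that average-linkage clustering of realized
  distances at the ~10⁴-variant-site scale recovers the generating topology
  reliably — a design-time power consideration, fixed once. Short indels
  (1–10 bp, truncated-geometric lengths) are placed on terminal branches
  with footprints that never collide with other variants, so truth call
  sets are well-formed and round-trippable.
* **Reads.** Fragments are placed uniformly; each yields a forward and a
  reverse read (default 2 × 100 bp, 300 bp insert, 30×), with per-base
  substitution errors at 0.1% — a short-read error floor. Reads are drawn
  from the strain's SNP-applied genome in indel-free coordinates, with the
  pileup's reference column taken from the mapping reference; indel calls
  enter the pipeline as the explicit upstream list they are in practice.
  Injected artifacts are realized exactly: a strand-biased site flips every
  forward-strand observation to one alternative allele (alt support is
  single-stranded by construction); a read-end artifact flips every
  observation within 10 bp of its read's nearest end (mean alt end distance
  ≤ 10 by construction); a depth spike multiplies pileup depth over a
  window. Requested artifacts that cannot be realized at the simulated
  depth raise an error rather than silently degrading the truth set.
* **Phenotypes.** Animal values are strain-sex means plus Gaussian noise,
  so an all-equal configuration is an exact null for family-wise error and
  a 5σ planted effect is a power control.

All generators are pure functions of their seed and configuration, and they
restore the caller's RNG state.

**What the simulator does not emulate** — and hence what green tests do and
do not show about real data: there is no read mapping step (reads sit at
their true positions, so reference bias, multi-mapping leakage and indel
misalignment around repeats are absent); base qualities are flat; error
rates are position-independent; no PCR duplicates, contamination or
residual heterozygosity. The filter stack is therefore validated as a
*specification* of the filtering rules against controlled violations of
them, not as an end-to-end benchmark of a production mapping pipeline.

# Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately modest sizes
chosen to exercise the asymptotics that matter while staying quick:
randomized filter-oracle instances at 150–500 bp with Poisson pileups (200
instances), artifact rejection and recovery at 50 kb × 30×, divergence
recovery at 100 kb × 30× for two strains at 0.8% divergence, dendrogram
recovery over 100 replicate tables of ~10,000 variant sites, and a
1,000-replicate phenotype null (5 strains × 2 sexes × 8 animals). Where a
quantity is an estimate, tests assert within three binomial standard
errors of the generating value rather than equality.

Coordinates are 0-based half-open internally and converted at the edges:
1-based in VCF and the flat call TSV, 0-based in BED, 1-based inclusive in
user-facing region requests. Ties in UPGMA break by input label order; the
most frequent alternative allele ties break by A < C < G < T column order.
Degenerate inputs fail loudly: empty pileups for depth statistics, zero
effective length between strains, fewer than two UPGMA labels, regions off
the chromosome end, overlapping variants in pseudo-sequence extraction.

# Known limitations

* The strand-balance reading (genotype alleles only) and the end-distance
  reading (mean over alt-supporting reads, nearest end, inclusive) are
  documented interpretations of ambiguous rule statements, not assertions
  about the original authors' code.
* Single-pass trimming is not idempotent at clipped-window termini (above).
* `read_mpileup()` recovers strand-resolved allele counts but not
  end distances or indel observations from mpileup text; the end-distance
  criterion is inert on such input.
* The simple fraction-threshold genotyper is a stand-in interface for
  whatever caller produced the pileup; it is not base-quality aware and
  makes no claim to genotype-likelihood correctness.
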
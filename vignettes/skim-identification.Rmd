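---
title: "Identifying a degraded specimen from a genome skim: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying a degraded specimen from a genome skim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Museum and archaeological specimens yield small amounts of highly degraded
DNA: short fragments (typically under 100 bp), chemical damage, and heavy
contamination by non-target DNA. Low-coverage shotgun sequencing — *genome
skimming* — is often the only practical assay. skimprov implements the
complete desk workflow that turns such a read set into a specimen
identification:

1. **Species** — competitive mapping against a panel of candidate
   reference genomes and a call from the *one-genome-only* read share.
2. **Authenticity** — the terminal C→T deamination profile that
   distinguishes genuinely old DNA from modern contamination.
3. **Genetic sex** — the chromosome-length-normalized X/autosome ratio of
   uniquely mapped reads.
4. **Hybrid status** — an f3 admixture statistic with a weighted block
   jackknife.
5. **Matriline and geography** — a depth-masked mitogenome consensus
   placed among labelled reference haplotypes by neighbor joining with
   bootstrap support.

Every stage is driven by a seeded simulator with recorded ground truth, so
the whole pipeline is testable offline; the same stage functions accept
external FASTA/FASTQ data.

## The simulator: what it emulates, and what it does not

`simulate_reads()` draws fragments from a donor genome embedded in a panel
of related references (`make_reference_panel()`). Its defaults are anchored
to what well-preserved degraded skims actually look like: mean fragment
length 59 bp (SD 12, truncated below at 30 bp), terminal C→T damage
probability 0.10 at the first 5′ position, and a configurable endogenous
fraction (the pipeline default, 0.6, sits at the well-preserved end of the
range such extracts show; published elephantid skims span roughly 24–63%).

The damage model is a single-exponential positional law applied after
fragment extraction, in read orientation: a C at 0-based 5′ position $i$
reads as T with probability $p_0 e^{-\lambda i}$, and symmetrically a G at
3′ position $j$ reads as A (double-stranded library chemistry). Published
profiles report only terminal frequencies, so the decay constant
$\lambda$ (default 0.3) and the fragment-length SD are free parameters of
this package. Base qualities are constant Q30: no downstream stage uses
them, and simulating quality noise would only blur the ground truth.
Truth labels (donor, source sequence, 0-based start, strand, damage count)
live in a sidecar TSV so the FASTQ itself stays standard.

Deliberate simplifications: no indels, no sequencing-error model beyond
deamination, no microbial background — the contaminant is another genome
*inside* the panel (by default the one most divergent from the donor).
A closed panel keeps every read's fate interpretable, but it also means a
high contaminant fraction behaves like a second congeneric sample rather
than unmappable noise; passing tests therefore demonstrate correct
behavior of the statistics under this model, not robustness to the full
messiness of real metagenomic backgrounds.

## Mapping: a deterministic k-mer-seeded ungapped mapper

`build_index()` stores every k-mer (default $k = 16$) of every panel
sequence on both strands; `map_reads()` seeds each read's k-mers on a
stride (default 4, the final window always included), extends every
candidate locus by full-length ungapped comparison, and keeps hits with at
most $\lceil f \cdot \mathrm{len} \rceil$ mismatches (default
$f = 0.1$). The score is $\mathrm{matches} - 2\,\mathrm{mismatches}$; a
read is *unique in a genome* when its best locus leads the second best by
at least 4 score points (ties at distinct loci are never assigned).
Ungapped alignment is a deliberate choice: ancient fragments are short,
the screen is read-count based, and indels would add cost without moving
category counts materially. `N` counts as a mismatch on either side.
Coordinates are 0-based half-open internally and 1-based in exported
tables.

Seeding is exhaustive for lightly damaged reads but is a heuristic in the
worst case: a read of length $L$ is guaranteed to be found only when it
has fewer than $\lfloor L/k \rfloor$ mismatches (pigeonhole over disjoint
seed windows — at the 30 bp minimum length every 16-mer window overlaps
the read centre, so a single central mismatch can defeat seeding). The
test suite's oracle-equivalence check — identity against a brute-force
all-offset `matchPattern` scan, per hit and per uniqueness flag — is
therefore run on exact reads, where the guarantee is unconditional.

Duplicate removal collapses hits sharing (genome, sequence, start, strand,
length) to the representative with fewest mismatches (ties: smallest read
id), mirroring PCR-clone removal; it is idempotent and feeds every
downstream counter, because duplicated fragments would pseudo-replicate
damage events and coverage.

## The species screen and the mismatch budget

`screen_reads()` classifies every mapped (read, genome) pair into the four
classical screen categories — unique-here-only (A), multi-here-only (B),
unique-here-but-also-elsewhere (C), multi-here-and-elsewhere (D) — and
`assign_species()` calls the genome maximizing the one-genome-only share
(A+B) when its lead is at least `min_margin` percentage points (default
2; the underlying verbal argument, "a much higher percentage", carries no
published threshold, so the margin is this package's explicit rule).

The informativeness of the exclusive categories depends on the ratio of
panel divergence to the mismatch budget. At 5% divergence and the
mapper's default $f = 0.1$ budget, essentially every endogenous read
cross-maps (the expected ~3 mismatches over 59 bp sit well inside the
budget of 6) and A+B collapses toward zero for all genomes. The screen
stage therefore defaults to $f = 0.015$, putting the budget at a third of
a 5% divergence; as a rule of thumb the screen is reliable when divergence
is at least 3× the budget. The damage stage, conversely, *must* use the
permissive budget: a strict budget censors exactly the reads that carry
terminal damage and biases the estimated terminal frequency downward. The
pipeline uses both mappings, one per purpose — the same reason real
workflows use different aligner settings for screening and damage
profiling.

`conplastic_check()` compares the nuclear and mitochondrial screen
assignments; discordance (the signature of a conplastic or hybrid
individual, which carries one species' mitogenome on another's nuclear
background) is flagged for the f3 follow-up rather than decided outright.

## Damage profiling and authentication

`estimate_damage()` tallies, over unique deduplicated hits, ref-C sites
and C→T events per 5′ offset and ref-G / G→A per 3′ offset (first 25
positions each; reads shorter than 50 bp contribute to both windows, with
overlap — simpler than exclusion and unbiased under the positional
model). Only those two substitution classes are damage under the
double-stranded model; all other mismatches are pooled into a background
rate that separates divergence noise from damage signal.
`authenticate_damage()` applies three explicit sub-checks: terminal 5′
frequency ≥ 0.05, terminal frequency above the interior mean (positions
10–24), and mean read length ≤ 100 bp. The cutoffs follow common
ancient-DNA practice; the source analyses report observed ranges
(7.7–11% terminal damage, 58–60 bp), not thresholds.

## Genetic sex

`normalized_ratio(reads_X, reads_A, len_X, len_A)` is the quotient of
per-bp read densities; with a diploid autosome the expectation is ~1.0
for an XX individual and ~0.5 for XY. `call_sex()` uses an explicit
abstention band: female at ≥ 0.8, male at ≤ 0.6, ambiguous between —
low-count degraded data deserve an abstention region rather than a
midpoint cut, and published descriptions ("close to 1", "closer to
0.5") fix no boundary. `sex_from_mapping()` additionally forces
ambiguity below 200 informative reads, where the binomial SD of the ratio
exceeds the band width. The reference is assumed to lack a Y sequence, as
is common for the relevant assemblies; X-dosage in simulations is
expressed through the `copy_number` weight of `simulate_reads()`.

## The f3 admixture test

For target C and sources A, B, the statistic is the mean over usable
sites of $(c-a)(c-b)$ on derived-allele frequencies. Two estimator
details matter:

* **Target sampling correction.** When C is a *sample* of $n_C \ge 2$
  alleles, the sampling variance of $\hat c$ biases the product upward and
  the unbiased correction $\hat c(1-\hat c)/(n_C-1)$ is subtracted per
  site. For a single pseudo-haploid specimen ($n_C = 1$) the correction is
  undefined and is not applied; the uncorrected expectation equals the
  within-population heterozygosity of the target's sources and is
  therefore **non-negative whether or not C is admixed**. A
  single-specimen f3 is thus sign-conservative: it can support "no
  evidence of admixture" (as positive values do) but has essentially no
  power to *detect* admixture. Detection power belongs to the
  population-frequency variant, which the test suite exercises with mosaic
  targets of $n_C = 10$ haplotypes.
* **Transversions only** by default: deamination inflates transition
  mismatches in ancient DNA, tying directly to the damage module's
  rationale.

`block_jackknife()` partitions sites into contiguous physical blocks
(default 5 kb), computes delete-one-block estimates, and applies the
weighted jackknife (weights = usable sites per block; with equal weights
it reduces exactly to the plain delete-one formula, which the tests
verify in closed form for two blocks). `interpret_f3()` calls "admixed"
only for $f_3 < 0$ with $Z \le -3$.

The pipeline's f3 stage must bridge a structural gap: a pseudo-haploid
specimen against two *fixed* reference sequences yields identically zero
products at every source-differential site (the specimen's base always
equals one of the two sources), a degenerate jackknife. The stage
therefore simulates small within-species source panels (default 10
alleles, 1% incomplete-lineage-sorting noise) around the two top-screened
genomes and tests the specimen's calls against those frequencies. For a
pure donor every per-site product is ≥ 0 and the verdict is "no evidence
of admixture" with a positive Z — the same sign behavior single-specimen
f3 shows in practice.

`simulate_f3_matrix()` provides the calibrated test bed: Balding–Nichols
drift (default $F_{ST} = 0.2$) around uniform ancestral frequencies,
binomial source panels, and a target that is either a null sample from
A's population or a block mosaic (independent ancestry per haplotype per
1 kb block, admixture fraction $\alpha$). Under the corrected estimator
the mosaic expectation is $-\alpha(1-\alpha)\,E[(p-q)^2] < 0$ and the
null expectation is 0, which is exactly what the acceptance properties
(negative in 20/20 admixed seeds, $|Z| < 3$ in ≥ 18/20 null seeds)
check.

## Mitogenome consensus with depth masks

`call_consensus()` emits, per site, `N` below the depth threshold,
otherwise the strict-majority base, with exact ties masked to `N` (rather
than IUPAC codes: downstream distances treat `N` uniformly as missing, so
tie-masking and depth-masking compose cleanly). Output is
reference-length: the ungapped mapper calls no insertions, and deletions
surface as depth gaps. The classical "with and without filtering" pair is
`min_depth = 1` versus `3`; `consensus_report()` reports mean depth,
zero-depth and below-threshold percentages, and %N per variant, and the
masking is provably monotone in the threshold (the `N`-set at depth $d$
is a subset of the set at $d' > d$). At a ~3× skim the depth-3 mask
removes roughly 40–50% of sites while the depth-1 mask removes ~5% — the
contrast low-coverage mitogenome work reports. An optional damage-aware
mask for sites whose majority hinges on a terminal C→T/G→A read
difference is off by default; a manually curated consensus cannot be
reproduced by rule, so only the rule-based variants are first-class.

## Placement: distances, NJ, bootstrap, clade call

Haplotypes are assumed pre-aligned (a strict same-length check replaces
alignment — reference mitogenome panels come aligned, and multiple
sequence alignment is out of scope). `pairwise_distance()` computes p- or
K2P distances with *pairwise deletion*: each pair is compared only over
sites where both carry an unambiguous base. Pairwise (not complete-case)
deletion is forced by the use case: a depth-3 consensus carries ~45%
missing data, and complete-case deletion would empty the matrix. K2P
domain violations and zero-usable pairs are hard errors naming the pair.

`neighbor_joining()` is the Saitou–Nei agglomeration with two
determinism guarantees: Q-ties break on the lexicographically smallest
pair of subtree keys (the minimal leaf label of each subtree), and
negative branch lengths clamp to zero with the total deficit recorded on
the tree. On additive matrices it reproduces the generating tree exactly
(topology and lengths; the tests assert to 1e-9 and cross-check the
topology against an independent NJ implementation).
`bootstrap_support()` resamples alignment columns with replacement,
recomputes distances and the tree per replicate (replicates whose
distances fail are dropped and counted), and scores each internal edge of
the full-data tree by the percentage of successful replicates containing
the same bipartition. Internally each pair's per-column event indicators
are precomputed once so a replicate costs two matrix–vector products
rather than an alignment scan.

`assign_clade()` assigns the query to the label of the *minimal*
bipartition containing it together with leaves of exactly one clade;
when no monochromatic bipartition contains the query (e.g. an attachment
between clades in a panel of ≥ 3 clades) the result is "unresolved". The
support quoted with the call is that of the query-plus-whole-clade
bipartition — the grouping the claim is actually about — because
within-clade cherries are legitimately unstable under bootstrap even when
the clade membership itself is at 100%. ML tree search and
partition-model selection are out of scope by design: they reproduce
external-software behavior on alignments this package does not ship, and
NJ with bootstrap covers the placement claim at desk scale.

## The pipeline

`run_pipeline()` wires the stages with one master seed; each stage draws
from a seed derived from the master seed and the stage name, so any
subset re-runs identically. The default synthetic scenario: a 3-genome
nuclear panel (chrX-like 50 kb + autosome-like 54 kb per genome, 5%
divergence), a 4-clade mitogenome panel (16 kb, 5% between / 0.5% within
clades, 4 haplotypes each, one clade's first haplotype serving as each
species' reference mitogenome), 20,000 nuclear reads at 60% endogenous,
and a ~3× mitochondrial skim. Reports are JSON plus a text summary;
omitted stages are marked `"skipped"`, and a stage failure halts the run
with the stage name after preserving the partial report. The test suite
runs the same scenario at reduced sizes (16–18 kb chromosomes, 5,000–6,000
reads, 6–8 kb mitogenomes, 40–100 bootstrap replicates) so a full
end-to-end recovery check over ten seeds completes in about a minute;
these sizes are the package's test-scale choice of the same scenario, and
all thresholds are identical at both scales.

```{r}
library(skimprov)
report <- run_pipeline(list(seed = 11), out_dir = "run1")
print(report)
```

## Numerical and degenerate-input choices

* Mismatch ceilings use `ceil(f * len)` with a 1e-9 guard against
  floating-point overshoot (`0.1 * 60` is not 6 in binary).
* NJ Q-minimization tolerates 1e-12 absolute slack before tie-breaking;
  newick branch lengths keep 12 significant digits internally.
* Empty pileups produce all-`N` consensus with a warning, not an error;
  zero autosomal reads make the sex ratio an error (not infinity); an f3
  jackknife with identical blocks errors as "degenerate" rather than
  reporting Z = ±∞.
* All randomness flows through explicit integer seeds, and the simulator
  is byte-deterministic given its config (the tests compare FASTQ files
  byte for byte). Seeded helpers restore the caller's RNG state.

## Known limitations

* The screen's exclusive categories lose information when panel
  divergence is below ~3× the mismatch budget, and a closed-panel
  contaminant at ≥ 50% can legitimately dominate them; both effects are
  properties of the model, surfaced in the margin and the ambiguous call.
* Single-specimen (pseudo-haploid, uncorrected) f3 cannot produce negative
  expectations and therefore cannot positively detect admixture; it can
  only fail to reject purity. The population-frequency variant carries the
  power.
* The mapper is ungapped and its seeding is heuristic beyond
  $\lfloor L/k \rfloor - 1$ mismatches.
* No MALT-style metagenomic assignment (requires an external database),
  no ML/Bayesian phylogenetics, no radiocarbon or morphological evidence
  — the package covers the sequence-analysis workflow only.
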
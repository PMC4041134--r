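---
title: "Methods: two-library small-RNA miRNA discovery and differential expression"
author: "srnamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small-RNA miRNA discovery and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnamir)
```

# Scope

`srnamir` implements the classical single-replicate two-library small-RNA
sequencing analysis used in plant miRNA studies: raw reads from a control
and a treatment library are cleaned and collapsed to unique tags, tags are
perfect-match mapped to a genome and pushed through an annotation cascade,
known miRNAs are called by exact identity with a mature catalog, novel
miRNAs are predicted from unannotated mapped tags by hairpin criteria, and
per-miRNA counts are compared between the two libraries with an exact
count-based test. A synthetic-data module generates complete two-condition
experiments with known ground truth so that every stage — and the pipeline
end to end — is testable without any external download.

# Read cleaning

Reads are discarded for exactly one reason, evaluated in a fixed order so
that tallies are reproducible: `low_quality`, `adaptor5_contaminant`,
`no_3prime_adaptor`, `no_insert`, `poly_A`, `too_short`. Definitions that
the classical pipelines leave implicit had to be fixed here:

* **Low quality**: more than 10% `N` bases, or any base below Phred 10
  (both configurable in `cleaning_config()`). This is conventional Illumina
  small-RNA practice.
* **3' adaptor**: exact match of the first 8 adaptor bases, leftmost
  occurrence wins; the insert is everything upstream. One mismatch can be
  allowed, but the default is exact so that tallies are bit-reproducible.
* **Poly-A artifact**: insert with at least 80% adenine or a terminal run
  of 10 or more A's — targets oligo-dA artifacts without discarding
  legitimately A-rich miRNAs.
* **Length**: inserts below 18 nt are discarded; inserts above 30 nt are
  kept in the clean set (they count toward library totals) but fall outside
  the miRNA length window.

The invariant `clean + discarded = raw` holds on every input and is
property-tested on randomized junk mixtures.

# Annotation cascade

Tags are perfect-match aligned to the genome on both strands; no mismatches,
no splicing. Each tag receives exactly one category with the priority

`miRNA > rRNA > tRNA > snRNA > snoRNA > exon_sense > exon_antisense >
intron_sense > intron_antisense > unannotated`

The order is configurable; the default preserves miRNA counts over
housekeeping ncRNA, mirroring the usual removal cascade. ncRNA categories
are strand-aware (a tag antisense to an rRNA locus is not rRNA). A `miRNA`
call requires exact (T/U-normalized) identity with a mature catalog entry —
isomiRs and length variants deliberately do not count. Category percentages
are reported per library against the unique-tag and total-read totals, with
the two-decimal round-half-up convention of printed summary tables.

The exact-match index prefilters query tags by a hash join on their first
18 bases against the set of genome substrings (both strands) before running
the positional search. This is an O(genome) structure aimed at the package's
testing scale (toy genomes up to a few hundred kilobases), not at full plant
genomes; swapping in an FM-index-backed mapper behind `genome_index()` would
be the natural extension.

# Novel miRNA prediction

Unannotated tags with 1–20 perfect genomic hits anchor candidate hairpins.
The criterion set is the conventional plant parameterization: mature length
18–25 nt, star length 20–23 nt, precursor minimum free energy at most
−18 kcal/mol, at most 300 nt between miRNA and miRNA\*, at least 16 base
pairs in the duplex, bulge at most 4 nt, duplex asymmetry at most 4 nt,
flank 20 nt, at most 20 genome copies.

Because the mature arm may sit on either side of the hairpin, two scan
windows are folded per hit: one extending `flank + max_spacing +
max_ref_len` upstream and one downstream (with `flank` on the near side).
Folding the wide scan window can entangle a few mature bases in long-range
pairings, so prediction is two-stage, as in hairpin-excision tools: the
window fold only locates the star arm (the densest contiguous cluster of
pairing partners; clusters are split at gaps > 10 nt), then the precursor is
trimmed to `[miRNA..miRNA*] ± flank` and refolded, and all criteria are
evaluated on that local structure. The star arm is extended by the canonical
2-nt 3' overhang of Dicer products, and this extension participates in the
spacing arithmetic. Duplex statistics are defined as: `paired_bases` =
mature positions paired into the star span; `max_bulge` = longest unpaired
run strictly interior to the duplex on either strand; `asymmetry` =
absolute difference of interior unpaired totals.

When several tags stack on one arm, the most abundant tag defines the
mature 5' end (a Dicer-cleavage proxy), candidates from the same hairpin are
merged by precursor-locus overlap, and a predicted miRNA's per-library count
sums tags exactly equal to its mature sequence.

Two folding backends stand behind `fold_rna()`: the ViennaRNA
nearest-neighbor folder (`RNAfold`, run as a batch process; the default
when the binary is on the PATH) and a bundled weighted base-pair
maximization dynamic program (compiled) with pair pseudo-energies G:C −3,
A:U −2, G:U −1 kcal/mol and a 3-nt minimum loop. The bundled model is
coarse; the synthetic designer therefore requires every designed precursor
to satisfy the criteria *with margin* (≥ 2 extra duplex pairs, bulges ≤
`max_bulge − 2`, MFE at least 5 kcal/mol below threshold) so that verdicts
do not flip between backends.

# Differential expression

Counts are normalized as tags per million clean reads,

$$\mathrm{TPM} = \frac{\text{count}}{\text{total clean reads}} \times 10^6,$$

and the fold change is $\log_2(\mathrm{TPM}_{\text{treatment}} /
\mathrm{TPM}_{\text{control}})$, with a pseudo-TPM floor of 0.01 applied
only inside the fold change (never in the test, which uses raw integer
counts). miRNAs below 10 TPM in *both* libraries are removed before
testing; reading the filter as "below in either library" is available via
`filter_mode = "either"`.

The test is the exact two-library (digital gene expression) test: with
library totals $N_1, N_2$ and counts $x, y$,

$$p(y\,|\,x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}},$$

with lower tail $C(y) = \sum_{k \le y} p(k|x)$ and upper tail
$D(y) = 1 - C(y-1)$. The reported p-value is two-sided,
$\min(1, 2\min(C, D))$, which is conservative and direction-symmetric; a
one-sided option exists. A miRNA is called differentially expressed at a
linear 1.5-fold cut-off ($|\log_2 \mathrm{FC}| \ge \log_2 1.5$) and
$p < 0.01$; a `--fc-scale log2`-style switch (`fc_scale = "log2"`) treats
the cut-off as a log2 threshold instead. No multiple-testing correction
enters the calls (a BH column is emitted for downstream use only).

Numerical notes. Tails are computed in log space with `lgamma` and
log-sum-exp, so counts in the tens of thousands do not overflow. The
complement form of $D$ has an absolute rounding floor near $10^{-16}$;
whenever the complement falls below $10^{-3}$ the implementation switches
to direct upward summation of the tail, giving close to full relative
precision for arbitrarily small p-values. One caveat worth stating: the
two-sided tail p-value is *not* exactly symmetric under exchanging the two
libraries at small counts (the pmf $p(y|x) = p(x|y)$ is symmetric at equal
depths; the half-open discrete tails are not) — this is a property of the
conditional formulation itself.

# Target prediction

Target sites are scored by gapless antiparallel alignment of the miRNA
against every transcript window of its length: mismatch 1.0, G:U wobble
0.5, and (if enabled) gap 2.0 penalty units, all doubled at miRNA positions
2–13; sites above a penalty cap (default 4.0) are dropped. These are the
conventional plant-miRNA complementarity rules. Positional constraints can
additionally be enforced: no mismatch opposite positions 10–11 (the
cleavage site) and at most one mismatch in positions 2–12. G:U wobbles
count toward the penalty but not toward these positional mismatch flags.
The scanner is exhaustive by construction and is verified against an
independently written window scorer. Hybridization free energy is not
scored; the rule set is purely complementarity-based.

# qPCR validation

Relative expression uses the ddCt model with amplification efficiency fixed
at 2 and a reference gene: $\Delta Ct = Ct_{\text{target}} -
Ct_{\text{reference}}$ per replicate, $\Delta\Delta Ct = \overline{\Delta
Ct}_{\text{treatment}} - \overline{\Delta Ct}_{\text{control}}$, and
$\mathrm{RE} = 2^{-\Delta\Delta Ct}$ with the control condition fixed at 1.
Sequencing/qPCR concordance counts a miRNA as validated when the qPCR
direction matches the sequencing call *and* the replicate
$\Delta Ct$ difference is significant (Welch t-test at 0.05); a
direction-only mode is available, since "comparable in magnitude" admits
more than one operationalization. The rate is reported as a percentage to
one decimal.

# The synthetic experiment generator

`synthetic_spec()` fixes the study conditions used across the test-suite:

* 100-kb i.i.d. uniform background genome, one chromosome;
* 20 planted miRNA precursors (mature lengths 20–24 nt with the mode at
  24 nt, echoing plant sRNA length profiles), placed with ≥ 100 nt
  separation on random strands;
* 4 up- and 4 down-regulated miRNAs at 4-fold (|log2 FC| = 2), the rest
  unchanged;
* baseline control abundances log-normal (median 400 TPM, log-sd 0.8)
  truncated to [50, 20000] TPM — low-TPM miRNAs near the truncation floor
  are intentionally hard cases for the exact test at this depth;
* 200,000 reads per library; junk fractions 5% poly-A, 5% missing 3'
  adaptor, 3% insertless, 5% sub-18-nt, 2% low quality (injected `N`
  bases, constant `I` qualities otherwise);
* 6 ncRNA decoy loci (rRNA/tRNA) receiving 20% of clean reads; the
  remaining clean reads are unannotated random background.

Each read draws its class from a single categorical distribution, so class
counts are multinomial: every planted miRNA's count is binomial with the
intended mean (Poisson-like at these fractions), FASTQ record counts equal
the configured depth exactly, and filter tallies are analytically
checkable. A per-locus gamma multiplier (`dispersion > 0`) provides
negative-binomial overdispersion when wanted; calibration tests use the
Poisson-like default, matching the sampling model the exact test assumes.

Designed precursors are `mature + loop + star`, the star a reverse
complement carrying 1–2 G:U wobble substitutions so the mature sequence
stays genomically unique while remaining fully paired. The designer searches
with the bundled folder and verifies the accepted set with the default
backend in one batch, erroring for matures that cannot form a stable stem
(e.g. homopolymers). What the generator does **not** emulate: sequencing
errors, base-composition bias, isomiR clouds, multi-mapping repeat families,
degradation products, or biological replicates. Passing recovery tests on
this generator therefore demonstrates correctness of the pipeline's logic
under its own sampling assumptions, not performance on real libraries.

# Problem sizes and budgets

The recovery study in the acceptance suite runs 20 independent seeds of the
default spec (2 × 200,000 reads each) and aggregates recall/precision over
seeds; the acceptance script runs 10 seeds and reports the aggregate, along
with an exact-test/oracle comparison over a 0–200 count grid at depth
ratios 0.5, 1, 2 and a 10,000-pair null calibration. These sizes were chosen
to give stable aggregate rates (hundreds of planted loci) at desk scale.

# Known limitations

* The exact-match index is hash-based and O(genome) in memory — suitable
  for the package's testing scale, not for a full genome.
* Gapless target alignment: a single-nucleotide bulge in a target site is
  scored as a run of mismatches rather than a 2.0-penalty gap.
* The `min_ref_len`/`max_ref_len` star-length bounds are interpreted as the
  allowed star-sequence length range and are applied implicitly through the
  duplex geometry rather than as an independent hard filter.
* One library per condition: the test captures sampling noise only;
  biological variability is out of reach by design, which is exactly why
  the qPCR concordance module exists.
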
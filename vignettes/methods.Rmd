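---
title: "Detecting mitochondrial 2'-O-methylation and mitoribosome occupancy: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mitochondrial 2'-O-methylation and mitoribosome occupancy: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtOmeScan)
```

# The problem

Ribose 2'-O-methylation has two physical consequences that sequencing can
read out. First, the methylated ribose renders the phosphodiester bond 3'
of the modified nucleotide resistant to alkaline hydrolysis, so in a
fragmentation library the modified bond is cleaved far less often than its
neighbours (the RiboMeth-Seq principle). Second, reverse transcriptase
stalls when it attempts to read through a 2'-O-methylated template
position under limiting dNTP concentrations, leaving a cDNA whose 5' end
maps one nucleotide downstream (3' in transcript sense) of the modified
site; at saturating dNTPs the enzyme reads through (the 2OMe-Seq
principle). `mtOmeScan` implements both read-outs over the same substrate
— per-position counts of read 5' starts, 3' ends and coverage on one
strand of one reference — and calls differential sites between a
knock-out and a parental genotype from replicate-level score comparisons.
The package targets the human mitochondrial transcriptome, where only a
handful of residues of the 16S mt-rRNA carry this mark, but nothing in
the machinery is mtDNA-specific.

# Count substrate

An `end_count_profile` holds, for positions $j = 1..L$ in 1-based
transcript-sense coordinates, coverage $C_j$, read 5'-start counts $S_j$
and 3'-end counts $E_j$, constrained by the coverage identity
$C_1 = S_1$, $C_j = C_{j-1} + S_j - E_{j-1}$. Every constructor and both
simulators enforce the identity, so any violation in a hand-edited count
table is caught at load time with the first offending position. Counting
from BAM/SAM uses the reference-consuming aligned span (soft clips
excluded), drops antisense records with a logged count (the libraries are
strand-specific), and treats the circular mtDNA as linear — the rRNA and
mRNA loci sit far from the origin junction, and origin-spanning
alignments are skipped with a counted warning rather than wrapped. No
duplicate removal or mapping-quality filtering is applied by default:
fragmentation assays are expected to produce many reads with coincident
ends, and removing "duplicates" would destroy the signal. A `min_mapq`
option exists for sensitivity analysis.

# Cleavage-protection score

Cleavage of the bond 3' of nucleotide $i$ produces a fragment 3' end at
$i$ and a fragment 5' start at $i+1$; the default per-bond cleavage count
is therefore $n_i = E_i + S_{i+1}$ (single-ended conventions are
selectable). For a position whose full 6-bond flanks lie in bounds, with
$m_L, s_L$ ($m_R, s_R$) the mean and population standard deviation of
$n$ over the left (right) flank,

$$A_i = \max\!\left(0,\; 1 - \frac{2 n_i + 1}
 {\tfrac12\max(m_L - s_L, 0) + n_i + \tfrac12\max(m_R - s_R, 0) + 1}\right),$$

which is 0 for a bond cleaved like its neighbours and approaches 1 for a
fully protected bond. The flank baseline is shrunk by one standard
deviation (floored at zero) so that noisy flanks make the score
conservative, and the $+1$ pseudocounts keep it defined at zero counts.
Scores are computed only at qualified positions: the median of $n$ over
the 12 flanking bonds (centre excluded) must strictly exceed 15 reads.
Qualification is deliberately computed on the cleavage-count track, not
raw coverage — it is the number of observed cleavage events, not the
number of overlapping reads, that determines the score's stability.
Choices the score-A family leaves open — population rather than sample
standard deviation, flank statistics on cleavage counts rather than
coverage — are pinned as above and verified against a literal
per-position re-implementation to $10^{-12}$ in the test suite.

Two closed-form fixtures anchor the formula: any uniform track scores
exactly 0 at every qualified position, and a silent bond flanked by
constant counts of 9 scores exactly $1 - 1/10 = 0.9$.

# RT-stop fold change

The per-position stop ratio is $r_i = S_{i+1} / C_{i+1}$ — the fraction
of reads covering the downstream position that begin there — defined
only where $C_{i+1} > 0$. "Downstream" is one nucleotide 3' in transcript
sense, and the ratio's denominator is the coverage at the *stop*
position, not at the methylated site (the two differ only by one
position, but the convention is pinned). The score contrasted between
dNTP conditions is the fold change $F_i = r_i(\text{low}) /
r_i(\text{high})$, defined where both ratios exist and the high-dNTP
ratio is positive; degenerate denominators make the position undefined,
never infinite.

# Differential calling

For each method, each genotype replicate contributes one score per
position (score A from each cleavage library; $F_i$ from each matched
low/high dNTP pair). Positions defined in at least two replicates per
genotype are compared by a two-tailed pooled-variance Student's t test on
the raw, untransformed scores. When the pooled variance is exactly zero
the test degenerates: equal means give $p = 1$; unequal means are
flagged `degenerate` with $p = 0$ and a warning rather than silently
producing `NaN`. Raw p-values are the primary output, matching a
transcriptome-wide volcano representation; Benjamini–Hochberg q-values
are appended per method as an extra column and never alter the primary
columns.

Positions entering the RT-stop comparison are additionally qualified by
depth and geometry: the stop-position coverage must exceed the same
15-read threshold in both dNTP conditions, and positions within the
minimum size-selected fragment length (default 25 nt) of the 3' terminus
are left untested. The latter is structural: no fragment-boundary read
5' start can occur there, so the stop ratio would rest entirely on rare
polymerase drop-off events — single-read numerators that produce
degenerate, zero-variance fold changes and arbitrarily extreme t
statistics.

## Statistical behaviour with three replicates

Two properties of this design are worth stating plainly. Under the null,
the cleavage method is conservative: score A is clamped at 0, most null
replicate scores are exactly 0, and its empirical rejection rate at
$\alpha = 0.05$ is well below nominal (~1% in our null simulations). The
RT-stop fold change is continuous and its t test is calibrated (~5%
empirical rejection); that calibration check is therefore run on the
RT-stop score. Second, with $n = 3$ per group the t statistic has 4
degrees of freedom and its extreme tail is sensitive to small-sample
variance flukes, so transcriptome-wide BH control occasionally admits a
single spurious call; across 20 independent null scans we require at
least 19 to be entirely clean rather than all 20.

## The stall shadow

A strong differential stall has a genuine secondary signature: in the
low-dNTP condition, cDNAs truncated at the stall never extend into the
region upstream of it, while reads that *start* within one fragment
length upstream of the stall must (by the size selection) span the stall
position. The stop ratio at positions up to one maximum fragment length
upstream of a strong stall is therefore systematically depressed in the
genotype that stalls, and a deeply sequenced differential scan can flag
such shadow positions alongside the true site. This is a feature of the
assay, not of the implementation; the acceptance suite asserts exact
single-site recovery for the cleavage method and, for the RT-stop
method, that any extra call lies in the annotated shadow window.

# Mitoribosome footprint occupancy

Footprints are assigned to genes by their 5' end on the sense strand. A
read is dropped when its 5' end lies (i) within the first 15 CDS
nucleotides — offsets 0–14, ribosomes paused at initiation; (ii) within
the final 45 CDS nucleotides — termination; (iii) inside the ATP8/ATP6
or ND4L/ND4 shared CDS intervals, where assignment is ambiguous and the
read is excluded from both genes; or (iv) on no annotated gene. The
windows are one-sided and lie inside the CDS, since a 5' end outside the
CDS is not assigned to the gene in the first place; the boundary
convention (offset 15 is the first kept position) is pinned in the tests.
Counts are normalised to reads per million of a user-supplied
positive-sense nuclear-mRNA read count — computing that normaliser is an
upstream alignment task outside this package — and translation
efficiency is footprint RPM over RNA-seq RPM. Per-gene occupancy is the
knock-out RPM as a percentage of parental RPM, summarised by mean,
sample SD, minimum, median and maximum over genes with positive parental
signal; genes without parental signal are excluded and listed. The
packaged annotation carries the 13 human mt-mRNA CDS intervals in rCRS
coordinates (BED-like on disk, 0-based half-open, converted on load).

# Synthetic data

Every stage is exercised against generators that plant explicit ground
truth.

**Fragmentation libraries.** Per-bond cleavage weights are mean-1 gamma
draws with variance $\phi$ (default 0.3), emulating sequence-dependent
hydrolysis; a methylated bond's weight is multiplied by $1 - p$. Each
fragment is the span between two sampled cut points, accepted when its
length falls in 25–55 nt (the sequenced insert range of
alkaline-fragmented libraries). The heterogeneity field is drawn once
per experiment and must be shared between genotypes being contrasted —
it models the molecule, not the sample; giving each genotype its own
field makes every position spuriously differential.

**RT-stop libraries.** Template fragments are drawn uniformly; reverse
transcription enters at the fragment 3' end and walks 5'-ward, failing
with per-nucleotide drop-off $\delta$ (default $10^{-3}$) and stalling at
a planted site with probability $q_\text{low}$ or $q_\text{high}$. A
stall at site $i$ emits a read starting at $i+1$, so fragmentation
boundaries and stall starts coexist in one profile, as in real libraries,
and the emitted profile satisfies the coverage identity by construction.

**Footprint libraries.** Per-gene expected counts are proportional to
allowed CDS length, a planted occupancy factor and a library scale;
counts are Poisson, 5' positions uniform over the allowed interval, and
lengths uniform over the 25–35 nt size selection.

**SILAC tables.** Log2 ratios are a subunit effect (mtLSU only) plus a
log2 mixing bias plus gaussian noise, emitted in both label orientations
with the effect sign flipped in the swapped orientation; the whole-cell
median equals the mixing bias so correction exactly inverts it at zero
noise.

All generators are pure functions of their parameters and seed.
Bit-reproducibility is guaranteed within a package version, not across
RNG algorithm changes.

## Study conditions and problem sizes

The default simulated experiment mirrors the real design: three
biological replicates per genotype, both assays, planted protection 0.9
and stall efficiencies 0.5 (low dNTP) versus 0.05 (high). Test and
acceptance runs use a 400-nt reference with 60,000 fragments per library
(~300 cleavage events per bond; mt-rRNA is abundant enough that real
RiboMeth-Seq coverage is orders of magnitude above the 15-read
qualification floor) and, for null-calibration batteries, a 300-nt
reference at 25,000 fragments over 20 seeds. The occupancy contrast uses
the full 13-gene annotation at roughly 20,000 parental footprints with
the knock-out factor set uniformly to 0.139, the scale of ribosome loss
observed in MRM2-deficient cells.

## What the simulations do not capture

The generators emulate count statistics, not sequences: there is no
aligner error model, no ligation or PCR bias, no per-position
sequence-composition effect beyond the gamma heterogeneity, and tRNA
structure effects on fragmentation are absent. Passing recovery tests
demonstrates that the scoring and calling machinery is correct and
calibrated under the stated noise model — not that any particular real
library will behave as cleanly.

# Ancillary quantifications

**SILAC mixing and enrichment.** All ratios are divided by the
whole-cell-mix median (a group action: correcting by $m_1$ then $m_2$
equals correcting by $m_1 m_2$). Per-protein enrichment averages the two
reciprocal labelling orientations in log2 space with the swapped
orientation sign-flipped; linear-space averaging is available behind a
flag. Subunit distributions are summarised by their median.

**Comparative Ct.** Pfaffl-style efficiency-corrected ratios with the
control-group mean Ct values as calibrator and per-amplicon efficiencies
in fold-per-cycle units (1.93 and 1.95 for the fly assay pair). With this
calibrator the *geometric* mean of control-group levels is exactly 1 by
construction; the arithmetic mean is not, for any non-degenerate Ct
spread.

**Climbing index.** With $c_k$ flies completing $k$ of $K = 5$ climbs,
$CI = \sum_k k c_k / (K \sum_k c_k)$ — the weighted performance
normalised to the maximum possible score, invariant to rescaling all
counts.

# Known limitations

- The assays detect ribose methylation generically; they do not identify
  which base is modified, and coincident modifications with similar
  biochemical consequences are indistinguishable.
- Circular-reference handling is by exclusion, which would bias profiles
  near the mtDNA origin if a locus of interest sat there.
- With three replicates the t test's extreme tails are fragile;
  single-run transcriptome-wide BH calls should be interpreted alongside
  effect sizes (the score means are reported for that reason).
- The RT-stop shadow (above) means positions just upstream of a strong
  differential stall are not independent nulls; interpreting novel calls
  requires checking for a nearby dominant site.
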
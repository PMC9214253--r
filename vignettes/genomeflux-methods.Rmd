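---
title: "Measuring a genome in flux: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring a genome in flux: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(genomeflux)
```

# The scientific problem

Birds carry a bimodal karyotype of large macrochromosomes and many small,
GC- and CpG-rich microchromosomes. When microchromosomes fuse onto larger
chromosomes — as happened repeatedly in falcons — the regions involved are
expected to experience lower recombination and therefore weaker GC-biased
gene conversion, pushing their base composition away from its old
equilibrium. `genomeflux` implements the comparative-genomic machinery
needed to measure that process from whole-genome alignments of a panel of
diploid assemblies against a single outgroup reference:

* small-variant and structural-variant calling from aligner coordinate
  tables plus sequences;
* polarization of variants private to one genome, using the outgroup
  allele as the ancestral state (maximum parsimony on recent mutations);
* AT–GC substitution spectra, the GC→AT odds ratio, and the equilibrium
  GC content it implies, with panel-wide CpG masking;
* fixed-window annotation of composition, isochore family, and
  ancestral/current chromosome size-class state;
* NUMT (nuclear mitochondrial insertion) and interstitial-telomere
  scanning;
* the supporting statistical layer.

Real panels of this kind run to hundreds of gigabytes of raw data, so
every stage is instead validated against a genome-evolution simulator
that plants known events and keeps complete truth tables.

# The core statistics

For private single-nucleotide variants polarized against the outgroup,
bases are pooled strand-symmetrically into the classes AT = {A, T} and
GC = {G, C}. With $N_{GC \to AT}$ and $N_{AT \to GC}$ the counts of
class-changing substitutions (changes within a class are ignored), the
genome-wide bias is summarized by the raw count ratio

$$\mathrm{OR}_{GC \to AT} = \frac{N_{GC \to AT}}{N_{AT \to GC}},$$

tested against equal expectation with a 1-df goodness-of-fit chi-square
$(N_{GC \to AT} - N_{AT \to GC})^2 / (N_{GC \to AT} + N_{AT \to GC})$.
The equilibrium GC content is the stationary point at which the two
fluxes balance,

$$\mathrm{GC}_{eq} = 1 - \frac{\mathrm{OR}}{1 + \mathrm{OR}}
                   = \frac{1}{1 + \mathrm{OR}},$$

so OR = 1 gives 50% and larger OR pushes the equilibrium below the
current GC content. We deliberately define the odds ratio on raw counts
rather than on opportunity-normalized rates: only the count form is
consistent with the published equilibrium values, which sit within a
couple of percentage points of the current genomic GC, whereas a rate
ratio would imply equilibria near 34%.

Per 100 kB window, where counts are sparse, the odds ratio is computed as
an upper-bound form with one pseudo-substitution of each direction,
$(N_{GC \to AT} + 1) / (N_{AT \to GC} + 1)$, so empty windows give
neither zero nor infinity.

CpG dinucleotides are hypermutable, so every analysis is run with and
without CpG-context sites. The mask is deliberately panel-wide: a
reference position is masked when it, *or any position aligned to it in
any haplotype of any panel genome*, is the C or the G of a CG
dinucleotide in that genome. Masking in one genome suffices.

# Variant calling from alignment geometry

Coordinate tables use the nine-column `show-coords` tab dialect
(1-based inclusive, reverse strand as S2 > E2); conversion to the
package-internal 0-based half-open convention happens in
`read_coords_table()` and nowhere else, so there is exactly one place an
off-by-one could live.

Within each (reference scaffold, query scaffold) pair we chain
majority-strand blocks into a one-to-one collinear run (weighted longest
increasing subsequence by aligned length). SNVs inside gapless anchor
blocks come from direct positionwise comparison. Between adjacent
anchors, a gap pair $(g_{ref}, g_{qry})$ with both sides under 50 bp is
resolved by global alignment (match +1, mismatch −1, gap open −2, gap
extend −1 — `Biostrings::pairwiseAlignment` with a length-$L$ gap costing
$1 + L$) into SNVs and indels; a pair with 50 bp or more on either side
is passed through unresolved as an SV candidate. Indels are left-aligned
to their leftmost equivalent position and trimmed to minimal anchored
representation before any analysis; normalization is idempotent.

A site is *callable* only when covered by exactly one alignment block
that belongs to the collinear chain — duplicated-region matches never
produce small-variant calls. Private-variant selection then requires the
site to be callable in **all** focal genomes, and no other focal genome
to carry any variant at that reference position.

The five structural-variant classes follow alignment geometry at a 50 bp
threshold: DEL/INS are gap pairs broken on exactly one side (the
tolerated break on the other side, `slack`, defaults to 0); INV are
maximal runs of minority-strand blocks, with length the summed aligned
bp of the run and the majority direction decided per scaffold pair by
aligned bp (ties to "+"); SEGDUP/SEGDEL are two or more disjoint,
proximal (≤1 kb) blocks of one genome matching a single locus of the
other, overlapping by at least 50 bp, with length the extra copies' bp
and the reported locus the extra copies only. INS/DEL/INV calls
overlapping duplicated regions — multi-covered bases or segmental-event
loci — are excluded; segmental events themselves are exempt (they *are*
the duplicated regions). The private filter removes an SV from every
genome when a same-type SV of another genome overlaps it by at least
1 bp in outgroup coordinates; different types never mask each other.

# The simulator and what it emulates

`simulate_panel()` builds an ancestral karyotype
(macro/intermediate/micro chromosomes with per-chromosome GC and CpG
targets, planted repeat intervals, ancestral tandem pairs, optional
terminal telomere arrays, a circular mitogenome), applies a fusion plan
on the ingroup stem (junction TTAGGG arrays of configurable unit count),
and evolves the outgroup from the unfused ancestor and a tree of diploid
focal genomes from the fused karyotype. Per branch, in fixed draw order
(substitutions, then indels, then SVs, then NUMTs) from a single seeded
RNG stream:

* substitutions with independent GC→AT ($u$) and AT→GC ($v$) rates, a
  within-class rate, and a CpG-context multiplier applied at the C and G
  of every CG evaluated on the current sequence;
* small indels (1–49 bp, geometric lengths), the five SV classes
  (lengths ≥ 50 bp, exponential with a minimum), and NUMT insertions
  copied from the lineage's own evolving mitogenome with configurable
  extra divergence, with insertion probability set to zero on
  micro-class scaffolds by default (the observed insertion bias is a
  property of the study system being emulated, and is configurable).

Every event is recorded in root coordinates. Inserted material is mapped
to fresh virtual scaffolds so the current-to-root homology map remains a
total bijection; truth tables can therefore express any planted event in
any descendant's coordinates, or in outgroup coordinates, at any time.
Segmental deletions consume ancestral tandem pairs (one copy of a
registered adjacent duplicate), which is the only way a copy-number loss
can leave the multi-block alignment signature the classifier looks for.

Three placement rules keep planted events analyzable, and are study
conditions rather than tuning: events on one branch keep a minimum
separation (default 150 bp) so each keeps its own anchor context; the
loci of events already planted by other branches are excluded (otherwise
two lineages could corrupt each other's anchors and, worse, spuriously
defeat the private filter); and ancestral tandem-pair loci are barred to
all other edits so the paralog-anchor geometry survives. Without these
rules a few percent of planted events become *unrecoverable in
principle* — not by any fault of the classifier — which would make
recall a property of collision chance rather than of the code under
test.

`emit_truth_alignments()` composes the focal and outgroup homology maps
into the gapless anchor blocks a whole-genome aligner would report:
blocks break only at indel/SV breakpoints, substitutions stay inside
blocks and lower the identity column, and blocks under the aligner's
100 bp minimum are dropped. Where a segmental event created copy-number
asymmetry, the corresponding cross-copy (paralog) anchor is emitted as
well, as a real aligner would; intact tandem pairs do not get paralog
anchors, an idealization that avoids planting spurious segmental
signatures at every ancestral duplicate.

What the simulator does *not* model: selection, recombination as a
process (biased gene conversion enters only through the rate asymmetry
it would produce), coalescent population structure, sequencing error,
assembly artifacts, and context-dependent substitution beyond the CpG
multiplier. Passing recovery tests therefore demonstrates that the
measurement machinery is correct on data satisfying the stated
generative assumptions, not that real assemblies meet those assumptions.

# Windows, states, and features

Genomes are tiled into nonoverlapping windows from position 0 with the
trailing partial window dropped (compositional comparability); 100 kB is
the conventional isochore scale, and scaled-down simulations use
proportionally smaller windows. GC percent is computed over non-N bases;
CpG counts use an overlapping scan. Isochore families follow the
classical boundaries L1 < 37 < L2 < 41 < H1 < 46 < H2 < 53 ≤ H3 percent
GC (the classical thresholds of the isochore literature; published
window-based analyses rarely print their exact boundaries).

A window "aligns to" a chromosome when at least one block of ≥ 100 bp
overlaps it; no minimum aligned fraction is imposed (the strictest
reading of "aligned exclusively"). The ancestral (outgroup-role) and
current (self/falcon-role) states are the size-class consensus across
all alignments in all assemblies of the role set — any disagreement
yields `ambiguous`, which is excluded from state contrasts. Size classes
default to the avian convention (micro < 20 Mb ≤ intermediate < 40 Mb ≤
macro) and scale with simulated genome size. Windows aligned to
annotated sex chromosomes carry a sex flag; W cannot be flagged from a
male current-role assembly, as in real falcon reference panels. Point features
are assigned by start position (no double counting across window
boundaries); repeat bp are clipped to the window.

# NUMTs and telomeres

The mitogenome template is rotated to a fixed anchor and concatenated
with itself so fragments spanning the circular origin align without a
break. Detection is a deterministic seed-and-extend search: exact 12-mer
seeds on both strands, a two-hit rule per diagonal (a lone exact 12-mer
is overwhelmingly noise), ungapped x-drop extension (drop 20) in a
±4 kb window around the seed cluster, merging of hits within 50 bp, and
floors of 100 bp length and 0.70 identity. Mito coordinates are reported
modulo the mitogenome length and a locus matched in both template copies
is reported once. Hits on only one haplotype are heterozygous; any
overlap across haplotypes in shared coordinates makes a hit fixed.
Synteny groups are connected components under ≥ 1 bp overlap in outgroup
coordinates.

Greedy clustering sorts sequences by descending length and assigns each
to the first centroid reaching 80% identity after testing every centroid
in order; identity is matches over alignment columns with terminal gaps
excluded under an ends-free global alignment. A shared-12-mer prescreen
skips centroid comparisons that cannot reach the threshold; this also
prevents degenerate "identity 1.0" joins on sub-12 bp overlaps.

The telomere scanner reports maximal runs of at least 3 tandem perfect
TTAGGG or CCCTAA units; a run is interstitial when both ends are at
least 1 kb from the scaffold ends. The thresholds are this package's
choices; published scans read such arrays off a repeat annotator's
simple-repeat output without stating explicit thresholds. Substitutions can split a long junction
array into adjacent runs, so array-level recovery is judged by overlap
with the planted junction, not by exact interval equality.

Repeat copies are flagged potentially active when their longest
six-frame ORF (ATG through stop, no internal stop, length counted
through the stop codon) reaches the class threshold: 2,000 bp for LINEs,
2,200 bp for LTR elements, 1,200 bp for DNA transposons.

# Statistical layer

Standard procedures delegate to base R and `nortest`, which pin down the
conventions that matter here: `binom.test`'s two-sided p-value is the
minimum-likelihood sum and its interval is Clopper–Pearson (for
$x = 0$ the upper bound is the closed form $1 - (\alpha/2)^{1/n}$);
`aov` + `TukeyHSD` provide the studentized-range adjustment; `nortest`'s
Anderson–Darling uses the estimated-parameter small-sample correction;
Poisson regression is `glm`'s IRLS run to a deviance tolerance of 1e−8.
The family-wise alpha is the Dunn–Šidák form
$1 - (1 - \alpha)^{1/m}$ with $m$ the number of tests actually run, as
enumerated in the pipeline's manifest. Count-like window features are
analysed on the $\log_2(x + 1)$ scale, with GC content regressed out
(OLS residuals) where it would otherwise drive a contrast. Generation
time uses $g = a + s/(1 - s)$ (maturity age plus expected adult
lifespan beyond it).

# Problem sizes, defaults, and numerical choices

The default demo panel is a ~9.4 Mb eight-chromosome karyotype — micros
at higher GC and relatively more CpG, all chromosomes CpG-depleted
(~30–45% of the iid expectation, as real vertebrate genomes are; the
builder realizes depletion by composition-preserving CG→GC swaps) —
with three diploid focal genomes on a two-clade tree plus a haploid
outgroup at branch 0.5. Substitution defaults are
$u = 1.3\times10^{-3}$, $v = 10^{-3}$, CpG multiplier 7: these were
calibrated analytically so the pooled fixed-variant odds ratios land
near the published falcon values (≈1.39 with CpG, ≈1.17 without),
accounting for the fact that the panel-wide mask also removes AT→GC
variants whose derived allele *creates* a CpG — a direction-asymmetric
masking effect that partially offsets CpG hypermutability. Indel rate
is $1.5\times10^{-5}$/bp, SV rates $2\times10^{-6}$/bp per class
($5\times10^{-7}$ for segmental deletions, bounded by the ancestral
tandem registry), NUMT rate $1.5\times10^{-6}$/bp. Size-class
thresholds scale with the simulated genome (1 Mb/2 Mb at this scale
standing in for 20 Mb/40 Mb). The fixed-versus-heterozygous odds-ratio
contrast reported for falcons cannot emerge here: it is produced by
biased gene conversion acting between mutation and fixation, a process
this simulator intentionally leaves out, so both zygosity strata share
one expectation. The
odds-ratio recovery panel uses the same machinery at 50% GC and CpG
multiplier 1, where the expected count odds ratio is exactly
$u \cdot n_{GC} / (v \cdot n_{AT}) \approx 2$; with a CpG multiplier
above 1 the expectation inflates only on the GC→AT side (CpG-context
sites are G or C), which is why the with-CpG ratio must exceed the
masked one.

Degenerate inputs are handled explicitly: all-N windows are excluded
from composition; a zero direction count triggers the +1 pseudocount
rule and a flag; conflicting alt alleles at one site are both kept as
het with a warning; unliftable intervals return empty or split results,
never silently merged coordinates. Determinism is absolute given (spec,
parameters, seed): one RNG stream, fixed draw order, preorder tree
traversal.

# Known limitations

* Variants adjacent to an unresolved SV gap are not called — the region
  is reported as unresolved instead; recovery tests treat exactly those
  regions as out of scope.
* Inversions, segmental events and tandem copies shorter than the
  aligner's 100 bp minimum block length cannot present their defining
  geometry; a sub-threshold tandem gain is (correctly) reported as a
  plain insertion.
* Parsimony polarization mistakes sites mutated on the outgroup branch;
  focusing on private variants makes this rare but not impossible, and
  back mutations bias the recovered odds ratio very slightly toward 1.
* The per-genome "current GC" used for the equilibrium delta is
  assembly-wide GC, not callable-site GC.
* The reconciliation of multiple variant callers, read-based evidence,
  and phylogenetic dating of NUMT clusters are out of scope.
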
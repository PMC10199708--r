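---
title: "Methods: repeat, centromere, cluster and heterozygosity calling in t2tscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat, centromere, cluster and heterozygosity calling in t2tscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

t2tscan annotates the repeat landscape of gap-free plant genome assemblies:
telomeres, centromeric satellite families and their higher-order units,
domain-seeded gene clusters, and windowed heterozygosity hotspots. This
vignette explains the underlying procedures, the parameters that matter, the
numerical choices, and what the synthetic benchmarks do and do not
demonstrate.

## Coordinate conventions and input handling

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive) and
VCF (1-based positions) are converted at the I/O boundary and converted back
on write, so no stage ever mixes conventions. FASTA input is uppercased, `U`
becomes `T`, and any other letter becomes `N` with a warning. `N` never
matches anything in repeat scanning — an alignment column containing `N`
counts as a mismatch. This is the right behavior for a gap-free target
genome, where `N`s occur only in synthetic controls.

## Tandem-repeat scanning

A tandem array of period $p$ satisfies $s[i] = s[i+p]$ over its span, up to
divergence. The scanner works in three steps:

1. **Seeding.** Exact 12-mers are indexed; distances between consecutive
   occurrences of the same 12-mer vote for candidate periods. A period needs
   at least 5 votes. On random sequence the expected number of coincidental
   votes per period is far below one per megabase, so seeding is effectively
   noise-free while a true array (even at a few percent divergence)
   produces thousands of votes.
2. **Verification.** For each candidate period, the binary match vector
   $m_i = [s_i = s_{i+p}]$ is summed in sliding windows of one period; a
   position is "good" when window identity is at least `min_identity`
   (default 0.80, chosen to transliterate the 80% match weighting of the
   classic tandem-repeat finder parameterization). Runs of good positions,
   bridging bad stretches up to one period, become candidate arrays; the
   span divided by the period gives fractional copies (reported to one
   decimal), so a 10-copy array with a 54-bp partial trailing copy of a
   107-bp monomer reports 10.5 copies.
3. **Consensus and boundary refinement.** The monomer consensus is a
   per-column majority vote over full copies (ties broken alphabetically).
   Because the windowed identity rule lets an array "leak" up to a fraction
   of a period into background, boundaries are then re-anchored: the array
   must begin and end with 10 consecutive positions matching the
   phase-aligned consensus. Random background matches a consensus at ~25%
   per position, so a clean 10-run pins the edge while costing at most a
   few positions on diverged arrays; residual boundary error is bounded by
   one period in practice and asserted at that tolerance in the tests.

**Harmonic ambiguity.** An exact tandem of period $p$ is also a tandem of
$2p$. The scanner resolves this in favor of the smallest period that clears
the identity threshold: if the consensus of a detected array is itself
exactly $k$-periodic, the array is relabeled to its fundamental period (and
dropped entirely if that fundamental period falls below the scan range —
this is how telomeric 7-mers are kept out of the 30–500 bp satellite
table). Overlapping detections of one period are merged to their union;
across periods, harmonically related overlaps collapse to the base period,
and non-harmonic overlaps of at least half the shorter span keep the higher
identity × span score. Non-harmonic units co-located below that threshold
are both kept, since real centromeres can stack distinct monomers in one
region.

**Monomer canonicalization.** A monomer is an equivalence class under
rotation and strand: `canonical_monomer()` returns the lexicographically
smallest string among all rotations of the unit and of its reverse
complement. It is idempotent and makes scans of a sequence and its reverse
complement report identical units, a property the tests assert directly.

**Harmonic grouping.** An array of period $kp$ joins a family with base
period $p$ when its consensus, cut into $k$ pieces of length $p$, matches
the base monomer at a **mean** piece identity of at least 0.80 under
rotation/strand. The mean (rather than a per-piece minimum) is deliberate:
a higher-order unit only surfaces as its own scanned period when at least
one sub-monomer has diverged past the scanner's identity threshold, so a
per-piece rule at the same threshold would make exactly the interesting
harmonics ungroupable. With the mean rule, a dimer with one pristine and
one 30%-diverged half (piece identities 1.0 and 0.7) still joins its base
family, mirroring how 214-bp and 321-bp units are unified under a 107-bp
monomer. Each array joins at most one family; the smallest qualifying base
period wins.

**Counting rule.** Genome-wide summaries (`summarize_repeat_units()`) count
distinct repeat units per scanned period, ranked by covered bp with ties
broken by ascending period. Whether "distinct units" should be counted per
period or per distinct consensus is ambiguous in general; the per-period
table is the stable choice and family-level totals are available separately
from `group_harmonics()`.

## Telomere calling

Telomere discovery is restricted to terminal windows (default 150 kb per
arm) and unit lengths 5–12 bp; interstitial telomeric repeats further in
are deliberately ignored. Candidate units are exact tandem runs whose
repeating unit has fundamental period within range — this excludes
homopolymer and dinucleotide tracts (period < 5) from masquerading as
longer units, so an AT microsatellite cannot outvote a genuine 7-mer. The
reported unit is the canonical unit covering the most terminal bp
genome-wide, with per-arm coverage returned as supporting evidence.

Per-arm calls locate the maximal run of exact unit matches (any rotation,
either strand) in the terminal window. Breaks of at most one unit length
are bridged (divergent positions inside an otherwise continuous array);
terminal match-blocks shorter than one unit are trimmed back, because an
isolated boundary match into background is chance (probability ~25% per
position), not array continuation. Presence requires 50 copies — a
deliberately conservative threshold given that genuine telomeres in
chromosome-scale plant assemblies run from hundreds to thousands of
copies, and it is configurable. For unmutated arrays, copies × unit length
equals array length exactly.

## Centromere calling

The centromeric family defaults to the genome-wide most-abundant monomer
family; a chromosome overrides to its locally dominant family when that
family carries at least twice the default family's bp there. This
reproduces the situation where most chromosomes share one satellite but
individual chromosomes are dominated by unrelated monomers (135/270/405,
66/132, 56 or 187 bp classes on particular chromosomes).

Candidate regions are target-family arrays merged across gaps up to
`max_gap` (500 kb), measured in bp, with boundaries snapped to the
outermost contributing arrays; candidates need at least `min_array_bp`
(50 kb) of array coverage. Candidates are visited in decreasing array-bp
order and the first satisfying the **depletion test** — mean gene+TE
covered bp per 100-kb window strictly lower inside than outside — becomes
the single call for that chromosome. The depletion test is an explicit
formalization of what is usually decided by eye in a genome browser
("satellite-rich, gene/TE-poor"); making it quantitative is a design
choice of this package, flagged as such. Chromosomes with arrays in many
regions keep one primary call; all candidates are emitted as diagnostics
so multi-region (holocentromere-like) chromosomes can be inspected.
Captured genes are genes overlapping a call by at least 1 bp.

## Gene clusters

Distance is measured in gene ordinals (rank along the chromosome by start
coordinate), not bp. For each accession, every maximal run of ≥ 3
consecutive carriers seeds a cluster; the cluster collects all carriers
within ±30 ordinals of the run, and clusters of one accession merge when
their collected ordinal ranges overlap. The merge rule is pinned by an
exhaustive-enumeration oracle test. Multi-domain genes seed on any shared
accession (the most permissive reading of "identical accessions");
similarity hits — filtered at e-value < 1e-5 (strict), identity > 30%
(strict), and non-empty domain intersection, then closed under symmetry —
describe the duplication landscape and can optionally be required of every
member (`require_hits = TRUE`). Both modes are tested. R-gene
classification is a pure domain-architecture rule (NB-ARC, TIR or C-JID
present, or LRR co-occurring with a kinase accession), fully
configuration-driven since accession vocabularies differ between
annotation pipelines. A toy Smith–Waterman scorer
(`align_proteins()`, BLOSUM62 local alignment with a Karlin–Altschul-style
e-value) exists so tests need no external aligner; it is not a production
search tool.

## Heterozygosity hotspots

Filters are applied in a fixed order with first-fail attribution: exactly
two alleles; no missing genotypes; all per-sample GQ ≥ 30; MAF ≥ 0.01
computed over the samples' genotypes. Filtering is idempotent and each
removal is tallied per rule. Sharing partitions filtered sites into
heterozygous-in-all versus heterozygous-in-1..(n−1) samples; the shared
percentage is reported to one decimal.

Window counts pool the samples' union (a site shared by four samples
counts once) in non-overlapping 100-kb windows; per-sample profiles are
also emitted. The hotspot threshold is the empirical 95th percentile
(type-1, inverse-ECDF) of window counts **restricted to nonzero windows**
— on sparse genomes a quantile over all windows collapses to zero and
would call everything; restricting to nonzero windows is documented and
configurable. Qualifying windows merge into fragments bridging one
sub-threshold window (multi-megabase fragments plainly tolerate local
dips), and fragments need at least two qualifying windows. Raising the
top fraction never disqualifies a previously qualifying window (quantile
monotonicity), and window counts conserve the number of sites; both are
asserted as properties.

## The synthetic-data generator

`simulate_genome()` emulates exactly the structure the callers assume:
i.i.d. uniform ACGT background; exact 7-bp telomeric arrays at both ends
(200–2000 copies per arm by default); one centromeric satellite array per
chromosome (107-bp monomer by default, 100–500 kb, 2% per-copy
substitution) in which 20% of the bp budget is emitted as dimer and 10% as
trimer concatemer blocks built from whole monomer copies so the array
stays phase-continuous; TE annotation features at 80 per Mb, thinned
5-fold inside centromeres; gene models that never overlap satellite
arrays, with domain accessions drawn from a configurable vocabulary and
planted clusters whose accessions are reserved (never drawn at random), so
planted memberships are exactly recoverable. Telomere arrays are exact by
default (a single conserved 7-mer); satellite arrays are diverged so that
identity thresholds are actually exercised. SNP simulation controls the
all-sample sharing fraction (default 0.853), background density, hotspot
intervals with elevated density (10× by default, or an absolute per-bp
rate), and a 5% rate of sub-30 GQ values so the GQ filter has work to do.
All outputs are deterministic given the spec seed, and truth files are
emitted alongside.

What the generator does **not** model — and hence what passing benchmarks
do not demonstrate: realistic base composition and isochores, TE sequence
content (TEs are annotation features over background sequence), indels
within satellite arrays (the scanner's identity is substitution-based;
wraparound indel-tolerant alignment is out of scope), nested or decayed
repeat structure, rDNA arrays, and linkage structure in the SNP sets.
Performance on real assemblies with indel-rich satellites may be worse
than the planted-truth recovery rates; the benchmarks validate the
algorithmic contracts, not sequencing reality.

## Benchmark problem sizes

The test-suite and acceptance benchmarks use sizes chosen to exercise the
full stack while keeping a complete run in minutes on one CPU: a
19-chromosome genome with 1–2 Mb chromosomes (telomere and centromere
recovery, with telomeres withheld from two short arms), a 5-Mb genome with
the dominant family planted at 3.95% of the sequence (fraction recovery to
±0.2 points), nine hotspot intervals at their reported multi-Mb positions
on chromosomes scaled to one tenth (with the analysis window scaled
alike, 100 kb → 10 kb), and 2-kb sequences for exhaustive-oracle
equivalence. The small-genome centromere recovery property (10 seeded
genomes × 3 chromosomes of 0.45–0.6 Mb) scales the calling parameters with
the genome (20-kb windows, 20-kb minimum array bp, 100-kb gap): with
100-kb windows a 40–80 kb array occupies a fraction of a window and the
depletion contrast drowns in flanking signal — window size should stay
well below expected array length in any real application of
`call_centromeres()`.

## Degenerate inputs and edge behavior

Empty scan results are valid everywhere (a repeat-free genome yields empty
tables, a telomere-free genome yields "no unit found" with a message, a
chromosome without target-family arrays yields no centromere call with a
warning). Hotspot calling refuses genomes with fewer than 20 windows (a
top-5% quantile is meaningless there) and returns an empty fragment set on
all-zero profiles. Terminal windows longer than the chromosome are
truncated with a warning. Overlapping simulated hotspot intervals are
merged with a warning. The VCF reader preserves multi-allelic records —
filtering is a later, attributable stage, not a parsing side effect.

## Known limitations

Substitution-only array model (no indel wraparound alignment); one
primary centromere call per chromosome (secondary regions only in
diagnostics); the toy aligner's e-values use nominal Karlin–Altschul
constants and are comparable only within a run; hotspot fragment counts
depend on the hotspot-to-genome ratio staying below the top fraction —
if elevated regions cover more than the chosen tail fraction of windows,
the empirical quantile necessarily lands inside them and fragments
split. These are documented trade-offs, not accidents.
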
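---
title: "Methods: lasso peptide mining, refactoring and MS/MS topology annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lasso peptide mining, refactoring and MS/MS topology annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lassomine)
```

## The problem

Lasso peptides are ribosomally synthesized and post-translationally
modified peptides (RiPPs) in which a C-terminal tail is threaded through
an N-terminal macrolactam ring, giving a mechanically interlocked
rotaxane-like fold. Their biosynthetic gene clusters (BGCs) minimally
encode a precursor (A gene), a leader peptidase (B, sometimes split into
B1/B2) and a macrolactam synthetase (C). Metagenomic assemblies are a
rich source of novel clusters, but two steps routinely defeat automated
tools: precursor genes are short and weakly conserved, so A genes are
missed by annotation pipelines; and after heterologous expression, mass
spectrometry alone must establish not only the sequence but the threaded
topology, which requires lasso-specific fragment chemistry.

`lassomine` implements the desk-side computations of that workflow:
contig filtering and six-frame ORF scanning with a precursor heuristic
(the A-gene call), cluster classification and in-silico refactoring into
expression inserts, an exact monoisotopic fragment-mass model for
threaded peptides, ppm-tolerance chromatogram extraction and MS2
annotation, and seeded generators that fabricate every input the
pipeline needs for validation.

## The fragment-mass model

A `lasso_topology(core, ring_size, loop_window)` fixes the mature core
peptide of length $N$, the ring $1..r$ closed by an isopeptide bond
between the residue-1 alpha-amine and the side-chain carboxyl of the
Asp/Glu at position $r$, and optionally the loop window (see below).

Masses are monoisotopic throughout, with the proton at 1.00727646 Da,
water at 18.0105646 Da and the standard 20 residue masses; these eight
significant figures leave margin against the four-decimal m/z precision
of a high-resolution instrument. Leucine and isoleucine share a mass and
are never disambiguated. No isotope envelopes, adducts other than
protons, or neutral-loss satellites are modelled.

Macrolactam closure condenses out one water, so the neutral lasso mass
is the bare residue sum. The water deficit is carried on the N-terminal
(b-side) moiety:

$$\mathrm{neutral}(b_i) = \sum_{1..i} m_k - m_{H_2O},\qquad
  \mathrm{neutral}(y_j) = \sum_{N-j+1..N} m_k + m_{H_2O}.$$

This assignment is forced, not a convention: it is the unique choice
under which $b_i + y_{N-i}$ reproduces the intact lasso mass for every
cleavage position, which the test suite verifies to $10^{-9}$ Da on
1,000 random topologies.

### Ring opening

Collisional activation cleaves the constrained ring at random backbone
amides. Opening the bond between ring residues $k$ and $k{+}1$
($1 \le k \le r-1$; the isopeptide bond itself is never the opened bond)
linearizes the ring into residue order $[k{+}1..r, 1..k]$, so an
$r$-residue ring yields exactly $r-1$ linearized forms — nine for a
10-residue ring. Each prefix of each form gives a secondary diagnostic b
ion; with the intact-ring ion that is $9 \times 9 + 1 = 82$ theoretical
labels per charge for $r = 10$. Observed spectra show only a subset.
Because no community convention fixes whether these secondary ions carry
the ring-closure water deficit, both conventions are implemented
(`water_offset = "-water"` by default, so the full-length prefix
reproduces $b_r$; `"0"` for the bare residue-sum form), and duplicate
m/z values arising from rotationally symmetric compositions are retained
under distinct labels.

### Interlocked species and the loop window

If two backbone cleavages both fall between the ring and the steric
lock, the resulting b and y fragments cannot separate — the tail stays
threaded — and a noncovalent $[(b_i)*(y_j)]$ complex survives into the
spectrum. These species are diagnostic of threading and are prominent
when the loop is long (five residues or more). The steric-lock position
is generally unknown a priori, so the loop window is a user parameter of
the topology. The enumeration rule: a cleavage after residue $i$ (the
$b_i$ site) and before residue $N-j+1$ (the $y_j$ site) qualify when
both residue indices lie in the inclusive window and at least one
residue is eliminated ($i + j \le N - 1$). The complex mass is the lasso
mass minus the eliminated residues; the complementary internal fragment
$(b_x y_{j'})$ with $x = N - j$, $j' = N - i$ spans exactly the
eliminated stretch and is enumerated alongside. Tests compare the
enumeration against an exhaustive double loop over all $(i, j)$ for
every topology up to $N = 12$.

## Annotation and the topology call

Matching is nearest-peak-in-window at a ppm tolerance (default 5 ppm,
the usual EIC tolerance on a high-resolution instrument); one peak may
serve several isobaric labels, and no intensity weighting is applied,
since the claim being tested is identity, not abundance. Evidence from
targeted scans at several normalized collision energies (default
simulation set 15/25/35/45) is merged as a union of matches: low
energies favour interlocked complexes, high energies the ring-opened
series. A precursor selection farther than half the isolation window
(default 2 Da) from every theoretical precursor m/z triggers a warning.

The topology call is deliberately conservative and threshold-based:
`threaded_supported` requires at least one matched interlocked species
*and* tail y coverage of at least 0.5, otherwise `inconclusive`. The
thresholds are configuration, not measurements — no community standard
defines how much of an ion series is "nearly complete" — and raising
them can only withdraw a call, never create one.

Extracted ion chromatograms sum peak intensity per MS1 scan inside the
ppm window. The apex estimate is the intensity-weighted centroid of the
scans at or above one quarter of the trace maximum: a plain argmax is
unstable under realistic scan-to-scan intensity noise, while the
quarter-height centroid averages over the peak and recovers simulated
apexes to well within one scan interval.

## The mining heuristic

Contigs are kept when strictly longer than the cutoff (default 5 kb —
lasso BGCs are small, and a lower cutoff than the 25-40 kb typical of
PKS/NRPS mining recovers more of them). ORFs are scanned stop-to-stop in
all six frames under bacterial genetic code 11 with ATG/GTG/TTG starts,
taking the first start per stop segment; coordinates are 1-based
inclusive on the forward strand and include the stop codon.

Each ORF protein is then split at every admissible core start $p$:
precursor length 25-90 aa, leader of at least 8 residues, a starter
residue at $p$ from {G, C, S, A} (the experimentally established set)
extended by N and Q (noncanonical ring-forming residues recently
observed or predicted), a D/E acceptor at core offset 7-10 (7-9 are the
classical ring sizes; 10 accommodates larger rings), and at least 3
tail residues. Candidates are scored by a weighted sum of qualitative
motif indicators:

| feature                          | weight |
|----------------------------------|-------:|
| Thr at position $-2$ of the core |    0.4 |
| canonical starter (G/C/S/A)      |    0.3 |
| acceptor offset in 7-9           |    0.2 |
| leader length 10-50 aa           |    0.1 |

The weights are heuristic — the underlying evidence is qualitative —
and all sets, ranges and weights are exposed in `mining_config()`. The
Thr(-2) term dominates deliberately: it is the most conserved feature of
lasso precursors and is what rescues precursors with noncanonical
starters that motif-strict tools miss. Gene roles (B vs C vs peptidase)
are taken from annotations supplied as GFF3 `role=` attributes, not
inferred: homology-based role assignment is a solved problem for
dedicated external tools and out of scope here. Architecture
classification (Group I: A/B/C; Group II: A/B1/B2/C with split
peptidase) and the colinearity check (all core genes on one strand,
accessory genes ignored) operate on those roles.

## Refactoring

A construct plan keeps the required genes for the architecture (plus
transporter/tailoring genes on request), always excludes peptidase
genes — lasso isopeptidases hydrolyse the macrolactam and would
linearize the product in the expression host — and re-orients the
cluster to the plus strand. Before every internal gene the native
upstream intergenic region is inspected for a Shine-Dalgarno-like
motif: an exact match of at least 4 consecutive bases of AGGAGG ending
4-14 bp upstream of the start codon. Where none is found, the
16 bp E. coli-optimized RBS spacer AGAGGAGAAATTAACC replaces the
intergenic region. The motif rule is an explicit, configurable stand-in
for "no clear native RBS on manual inspection"; no quantitative
definition exists in the literature. `build_insert()` concatenates the
parts, reports per junction the terminal bases each Gibson-style
assembly primer would carry (default 20 bp, truncated at short parts
such as the spacer), warns on internal in-frame stops, and emits a
GenBank record whose features round-trip the plan exactly. Vector
handling is abstract (the plan records the vector name, default pET28a);
codon optimization, primer melting temperatures and ligation simulation
are out of scope.

## The synthetic-data generators

`synth_config()` fixes the simulated study conditions; everything
downstream of the seed is deterministic.

* **Precursors** carry the full planted motif: Met start, Thr at $-2$,
  a configured starter (default N, the noncanonical asparagine case),
  the D acceptor at the ring size (default 10), default 20-residue
  leader and 10-residue tail. All remaining positions are drawn from
  residues that can neither act as acceptor nor as starter, so the
  planted split is the unique scoring candidate by construction — the
  generator plants one motif-perfect precursor, it does not sprinkle
  near-misses.
* **Contigs** (default 6 kb, above the mining cutoff) embed the A gene
  reverse-translated with a fixed most-used E. coli codon table, dummy
  B/C (or B1/B2) genes, an inverted peptidase, and decoy ORFs whose
  proteins contain no D/E and therefore cannot form candidates. An
  in-frame stop codon is placed immediately upstream of every planted
  gene so that ORF scanning recovers the truth coordinates exactly, and
  intergenic DNA is scrubbed of Shine-Dalgarno 4-mers so the RBS
  decision is deterministic.
* **MS2 spectra** (one per collision energy) contain every theoretical
  ion inside the 200-2500 Th scan range with Gaussian m/z jitter
  (default sigma 2 ppm, a realistic calibration spread for an Orbitrap
  class instrument), log-normal intensity spread (CV 0.3), and Poisson
  decoy peaks uniform in m/z with exponential intensities — the
  simplest null that exercises the matcher's false-positive behaviour.
  Note that low-mass ions (e.g. $y_1$ near 130 Th) fall below the scan
  range and are therefore absent by design; tail y coverage on such
  simulations tops out at 90% for a 10-residue tail.
* **MS1 runs** place the precursor charge states on a 0.05-min scan
  grid with a Gaussian elution profile (apex 4 min, sigma 0.15 min,
  within a 10-min gradient).

What the simulations do *not* emulate: isotope envelopes, co-eluting
isobaric interference, chromatographic tailing, intensity structure
across collision energies, detector saturation, and — most importantly
— a real ring sequence. The shipped `metanodin_like_topology()` is a
synthetic stand-in (Asn-opened 10-residue ring closed on Asp, tail
NIQGDHGLNI); its ring filler, and hence its precise neutral mass, is
not the natural compound's. Passing round-trip tests therefore
demonstrate the internal consistency of the mass model and matcher, not
instrument-level performance on real extracts.

## Validation problem sizes

The shipped checks use: 1,000 random topologies for the
complementarity identity; 150 random topologies with $N \le 12$ against
the brute-force interlocked oracle; 100 seeded simulate-annotate
replicates at 2 ppm jitter / 5 ppm tolerance (union over four collision
energies, which is why recovery is effectively complete: an ion must
jitter outside the window in all four scans to be lost); 200 seeded
contigs for mining recall; and one Group I refactoring fixture. These
sizes give stable percentages while keeping the whole suite in the
minutes range on a single core.

## Known limitations

* Scores and thresholds are heuristics with exposed knobs, not
  calibrated probabilities; ranking across unrelated proteins is not
  meaningful beyond the motif indicators.
* The interlocked loop window must be supplied; the package does not
  predict the steric lock.
* mzML input is not parsed; peak lists are exchanged as MGF (MS1 blocks
  are stored as nonstandard MGF entries tagged `MSLEVEL=1`).
* Role annotation, homology search and taxonomic placement are out of
  scope by design and must come from external tools.
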
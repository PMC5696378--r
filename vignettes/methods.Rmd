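---
title: "Models and methods behind bridgepet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bridgepet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgepet)
```

# The ligation-kinetics models

Proximity ligation converts spatial proximity of chromatin fragments into
ligation products. We model the pool of free proximal fragments as a single
species $\omega$ with $\omega(0) = 2N$, producing *signal* pairs $y$
(fragments held together by a protein complex, rate $p_1$) and *noise*
pairs $z$ (random collisions with isolated fragments of abundance $\beta$,
rate $p_2$).

**One-step ligation** joins fragments directly:
$$\frac{d\omega}{dt} = -(p_1+p_2)\,\omega,\qquad
  \frac{dy}{dt} = p_1\omega^2,\qquad
  \frac{dz}{dt} = p_2\beta\,\omega .$$

**Two-step ligation** interposes a bridge linker: fragments first acquire a
linker at rate $p_0$ (two ligatable linker ends, hence the factor 2),
forming intermediates $x$, and only intermediates complete a junction:
$$\frac{d\omega}{dt} = -2p_0\omega,\quad
  \frac{dx}{dt} = 2p_0\omega - (p_1+p_2)x,\quad
  \frac{dy}{dt} = p_1 x \omega,\quad
  \frac{dz}{dt} = p_2 x \beta .$$

Both systems integrate in closed form (`one_step_closed_form()`,
`two_step_closed_form()`); the two-step solution carries the coefficient
$\alpha = 2p_0 / (2p_0 - (p_1+p_2))$. Two exact identities follow
algebraically and are enforced by the tests:

* the noise asymptote is model-independent,
  $z(\infty) = p_2\beta\,2N/(p_1+p_2)$ — the linker step delays noise but
  does not change its total;
* as $t \to 0^+$ the signal-to-noise ratio $y/z$ tends to
  $(p_1/p_2)(2N/\beta)$ for both models (80 at the default rates).

The default rates are $p_0 = 0.05$, $p_1 = 1$, $p_2 = 0.025$. $N$ and
$\beta$ are scale factors that cancel from all ratios we report; we fix
$N = \beta = 1$ so that the curves are pure functions of the rates, and
state this explicitly because no principled value is available for either.

Note a subtlety the package deliberately reports but does not adjudicate:
at these rates the *asymptotic* $y$ is smaller under two-step ligation
($y_\infty$ gains a $p_1+p_2+2p_0$ denominator term), while $z_\infty$ is
identical — so the endpoint ratio alone does not favour two-step ligation.
The kinetic advantage is a finite-time statement (the two-step $y/z$ stays
near its initial 80 for much longer, cf. `analysis/01_ligation_kinetics.R`:
at $t = 1$, $y/z$ is 75 for two-step versus 54 for one-step), and in the
full protocol it compounds with the selection step: only linker-carrying
junctions are enriched for sequencing. `signal_noise_curve()` therefore
returns both curves per time point and no test asserts a direction for the
asymptotes.

## Numerics

* **Integrator.** Fixed-step classical RK4 with hard-coded right-hand
  sides (compiled), `integrate_kinetics()`. With 50 000 steps over
  $t \in [0, 50]$ and rates $\le 2$ the worst-case relative deviation from
  the closed forms is below $10^{-8}$; the tests require $10^{-6}$. A
  general-purpose ODE suite would add nothing here — the systems are fixed,
  tiny, and the integrator doubles as the oracle on the singular manifold.
* **Singular manifold.** At $2p_0 = p_1+p_2$ the printed $\alpha$ is
  undefined ($0/0$ solution form). We detect
  $|2p_0-(p_1+p_2)| < 10^{-9}(2p_0+p_1+p_2)$ and switch to the analytic
  L'Hôpital limit (with $s = p_1+p_2$): $x = 2N\,s\,t\,e^{-st}$,
  $y = p_1(2N)^2[1-(1+2st)e^{-2st}]/(4s)$,
  $z = p_2\beta\,2N[1-(1+st)e^{-st}]/s$. Continuity across the switch is
  tested against the integrator.
* **Cancellation.** All $1-e^{-x}$ terms use `expm1` so small-$t$ ratios
  (the 80 limit) are exact to working precision.

# In-silico digestion

Cut sites are occurrences of the recognition sequence (HaeIII `GGCC`
cutting G G | C C, MboI `GATC` cutting before the site, HindIII `AAGCTT`
cutting after the first base), scanned on one strand only — all supported
enzymes are palindromic, and the package refuses non-palindromic sites
rather than silently missing the minus strand. Overlapping occurrences are
all counted: the quantity of interest is a sequence statistic, not a
chemistry simulation. Coordinates are 0-based half-open (BED-compatible)
with cut positions as between-base coordinates. `N` bases never match and
are excluded from the spacing denominator, so `mean_spacing` is non-N
length over site count. On i.i.d. uniform sequence a $k$-mer site recurs
every $4^k$ bp in expectation (256 for the 4-cutters, 4096 for HindIII) —
the acceptance suite checks this on a 10 Mb genome, where the spacing
estimator has a standard error of about 1.3 bp for 4-cutters and about
83 bp for a 6-cutter.

`proximity_profile()` averages signal depth in signed-distance bins around
reference peak centers (summit if provided, else midpoint), over *all*
reference peaks — peaks with no nearby signal pull the average down rather
than being dropped — and scales to counts per million sequenced reads.

# Linker detection and PET formation

Bridge-linker search uses the bitap (shift-and) algorithm with bit-parallel
mismatch counting, substitutions only. Hamming matching (no indels) is the
deliberate scope: the tolerance convention for linker trimming is one
substitution, patterns are 15–20 bases (well under the 64-bit word), and a
Hamming oracle is trivially verifiable — the test suite replays 10 000
random (text, pattern, k) cases against a naive scan. Two-step libraries
are searched with both half-linkers and both reverse complements (the
junction may be read from either side and the linker inserts in either
orientation); ties at the same position resolve by pattern order. Reads
whose junction falls within the last 14 bases get a second chance through a
read-end suffix match of at least 8 bases of a pattern prefix with at most
one mismatch. When one read carries genomic sequence on both sides of the
linker, only the upstream tag is kept.

The synthetic-genome aligner is exact-match by design: a 16-mer seed index
plus full verification of the tag and its reverse complement, with `pos`
reported as the tag's 5′-most genomic coordinate (left end on `+`, right
end on `-`). Real libraries should be aligned with a production aligner
and imported via `read_tag_table()` (read_id / mate / chrom / pos / strand
/ mapq); rows under the mapq threshold are treated as multi-mapping.

PETs are pairs with both mates uniquely aligned, anchors ordered
canonically. Cis PETs closer than 1000 bp (configurable; the protocol
gives no value) are flagged self-ligation and removed. Duplicates are
exact coordinate+strand matches of both ends; first occurrence kept. The
library statistics partition input pairs exactly —
`linker_unusable + not_both_unique + self_ligation + duplicates +
unique_pets = total` — and this identity is tested.

`call_peaks_simple()` is a transparent depth-threshold caller (fixed-width
tag extension, per-base coverage, maximal runs above threshold, leftmost
argmax summit, depth rank as a q-value surrogate). It stands where a full
peak caller would be used on real data and is kept deliberately simple so
peak-level tests are exactly reproducible.

# Contact analytics

* **Overlap fractions** count PET *tags* (two per PET) by default, with an
  either-end PET-level option — published percentages are ambiguous between
  the two, so both are exposed and the default follows the per-tag files
  used in practice.
* **Fold-change grouping** uses
  $\log_2[(d_A+1)/T_A] - \log_2[(d_B+1)/T_B]$; high / normal / low at
  $>1$ / $[-1, 1]$ / $<-1$, with the boundary closed on *normal* (the
  published wording gives the open intervals to high and low). The
  pseudocount of one tag handles zero-depth peaks, which the thresholds
  otherwise cannot.
* **Loop clustering** extends both PET ends by 2 500 bp and single-links
  PETs whose extended ends mutually overlap; components with at least five
  PETs (the one printed count threshold) become loops with union-span
  anchors. The anchor extension is not published; 2 500 bp matches the
  scale of anchor regions at typical sequencing depth and is configurable
  and reported. No statistical confidence model is attached — that is an
  external method's role and out of scope.
* **Loop classification** requires both anchors to overlap (within an
  optional slack), testing the direct and the swapped anchor pairing, i.e.
  the `pairtopair -type both` contract; one shared anchor is never enough.
* **Motif orientation** uses only loops with exactly one stranded motif
  per anchor; `(+,-)` in genomic order is convergent.
* **Contact matrices** are binned at `floor(pos/resolution)`, kept
  symmetric, normalised to counts per million PETs. No ICE/KR balancing:
  the comparisons these matrices serve are depth-normalised differences,
  not normalised-contact modelling.
* **Virtual 4C** selects PETs with exactly one end in the viewpoint
  (both-end PETs are self-interactions and excluded), merges distal ends
  within 5 kb by default, and reports clusters with at least five PETs as
  arcs.

# The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture: a
seeded random genome (i.i.d. bases at a set GC content, equal-size
chromosomes), planted non-overlapping stranded binding sites, loops pairing
same-chromosome sites at log-uniform distances, junction molecules, and
paired FASTQ with i.i.d. substitution errors. Default study conditions: a
1 Mb genome on 2 chromosomes, 200 sites (width 200 bp) of which 100 anchor
50 loops at 10–200 kb, 50 000 read pairs of 150 bp (current-platform read
length), 1% per-base error, 10% noise events of which 85% are trans —
random collisions are dominated by inter-chromosomal pairs, and this keeps
intra-chromosomal noise too sparse to assemble spurious loop clusters —
5% duplicate molecules, HaeIII digestion, two-step linker, convergent
anchor-motif fraction 0.9 (the canonical convergence rate of CTCF-anchored
loops).

Junction molecules take one restriction-fragment arm adjacent to the cut
site nearest each anchor (random fragment side), sonication-truncated to a
uniform 50–500 bp (no published arm-length distribution; uniform on a
plausible sonication range), each arm independently inverted with
probability 0.5 and the linker insert inverted with probability 0.5 — so
all four search patterns and both strands are exercised. Reads of 150 bp
are taken from both molecule ends (truncated for short molecules);
junction offsets, per-region error counts and duplicate lineage are
recorded per read pair.

Randomness is governed by one master seed; each stage draws from a
labelled sub-seed, so stages are independently reproducible and inserting a
stage never reshuffles the others.

**Designed recovery.** Because the provenance records where every error
fell, the generator can compute which pairs a perfect pipeline could
recover: both tags error-free (exact-match alignment tolerates none),
junction either beyond the read or with at most one error in the half
linker, not self-ligation-like — reduced to distinct expected PET
coordinate tuples, since arms inverted toward the junction snap tag 5′
ends to the cut site and distinct events can legitimately collide into one
coordinate duplicate. The pipeline's `unique_pet_fraction` is tested
against this yardstick, not against an absolute constant.

**What passing does and does not show.** The generator emulates junction
structure, orientation, sonication, substitution errors, duplicates and
cis/trans composition. It does not emulate polymer-physics distance decay,
ChIP-style pulldown, indels, base-quality structure, repeats, or
mappability — so end-to-end recovery here validates the *logic* of the
chain (trimming offsets, orientation handling, canonicalisation,
clustering), not performance on real genomes. At the default conditions
the expected exact-offset linker-detection rate is
$P(\le 1\ \text{error in }15) = 0.9904$ at 1% error — only half a
standard error above the 0.99 acceptance line at the realised number of
linker-bearing reads, which is the intended strictness of that check, not
slack.

# Problem sizes

The test suite runs module tests on 50–300 kb genomes with 400–5 000 read
pairs and reserves the full study conditions (1 Mb / 50 000 pairs / 10 Mb
digestion genome / 10 000 bitap cases / 100 kinetics draws) for the
acceptance tests, which complete in a few minutes on one CPU. These sizes
were chosen so every statistical check retains the power quoted above
while the whole suite stays comfortably interactive.

# Known limitations

Exact-match alignment makes the recovered fraction a strong function of
the error rate ($0.99^{\ell}$ per tag of length $\ell$); this is by
design — alignment fidelity is not the object of study — but it means
absolute yields are not comparable to real pipelines with mismatch-tolerant
aligners. Loop calling has no background model, so `min_count` is the only
guard against noise clusters; the generator's noise level is set where that
guard is demonstrably sufficient, and callers on denser noise should raise
it. The one-step/two-step comparison is kinetic only; library-preparation
selection effects are outside the model.
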
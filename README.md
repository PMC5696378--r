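# bridgepet

Analysis of bridge-linker mediated (two-step) proximity ligation for
chromatin-contact mapping, built as an R package plus a set of numbered
analysis drivers. The package models why a two-step protocol — digesting
chromatin with a frequent CG-rich cutter and joining fragments through a
biotinylated 20-bp bridge linker before the partner-ligation step — enriches
protein-centric chromatin contacts over conventional one-step in situ
ligation, and implements the complete read-processing and contact-analysis
chain needed to test that model on synthetic libraries with known ground
truth.

## What it computes

**Ligation kinetics.** Free proximal fragments ω (initially 2N) produce
signal contacts y and noise contacts z (via isolated fragments of abundance
β). One-step ligation:

    dω/dt = −(p1+p2) ω      ω(t) = 2N e^{−(p1+p2)t}
    dy/dt = p1 ω²           y(t) = p1 (2N)² (1 − e^{−2(p1+p2)t}) / (2(p1+p2))
    dz/dt = p2 β ω          z(t) = p2 β (2N) (1 − e^{−(p1+p2)t}) / (p1+p2)

Two-step ligation adds a linker-bound intermediate pool x with linker rate
p0 (dω/dt = −2p0 ω; dx/dt = 2p0 ω − (p1+p2)x; dy/dt = p1 x ω;
dz/dt = p2 x β), with closed forms built on
α = 2p0 / (2p0 − (p1+p2)) and an analytic limit on the singular manifold
2p0 = p1 + p2. Both models share the noise asymptote
z(∞) = p2 β 2N / (p1+p2) and the small-time signal-to-noise limit
(p1/p2)(2N/β). A fixed-step RK4 integrator cross-checks every closed form.

**Read processing.** Bridge-linker detection by bit-parallel bitap fuzzy
search (Hamming distance, default 1 mismatch, half-linkers
`ACGCGATATCTTATC` / `AGTCAGATAAGATAT` and their reverse complements), tag
trimming with read-end suffix rescue, exact-match alignment on synthetic
genomes (k-mer seed index; external aligner output imported via a tag TSV
for real libraries), PET formation with canonical anchor ordering,
self-ligation filtering, duplicate removal and full library statistics
(cis/trans unique PETs, unique-PET fraction).

**In-silico digestion.** Cut-site scanning (HaeIII GGCC, MboI GATC, HindIII
AAGCTT, or custom palindromic sites), fragment statistics, and proximity
profiles of signal depth around reference peak centers (per million reads).

**Contact analytics.** PET–peak overlap fractions, per-TF enrichment
ratios, log2 fold-change peak grouping (high / normal / low at ±1, closed
boundary), feature annotation with precedence, binned contact matrices with
per-million normalisation and differential maps, PET clustering into loops
(transitive single-linkage of ±2.5 kb anchors, ≥5 PETs), common/specific
loop classification with both-anchor semantics, CTCF motif orientation
(convergent / divergent / identical), and virtual-4C viewpoint profiles.

**Synthetic data.** A seeded generator plants binding sites and loops on a
random genome, simulates two-step (or one-step) junction molecules with
sonication arms, emits paired FASTQ with substitution errors and duplicate
molecules, and records full per-read provenance so every downstream claim
can be checked against ground truth.

## Worked example

```r
library(bridgepet)

# kinetics at the inferred rates
p <- kinetics_params(N = 1, beta = 1, p0 = 0.05, p1 = 1, p2 = 0.025)
one_step_closed_form(p, 5000)[, c("y", "z")]
#>         y          z
#> 1 1.95122 0.04878049
signal_noise_limit0(p)
#> [1] 80

# a synthetic library, processed end to end
cfg <- sim_config(seed = 1)          # 1 Mb, 200 sites, 50 loops, 50k pairs
lib <- simulate_library(cfg)
res <- process_library(lib$reads$reads1, lib$reads$reads2, lib$genome)
res$stats$unique_pet_fraction        # 0.0542 (designed recovery 0.0522)
res$stats$cis_trans_ratio            # 8.56

loops <- cluster_pets(res$pets, anchor_extension = 2500, min_count = 5)
truth <- truth_loop_table(lib$truth, half_width = cfg$site_width)
mean(classify_loops(truth, loops, slack = 2500)$label_A == "common")
#> [1] 1   # every planted loop recovered; no loop called outside truth
```

The first block evaluates the one-step closed form at late time: the
signal product saturates at p1(2N)²/(2(p1+p2)) = 1.95122 and the noise
product at p2β(2N)/(p1+p2) = 0.04878. The second block generates the
default ground-truth library, recovers 5.4% of read pairs as unique PETs
(against a designed recoverable fraction of 5.2% — most loss is the 1%
per-base error against exact matching), and calls back all 50 planted
loops with zero false loops at the ≥5-PET threshold.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data and
write tables under `results/` (large regenerable artifacts go to
`scratch/`):

1. `01_ligation_kinetics.R` — one-step vs two-step trajectories and y/z.
2. `02_enzyme_digestion.R` — spacing laws; biased vs flat cutter profiles.
3. `03_simulate_library.R` — reference library + ground truth.
4. `04_process_reads.R` — trimming, alignment, PETs, library statistics.
5. `05_contacts_loops.R` — peaks, enrichment, fold-change groups, loops,
   motif orientation, contact matrix, virtual 4C.

## Limitations

The built-in aligner is exact-match and intended for synthetic genomes;
real libraries should be aligned externally and imported with
`read_tag_table()`. Loop calling is plain PET clustering without a
statistical confidence model, and contact matrices are depth-normalised
but not balanced. See the methods vignette (`vignettes/methods.Rmd`) for
model assumptions and design choices.
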
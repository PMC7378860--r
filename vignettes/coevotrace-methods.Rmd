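---
title: "Methods: tracing host–parasite RNA coevolution from serial-transfer sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing host-parasite RNA coevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The system and the analysis problem

coevotrace analyses deep-sequencing data from long-term serial-transfer
replication experiments with a self-replicating host RNA (~2040 nt, encoding
the catalytic subunit of its own replicase) and its parasitic deletion
mutants. Parasites arise spontaneously from the host by large internal
deletions of the replicase gene and replicate only by exploiting
host-supplied replicase; because they are shorter they replicate faster and
compete with the host. Three parasite size classes recur: parasite-α
(~220 nt, lacking the whole gene), parasite-β (~1070 nt, lacking roughly the
3′ half) and parasite-γ (~510 nt, additionally lacking part of the remaining
5′ region). The experiment encapsulates molecules in ~2 µm water-in-oil
droplets, incubates them, removes 80% of the droplets, replaces them with
fresh translation mix (a five-fold dilution), and mixes — one round; the
sequencing samples are RNA pools drawn at selected rounds.

The analysis question is population-genetic: which mutations rise to
appreciable frequency in which species and round, which combinations of
mutations (genotypes) dominate, how the genotype cloud moves through
sequence space over rounds, and where parasites are generated from evolving
hosts. Every stage of that reconstruction is implemented here, together
with a ground-truth simulator of the protocol so that each stage can be
validated by recovery of planted signal.

## Pipeline model

1. **Classification.** Reads are assigned to species classes by length
   alone, using non-overlapping bins (defaults: host 1800–2300 nt, β
   900–1300, γ 400–700, α 150–350). Classification is total: a read in no
   bin is `unclassified` and excluded downstream.
2. **Pass filtering.** Circular-consensus pass counts act as a quality
   filter: host reads need ≥ 5 passes, parasite reads ≥ 10 (boundaries
   inclusive). Reads without pass metadata are kept, with a warning,
   because short-read data carry no pass counts.
3. **Alignment.** Each read is aligned end-to-end to its class reference
   with an affine-gap global aligner (match +1, mismatch −2, gap open −4,
   gap extend −1; a length-k gap costs 4 + k). Parasite references are the
   host reference with the class deletion window excised, so parasite
   event coordinates lift exactly onto host coordinates through the
   retained-site map. Pre-aligned (gapped FASTA) input bypasses the
   aligner so externally aligned data can be consumed unchanged.
4. **Mutation calling.** One event per mismatch column (substitution), per
   deleted reference base (multi-base deletions decompose into per-base
   events) and per insertion run (anchored after the preceding reference
   position). Coordinates are 1-based on the original host reference;
   labels follow the field convention (`C1986U`, `G100del`, `72insA`).
5. **Frequency tables and dominance.** Per (round, class), event frequency
   is carrier reads over class depth. A mutation is *dominant* when its
   frequency strictly exceeds 10% in at least one (round, class) sample —
   the threshold is strict because dominance is defined as "more than" the
   cutoff, and it is applied per round and per class. Since different
   mutations can hit one site, the distinct-site count is tracked
   separately.
6. **Genotype projection.** Each read reduces to a presence vector over the
   dominant mutations: 1/0, or masked (`-`) at sites inside the read's
   class deletion window. Reads with `N` at an unmasked dominant site are
   dropped so vectors stay total. Identical vectors pool; frequencies are
   normalized within (round, class) *before* truncation to the top 90
   genotypes, because the top-90 cut is a display/selection step, not a
   re-normalization.
7. **Genotype space.** The joint set of top genotypes of all classes and
   rounds enters one squared-Hamming distance matrix D (masked sites
   contribute zero, so a parasite perfectly matching a host outside the
   deletion is at distance zero). D is double-centered into the kernel
   K = −½·C·D·C and eigendecomposed; genotype i is plotted at
   (√λ₁·e₁ᵢ, −√λ₂·e₂ᵢ).
8. **Networks and lineages.** Within-class edges connect pairs at Hamming
   distance 1; cross-class edges connect pairs at masked distance 0 — the
   candidate parasite-generation events. Parasite-unique mutations are
   dominant parasite mutations in the retained region never rising above
   the threshold in the host; persistence tracks report the rounds a
   mutation stayed above threshold, with gaps.

## Numerical and design choices

**Coordinate scaling.** The principal-coordinate formula is implemented
with the square root of the eigenvalue, the standard scaling under which
embedded inter-point distances reproduce the input distances for Euclidean
D; two genotypes at Hamming distance h embed at separation exactly h
(λ₁ = h²/2, coordinates ±h/2). A literal `coord_scaling = "eigenvalue"`
variant (λ_k in place of √λ_k) is provided as a switch because that form
also circulates; it only rescales axes.

**Negative eigenvalues.** A squared-Hamming D need not be Euclidean under
masking, so K can have negative eigenvalues. They are excluded from
coordinates and summarized as a diagnostic (their absolute mass over the
total absolute eigenvalue mass). If λ₂ ≤ 0 the second coordinate is set to
zero and flagged.

**Determinism.** Eigenvector signs are fixed by making the
largest-magnitude component positive; aligner traceback ties prefer an
aligned pair over a read gap over a reference gap, with greedy gap
extension, so identical inputs always give identical output. Genotype rank
ties break lexicographically on the vector string. All stochastic steps
run under one seed threaded from the configuration, and the pipeline
writes a manifest (config hash, seed, versions, row counts) so runs are
reproducible byte for byte.

**Threshold semantics.** Dominance uses strict inequality (> 0.10). The
same threshold defines "not found in the host" for unique-mutation calling
by default, because sequencing error makes literal absence unattainable in
real data; a literal `mode = "absent"` (zero host reads carrying the
mutation) is available for comparison.

**Origin search window.** Parasite-origin matching scans host genotypes of
the same round and all earlier sequenced rounds; generation may predate the
round in which both genotypes are first sampled, and the closest round is
reported first.

**Overlapping deletion windows.** Parasite classes may have nested or
overlapping deletion windows — the real classes do (the α deletion contains
most of the β and γ deletions), and disjoint windows could not reproduce
the observed class lengths on one host. Class identity remains unambiguous
because every simulated deletion event carries an explicit class label and
read classification uses length bins; only *identical* windows for two
classes are rejected. Every window must leave both termini intact, since
all species retain the terminal replicase-recognition regions.

## The simulator: what it emulates, and what it does not

`simulate_serial_transfer()` reproduces the protocol structure round by
round: Poisson partitioning of molecules into droplets (mean
`droplet_lambda`, default 2), within-droplet replication during
incubation, per-base mutation of each new copy, rare large deletions
converting a host copy into a parasite class, and binomial dilution with
retention probability `dilution_keep` (default 0.2 — the 80% droplet
removal / five-fold dilution of the protocol). The reported population for
each round is the post-incubation, pre-dilution pool, which is what a
sequencing sample is drawn from. Reads are drawn multinomially by copy
number, with independent per-base sequencing errors, and each read carries
round, class, source-molecule and pass-count annotations.

The replication kinetics inside a droplet are not measured by the
experiment, so the simulator uses the simplest model with the right
qualitative behaviour: a host molecule leaves Poisson(r − 1) new copies
(r = `replication_factor_host`, default 5, balancing the five-fold
dilution), a parasite of length L replicates only in droplets containing
at least one host and with factor r·(L_host/L)^k (k =
`replication_advantage_exponent`, default 1) — shorter parasites replicate
faster — and each droplet produces at most `droplet_capacity` new copies,
standing in for the finite translation/replication resources. Defaults:
substitution rate 1.0 × 10⁻⁵ per base per replication (the error-prone
replicase), indels ten-fold rarer, and a per-replication deletion-event
rate of 10⁻⁴.

Internally a molecule is a set of mutation events in host coordinates plus
a class label; sequences are materialized from the reference on demand.
Ground truth (per-round per-class mutation frequencies, every deletion
event, and the full parentage map) is therefore exact by construction, not
re-estimated by alignment.

The simulator deliberately omits: translation and replicase biochemistry,
droplet volume and oil-phase physics, within-droplet resource dynamics
beyond the capacity cap, recombination, and any fitness effect of point
mutations (all mutations are neutral). Passing recovery tests on simulated
data therefore demonstrates that the analysis stages are correct
transformations of reads into frequencies, genotypes and networks — not
that real populations evolve neutrally, and not that the growth model fits
measured concentration trajectories.

A configuration guard rejects settings whose expected population exceeds
`max_population` (estimated from host growth and the droplet capacity
bound), and a hard runtime cap backs the estimate up, because geometric
growth can otherwise explode silently.

## Problem sizes and validation design

The validation suite runs entirely on synthetic data built in code. Unit
fixtures use hosts of 100–200 nt with a single parasite class so every
alignment is exhaustively checkable; recovery checks use planted mutation
frequencies {0.05, 0.15, 0.5} at read depth 2000 over 5 rounds and four
classes (host length 400 nt), a planted 0.7/0.3 haplotype mixture at depth
2000, 20 planted deletion events over 12 dominant sites, and 200 random
short sequence pairs against an independently written recursive alignment
oracle (itself validated against full enumeration on very short pairs).
These sizes give multinomial standard errors an order of magnitude below
the decision thresholds while keeping the whole suite fast. The
`scripts/acceptance.R` driver recomputes the same quantities from scratch
against the installed package and writes them as JSON.

## Known limitations

- Reads are assumed to cover the full reference; truncated reads are
  called as long deletions rather than flagged as partial coverage.
- Quality scores are ignored beyond the pass-count filter; there is no
  strand-aware or error-model-aware calling.
- The aligner is O(nm) in time and memory and refuses sequences beyond a
  configurable bound (default 5000 nt); longer inputs should be supplied
  pre-aligned.
- Structural variation other than the configured class deletions is not
  modelled; a novel deletion class would surface as `unclassified` reads.
- The 2D embedding is a projection: distances between distant clusters are
  faithful only insofar as the leading two eigenvalues dominate, which the
  negative-eigenvalue diagnostic helps judge.
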
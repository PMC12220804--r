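---
title: "Detecting endogenous polinton-like viruses: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting endogenous polinton-like viruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plvscan)
```

## The problem

Polinton-like viruses (PLVs) and virophages are small (roughly 6--80 kb)
double-stranded DNA elements that integrate into the nuclear genomes of
protists. An integrated ("endogenous") element leaves three physical
signatures in an assembly:

1. **Terminal inverted repeats (TIRs):** the two ends of the element are
   reverse complements of each other, from about a hundred bases up to
   several kilobases long, with an arm-to-arm identity that reflects how
   recently the element was mobile.
2. **A GC-composition shift:** the element's base composition usually
   differs from the host's by ten or more percentage points over the
   whole insert.
3. **A target site duplication (TSD):** integrase-mediated insertion
   duplicates a short stretch of host sequence (canonically ~4--6 bp for
   retroviral-type integrases; 7--23 bp, sometimes offset from the TIR by
   1--3 bp, for tyrosine-recombinase-associated elements), leaving one
   copy immediately outside each TIR.

plvscan detects candidate elements from these signals plus
hallmark-gene evidence (major capsid proteins, packaging ATPase,
integrases, maturation protease, protein-primed polymerase) supplied as
a hit table by an external HMM scan, classifies them (PLV / virophage /
hybrid by capsid type), calls TSDs, computes per-genome expansion
statistics, and clusters elements by gene sharing in a bipartite
genome--ortholog network.

## Detection model and parameters

### Windowed GC segmentation

GC is computed in non-overlapping 500 bp windows (`windowed_gc()`), the
scale at which composition shifts are normally triaged in a genome
browser. Maximal runs of windows deviating from the host baseline by at
least `min_delta_points` (default 10) are reported as segments when
5--80 kb long. Ten points is a deliberate convention: reported
element-vs-host deltas run from about 14 to 28 points, so a 10-point
gate keeps sensitivity below the smallest of them while rejecting
compositional noise. Runs may bridge a single non-deviant window,
because nested GC-divergent insertions inside elements would otherwise
split one element into two segments; all-N windows carry an undefined
GC and neither break nor extend a run. GC is corroborating evidence,
not a gate: `min_gc_delta` defaults to 0 in element calling because
population-level deltas do not bound the per-element delta.

### Inverted-repeat search

Scoring follows the EMBOSS einverted conventions (match +3, mismatch
-4, linear gap 12 per base, threshold 50) with the maximum separation
between the outer arm edges set to 80 kb; the downstream size filter
retains inserts of 6--80 kb with both arms 100 bp--8 kb, all bounds
inclusive. N scores as a mismatch against everything.

Two search modes share this definition. Contigs up to `exact_max_len`
(default 1500 bp) are scanned by a full local-alignment DP of the
contig against its reverse complement, with start tracking, endpoint
constraints (arm5 strictly upstream of arm3, separation capped) and
iterative best-hit extraction that removes both arm regions before
rescanning. Longer contigs use reverse-complement 12-mer seeding within
the separation window followed by banded (half-width 16) X-drop
extension; 12-mers keep the expected number of chance seeds per genome
small while any arm pair at the identities worth reporting contains
many exact 12-mers, and gaps are rare under a 12-per-base penalty so a
narrow band suffices. Every reported pair's score is recomputed by an
end-to-end alignment of arm5 against revcomp(arm3), so reported scores
are reproducible from reported coordinates by construction.

### Boundary refinement

Two post-processing steps place element boundaries more accurately than
the raw maximum-scoring alignment:

* **Terminal trimming.** A maximum-scoring local alignment keeps any
  net-positive terminal extension, so it overruns the true repeat
  boundary whenever a few chance flank bases pair. Terminal alignment
  columns are trimmed back to the maximal-scoring core under a +1
  match / -2 mismatch-or-gap weighting, which removes terminal segments
  below two-thirds identity -- a level sparse chance extensions
  essentially never reach while genuine arm ends do.
* **TSD-guided polish.** A TSD is a direct repeat; when its copies
  happen to contain reverse-complement-palindromic positions, the
  duplication itself extends the inverted repeat and pulls both element
  edges outward symmetrically -- and such terminal segments can pass
  the two-thirds rule. The element caller therefore scans symmetric
  inward shifts t = 0..15 and maximises J(t) = (TSD matches minus
  mismatches at that boundary) minus the number of matching alignment
  columns discarded by the shift (discarded mismatch columns are free;
  every non-zero shift costs at least one). Ties prefer the
  interpretation whose TSD needs no offset pad, then the smaller shift.

The polish faces a genuinely ambiguous case: when the host base
adjacent to the duplication equals the complement of the arm's outer
base on both sides (probability about 1/16 per element at the default
compositions), the sequence contains a strictly longer perfect
duplication consistent with a one-base-shifted boundary, and no local
evidence can distinguish the two readings. The decision rule accepts
the shift, which is the posterior-favoured reading (the configuration
that makes the shift correct arises about four times more often than
the one that makes it wrong). The consequence is visible in
`analysis/03_tsd.R`: planted duplications are recovered exactly from
true element boundaries in ~99% of elements, but only ~88% through
detected boundaries -- the gap is this irreducible ambiguity, not a
caller defect.

### TSD calling

`call_tsd()` exhaustively scores every (length 4--25, left pad 0--3,
right pad 0--3) placement of a candidate duplication across the two
50 bp flanks; a candidate is valid when its Hamming mismatches are at
most min(2, floor(L/5)). The proportional cap encodes that one
mismatch is acceptable in a 7-mer while degenerate short matches are
spurious. The best candidate maximises matches minus mismatches, with
ties to the longer length, the smaller total pad, fewer mismatches,
then the smaller left pad (the last key is a declared convention that
makes the order total). Low-complexity calls -- at most two distinct
bases, or one base at 80% or more -- are flagged as likely spurious;
this is the weakest rule that flags GAGGG while passing GTTAT and
TGAATAA. Note that under these defaults unrelated flanks yield a
chance call in roughly a fifth of cases (dominated by exact 4-mers
across the 16 pad placements), which is why conservation summaries
exclude low-complexity calls and why downstream interpretation leans
on mismatch counts.

### Element calling and statistics

Every size-filtered TIR pair is a candidate element spanning
TIR-outer-edge to TIR-outer-edge (TSDs lie outside the element).
Candidates require at least one interior hallmark-gene hit by default;
TIR-only candidates are diverted to a separate unconfirmed track
rather than silently dropped, because requiring markers is a policy,
not a physical necessity. Marker hits are filtered at e-value < 1e-3,
with a 0.70 model-and-query coverage floor for capsid (MCP) classes
only -- capsid assignments feed classification, so they are held to
the stricter regime, while accessory markers default to no coverage
floor. Classification: PLV-type MCP only gives PLV, virophage-type
only gives virophage, both give hybrid, anything else is unassigned.
Genome statistics follow directly (density per Mb, percent of assembly
in elements, mean TIR identity, conserved-TSD fraction); densities are
kept at full precision and rounded to one decimal only for display.

### Gene-sharing network

Genomes and ortholog clusters (memberships computed externally; protein
clusters with fewer than ten members are excluded) form a bipartite
graph whose communities are found by maximising Barber's bipartite
modularity

$$Q_B = \frac{1}{m}\sum_{i,j}\left(A_{ij} - \gamma\,\frac{k_i d_j}{m}\right)\,\delta(c_i, c_j)$$

with A the genome-by-ortholog weight matrix, k and d the class degrees
and m the total edge weight. When the smaller node class has at most
eight members the optimum is found exactly: all partitions of the
smaller class are enumerated and each node of the larger class joins
its best community independently, which is globally optimal because,
conditional on the smaller class's partition, the objective separates
over larger-class nodes. Larger graphs use a multi-level Louvain-style
heuristic: greedy sweeps alternating over the two node classes (so
genome and ortholog clusters form independently), aggregation of
communities into super-nodes, and eight seed-shuffled restarts keeping
the best Q_B. Zero-gain ties move toward the lower community id, which
both guarantees termination and resolves the single-edge graph to one
merged community. Dereplication of near-identical elements
(greedy longest-first, 90% identity over 90% of the shorter sequence)
uses local alignment via Biostrings.

## The synthetic-data generator

`simulate_assembly()` plants the full signature stack with exact ground
truth. Defaults define the package's reference study condition: ten
2 Mb contigs at host GC 0.55; 100 elements of 6--80 kb at GC 0.38 (a
17-point shift, mid-range for reported endogenous PLV deltas) with arm
identity 0.95 and arms of 100 bp--8 kb; exact, flush 5--8 bp TSDs
(canonical integrase behaviour; mismatches and 0--3 bp pads are knobs);
a four-gene marker cassette (PLV-type MCP, packaging ATPase,
retroviral-type integrase, protease) mirrored into a synthetic hit
table with scores passing the default filters; and ten elements
carrying a nested GC-rich (0.62) insertion of 4--9.5 kb flanked by
300 bp direct repeats ("a few hundred base pairs" made concrete). The
fraction of elements with nested insertions is not a settled quantity
and is exposed as a knob with no claimed realism.

Background sequence is i.i.d. per base. That is deliberate: the
detection signals used downstream (window GC, repeats, flank
duplications) do not require realistic k-mer structure, and the i.i.d.
model makes analytic expectations (seed counts, chance-duplication
rates, palindromic-overshoot probabilities) available for tests. The
generator does not simulate reads, sequencing error, assembly
artifacts, real gene content, tandem repeat families, or host repeat
landscapes -- so passing recovery tests demonstrates correctness of the
detection logic under clean signals, not performance on real
assemblies, where repeat-rich regions and degraded elements will lower
both precision and recall in ways the simulation cannot expose.

Problem sizes used throughout the analysis scripts and acceptance
checks -- a 20 Mb assembly with 100 elements, 1000-case oracle
comparisons capped at 300 bp, exhaustive modularity checks on graphs of
up to twelve nodes, twenty planted-graph seeds -- were chosen as the
smallest scales at which every signal class (long arms, nested
insertions, multi-hit contigs, chance TSDs) appears many times.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open in memory; GFF3 is written 1-based
  inclusive, BED 0-based half-open; conversions happen only at I/O.
* Ambiguity codes are collapsed to N on read (with a reported count);
  N is a universal mismatch in every aligner and a non-base in GC.
* Empty contigs, empty assemblies, zero planted elements and empty hit
  tables all produce empty outputs, not errors; infeasible element
  packing and duplicate FASTA headers are hard errors.
* An element covering a whole contig has no flank; its GC delta falls
  back to the assembly-wide baseline with a warning.
* Determinism: every stochastic step (simulation, node-order shuffles)
  is seeded; identical seeds give byte-identical outputs, and run
  manifests archive the configuration and input checksums.

## Known limitations

* TIR discovery in seeded mode requires one exact 12-mer shared by the
  arms; arm pairs below roughly 70% identity, or shorter than the seed,
  can be missed. The exhaustive mode has no such floor but is quadratic.
* Boundary placement is ambiguous at about the 1/16-per-element level
  discussed above; consumers needing exact insertion sites should
  inspect the reported TSD offsets.
* The gene-sharing stage consumes ortholog memberships; it does not
  reproduce the external protein clustering, and the dereplication step
  makes no claim of equivalence to any particular clustering tool.
* Marker evidence is taken from hit tables at face value after
  thresholding; the pipeline neither predicts genes nor scans HMMs.
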
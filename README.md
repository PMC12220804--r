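# plvscan

Detection of endogenous polinton-like viruses (PLVs) and virophages in
genome assemblies.

PLVs are 6–80 kb dsDNA elements that integrate into protist nuclear
genomes. An integrated copy is recognisable by three physical
signatures: terminal inverted repeats (TIRs — the element's two ends
are reverse complements, 100 bp–8 kb long), a GC-composition shift of
10–30 percentage points against the host, and a short target site
duplication (TSD) of host sequence left immediately outside each TIR by
the integrase (~4–6 bp canonically; 7–23 bp, sometimes offset by
1–3 bp, for tyrosine-recombinase-associated elements). plvscan combines
these signals with hallmark-gene evidence (capsid, ATPase, integrase,
protease hits from an external HMM scan) to call complete, classified
elements, then quantifies per-genome expansions and clusters elements
by gene sharing.

At its core are four pieces:

* an inverted-repeat search under einverted-style scoring (match +3,
  mismatch −4, linear gap 12, score ≥ 50, separation ≤ 80 kb) — an
  exhaustive local-alignment DP on small contigs, reverse-complement
  k-mer seeding with banded X-drop extension on large ones — followed
  by size filters (insert 6–80 kb, arms 100 bp–8 kb) and TSD-guided
  boundary polishing;
* a sliding/padding TSD caller that exhaustively scores every
  (length 4–25, per-side pad 0–3) placement across the two 50 bp
  flanks, with a proportional mismatch cap and a low-complexity flag;
* per-genome statistics (element density per Mb, fraction of the
  assembly inside elements, TIR identity, conserved-TSD fraction);
* bipartite genome–ortholog community detection maximising Barber's
  modularity `Q_B = (1/m) Σ_ij (A_ij − k_i d_j / m) δ(c_i, c_j)` —
  exact for small graphs, multi-level Louvain with restarts otherwise.

A synthetic-genome generator plants the full signature stack (elements,
TIRs at configurable identity, TSDs, marker cassettes, nested GC-rich
retroelement insertions with direct repeats) with exact ground truth,
so every stage is testable offline.

## Worked example

Simulate a 20 Mb assembly with 100 planted elements, run detection, and
score the calls against the planted truth:

```r
library(plvscan)

sim <- simulate_assembly(sim_config(seed = 1))
res <- detect_elements(sim$assembly, filter_marker_hits(sim$marker_hits))
res$funnel
#> # A tibble: 3 x 2
#>   stage                         n
#>   <chr>                     <int>
#> 1 tir_pairs_raw               435
#> 2 tir_pairs_size_filtered     100
#> 3 elements_marker_confirmed   100
score_detection(res$elements, sim$truth$elements, tol_bp = 5)
#> # A tibble: 1 x 5
#>   n_called n_truth n_matched precision recall
#>      <int>   <int>     <int>     <dbl>  <dbl>
#> 1      100     100        97      0.97   0.97
```

The funnel reads: 435 raw inverted-repeat pairs genome-wide (mostly
short chance repeats), 100 surviving the insert/arm size filters, 100
confirmed by an interior hallmark gene — and 97 of the 100 planted
elements are recovered with both boundaries within ±5 bp.

The TSD caller on the two fixed worked constructs (an element whose
flanks carry TGAATAA/TCAATAA, and one flanked by exact GTTAT copies):

```r
toy <- toy_worked_examples()
e <- toy$truth$elements
fl <- extract_flanks(toy$assembly$seq[1], e$start[1], e$end[1])
call_tsd(fl$left, fl$right)[, 1:5]
#> # A tibble: 1 x 5
#>   left_copy right_copy consensus length_bp n_mismatches
#>   <chr>     <chr>      <chr>         <int>        <int>
#> 1 TGAATAA   TCAATAA    TGAATAA           7            1
```

— a 7 bp duplication with one mismatched base, the signature of a
retroviral-type integrase insertion.

The numbered scripts under `analysis/` run the same stages as a
narrative workflow (`01_simulate.R` → `04_network.R`), writing tables
under `results/`.

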
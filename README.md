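# viromics

Post-assembly profiling of RNA viruses found in host transcriptome data.

Transcriptome assemblies of wild-caught animals — filter feeders such as
bivalves most of all — routinely contain contigs of RNA viruses whose host
cannot be assigned from abundance alone. `viromics` implements the analysis
layer that runs after assembly and external homology searches:

* **Screening** — turn BLASTP/HMMER evidence tables into viral candidates:
  the five-hit BLASTP rule at E ≤ 10⁻⁵⁰, the viral RdRp PFAM domain route
  (PF00680, PF00978, PF00998, PF02123, PF07925, PF04197) at E ≤ 10⁻⁵,
  host-genome subtraction, greedy 90%-identity clustering, ORF prediction
  (≥ 100 codons, six frames), polyA-tail detection, and the completeness
  rule (*nearly complete* = single contig > 5 kb with a complete ORF).
* **Abundance** — stringent read counting (length/similarity fractions
  0.9/0.9 for viruses, 0.8/0.8 for the COI contamination screen), per-mille
  viral fractions, TPM, informative-sample selection (≥ 1000 viral reads),
  and COI profiles of which organisms contributed reads to a library.
* **Editing** — a low-frequency pileup SNP caller (coverage ≥ 50×,
  count ≥ 5, frequency ≥ 1%, 5-base context quality ≥ PHRED 30), selection
  of ADAR-compatible A→G calls, and 5′-neighbour distributions.
* **Motif under-representation** — a permutation test for depletion of
  editable dinucleotides (WA/AA/CA/GA/TA). The null shuffles third codon
  positions within groups sharing the same first two bases and amino acid,
  preserving the protein and the exact base composition. For a motif count
  $m_{\mathrm{obs}}$ and shuffled counts $m_1,\dots,m_N$ (N = 1000),

  $$p_{\mathrm{below}} = \frac{1}{N}\#\{i : m_i < m_{\mathrm{obs}}\},$$

  with under-representation at $p < 0.05$ and over-representation at
  $p > 0.95$; the companion *repTrFrac* statistic (fraction of motif
  occurrences whose A→G transition is non-synonymous) flags **maximal**
  under-representation when the count is depleted but the survivors are
  mutation-constrained.
* **Small RNAs** — pair merging, 15–50 nt size profiles with 20–22 nt and
  29–30 nt band fractions, exact fragment matching to viral contigs, and
  the count-vs-expression r² that separates RNAi products from degradation
  fragments.
* **Simulation** — generators for all of the above with exact truth tables
  (coding sequences, motif-depleted coding sequences, edited read pileups
  as SAM, small-RNA libraries in three regimes), so every stage is testable
  without sequencing data.

Functions take data frames first and return tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(viromics)
library(dplyr)

# a synthetic viral contig: 5.4 kb coding sequence plus a polyA tail
contig <- paste0(gen_cds(1800, seed = 1), strrep("A", 30))
find_orfs(contig, min_codons = 100)
#> # A tibble: 2 × 9
#>   orf_id       start   end strand n_codons complete ...
#> 1 contig1_orf1     1  5400 +          1800 TRUE
#> 2 contig1_orf2  4649  4957 -           103 TRUE
detect_polya(contig)
#> [1] TRUE
```

The main ORF spans the whole contig (1800 codons, complete), so the contig
would classify as *nearly complete*; the polyA tail suggests a
polyadenylated virus or polyA-selected library.

```r
# does a coding sequence avoid editable dinucleotides?
dep <- gen_depleted_cds(600, motif = "AA", strength = 1, seed = 4)
cdur_test(dep, motifs = c("AA", "TA", "WA"), n_shuffles = 1000, seed = 2) |>
  tidy() |>
  select(motif, observed_count, below_p, reptrfrac_p, below_class, maximal)
#> # A tibble: 3 × 6
#>   motif observed_count below_p reptrfrac_p below_class maximal
#> 1 AA                64   0           0     under       FALSE
#> 2 TA                92   0.508       0.508 neutral     FALSE
#> 3 WA               156   0           0     under       FALSE
```

The AA-depleted sequence shows `below_p = 0`: none of 1000
composition-preserving shuffles had as few AA motifs — strong
under-representation (WA follows because AA ⊂ WA); TA, which was not
selected against, is neutral.

```r
# editing footprint recovery on a simulated pileup
pu <- gen_edited_pileup(
  gen_cds(1000, seed = 3),
  sim_config(seed = 8, coverage = 100, edit_rate = 0.03)
)
calls <- call_snps(pu, pu$reference) |> select_adar(cds_only = FALSE)
nrow(calls) # 19 of the 23 injected edits pass the calling thresholds
neighbor_distribution(calls)
#> # A tibble: 4 × 3
#>   neighbor_5p     n fraction
#> 1 A               5   0.263
#> 2 C               3   0.158
#> 3 G               1   0.0526
#> 4 T              10   0.526
```

All calls are A→G, and their 5′ neighbours lean A/T — the ADAR-like context
preference the simulation injected (the four sub-threshold sites have
alternate counts below 5 and are correctly not called).

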
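---
title: "Profiling RNA viruses in transcriptome assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling RNA viruses in transcriptome assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromics)
library(dplyr)
```

RNA viruses leave recognisable traces in the transcriptomes of their hosts:
contigs encoding RNA-dependent RNA polymerase (RdRp) domains, read pileups
carrying low-frequency A-to-G substitutions from host ADAR editing,
dinucleotide compositions skewed by sustained selection against editable
motifs, and — where an RNAi response is active — virus-derived small RNAs
with characteristic 21 nt or 30 nt size modes. `viromics` packages the
post-assembly side of such an analysis: everything after the assembler and
the external search tools, and everything needed to validate it on
synthetic data with known truth.

This vignette explains each method, its assumptions and tunable parameters,
what the synthetic-data generators emulate (and deliberately do not), and
the numerical and design choices that were genuinely open.

## Screening contigs for viral candidates

The screen consumes tabular evidence from external tools — BLASTP hits of
known viral proteins against the assembly's predicted proteins and HMMER
domain hits — and applies a decision cascade:

1. **Evidence filtering** (`filter_evidence()`). A contig is kept if it has
   at least `min_hits = 5` distinct BLASTP alignments at
   `evalue <= 1e-50`, or at least one hit to a viral RdRp PFAM model
   (`VRDRP_PFAM`: PF00680, PF00978, PF00998, PF02123, PF07925, PF04197) at
   `evalue <= 1e-5`. Hits are counted per query–subject pair so that HSP
   fragmentation of one alignment cannot inflate the tally. The hit-count
   rule is applied to the BLASTP route only: a single confident RdRp domain
   is accepted on its own, since the domain is itself strong evidence of an
   RNA virus.
2. **Host subtraction** (`subtract_host()`). Candidates matching the host
   genome at `1e-5` are removed; endogenised or host-derived sequences are
   the main false-positive class in transcriptome virome screens.
3. **Redundancy reduction** (`cluster_by_identity()`). Longest-first greedy
   clustering at 90% identity, with identity defined as matched positions
   of a global alignment divided by the length of the shorter sequence —
   the convention of greedy redundancy clusterers, so that a fragment of a
   longer protein joins the longer protein's cluster. Ties in the length
   sort are broken lexicographically, making the result deterministic for
   a given input set.
4. **Completeness** (`classify_completeness()`). A candidate is
   `nearly_complete` when a single contig is longer than 5 kb and encodes
   at least one complete ORF; otherwise `partial`. Both conditions are
   strict and the classifier is a pure function of (length, ORF table), so
   the tests exercise the exact boundary grid (4999/5001 nt, with and
   without a complete ORF).

ORF prediction (`find_orfs()`) is a six-frame scan reporting every maximal
ORF of at least 100 codons, where the codon count runs from the ATG through
the stop codon inclusive. ATG-initiated ranges that run off the contig edge
are reported with `complete = FALSE`: they are useful for annotation but
never satisfy the completeness rule, which demands an intact coding unit.
A polyA tail (`detect_polya()`) is called when some terminal window of at
least 15 nt contains at most 10% non-A bases; the window length and
tolerance are heuristic knobs (the underlying observation is simply "the
contig ends in a long A run", and real tails are occasionally interrupted
by sequencing errors).

## Abundance and contamination

`count_mapped()` counts a read for a reference when its primary alignment
covers at least a fraction `min_len_frac` of the read and matches over at
least `min_sim_frac` of the aligned length; similarity is taken as
`(aligned_length - NM) / aligned_length`, the standard proxy when only the
edit distance is available. Viral quantification uses 0.9/0.9 (stringent:
cross-mapping between related viruses is the risk), the COI contamination
screen 0.8/0.8 (permissive: the barcode collection cannot contain every
haplotype). One read, one vote: secondary and supplementary alignments are
ignored. Abundances are reported per-mille of total sample reads
(`viral_fraction()`), which compares samples without depth bias;
`select_informative()` keeps samples with at least 1000 viral reads
(at-least convention), and `tpm()` provides length-normalised expression
summing to $10^6$. `coi_profile()` turns counts over a COI barcode
collection into percentages and reports entries at or above 0.01% —
profiling which organisms actually contributed RNA to a library.

## Editing footprints

`call_snps()` is a pileup caller tuned for low-frequency variants on viral
genomes: a site call requires coverage ≥ 50, alternate count ≥ 5, alternate
frequency ≥ 1% (per alternate base, with reads locally aligned across the
site as denominator), and a mean PHRED quality ≥ 30 over the 5-base read
window centred on the site (site ± 2, clipped at read ends), averaged over
the supporting reads. The window width is configurable; "the five
surrounding bases" is read as the centred window, which penalises calls in
locally noisy sequence either side of the variant. ADAR-compatible calls
(`select_adar()`) are A-to-G on the reported strand; T-to-C can optionally
be included as antisense evidence but is off by default, since strandedness
of the source library is usually unknown. The 5' neighbour
(`annotate_neighbor()`) is read from the reference consensus — editing is
annotated at genome positions, not per read — and `neighbor_distribution()`
summarises it over calls, excluding reference-edge sites from the
denominator. An A/U-rich 5' context is the classical ADAR signature; the
`in_cds` flag (computed against the ORF table) restricts attention to
coding regions where the under-representation analysis applies.

## Dinucleotide under-representation (the permutation test)

The central statistic asks: does a coding sequence contain fewer editable
dinucleotides (WA, AA, CA, GA, TA — the edited A in second position) than
expected, given its protein and its base composition?

The null model (`shuffle_third_positions()`) permutes third codon positions
within exchangeability groups keyed by *(first two bases, encoded amino
acid)*. This is the only permutation family that simultaneously preserves
the protein sequence and the exact per-base multiset (hence GC content),
including the boxes where the third base changes the amino acid (ATA vs
ATG, TGA vs TGG, AGA/AGG vs AGC/AGT). Preserving GC matters: shuffles that
drift in GC are known to bias dinucleotide null distributions.

Two statistics are referred to this null, each repeated over
`n_shuffles = 1000` permutations (`cdur_test()`):

* **below**: the motif count. `below_p` is the fraction of shuffles with
  *strictly fewer* occurrences than observed; under 0.05 the motif is
  under-represented, over 0.95 over-represented. Ties contribute nothing
  under the strict rule (the literal definition); a midrank option
  (`ties = "midrank"`) is available for users who prefer ties to count
  half, but it is off by default.
* **repTrFrac**: over all motif occurrences, the fraction at which the
  defining A→G transition changes the encoded amino acid. Its permutation
  p-value asks whether the *remaining* motifs are unusually
  mutation-constrained. Shuffles with zero occurrences have no defined
  ratio and are excluded from this denominator; if the observed sequence
  itself has no occurrence the p-value is `NA`.

A sequence under-represented in the count *and* over-represented in
repTrFrac has attained **maximal** under-representation: every occurrence
that could be removed synonymously has been removed, and what is left is
protected by protein constraint. `aggregate_by_group()` summarises batches
of per-ORF reports per label (e.g. viral host class) as percentages of
under-represented and maximal ORFs.

Numerical notes: the stop codon is stripped before analysis, so a
transition can never create or destroy termination; W-motif occurrences are
counted once per sequence position (an AA occurrence inside WA is not
double-counted); for sequences composed only of single-codon amino acids
every shuffle equals the input and `below_p` is 0 under the strict-less
rule — a degenerate report, not an error. The permutation loop runs on a
precomputed representation (fixed first-two-base masks, non-synonymy lookup
tables, one radix-order pass per permutation) that the test suite verifies
against the plain string-based `count_motif()`/`reptrfrac()` on every
motif.

## Small-RNA evidence

Paired small-RNA reads are joined on their maximal exact 3' overlap
(`merge_pairs()`, minimum 10 nt; pairs without an overlap are dropped and
counted), profiled over 15–50 nt (`size_profile()`), and matched exactly
(both strands) against viral contigs (`match_fragments()`; a 1-mismatch
mode exists but exact matching mirrors the perfect complementarity of RNAi
products). Two diagnostics separate genuine virus-derived small RNAs from
degradation fragments:

* `degradation_test()`: the squared Pearson correlation between per-ORF
  fragment counts and transcript expression. Breakdown products of
  abundant transcripts track expression (r² near 1); RNAi products are
  produced by the pathway, not by abundance (low r²).
* the 20–22 nt fraction of the size profile: Dicer products are tightly
  sized; degradation fragments are not.

No hard threshold is imposed on either number — the package reports them,
and the synthetic anchors below show what the two regimes look like. The
29–30 nt band is reported alongside for piRNA-like signatures.

## What the generators emulate

`sim_config()` collects the simulation knobs; all generators are
bit-reproducible given a seed.

* `gen_cds()` draws internal codons i.i.d. from a codon-usage distribution
  (uniform by default) between a fixed ATG and a stop, `3 * n_codons` nt
  in total.
* `gen_depleted_cds()` models selection against an editable motif. A draw
  from `gen_cds()` is post-processed by motif-removing swaps of
  third-position bases *within the exchangeability groups of the shuffle
  null*; `strength` scales the fraction of improving swaps applied, so
  strength 0 is byte-identical to the null draw and strength 1 sits at a
  local minimum of the motif count reachable under the null. This is a
  deliberate design point: a generator that avoided motifs by changing
  codon composition would look unremarkable to a composition-preserving
  permutation test — depletion visible to the test must live in the
  arrangement, which is exactly what sustained synonymous selection
  produces.
* `gen_edited_pileup()` tiles error-free (or uniformly erroneous),
  single-end, fixed-length reads over a reference and injects A-to-G edits.
  Edited sites are allocated across 5'-neighbour classes by a multinomial
  on `neighbor_prefs` (defaults A 0.31, C 0.12, G 0.15, T 0.42 — an
  A/U-rich editing context used as a simulation parameter, not a claim
  about any particular dataset), and each site's injected frequency
  (uniform on 0.02–0.20 by default, spanning the 1% calling threshold) is
  realised as an exact alternate-read count, so the truth table equals the
  emitted SAM exactly. Sites whose realised count would be zero are not
  edited and not listed. Simulated alignment coordinates are ground truth
  (the simulator writes its own SAM); mapper behaviour, indels, quality
  miscalibration and strand effects are out of scope, so passing tests
  validate the counting and thresholding logic, not robustness to
  alignment artefacts.
* `gen_srna_library()` draws fragments from viral ORFs under three models:
  `degradation` (counts proportional to expression weights, lengths
  uniform on 15–50 nt), `dicer21` and `piwi30` (counts independent of
  expression, integer lengths from a truncated normal centred on 21 or
  30 nt, `srna_size_sd = 1` by default — with sd 1 about 87% of the mass
  falls in 20–22 nt). Real libraries mix regimes and carry ligation
  biases; the generator produces pure regimes so the diagnostics have
  known answers.

## Verification scale and reproducibility

The test suite and `scripts/acceptance.R` recompute the package's
properties from scratch at these problem sizes, chosen to give the
binomial/multinomial tolerances quoted: shuffle invariants over 100 CDSs of
100–1000 codons × 1000 shuffles (zero violations required); null
calibration of `below_p` over 200 null CDSs of 300 codons × 1000 shuffles
(rejection rate at 0.05 expected in 0.02–0.09; note that the literal
strict-less rule is mildly *anti*-conservative on discrete counts — ties at
the observed value shrink `below_p`, so the null rate runs somewhat above
0.05 and reaches 1 in the fully degenerate single-codon case. The
`ties = "midrank"` option removes this bias for users who want calibrated
p-values; the default follows the literal definition); depletion power over 50 replicates of
500-codon, strength-1 TA-depleted sequences (≥ 90% required, 100%
observed); SNP-caller equality against a brute-force per-column counter on
a 10 kb genome at coverage 100 with full recall of threshold-passing truth
sites and zero false positives; neighbour recovery over ~1500 injected
edits within ±3 percentage points; and the small-RNA mode separation
(degradation r² ≥ 0.95, dicer21 r² ≤ 0.5 with 20–22 nt fraction ≥ 0.8 and
mode 21 nt, piwi30 mode 30 nt) over 8000-fragment libraries on six ORFs
spanning a 40-fold expression range.

```{r example, eval = FALSE}
# a miniature end-to-end run on one synthetic contig
contig <- paste0(gen_cds(1800, seed = 1), strrep("A", 30))
orfs <- find_orfs(contig, min_codons = 100)
detect_polya(contig)
cds <- substr(contig, orfs$start[1], orfs$end[1])
tidy(cdur_test(cds, motifs = c("TA", "AA"), n_shuffles = 1000, seed = 1))
```

## Known limitations

The screen consumes external search output and re-implements only the
decision logic; database composition and search sensitivity are inherited
from the caller. The SNP caller assumes base qualities are meaningful and
has no strand-bias or hyper-editing cluster model. The under-representation
test conditions on the observed protein and composition — it cannot see
depletion achieved through amino-acid or GC changes, which is a property of
the method, not a bug of the implementation. The small-RNA diagnostics are
descriptive: with few ORFs or a narrow expression range, r² is noisy, and
the package deliberately leaves the degradation/vsRNA verdict to the
analyst.
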
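#' Simulation configuration
#'
#' Bundles the knobs shared by the synthetic-data generators: codon usage for
#' coding sequences, the editing model (rate, per-site frequency range and
#' 5'-neighbour preferences of the deaminase), read-level parameters
#' (coverage, length, error rate, base quality) and the small-RNA library
#' model. A fixed `seed` makes every generator output reproducible
#' bit-for-bit.
#'
#' @param seed Integer seed fixing all random draws.
#' @param codon_usage Named probability vector over sense codons, or `NULL`
#'   for uniform usage. Stop codons are not allowed (the terminal stop is
#'   drawn separately).
#' @param edit_rate Fraction of adenosine sites that receive an edit.
#' @param neighbor_prefs Named probabilities for the 5' neighbour of edited
#'   sites, over `A`, `C`, `G`, `T`; normalised internally. The defaults
#'   reflect the A/U-rich 5' context preference of ADAR-like editing.
#' @param coverage Mean read depth of the simulated pileup.
#' @param error_rate Per-base sequencing error probability.
#' @param srna_mode Small-RNA library model: `"degradation"` (fragment counts
#'   track transcript abundance, lengths uniform on 15-50 nt), `"dicer21"`
#'   (siRNA-like, lengths centred on 21 nt, counts independent of
#'   expression) or `"piwi30"` (piRNA-like, centred on 30 nt).
#' @param srna_size_sd Standard deviation (nt) of the fragment-length
#'   distribution in the `dicer21`/`piwi30` modes.
#' @param n_fragments Number of small-RNA fragments to generate.
#' @param read_length Simulated read length (nt); reads are single-end.
#' @param edit_freq_range Range the per-site injected editing frequency is
#'   drawn from (uniformly). The default spans low-frequency editing that
#'   still clears a 1% variant-calling threshold.
#' @param base_quality Constant PHRED base quality assigned to simulated
#'   reads.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 42, coverage = 50, edit_rate = 0.02)
sim_config <- function(seed = 1L,
                       codon_usage = NULL,
                       edit_rate = 0.05,
                       neighbor_prefs = c(A = 0.31, C = 0.12, G = 0.15, T = 0.42),
                       coverage = 100,
                       error_rate = 0,
                       srna_mode = c("degradation", "dicer21", "piwi30"),
                       srna_size_sd = 1,
                       n_fragments = 10000L,
                       read_length = 100L,
                       edit_freq_range = c(0.02, 0.20),
                       base_quality = 37L) {
  srna_mode <- match.arg(srna_mode)
  if (!is.null(codon_usage)) codon_usage <- check_codon_usage(codon_usage)
  if (edit_rate < 0 || edit_rate > 1 || error_rate < 0 || error_rate > 1) {
    abort("edit_rate and error_rate must lie in [0, 1]",
      class = "viromics_config_error"
    )
  }
  if (!setequal(names(neighbor_prefs), DNA_BASES)) {
    abort("neighbor_prefs must be named over A, C, G, T",
      class = "viromics_config_error"
    )
  }
  neighbor_prefs <- normalize_probs(neighbor_prefs[DNA_BASES], "neighbor_prefs")
  if (length(edit_freq_range) != 2L || edit_freq_range[1] > edit_freq_range[2] ||
    edit_freq_range[1] < 0 || edit_freq_range[2] > 1) {
    abort("edit_freq_range must be an increasing pair in [0, 1]",
      class = "viromics_config_error"
    )
  }
  structure(
    list(
      seed = as.integer(seed),
      codon_usage = codon_usage,
      edit_rate = edit_rate,
      neighbor_prefs = neighbor_prefs,
      coverage = coverage,
      error_rate = error_rate,
      srna_mode = srna_mode,
      srna_size_sd = srna_size_sd,
      n_fragments = as.integer(n_fragments),
      read_length = as.integer(read_length),
      edit_freq_range = edit_freq_range,
      base_quality = as.integer(base_quality)
    ),
    class = "sim_config"
  )
}

check_codon_usage <- function(codon_usage) {
  if (is.null(names(codon_usage)) || !all(names(codon_usage) %in% SENSE_CODONS)) {
    abort("codon_usage must be named by sense codons (no stop codons)",
      class = "viromics_config_error"
    )
  }
  normalize_probs(codon_usage, "codon_usage")
}

#' Generate a random coding sequence
#'
#' Draws internal codons independently from `codon_usage`, prepends the ATG
#' start and appends a stop codon, for a total of `3 * n_codons` nucleotides
#' (start and stop included in the codon count).
#'
#' @param n_codons Total codon count including start and stop; at least 2.
#' @param codon_usage Named probability vector over sense codons (`NULL` for
#'   uniform).
#' @param seed Integer seed; identical arguments give identical sequences.
#' @return A single DNA string.
#' @export
#' @examples
#' gen_cds(10, seed = 1)
gen_cds <- function(n_codons, codon_usage = NULL, seed = 1L) {
  gen_depleted_cds(n_codons,
    motif = "TA", strength = 0,
    codon_usage = codon_usage, seed = seed
  )
}

#' Generate a coding sequence depleted of a dinucleotide motif
#'
#' Draws a coding sequence exactly as [gen_cds()] does, then removes target
#' motif occurrences by synonymous rearrangement: third-position bases are
#' swapped within the exchangeability groups of
#' [shuffle_third_positions()] (same first two bases, same amino acid)
#' whenever a swap lowers the motif count, covering both codon-internal and
#' codon-junction occurrences while leaving the protein, the length and the
#' base composition untouched. `strength` scales the fraction of improving
#' rearrangements applied: 0 leaves the [gen_cds()] draw unchanged, 1
#' applies all of them, yielding a sequence at (a local minimum of) the
#' fewest motif occurrences reachable under the composition-preserving
#' null — the footprint of selection against the motif.
#'
#' @inheritParams gen_cds
#' @param motif Target dinucleotide, one of `"AA"`, `"CA"`, `"GA"`, `"TA"`,
#'   `"WA"` (`W` = A or T).
#' @param strength Depletion strength in `[0, 1]`.
#' @return A single DNA string of `3 * n_codons` nucleotides.
#' @export
#' @examples
#' gen_depleted_cds(100, motif = "TA", strength = 1, seed = 7)
gen_depleted_cds <- function(n_codons, motif = "TA", strength = 1,
                             codon_usage = NULL, seed = 1L) {
  motif <- check_motif(motif)
  if (n_codons < 2) {
    abort("n_codons must be at least 2 (start + stop)",
      class = "viromics_input_error"
    )
  }
  if (strength < 0 || strength > 1) {
    abort("strength must lie in [0, 1]", class = "viromics_input_error")
  }
  usage <- if (is.null(codon_usage)) {
    setNames(rep(1 / length(SENSE_CODONS), length(SENSE_CODONS)), SENSE_CODONS)
  } else {
    check_codon_usage(codon_usage)
  }
  withr::local_seed(seed)
  codons <- character(n_codons)
  codons[1] <- "ATG"
  n_internal <- n_codons - 2L
  if (n_internal > 0) {
    codons[1L + seq_len(n_internal)] <-
      sample(names(usage), n_internal, replace = TRUE, prob = usage)
  }
  codons[n_codons] <- sample(STOP_CODONS, 1L)
  if (strength > 0 && n_codons > 2L) {
    body <- codons[-n_codons] # stop codon never carries motif statistics
    codons <- c(deplete_arrangement(body, motif, strength), codons[n_codons])
  }
  collapse(codons)
}

# Remove motif occurrences by swapping third-position bases within
# shuffle-exchangeability groups. Improving swaps are collected by
# hill-climbing sweeps until none remains; the first `strength` fraction of
# them is applied to the original arrangement.
deplete_arrangement <- function(codons, motif, strength) {
  c1 <- substr(codons, 1L, 1L)
  c2 <- substr(codons, 2L, 2L)
  t3 <- substr(codons, 3L, 3L)
  m1set <- motif_first_bases(motif)
  c1_next_A <- c(c1[-1L] == "A", FALSE)
  # motif occurrences contributed by base b at third position i
  cost <- function(i, b) {
    (c2[i] %in% m1set & b == "A") + (b %in% m1set & c1_next_A[i])
  }
  groups <- third_position_groups(codons)
  t3_orig <- t3
  swaps <- list()
  repeat {
    swapped <- FALSE
    for (ix in groups) {
      k <- length(ix)
      for (a in seq_len(k - 1L)) {
        for (b in (a + 1L):k) {
          i <- ix[a]
          j <- ix[b]
          if (t3[i] == t3[j]) next
          delta <- cost(i, t3[j]) + cost(j, t3[i]) -
            cost(i, t3[i]) - cost(j, t3[j])
          if (delta < 0) {
            tmp <- t3[i]
            t3[i] <- t3[j]
            t3[j] <- tmp
            swaps[[length(swaps) + 1L]] <- c(i, j)
            swapped <- TRUE
          }
        }
      }
    }
    if (!swapped) break
  }
  n_apply <- ceiling(strength * length(swaps))
  t3 <- t3_orig
  for (s in head(swaps, n_apply)) {
    tmp <- t3[s[1]]
    t3[s[1]] <- t3[s[2]]
    t3[s[2]] <- tmp
  }
  paste0(substr(codons, 1L, 2L), t3)
}

#' Simulate an edited read pileup over a reference
#'
#' Tiles single-end reads over `reference` at the configured mean coverage
#' and injects A-to-G edits: a binomial number of adenosine sites (rate
#' `edit_rate`) is selected so that the distribution of their 5' neighbours
#' follows `neighbor_prefs`, and each selected site receives an injected
#' editing frequency drawn from `edit_freq_range`, realised as an exact read
#' count so truth frequencies match the emitted alignments. Optional uniform
#' sequencing errors are added afterwards.
#'
#' Sites whose realised alternate count would be zero (no covering read
#' altered) are not edited and do not appear in the truth table.
#'
#' @param reference A single DNA string (optionally named; the name becomes
#'   the reference id, default `"ref1"`).
#' @param config A [sim_config()] object.
#' @return An object of class `edited_pileup`: a list with `alignments`
#'   (tibble of SAM-style records), `truth` (tibble of edited sites with
#'   1-based `pos`, `neighbor_5p`, injected and realised `frequency`),
#'   `reference` (named string) and `read_length`. Write it out with
#'   [write_sam()].
#' @export
#' @examples
#' ref <- gen_cds(200, seed = 3)
#' pu <- gen_edited_pileup(ref, sim_config(seed = 9, coverage = 30))
#' nrow(pu$truth)
gen_edited_pileup <- function(reference, config = sim_config()) {
  ref_id <- names(reference) %||% "ref1"
  reference <- unname(reference)
  assert_dna(reference, allow_n = FALSE, arg = "reference")
  L <- nchar(reference)
  if (L == 0) abort("reference must be non-empty", class = "viromics_input_error")
  rl <- min(config$read_length, L)
  ref_chars <- chars(reference)

  withr::local_seed(config$seed)
  n_reads <- max(1L, as.integer(round(config$coverage * L / rl)))
  starts <- sort(sample.int(L - rl + 1L, n_reads, replace = TRUE))
  ends <- starts + rl - 1L

  # pick edited sites so the 5'-neighbour distribution follows neighbor_prefs
  a_pos <- which(ref_chars == "A")
  a_pos <- a_pos[a_pos > 1L] # need a 5' neighbour on the reference
  truth <- empty_truth()
  edited <- integer(0)
  inj <- numeric(0)
  if (length(a_pos) == 0L) {
    warn("reference contains no eligible A sites; truth table is empty")
  } else {
    n_edit <- rbinom(1L, length(a_pos), config$edit_rate)
    if (n_edit > 0) {
      nb <- ref_chars[a_pos - 1L]
      by_class <- split(a_pos, factor(nb, levels = DNA_BASES))
      alloc <- as.vector(stats::rmultinom(1L, n_edit, config$neighbor_prefs))
      names(alloc) <- DNA_BASES
      # cap by availability; surplus is dropped rather than reassigned so the
      # neighbour mix is never distorted
      alloc <- pmin(alloc, lengths(by_class))
      edited <- unlist(lapply(DNA_BASES, function(b) {
        k <- alloc[[b]]
        if (k == 0L) integer(0) else sort(sample(by_class[[b]], k))
      }), use.names = FALSE)
      edited <- sort(edited)
      inj <- runif(length(edited), config$edit_freq_range[1], config$edit_freq_range[2])
    }
  }

  # realise edits as exact alternate-read counts
  seqs <- substring(reference, starts, ends)
  seq_mat <- NULL
  if (length(edited) > 0 || config$error_rate > 0) {
    seq_mat <- strsplit(seqs, "", fixed = TRUE)
  }
  keep <- logical(length(edited))
  realized <- numeric(length(edited))
  covn <- integer(length(edited))
  altn <- integer(length(edited))
  for (j in seq_along(edited)) {
    p <- edited[j]
    covering <- which(starts <= p & ends >= p)
    k <- as.integer(round(inj[j] * length(covering)))
    if (length(covering) == 0L || k == 0L) next
    carriers <- sample(covering, k)
    for (r in carriers) seq_mat[[r]][p - starts[r] + 1L] <- "G"
    keep[j] <- TRUE
    realized[j] <- k / length(covering)
    covn[j] <- length(covering)
    altn[j] <- k
  }
  if (any(keep)) {
    truth <- tibble(
      reference_id = ref_id,
      pos = edited[keep],
      ref_base = "A",
      alt_base = "G",
      neighbor_5p = ref_chars[edited[keep] - 1L],
      injected_freq = inj[keep],
      frequency = realized[keep],
      coverage = covn[keep],
      alt_count = altn[keep]
    )
  }

  if (config$error_rate > 0) {
    for (r in seq_along(seq_mat)) {
      hit <- which(runif(rl) < config$error_rate)
      for (i in hit) {
        seq_mat[[r]][i] <- sample(setdiff(DNA_BASES, seq_mat[[r]][i]), 1L)
      }
    }
  }
  if (!is.null(seq_mat)) {
    seqs <- vapply(seq_mat, collapse, character(1))
  }

  nm <- mapply(function(s, a, b) {
    sum(chars(s) != ref_chars[a:b])
  }, seqs, starts, ends, USE.NAMES = FALSE)

  alignments <- tibble(
    qname = sprintf("read%06d", seq_along(starts)),
    flag = 0L,
    rname = ref_id,
    pos = starts,
    mapq = 60L,
    cigar = sprintf("%dM", rl),
    seq = seqs,
    qual = strrep(int_to_phred(config$base_quality), rl),
    nm = as.integer(nm)
  )
  structure(
    list(
      alignments = alignments,
      truth = truth,
      reference = setNames(reference, ref_id),
      read_length = rl
    ),
    class = "edited_pileup"
  )
}

empty_truth <- function() {
  tibble(
    reference_id = character(), pos = integer(), ref_base = character(),
    alt_base = character(), neighbor_5p = character(),
    injected_freq = numeric(), frequency = numeric(),
    coverage = integer(), alt_count = integer()
  )
}

#' Write simulated alignments as a SAM file
#'
#' Emits a valid header (`@HD`, `@SQ`) followed by one line per alignment
#' with an `NM` tag, suitable for [read_alignments()] or any SAM-aware tool.
#'
#' @param x An `edited_pileup` object or an alignments tibble with columns
#'   `qname, flag, rname, pos, mapq, cigar, seq, qual, nm`.
#' @param path Output file path.
#' @param reference Named reference string(s) for the `@SQ` lines; taken from
#'   `x` when it is an `edited_pileup`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, path, reference = NULL) {
  if (inherits(x, "edited_pileup")) {
    reference <- reference %||% x$reference
    x <- x$alignments
  }
  if (is.null(reference) || is.null(names(reference))) {
    abort("`reference` must be a named character vector", class = "viromics_input_error")
  }
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference))
  )
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNM:i:%d",
    x$qname, x$flag, x$rname, x$pos, x$mapq, x$cigar, x$seq, x$qual, x$nm
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a small-RNA fragment library
#'
#' Draws `n_fragments` fragments from a set of viral ORFs under one of three
#' models: `degradation` assigns fragments to ORFs proportionally to their
#' expression weight with lengths uniform on 15-50 nt (breakdown products);
#' `dicer21` and `piwi30` assign fragments uniformly across ORFs (independent
#' of expression) with lengths from a truncated normal centred on 21 or
#' 30 nt — the siRNA- and piRNA-like signatures.
#'
#' @param viral_orfs A data frame with columns `orf_id`, `seq` and `weight`
#'   (relative expression; non-negative, at least one positive).
#' @param config A [sim_config()] object (`srna_mode`, `srna_size_sd`,
#'   `n_fragments`, `seed`).
#' @return A tibble with one row per fragment: `fragment_id`, `orf_id`,
#'   `start`, `length`, `strand`, `seq`.
#' @export
#' @examples
#' orfs <- tibble::tibble(
#'   orf_id = c("o1", "o2"),
#'   seq = c(gen_cds(80, seed = 1), gen_cds(80, seed = 2)),
#'   weight = c(1, 4)
#' )
#' lib <- gen_srna_library(orfs, sim_config(seed = 5, n_fragments = 100))
#' dplyr::count(lib, orf_id)
gen_srna_library <- function(viral_orfs, config = sim_config()) {
  stopifnot(all(c("orf_id", "seq", "weight") %in% names(viral_orfs)))
  w <- viral_orfs$weight
  if (any(w < 0) || all(w == 0)) {
    abort("expression weights must be non-negative with at least one positive",
      class = "viromics_config_error"
    )
  }
  n <- config$n_fragments
  if (n == 0L) {
    return(tibble(
      fragment_id = character(), orf_id = character(), start = integer(),
      length = integer(), strand = character(), seq = character()
    ))
  }
  withr::local_seed(config$seed)
  origin <- switch(config$srna_mode,
    degradation = sample.int(nrow(viral_orfs), n, replace = TRUE, prob = w),
    sample.int(nrow(viral_orfs), n, replace = TRUE)
  )
  len <- switch(config$srna_mode,
    degradation = sample(15:50, n, replace = TRUE),
    dicer21 = rnorm_trunc_int(n, 21, config$srna_size_sd, 15L, 50L),
    piwi30 = rnorm_trunc_int(n, 30, config$srna_size_sd, 15L, 50L)
  )
  strand <- switch(config$srna_mode,
    degradation = rep("+", n),
    sample(c("+", "-"), n, replace = TRUE)
  )
  orf_len <- nchar(viral_orfs$seq)[origin]
  len <- pmin(len, orf_len)
  start <- 1L + as.integer(floor(runif(n) * (orf_len - len + 1L)))
  frag <- substring(viral_orfs$seq[origin], start, start + len - 1L)
  minus <- strand == "-"
  if (any(minus)) {
    frag[minus] <- vapply(frag[minus], revcomp, character(1), USE.NAMES = FALSE)
  }
  tibble(
    fragment_id = sprintf("frag%06d", seq_len(n)),
    orf_id = viral_orfs$orf_id[origin],
    start = start,
    length = len,
    strand = strand,
    seq = frag
  )
}

# integer truncated-normal lengths via inverse-CDF sampling
rnorm_trunc_int <- function(n, mean, sd, lo, hi) {
  u <- runif(
    n, stats::pnorm(lo - 0.5, mean, sd),
    stats::pnorm(hi + 0.5, mean, sd)
  )
  pmin(pmax(as.integer(round(stats::qnorm(u, mean, sd))), lo), hi)
}

#' Write sequences as a FASTA file
#'
#' @param seqs Named character vector of sequences, or a data frame with id
#'   and sequence columns (first two columns used).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    stopifnot("seq" %in% names(seqs))
    seqs <- setNames(seqs$seq, seqs[[1]])
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
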
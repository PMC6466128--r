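# Low-frequency variant detection on viral genomes and extraction of the
# ADAR-compatible (A-to-G) editing footprint with 5'-neighbour annotation.

# expand one alignment into (ref_pos, read_pos) runs over aligned bases
walk_cigar <- function(cigar, pos) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  lens <- as.integer(m[, 2])
  ops <- m[, 3]
  ref_pos <- integer(0)
  read_pos <- integer(0)
  rp <- pos
  qp <- 1L
  for (k in seq_along(ops)) {
    op <- ops[k]
    len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, rp:(rp + len - 1L))
      read_pos <- c(read_pos, qp:(qp + len - 1L))
      rp <- rp + len
      qp <- qp + len
    } else if (op %in% c("D", "N")) {
      rp <- rp + len
    } else if (op %in% c("I", "S")) {
      qp <- qp + len
    }
  }
  list(ref_pos = ref_pos, read_pos = read_pos)
}

#' Call low-frequency SNPs from a read pileup
#'
#' Builds a per-position pileup over the reference and emits one call per
#' (position, alternate base) satisfying all of: local coverage at least
#' `min_cov`, alternate count at least `min_count`, alternate frequency at
#' least `min_freq` (denominator: reads locally aligned across the site,
#' deletions excluded), and mean base quality over the 5-base read window
#' centred on the site (site +/- 2, clipped at read ends), averaged over the
#' supporting reads, at least `min_context_q`.
#'
#' @param alignments Alignment tibble, SAM path or `edited_pileup`; only
#'   primary alignments are used.
#' @param reference Named single DNA string the reads were aligned to.
#' @param min_freq Minimal alternate-allele frequency (per alternate base).
#' @param min_cov Minimal coverage.
#' @param min_count Minimal alternate read count.
#' @param min_context_q Minimal mean PHRED quality of the 5-base context.
#' @param orfs Optional ORF table ([find_orfs()]) used to flag calls inside
#'   coding regions (`in_cds`); `NA` when not supplied.
#' @param strict When `TRUE`, reads without base qualities (`*`) are an
#'   error; by default they pass the quality filter with a warning.
#' @return A tibble of site calls: `reference_id`, `pos` (1-based),
#'   `ref_base`, `alt_base`, `coverage`, `alt_count`, `frequency`,
#'   `mean_context_quality`, `neighbor_5p`, `adar_compatible`, `in_cds`.
#' @export
#' @examples
#' ref <- gen_cds(300, seed = 11)
#' pu <- gen_edited_pileup(ref, sim_config(seed = 2, coverage = 60))
#' calls <- call_snps(pu, pu$reference)
call_snps <- function(alignments, reference, min_freq = 0.01, min_cov = 50L,
                      min_count = 5L, min_context_q = 30, orfs = NULL,
                      strict = FALSE) {
  if (inherits(alignments, "edited_pileup") && missing(reference)) {
    reference <- alignments$reference
  }
  aln <- as_alignments(alignments)
  ref_id <- names(reference) %||%
    (if (nrow(aln)) unique(aln$rname)[1] else "ref1")
  reference <- unname(reference)
  assert_dna(reference, allow_n = TRUE, arg = "reference")
  L <- nchar(reference)
  ref_chars <- chars(reference)

  aln <- aln |>
    filter(
      .data$rname == ref_id,
      bitwAnd(.data$flag, 0x4L) == 0L,
      bitwAnd(.data$flag, 0x100L) == 0L,
      bitwAnd(.data$flag, 0x800L) == 0L
    )
  if (nrow(aln) == 0L) {
    return(empty_calls())
  }
  no_qual <- aln$qual == "*" | is.na(aln$qual)
  if (any(no_qual)) {
    if (strict) {
      abort("reads without base qualities in strict mode",
        class = "viromics_input_error"
      )
    }
    warn(sprintf(
      "%d read(s) without base qualities treated as passing the quality filter",
      sum(no_qual)
    ))
  }

  # flatten aligned bases into parallel vectors; per-read blocks are
  # contiguous so context windows can be looked up inside a block
  walks <- purrr::map2(aln$cigar, aln$pos, walk_cigar)
  block_len <- lengths(lapply(walks, `[[`, "ref_pos"))
  block_end <- cumsum(block_len)
  block_start <- block_end - block_len + 1L
  ref_pos <- unlist(lapply(walks, `[[`, "ref_pos"), use.names = FALSE)
  read_pos <- unlist(lapply(walks, `[[`, "read_pos"), use.names = FALSE)
  if (length(ref_pos) && max(ref_pos) > L) {
    abort("alignments extend beyond the reference; wrong reference?",
      class = "viromics_input_error"
    )
  }
  read_of <- rep.int(seq_len(nrow(aln)), block_len)
  seq_chars <- strsplit(aln$seq, "", fixed = TRUE)
  base <- unlist(purrr::map2(seq_chars, lapply(walks, `[[`, "read_pos"), `[`),
    use.names = FALSE
  )
  qual_int <- unlist(purrr::map2(
    strsplit(aln$qual, "", fixed = TRUE),
    lapply(walks, `[[`, "read_pos"),
    function(q, i) {
      if (length(q) == 1L && q[1] == "*") rep(Inf, length(i)) else phred_to_int(collapse(q))[i]
    }
  ), use.names = FALSE)

  coverage <- tabulate(ref_pos, nbins = L)
  is_alt <- base != ref_chars[ref_pos] & base %in% DNA_BASES
  alt_key <- paste0(ref_pos[is_alt], "_", base[is_alt])
  if (!length(alt_key)) {
    return(empty_calls())
  }
  alt_tab <- table(alt_key)
  cand <- tibble(
    key = names(alt_tab),
    alt_count = as.integer(alt_tab)
  ) |>
    tidyr::separate_wider_delim("key", "_", names = c("pos", "alt_base")) |>
    mutate(
      pos = as.integer(.data$pos),
      coverage = coverage[.data$pos],
      frequency = .data$alt_count / .data$coverage
    ) |>
    filter(
      .data$coverage >= min_cov,
      .data$alt_count >= min_count,
      .data$frequency >= min_freq
    )
  if (nrow(cand) == 0L) {
    return(empty_calls())
  }

  alt_idx_all <- which(is_alt)
  cand$mean_context_quality <- vapply(seq_len(nrow(cand)), function(i) {
    p <- cand$pos[i]
    b <- cand$alt_base[i]
    sup <- alt_idx_all[ref_pos[alt_idx_all] == p & base[alt_idx_all] == b]
    mean(vapply(sup, function(j) {
      r <- read_of[j]
      blk <- block_start[r]:block_end[r]
      win <- blk[ref_pos[blk] >= p - 2L & ref_pos[blk] <= p + 2L]
      mean(qual_int[win])
    }, numeric(1)))
  }, numeric(1))
  cand <- filter(cand, .data$mean_context_quality >= min_context_q)
  if (nrow(cand) == 0L) {
    return(empty_calls())
  }

  calls <- cand |>
    mutate(
      reference_id = ref_id,
      ref_base = ref_chars[.data$pos],
      adar_compatible = .data$ref_base == "A" & .data$alt_base == "G",
      .before = 1
    ) |>
    select(
      "reference_id", "pos", "ref_base", "alt_base", "coverage",
      "alt_count", "frequency", "mean_context_quality", "adar_compatible"
    ) |>
    arrange(.data$pos, .data$alt_base) |>
    annotate_neighbor(setNames(reference, ref_id))
  calls$in_cds <- if (is.null(orfs)) {
    NA
  } else {
    in_any_orf(calls$pos, orfs[orfs$contig_id == ref_id, , drop = FALSE])
  }
  calls
}

empty_calls <- function() {
  tibble(
    reference_id = character(), pos = integer(), ref_base = character(),
    alt_base = character(), coverage = integer(), alt_count = integer(),
    frequency = numeric(), mean_context_quality = numeric(),
    adar_compatible = logical(), neighbor_5p = character(), in_cds = logical()
  )
}

in_any_orf <- function(pos, orfs) {
  if (nrow(orfs) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  vapply(pos, function(p) any(orfs$start <= p & orfs$end >= p), logical(1))
}

#' Annotate calls with the 5' neighbouring reference base
#'
#' ADAR editing prefers an A or U 5' of the edited adenosine, so the
#' reference base immediately upstream of each call is the key context
#' feature. Positions at the reference start are annotated `"edge"`.
#'
#' @param calls A site-call tibble with `pos` (1-based).
#' @param reference The reference sequence the positions refer to.
#' @return `calls` with a `neighbor_5p` column.
#' @export
annotate_neighbor <- function(calls, reference) {
  reference <- unname(reference)
  ref_chars <- chars(reference)
  if (nrow(calls) && max(calls$pos) > nchar(reference)) {
    abort("call position beyond reference end", class = "viromics_input_error")
  }
  mutate(calls, neighbor_5p = ifelse(.data$pos == 1L, "edge",
    ref_chars[pmax(.data$pos - 1L, 1L)]
  ))
}

#' Select ADAR-compatible calls
#'
#' Keeps A-to-G substitutions on the reported genome strand — the signature
#' of adenosine-to-inosine editing — optionally also T-to-C as antisense
#' evidence. When the calls carry a defined `in_cds` flag the selection is
#' restricted to coding regions by default.
#'
#' @param calls A site-call tibble ([call_snps()] output).
#' @param include_tc Also keep T-to-C calls (antisense evidence).
#' @param cds_only Restrict to calls with `in_cds = TRUE` when the flag is
#'   available.
#' @return The filtered tibble.
#' @export
select_adar <- function(calls, include_tc = FALSE, cds_only = TRUE) {
  keep <- calls$ref_base == "A" & calls$alt_base == "G"
  if (include_tc) {
    keep <- keep | (calls$ref_base == "T" & calls$alt_base == "C")
  }
  out <- calls[keep, , drop = FALSE]
  if (cds_only && "in_cds" %in% names(out) && !all(is.na(out$in_cds))) {
    out <- filter(out, .data$in_cds)
  }
  out
}

#' Distribution of 5' neighbour bases over calls
#'
#' @param calls A site-call tibble with a `neighbor_5p` column; `"edge"`
#'   entries are excluded from the denominator.
#' @return A tibble with one row per base `A`, `C`, `G`, `T`: `n` and
#'   `fraction` (summing to 1).
#' @export
neighbor_distribution <- function(calls) {
  nb <- calls$neighbor_5p[calls$neighbor_5p %in% DNA_BASES]
  if (length(nb) == 0L) {
    abort("no calls with a defined 5' neighbour", class = "viromics_input_error")
  }
  counts <- table(factor(nb, levels = DNA_BASES))
  tibble(
    neighbor_5p = DNA_BASES,
    n = as.integer(counts),
    fraction = as.numeric(counts) / length(nb)
  )
}
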
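#' Find open reading frames in a contig
#'
#' Six-frame scan returning every maximal ORF of at least `min_codons`
#' codons. Within each reading frame, an ORF runs from the first ATG after
#' the previous in-frame stop through the next stop codon (stop included in
#' the codon count); such ORFs are `complete`. An ATG-initiated reading
#' range that runs off the contig edge without reaching a stop is reported
#' with `complete = FALSE` and never satisfies completeness-based
#' classification.
#'
#' @param contig A single DNA string (characters `ACGTN`), or a named
#'   character vector of contigs to scan in one call.
#' @param min_codons Minimal ORF length in codons (ATG through stop).
#' @param contig_id Identifier used when `contig` is a single unnamed
#'   string.
#' @return A tibble with one row per ORF: `contig_id`, `orf_id`, `start`,
#'   `end` (1-based inclusive, on the forward strand), `strand`, `frame`,
#'   `n_codons`, `complete`, `protein` (stop not translated).
#' @export
#' @examples
#' contig <- gen_cds(120, seed = 4)
#' find_orfs(contig, min_codons = 100)
find_orfs <- function(contig, min_codons = 100L, contig_id = "contig1") {
  if (length(contig) > 1L || !is.null(names(contig))) {
    ids <- names(contig) %||% paste0("contig", seq_along(contig))
    return(purrr::map2_dfr(
      unname(contig), ids,
      ~ find_orfs(.x, min_codons = min_codons, contig_id = .y)
    ))
  }
  assert_dna(contig, allow_n = TRUE, arg = "contig")
  L <- nchar(contig)
  if (L < 3L) {
    abort("contig must be at least 3 nt", class = "viromics_input_error")
  }
  res <- bind_rows(
    scan_frames(contig, "+", L),
    scan_frames(revcomp(contig), "-", L)
  )
  res <- res[res$n_codons >= min_codons, , drop = FALSE]
  if (nrow(res) == 0L) {
    return(tibble(
      contig_id = character(), orf_id = character(), start = integer(),
      end = integer(), strand = character(), frame = integer(),
      n_codons = integer(), complete = logical(), protein = character()
    ))
  }
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  tibble(
    contig_id = contig_id,
    orf_id = sprintf("%s_orf%d", contig_id, seq_len(nrow(res))),
    res
  )
}

# ORFs on one strand of the (possibly reverse-complemented) sequence;
# coordinates are mapped back to the forward strand.
scan_frames <- function(s, strand, L) {
  out <- list()
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < 1L) next
    starts <- f + seq(1L, by = 3L, length.out = n_cod)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    seg_start <- 1L
    bounds <- c(which(is_stop), if (!length(is_stop) || !is_stop[n_cod]) NA_integer_)
    for (b in bounds) {
      seg_end <- if (is.na(b)) n_cod else b
      rng <- seg_start:seg_end
      atg <- rng[is_atg[rng]][1]
      has_stop <- !is.na(b)
      if (!is.na(atg)) {
        last <- seg_end
        n_codons <- last - atg + 1L
        p1 <- f + 3L * (atg - 1L) + 1L
        p2 <- f + 3L * last
        prot_idx <- if (has_stop) atg:(last - 1L) else atg:last
        prot <- if (has_stop && length(prot_idx) == 0L) {
          ""
        } else {
          aa <- GENCODE[codons[prot_idx]]
          aa[is.na(aa)] <- "X"
          collapse(aa)
        }
        out[[length(out) + 1L]] <- tibble(
          start = if (strand == "+") p1 else L - p2 + 1L,
          end = if (strand == "+") p2 else L - p1 + 1L,
          strand = strand,
          frame = f,
          n_codons = n_codons,
          complete = has_stop,
          protein = prot
        )
      }
      seg_start <- seg_end + 1L
      if (seg_start > n_cod) break
    }
  }
  bind_rows(out)
}

#' Detect a 3' polyA tail
#'
#' Reports `TRUE` when some terminal window of at least `min_run`
#' nucleotides is composed of adenosines up to a tolerated fraction of
#' other bases.
#'
#' @param contig A single DNA string.
#' @param min_run Minimal window length (nt).
#' @param max_nonA_frac Maximal tolerated fraction of non-A bases in the
#'   window.
#' @return Logical scalar.
#' @export
#' @examples
#' detect_polya(paste0(gen_cds(50, seed = 1), strrep("A", 25)))
detect_polya <- function(contig, min_run = 15L, max_nonA_frac = 0.1) {
  assert_dna(contig, allow_n = TRUE, arg = "contig")
  L <- nchar(contig)
  if (L < min_run) {
    return(FALSE)
  }
  tail_chars <- rev(chars(contig))
  non_a <- cumsum(tail_chars != "A")
  k <- seq_len(L)
  any(k >= min_run & non_a / k <= max_nonA_frac)
}
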
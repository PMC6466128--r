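# Independent brute-force oracles and small random-input helpers. These are
# deliberately written with different algorithms from the package internals
# so that agreement is informative.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

GC <- Biostrings::GENETIC_CODE
STOPS <- c("TAA", "TAG", "TGA")

# All maximal ATG..stop spans (plus ATG-initiated edge ranges) in six frames,
# enumerated from the full list of ATG..stop pairs rather than by segment
# walking: for every ATG take the nearest downstream in-frame stop, then
# keep only the longest span per stop.
oracle_orfs <- function(contig, min_codons) {
  scan_one <- function(s, strand, L) {
    rows <- list()
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3
      if (n_cod < 1) next
      starts <- f + seq(1, by = 3, length.out = n_cod)
      codons <- substring(s, starts, starts + 2)
      atg_idx <- which(codons == "ATG")
      stop_idx <- which(codons %in% STOPS)
      spans <- lapply(atg_idx, function(a) {
        later <- stop_idx[stop_idx > a]
        if (length(later)) c(a, min(later), 1L) else c(a, n_cod, 0L)
      })
      if (!length(spans)) next
      spans <- do.call(rbind, spans)
      # maximality: keep the earliest ATG per terminating codon index
      keep <- !duplicated(spans[, 2])
      spans <- spans[keep, , drop = FALSE]
      for (r in seq_len(nrow(spans))) {
        a <- spans[r, 1]
        e <- spans[r, 2]
        n_codons <- e - a + 1
        if (n_codons < min_codons) next
        p1 <- f + 3 * (a - 1) + 1
        p2 <- f + 3 * e
        rows[[length(rows) + 1]] <- data.frame(
          start = if (strand == "+") p1 else L - p2 + 1,
          end = if (strand == "+") p2 else L - p1 + 1,
          strand = strand, n_codons = n_codons,
          complete = spans[r, 3] == 1L
        )
      }
    }
    do.call(rbind, c(rows, list(data.frame(
      start = integer(), end = integer(), strand = character(),
      n_codons = integer(), complete = logical()
    ))))
  }
  L <- nchar(contig)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(contig)))
  out <- rbind(scan_one(contig, "+", L), scan_one(rc, "-", L))
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# overlap-aware motif counting through a lookahead regex
oracle_count_motif <- function(seq, motif) {
  pat <- if (motif == "WA") "(?=[AT]A)" else paste0("(?=", motif, ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  sum(m > 0)
}

# per-column pileup counter looping positions, with per-read substr access
oracle_snp_calls <- function(alignments, reference, min_freq, min_cov,
                             min_count, min_context_q) {
  L <- nchar(reference)
  ref_chars <- strsplit(reference, "")[[1]]
  starts <- alignments$pos
  rl <- nchar(alignments$seq)
  ends <- starts + rl - 1 # M-only cigars in simulated data
  quals <- lapply(alignments$qual, function(q) as.integer(charToRaw(q)) - 33L)
  out <- list()
  for (p in seq_len(L)) {
    covering <- which(starts <= p & ends >= p)
    cov <- length(covering)
    if (cov < min_cov) next
    bases <- substr(alignments$seq[covering], p - starts[covering] + 1,
      p - starts[covering] + 1
    )
    for (alt in setdiff(c("A", "C", "G", "T"), ref_chars[p])) {
      sup <- covering[bases == alt]
      k <- length(sup)
      if (k < min_count || k / cov < min_freq) next
      ctxq <- mean(vapply(sup, function(r) {
        w <- (p - 2):(p + 2)
        w <- w[w >= starts[r] & w <= ends[r]]
        mean(quals[[r]][w - starts[r] + 1])
      }, numeric(1)))
      if (ctxq < min_context_q) next
      out[[length(out) + 1]] <- data.frame(
        pos = p, ref_base = ref_chars[p], alt_base = alt,
        coverage = cov, alt_count = k
      )
    }
  }
  do.call(rbind, c(out, list(data.frame(
    pos = integer(), ref_base = character(), alt_base = character(),
    coverage = integer(), alt_count = integer()
  ))))
}

# greedy clustering re-derived from a full all-pairs identity matrix
oracle_greedy_clusters <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), seqs)
  seqs <- seqs[ord]
  n <- length(seqs)
  idm <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) idm[i, j] <- pairwise_identity(seqs[[i]], seqs[[j]])
    }
  }
  reps <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- which(idm[i, reps] >= threshold)
    if (length(hit)) {
      assign[i] <- hit[1]
    } else {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  assign
}

site_key <- function(d) paste(d$pos, d$alt_base)
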
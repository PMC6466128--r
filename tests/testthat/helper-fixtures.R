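# hand-built pileups: reads tiling a short reference with chosen alt bases
build_reads <- function(ref, n_reads, alt_pos = NULL, alt_base = "G",
                        n_alt = 0L, qual_char = "D") { # "D" = PHRED 35
  L <- nchar(ref)
  seqs <- rep(ref, n_reads)
  if (n_alt > 0) {
    for (i in seq_len(n_alt)) {
      substr(seqs[i], alt_pos, alt_pos) <- alt_base
    }
  }
  tibble::tibble(
    qname = paste0("r", seq_len(n_reads)), flag = 0L, rname = "ref1",
    pos = 1L, mapq = 60L, cigar = paste0(L, "M"), seq = seqs,
    qual = strrep(qual_char, L),
    nm = as.integer(seq_len(n_reads) <= n_alt)
  )
}
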
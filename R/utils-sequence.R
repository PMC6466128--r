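# Sequence helpers shared across modules. Sequences are plain upper-case
# character scalars at the interface; Biostrings objects are used where an
# operation (translation, alignment, pattern matching) calls for them.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# standard genetic code, keyed by DNA codon
GENCODE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

SENSE_CODONS <- setdiff(names(GENCODE), STOP_CODONS)

chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

collapse <- function(x) paste(x, collapse = "")

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

translate_codons <- function(codons) unname(GENCODE[codons])

#' Split a sequence into codons
#' @noRd
codon_split <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    abort("sequence length must be divisible by 3", class = "viromics_input_error")
  }
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

assert_dna <- function(seq, allow_n = TRUE, arg = "seq") {
  ok_chars <- if (allow_n) "ACGTN" else "ACGT"
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("`%s` must be a single string", arg), class = "viromics_input_error")
  }
  if (grepl(sprintf("[^%s]", ok_chars), seq)) {
    abort(
      sprintf("`%s` contains characters outside [%s]", arg, ok_chars),
      class = "viromics_input_error"
    )
  }
  invisible(seq)
}

# normalize a probability vector, complaining if it cannot be normalized
normalize_probs <- function(p, what = "probabilities") {
  if (any(!is.finite(p)) || any(p < 0) || sum(p) <= 0) {
    abort(
      sprintf("%s must be non-negative, finite and not all zero", what),
      class = "viromics_config_error"
    )
  }
  p / sum(p)
}

phred_to_int <- function(qual) as.integer(charToRaw(qual)) - 33L

int_to_phred <- function(q) rawToChar(as.raw(q + 33L))
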
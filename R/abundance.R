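#' Read alignments from a SAM/BAM file
#'
#' Parses a SAM (or BAM) file into the flat alignment tibble used by
#' [count_mapped()] and [call_snps()]. SAM input is converted through
#' `Rsamtools`, so the file must carry a valid header.
#'
#' @param path Path to a SAM or BAM file.
#' @return A tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual` and `nm` (NA when the NM tag is absent).
#' @export
read_alignments <- function(path) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "NM"
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  tibble(
    qname = res$qname,
    flag = res$flag,
    rname = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    nm = res$tag$NM %||% rep(NA_integer_, length(res$qname))
  )
}

as_alignments <- function(alignments) {
  if (is.character(alignments) && length(alignments) == 1L) {
    return(read_alignments(alignments))
  }
  if (inherits(alignments, "edited_pileup")) {
    return(alignments$alignments)
  }
  as_tibble(alignments)
}

cigar_aligned_length <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  vapply(ops, function(m) {
    sum(as.integer(m[m[, 3] %in% c("M", "=", "X"), 2]))
  }, integer(1))
}

#' Count stringently mapped reads per reference
#'
#' A read is counted for its reference when its primary alignment covers at
#' least `min_len_frac` of the read length and matches the reference over at
#' least `min_sim_frac` of the aligned length (similarity taken as
#' `(aligned_length - NM) / aligned_length`). Each read counts at most once;
#' secondary and supplementary alignments are ignored. Reads without an NM
#' tag are skipped with a warning.
#'
#' @param alignments Alignment tibble ([read_alignments()] output), a SAM
#'   file path, or an `edited_pileup`.
#' @param min_len_frac Minimal aligned fraction of the read length.
#' @param min_sim_frac Minimal identity fraction over the aligned length.
#' @return A tibble with `reference_id` and `mapped_reads`.
#' @export
count_mapped <- function(alignments, min_len_frac = 0.9, min_sim_frac = 0.9) {
  aln <- as_alignments(alignments)
  primary <- aln |>
    filter(
      bitwAnd(.data$flag, 0x4L) == 0L,
      bitwAnd(.data$flag, 0x100L) == 0L,
      bitwAnd(.data$flag, 0x800L) == 0L
    ) |>
    distinct(.data$qname, .keep_all = TRUE)
  no_nm <- is.na(primary$nm)
  if (any(no_nm)) {
    warn(sprintf("%d read(s) without an NM tag skipped", sum(no_nm)))
    primary <- primary[!no_nm, , drop = FALSE]
  }
  if (nrow(primary) == 0L) {
    return(tibble(reference_id = character(), mapped_reads = integer()))
  }
  alen <- cigar_aligned_length(primary$cigar)
  rlen <- nchar(primary$seq)
  ok <- alen / rlen >= min_len_frac & (alen - primary$nm) / alen >= min_sim_frac
  primary[ok, , drop = FALSE] |>
    count(reference_id = .data$rname, name = "mapped_reads") |>
    arrange(.data$reference_id)
}

#' Viral read fraction in per-mille
#'
#' @param mapped Number of reads mapped to the virus.
#' @param total Total reads in the sample; must be positive and at least
#'   `mapped`.
#' @return `mapped / total * 1000` (vectorised).
#' @export
#' @examples
#' viral_fraction(3000, 1e6)
viral_fraction <- function(mapped, total) {
  if (any(total <= 0)) {
    abort("total read count must be positive", class = "viromics_input_error")
  }
  if (any(mapped > total)) {
    abort("mapped reads cannot exceed total reads", class = "viromics_input_error")
  }
  mapped / total * 1000
}

#' Build per-sample, per-reference abundance records
#'
#' @param counts A data frame with `sample_id`, `reference_id` and
#'   `mapped_reads`.
#' @param totals Named numeric vector of total read counts per sample.
#' @return The input with `total_reads` and `fraction_permille` columns.
#' @export
abundance_records <- function(counts, totals) {
  stopifnot(all(c("sample_id", "reference_id", "mapped_reads") %in% names(counts)))
  missing <- setdiff(unique(counts$sample_id), names(totals))
  if (length(missing)) {
    abort(sprintf(
      "no total read count for sample(s): %s",
      paste(head(missing, 5), collapse = ", ")
    ), class = "viromics_input_error")
  }
  counts |>
    mutate(
      total_reads = unname(totals[.data$sample_id]),
      fraction_permille = viral_fraction(.data$mapped_reads, .data$total_reads)
    )
}

#' Select samples informative for viral analysis
#'
#' Keeps samples whose summed viral read count reaches `min_viral_reads`
#' (at-least convention).
#'
#' @param records Abundance records with `sample_id` and `mapped_reads`.
#' @param min_viral_reads Threshold on the per-sample sum.
#' @return A tibble with `sample_id` and `viral_reads` for kept samples.
#' @export
select_informative <- function(records, min_viral_reads = 1000L) {
  if (nrow(records) == 0L) {
    return(tibble(sample_id = character(), viral_reads = integer()))
  }
  records |>
    group_by(.data$sample_id) |>
    summarise(viral_reads = sum(.data$mapped_reads), .groups = "drop") |>
    filter(.data$viral_reads >= min_viral_reads)
}

#' Transcripts per million
#'
#' Length-normalised expression: per-feature count rates (`count / length`)
#' rescaled to sum to one million. An all-zero count vector yields all-zero
#' TPM.
#'
#' @param counts Named numeric vector of read counts, or a data frame with
#'   `feature`, `count` and `length` columns.
#' @param lengths Named numeric vector of feature lengths (nt); required
#'   when `counts` is a vector. Every counted feature must have a positive
#'   length.
#' @return A tibble with `feature`, `count`, `length` and `tpm`.
#' @export
#' @examples
#' tpm(c(g1 = 10, g2 = 10), c(g1 = 100, g2 = 200))
tpm <- function(counts, lengths = NULL) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("feature", "count", "length") %in% names(counts)))
    df <- as_tibble(counts)
  } else {
    if (is.null(names(counts)) || is.null(names(lengths))) {
      abort("counts and lengths must be named", class = "viromics_input_error")
    }
    missing <- setdiff(names(counts), names(lengths))
    if (length(missing)) {
      abort(sprintf(
        "no length for feature(s): %s",
        paste(head(missing, 5), collapse = ", ")
      ), class = "viromics_input_error")
    }
    df <- tibble(
      feature = names(counts),
      count = unname(counts),
      length = unname(lengths[names(counts)])
    )
  }
  if (any(df$length <= 0)) {
    abort("feature lengths must be positive", class = "viromics_input_error")
  }
  rate <- df$count / df$length
  df$tpm <- if (sum(rate) == 0) rep(0, nrow(df)) else rate / sum(rate) * 1e6
  df
}

#' COI contamination profile
#'
#' Expresses per-entry mapped-read counts of a COI barcode screen as
#' percentages of all COI-mapped reads and reports the entries above a
#' minimal percentage, largest first. Used to profile which organisms
#' contributed reads to a sample.
#'
#' @param coi_counts Named numeric vector of mapped-read counts per COI
#'   entry, or a data frame with `coi_id` and `mapped_reads`.
#' @param report_min_percent Report threshold in percent.
#' @return A tibble with `coi_id`, `mapped_reads` and
#'   `percent_of_coi_mapped`, sorted descending; empty (with a warning)
#'   when no reads mapped.
#' @export
#' @examples
#' coi_profile(c(oyster = 950, clam = 50))
coi_profile <- function(coi_counts, report_min_percent = 0.01) {
  df <- if (is.data.frame(coi_counts)) {
    tibble(
      coi_id = coi_counts$coi_id,
      mapped_reads = coi_counts$mapped_reads
    )
  } else {
    tibble(coi_id = names(coi_counts), mapped_reads = unname(coi_counts))
  }
  total <- sum(df$mapped_reads)
  if (total == 0) {
    warn("no COI-mapped reads; profile is empty")
    return(tibble(
      coi_id = character(), mapped_reads = numeric(),
      percent_of_coi_mapped = numeric()
    ))
  }
  df |>
    mutate(percent_of_coi_mapped = .data$mapped_reads / total * 100) |>
    filter(.data$percent_of_coi_mapped >= report_min_percent) |>
    arrange(desc(.data$percent_of_coi_mapped))
}
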
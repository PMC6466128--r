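# Small-RNA evidence for host assignment: pair merging, 15-50 nt size
# profiles, exact fragment matching against viral contigs, and the
# count-vs-expression correlation that separates RNAi products from
# degradation fragments.

#' Merge read pairs into fragments
#'
#' Reverse-complements the mate, finds the maximal exact 3' overlap of at
#' least `min_overlap` nt and joins each pair into a single fragment
#' (`length = len1 + len2 - overlap`). Pairs without a qualifying overlap
#' are dropped and counted.
#'
#' @param r1,r2 Forward and reverse reads: character vectors of equal
#'   length, or paths to FASTQ files.
#' @param min_overlap Minimal exact overlap (nt).
#' @return A tibble of merged fragments (`pair_id`, `seq`, `length`,
#'   `overlap`) with the number of dropped pairs in attribute
#'   `n_dropped`.
#' @export
#' @examples
#' insert <- "ACGTACGTACGTACGTACGT"
#' merge_pairs(insert, as.character(
#'   Biostrings::reverseComplement(Biostrings::DNAString(insert))
#' ))
merge_pairs <- function(r1, r2, min_overlap = 10L) {
  if (length(r1) == 1L && file.exists(r1[1])) {
    r1 <- as.character(Biostrings::readDNAStringSet(r1, format = "fastq"))
    r2 <- as.character(Biostrings::readDNAStringSet(r2, format = "fastq"))
  }
  if (length(r1) != length(r2)) {
    abort("r1 and r2 must contain the same number of reads",
      class = "viromics_input_error"
    )
  }
  out <- purrr::map2(r1, r2, function(a, b) {
    rc <- revcomp(b)
    la <- nchar(a)
    lb <- nchar(rc)
    if (min(la, lb) < min_overlap) {
      return(NULL)
    }
    for (k in seq(min(la, lb), min_overlap, by = -1L)) {
      if (substr(a, la - k + 1L, la) == substr(rc, 1L, k)) {
        return(list(seq = paste0(substr(a, 1L, la - k), rc), overlap = k))
      }
    }
    NULL
  })
  kept <- !vapply(out, is.null, logical(1))
  res <- tibble(
    pair_id = which(kept),
    seq = vapply(out[kept], `[[`, character(1), "seq"),
    overlap = vapply(out[kept], `[[`, integer(1), "overlap")
  ) |>
    mutate(length = nchar(.data$seq), .after = "seq")
  attr(res, "n_dropped") <- sum(!kept)
  res
}

#' Fragment size profile
#'
#' Histogram of fragment lengths within `[min_len, max_len]`, with the mode
#' and the fractions in the 20-22 nt (siRNA/miRNA) and 29-30 nt (piRNA)
#' bands. A dominant 20-22 nt fraction on expression-independent fragments
#' is the signature of genuine virus-derived small RNAs.
#'
#' @param fragments Fragment lengths: a data frame with a `length` column,
#'   a character vector of sequences, or an integer vector of lengths.
#' @param min_len,max_len Profiled length range (nt); fragments outside it
#'   are excluded (and counted in `n_excluded`).
#' @return An object of class `size_profile` with the histogram tibble,
#'   `mode_length`, `frac_20_22`, `frac_29_30`, `n_profiled` and
#'   `n_excluded`. `tidy()` returns the histogram; `glance()` the scalar
#'   summary; `autoplot()` draws the profile.
#' @export
#' @examples
#' glance(size_profile(rep(c(21L, 30L), c(70, 30))))
size_profile <- function(fragments, min_len = 15L, max_len = 50L) {
  len <- if (is.data.frame(fragments)) {
    fragments$length
  } else if (is.character(fragments)) {
    nchar(fragments)
  } else {
    as.integer(fragments)
  }
  inside <- len >= min_len & len <= max_len
  kept <- len[inside]
  if (length(kept) == 0L) {
    warn("no fragments inside the profiled length range")
  }
  histogram <- tibble(
    length = min_len:max_len,
    count = as.integer(table(factor(kept, levels = min_len:max_len)))
  )
  n <- length(kept)
  structure(
    list(
      histogram = histogram,
      mode_length = if (n) histogram$length[which.max(histogram$count)] else NA_integer_,
      frac_20_22 = if (n) sum(kept >= 20 & kept <= 22) / n else NA_real_,
      frac_29_30 = if (n) sum(kept >= 29 & kept <= 30) / n else NA_real_,
      n_profiled = n,
      n_excluded = sum(!inside)
    ),
    class = "size_profile"
  )
}

#' @describeIn size_profile Length histogram as a tibble.
#' @param x A `size_profile`.
#' @param ... Unused.
#' @method tidy size_profile
#' @export
tidy.size_profile <- function(x, ...) x$histogram

#' @describeIn size_profile One-row summary (mode, band fractions, counts).
#' @method glance size_profile
#' @export
glance.size_profile <- function(x, ...) {
  tibble(
    mode_length = x$mode_length,
    frac_20_22 = x$frac_20_22,
    frac_29_30 = x$frac_29_30,
    n_profiled = x$n_profiled,
    n_excluded = x$n_excluded
  )
}

#' @describeIn size_profile Bar plot of the length histogram with the
#'   20-22 nt band shaded.
#' @param object A `size_profile`.
#' @method autoplot size_profile
#' @export
autoplot.size_profile <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::annotate("rect",
      xmin = 19.5, xmax = 22.5, ymin = -Inf, ymax = Inf,
      alpha = 0.15, fill = "steelblue"
    ) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = "fragment length (nt)", y = "fragments",
      title = sprintf(
        "Size profile (mode %d nt, 20-22 nt fraction %.2f)",
        object$mode_length, object$frac_20_22
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.size_profile <- function(x, ...) {
  cat(sprintf(
    "<size_profile> %d fragments (%d excluded); mode %s nt; 20-22 nt %.3f; 29-30 nt %.3f\n",
    x$n_profiled, x$n_excluded,
    as.character(x$mode_length), x$frac_20_22, x$frac_29_30
  ))
  invisible(x)
}

#' Match small-RNA fragments against target contigs
#'
#' Assigns each fragment to every target containing it on either strand
#' within `max_mismatch` mismatches, and (when an ORF table is supplied)
#' tallies matches per ORF interval. Multi-target fragments count once per
#' target.
#'
#' @param fragments A data frame with `fragment_id` and `seq`, or a
#'   character vector of fragment sequences.
#' @param targets Named character vector of target (contig) sequences.
#' @param orfs Optional ORF table ([find_orfs()]) for per-ORF counts; ORF
#'   `contig_id`s must use the target names.
#' @param max_mismatch Allowed mismatches per match (0 = exact, mirroring
#'   perfect RNAi complementarity).
#' @return A list of class `fragment_matches` with tibbles `matches`
#'   (`fragment_id`, `target_id`, `strand`, `start`, `end`), `per_target`
#'   and `per_orf` counts of distinct matching fragments.
#' @export
match_fragments <- function(fragments, targets, orfs = NULL, max_mismatch = 0L) {
  if (!is.data.frame(fragments)) {
    fragments <- tibble(
      fragment_id = paste0("frag", seq_along(fragments)),
      seq = unname(fragments)
    )
  }
  stopifnot(all(c("fragment_id", "seq") %in% names(fragments)))
  if (is.null(names(targets))) names(targets) <- paste0("target", seq_along(targets))
  subjects <- lapply(targets, Biostrings::DNAString)
  hit_rows <- list()
  for (ti in seq_along(subjects)) {
    tid <- names(targets)[ti]
    for (fi in seq_len(nrow(fragments))) {
      fseq <- fragments$seq[fi]
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") fseq else revcomp(fseq)
        m <- Biostrings::matchPattern(pat, subjects[[ti]],
          max.mismatch = max_mismatch
        )
        if (length(m)) {
          hit_rows[[length(hit_rows) + 1L]] <- tibble(
            fragment_id = fragments$fragment_id[fi],
            target_id = tid,
            strand = strand,
            start = Biostrings::start(m),
            end = Biostrings::end(m)
          )
        }
      }
    }
  }
  matches <- if (length(hit_rows)) {
    bind_rows(hit_rows)
  } else {
    tibble(
      fragment_id = character(), target_id = character(),
      strand = character(), start = integer(), end = integer()
    )
  }
  per_target <- matches |>
    distinct(.data$fragment_id, .data$target_id) |>
    count(.data$target_id, name = "n_fragments")
  per_orf <- NULL
  if (!is.null(orfs)) {
    per_orf <- matches |>
      dplyr::inner_join(orfs,
        by = c(target_id = "contig_id"),
        relationship = "many-to-many", suffix = c("", ".orf")
      ) |>
      filter(.data$start <= .data$end.orf, .data$end >= .data$start.orf) |>
      distinct(.data$fragment_id, .data$orf_id) |>
      count(.data$orf_id, name = "srna_count")
  }
  structure(
    list(matches = matches, per_target = per_target, per_orf = per_orf),
    class = "fragment_matches"
  )
}

#' Correlation diagnostic for degradation-derived small RNAs
#'
#' Squared Pearson correlation between per-ORF small-RNA counts and
#' transcript expression. Fragments that are breakdown products of abundant
#' transcripts track expression closely (r-squared near 1), whereas genuine
#' RNAi products are produced independently of transcript abundance
#' (low r-squared); callers combine this with the 20-22 nt enrichment of
#' the size profile. No hard classification threshold is imposed.
#'
#' @param per_orf A data frame with columns `srna_count` and `expression`
#'   (count or TPM), one row per ORF; at least 3 ORFs with defined
#'   expression.
#' @return An object of class `degradation_test` with `r_squared`,
#'   `n_orfs` and the data; `glance()` returns the one-row summary.
#' @export
#' @examples
#' d <- tibble::tibble(expression = c(1, 2, 4, 8), srna_count = c(11, 19, 42, 78))
#' glance(degradation_test(d))
degradation_test <- function(per_orf) {
  stopifnot(all(c("srna_count", "expression") %in% names(per_orf)))
  d <- filter(per_orf, !is.na(.data$expression), !is.na(.data$srna_count))
  if (nrow(d) < 3L) {
    abort("need at least 3 ORFs with defined expression",
      class = "viromics_input_error"
    )
  }
  if (stats::sd(d$srna_count) == 0 || stats::sd(d$expression) == 0) {
    abort("zero variance in counts or expression; correlation undefined",
      class = "viromics_input_error"
    )
  }
  structure(
    list(
      r_squared = cor(d$srna_count, d$expression)^2,
      n_orfs = nrow(d),
      data = as_tibble(d)
    ),
    class = "degradation_test"
  )
}

#' @describeIn degradation_test One-row summary (`r_squared`, `n_orfs`).
#' @param x A `degradation_test`.
#' @param ... Unused.
#' @method glance degradation_test
#' @export
glance.degradation_test <- function(x, ...) {
  tibble(r_squared = x$r_squared, n_orfs = x$n_orfs)
}

#' @describeIn degradation_test The per-ORF data with the fitted
#'   proportionality line.
#' @param object A `degradation_test`.
#' @method autoplot degradation_test
#' @export
autoplot.degradation_test <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$expression, y = .data$srna_count)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "firebrick") +
    ggplot2::labs(
      x = "viral ORF expression", y = "mapped small-RNA fragments",
      title = sprintf("r² = %.3f over %d ORFs", object$r_squared, object$n_orfs)
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.degradation_test <- function(x, ...) {
  cat(sprintf(
    "<degradation_test> r-squared %.4f over %d ORFs\n", x$r_squared, x$n_orfs
  ))
  invisible(x)
}
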
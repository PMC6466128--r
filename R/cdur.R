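# Dinucleotide under-representation by codon-preserving permutation.
#
# The null model permutes third codon positions within exchangeability
# groups keyed by (first two bases, encoded amino acid). This is the only
# permutation family that leaves both the protein sequence and the per-base
# multiset (hence GC content) of the CDS invariant, including the edge boxes
# where the third base changes the amino acid (ATA/ATG, TGA/TGG, AGA/AGG vs
# AGC/AGT, ...). Two statistics are referred to the permutation null:
# "below" (motif count) and "repTrFrac" (fraction of motif occurrences whose
# defining A->G transition is non-synonymous).

MOTIFS <- c("AA", "CA", "GA", "TA", "WA")

check_motif <- function(motif) {
  motif <- toupper(motif)
  bad <- setdiff(motif, MOTIFS)
  if (length(bad)) {
    abort(
      sprintf(
        "unsupported motif(s) %s; choose from %s",
        paste(bad, collapse = ", "), paste(MOTIFS, collapse = ", ")
      ),
      class = "viromics_input_error"
    )
  }
  motif
}

motif_first_bases <- function(motif) {
  if (motif == "WA") c("A", "T") else substr(motif, 1L, 1L)
}

#' Validate a coding sequence and split it into codons
#'
#' Checks that the sequence length is a multiple of three and contains no
#' internal stop codon, strips a terminal stop codon if present, and returns
#' the codon vector. All motif statistics operate on this stripped CDS so an
#' A-to-G transition can never create or destroy a termination codon.
#'
#' @param seq A single in-frame DNA string, or an already-split codon vector.
#' @return Character vector of codons.
#' @export
#' @examples
#' strip_and_validate_cds("ATGAAATAA")
strip_and_validate_cds <- function(seq) {
  codons <- if (length(seq) == 1L && nchar(seq[1]) != 3L) {
    assert_dna(seq, allow_n = FALSE)
    codon_split(seq)
  } else {
    if (any(nchar(seq) != 3L)) {
      abort("codon vector must contain 3-mers only", class = "viromics_input_error")
    }
    seq
  }
  n <- length(codons)
  if (n > 0L && codons[n] %in% STOP_CODONS) codons <- codons[-n]
  if (any(codons %in% STOP_CODONS)) {
    abort("internal stop codon in coding sequence", class = "viromics_input_error")
  }
  codons
}

third_position_groups <- function(codons) {
  key <- paste0(substr(codons, 1L, 2L), translate_codons(codons))
  grp <- split(seq_along(codons), key)
  grp[lengths(grp) > 1L]
}

#' Shuffle third codon positions, preserving protein and base composition
#'
#' Permutes third-position bases uniformly at random within groups of codons
#' sharing the same first two bases and the same encoded amino acid, so the
#' translation, the sequence length and the multiset of bases (hence GC
#' content) are all unchanged.
#'
#' @inheritParams strip_and_validate_cds
#' @param seed Optional integer seed for a reproducible permutation.
#' @return The shuffled CDS, in the same form as the input (string or codon
#'   vector). A terminal stop codon, if present, is kept in place.
#' @export
#' @examples
#' shuffle_third_positions(c("AAA", "AAG"), seed = 1)
shuffle_third_positions <- function(seq, seed = NULL) {
  as_string <- length(seq) == 1L && nchar(seq[1]) != 3L
  codons <- if (as_string) codon_split(assert_dna(seq, allow_n = FALSE)) else seq
  n <- length(codons)
  stop_tail <- n > 0L && codons[n] %in% STOP_CODONS
  body <- if (stop_tail) codons[-n] else codons
  if (any(body %in% STOP_CODONS)) {
    abort("internal stop codon in coding sequence", class = "viromics_input_error")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  t3 <- substr(body, 3L, 3L)
  grp <- third_position_groups(body)
  if (length(grp)) {
    flat <- unlist(grp, use.names = FALSE)
    gid <- rep.int(seq_along(grp), lengths(grp))
    t3 <- permute_within(t3, flat, gid)
  }
  shuffled <- paste0(substr(body, 1L, 2L), t3)
  out <- if (stop_tail) c(shuffled, codons[n]) else shuffled
  if (as_string) collapse(out) else out
}

#' Count overlapping dinucleotide motif occurrences
#'
#' Counts occurrences of the motif in the concatenated coding sequence,
#' including codon-junction positions; `W` matches A or T at the first
#' position, and each sequence position is counted once.
#'
#' @param seq DNA string or codon vector.
#' @param motif One of `"AA"`, `"CA"`, `"GA"`, `"TA"`, `"WA"`.
#' @return Integer count.
#' @export
#' @examples
#' count_motif("AATAA", "WA")
count_motif <- function(seq, motif) {
  motif <- check_motif(motif)
  s <- chars(if (length(seq) > 1L) collapse(seq) else seq)
  if (length(s) < 2L) {
    return(0L)
  }
  m1 <- motif_first_bases(motif)
  sum(s[-length(s)] %in% m1 & s[-1L] == "A")
}

#' Fraction of motif occurrences whose A-to-G transition is non-synonymous
#'
#' For every motif occurrence, applies the A-to-G transition at the edited
#' (second) base, translates the affected codon and asks whether the amino
#' acid changes; returns changed occurrences over total occurrences
#' ("repTrFrac"). Undefined (`NA`) when the motif does not occur.
#'
#' @inheritParams count_motif
#' @return A fraction in `[0, 1]`, or `NA_real_` when the motif is absent.
#' @export
#' @examples
#' reptrfrac(c("ATG", "AAA"), "AA") # one syn + one nonsyn occurrence -> 0.5
reptrfrac <- function(seq, motif) {
  motif <- check_motif(motif)
  codons <- if (length(seq) == 1L && nchar(seq[1]) != 3L) {
    codon_split(assert_dna(seq, allow_n = FALSE))
  } else {
    seq
  }
  s <- chars(collapse(codons))
  if (length(s) < 2L) {
    return(NA_real_)
  }
  m1 <- motif_first_bases(motif)
  occ <- which(s[-length(s)] %in% m1 & s[-1L] == "A") # first-base index
  if (length(occ) == 0L) {
    return(NA_real_)
  }
  edited <- occ + 1L # position of the A
  ci <- (edited - 1L) %/% 3L + 1L
  within <- (edited - 1L) %% 3L + 1L
  changed <- vapply(seq_along(edited), function(k) {
    cod <- chars(codons[ci[k]])
    mut <- cod
    mut[within[k]] <- "G"
    GENCODE[[collapse(cod)]] != GENCODE[[collapse(mut)]]
  }, logical(1))
  sum(changed) / length(changed)
}

# Precomputed machinery for the permutation loop: all quantities that do not
# depend on the permuted third bases are cached once per CDS, so each of the
# (typically 1000) shuffles costs a handful of vectorised operations.
cdur_prepare <- function(codons, motifs) {
  c1 <- substr(codons, 1L, 1L)
  c2 <- substr(codons, 2L, 2L)
  t3 <- substr(codons, 3L, 3L)
  n <- length(codons)
  # non-synonymy lookup tables for A->G at codon positions 1, 2 and 3
  ns1 <- outer(DNA_BASES, DNA_BASES, function(b2, b3) {
    GENCODE[paste0("A", b2, b3)] != GENCODE[paste0("G", b2, b3)]
  })
  dimnames(ns1) <- list(DNA_BASES, DNA_BASES)
  ns2 <- outer(DNA_BASES, DNA_BASES, function(b1, b3) {
    GENCODE[paste0(b1, "A", b3)] != GENCODE[paste0(b1, "G", b3)]
  })
  dimnames(ns2) <- list(DNA_BASES, DNA_BASES)
  ns3 <- GENCODE[paste0(c1, c2, "A")] != GENCODE[paste0(c1, c2, "G")]
  per_motif <- lapply(motifs, function(m) {
    m1 <- motif_first_bases(m)
    occ1_pos <- which(c1 %in% m1 & c2 == "A") # codon positions 1-2, fixed
    list(
      m1 = m1,
      occ1_pos = occ1_pos,
      occ1_c1 = c1[occ1_pos],
      c2_in_m1 = c2 %in% m1
    )
  })
  names(per_motif) <- motifs
  grp <- third_position_groups(codons)
  list(
    c1 = c1, c2 = c2, t3 = t3, n = n,
    c1_next_A = c(c1[-1L] == "A", FALSE),
    flat = unlist(grp, use.names = FALSE),
    gid = rep.int(seq_along(grp), lengths(grp)),
    ns1 = ns1, ns2 = ns2, ns3 = ns3,
    per_motif = per_motif
  )
}

# count and repTrFrac for one permuted third-base vector
cdur_eval <- function(prep, t3, motif) {
  pm <- prep$per_motif[[motif]]
  occ2 <- pm$c2_in_m1 & t3 == "A"
  occ3 <- t3 %in% pm$m1 & prep$c1_next_A
  cnt <- length(pm$occ1_pos) + sum(occ2) + sum(occ3)
  if (cnt == 0L) {
    return(c(0, NA_real_))
  }
  ch1 <- if (length(pm$occ1_pos)) {
    sum(prep$ns2[cbind(pm$occ1_c1, t3[pm$occ1_pos])])
  } else {
    0L
  }
  ch2 <- sum(prep$ns3[occ2])
  j <- which(occ3) + 1L
  ch3 <- if (length(j)) sum(prep$ns1[cbind(prep$c2[j], t3[j])]) else 0L
  c(cnt, (ch1 + ch2 + ch3) / cnt)
}

# one uniform within-group permutation of third bases: positions are sorted
# by (group, random key) so each group's block is independently randomised
permute_within <- function(t3, flat, gid) {
  ord <- order(gid, runif(length(flat)), method = "radix")
  t3[flat] <- t3[flat[ord]]
  t3
}

#' Permutation test for dinucleotide under-representation in a CDS
#'
#' Compares the observed motif count ("below" metric) and the observed
#' fraction of non-synonymous A-to-G transition opportunities at motif sites
#' ("repTrFrac" metric) against `n_shuffles` codon-preserving third-position
#' shuffles of the same sequence ([shuffle_third_positions()]). Each p-value
#' is the fraction of shuffles with a strictly smaller value than the
#' observed one; a metric is classified `under`-represented below
#' `under_p` and `over`-represented above `over_p`. A sequence that is
#' under-represented in the count and over-represented in repTrFrac has
#' attained *maximal* under-representation: every synonymously removable
#' motif occurrence has been removed.
#'
#' Shuffles in which the motif is absent contribute no defined repTrFrac and
#' are excluded from that denominator; when the observed sequence itself has
#' no motif occurrence, `reptrfrac_p` is `NA`.
#'
#' @param seq In-frame coding sequence (string or codon vector); a terminal
#'   stop codon is stripped.
#' @param motifs Motifs to test, a subset of `"WA", "AA", "CA", "GA", "TA"`.
#' @param n_shuffles Number of permutations.
#' @param seed Integer seed; results are bit-reproducible.
#' @param under_p,over_p Classification thresholds on the permutation
#'   p-values.
#' @param ties How ties between a shuffle and the observed value enter the
#'   p-value: `"strict"` (ties contribute nothing) or `"midrank"` (ties
#'   contribute 1/2).
#' @param orf_id Identifier carried into the report.
#' @return An object of class `cdur_result`; see [tidy.cdur_result()] for
#'   the per-motif report columns.
#' @export
#' @examples
#' res <- cdur_test(gen_depleted_cds(150, "TA", 1, seed = 2),
#'   motifs = c("TA", "AA"), n_shuffles = 200, seed = 1
#' )
#' tidy(res)
cdur_test <- function(seq, motifs = MOTIFS, n_shuffles = 1000L, seed = 1L,
                      under_p = 0.05, over_p = 0.95,
                      ties = c("strict", "midrank"), orf_id = "cds1") {
  ties <- match.arg(ties)
  motifs <- check_motif(motifs)
  codons <- strip_and_validate_cds(seq)
  if (length(codons) < 2L) {
    abort("coding sequence must contain at least two codons after stop stripping",
      class = "viromics_input_error"
    )
  }
  observed_count <- vapply(motifs, function(m) count_motif(codons, m), integer(1))
  observed_rtf <- vapply(motifs, function(m) reptrfrac(codons, m), numeric(1))

  prep <- cdur_prepare(codons, motifs)
  counts <- matrix(0, nrow = n_shuffles, ncol = length(motifs))
  rtfs <- matrix(NA_real_, nrow = n_shuffles, ncol = length(motifs))
  withr::local_seed(seed)
  for (s in seq_len(n_shuffles)) {
    t3 <- permute_within(prep$t3, prep$flat, prep$gid)
    for (k in seq_along(motifs)) {
      v <- cdur_eval(prep, t3, motifs[k])
      counts[s, k] <- v[1]
      rtfs[s, k] <- v[2]
    }
  }

  half <- if (ties == "midrank") 0.5 else 0
  below_p <- vapply(seq_along(motifs), function(k) {
    (sum(counts[, k] < observed_count[k]) +
      half * sum(counts[, k] == observed_count[k])) / n_shuffles
  }, numeric(1))
  rtf_p <- vapply(seq_along(motifs), function(k) {
    if (is.na(observed_rtf[k])) {
      return(NA_real_)
    }
    v <- rtfs[, k]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      return(NA_real_)
    }
    (sum(v < observed_rtf[k]) + half * sum(v == observed_rtf[k])) / length(v)
  }, numeric(1))

  classify <- function(p) {
    dplyr::case_when(
      is.na(p) ~ NA_character_,
      p < under_p ~ "under",
      p > over_p ~ "over",
      TRUE ~ "neutral"
    )
  }
  report <- tibble(
    orf_id = orf_id,
    motif = motifs,
    observed_count = as.integer(observed_count),
    observed_reptrfrac = observed_rtf,
    n_shuffles = as.integer(n_shuffles),
    n_reptrfrac_defined = colSums(!is.na(rtfs)),
    below_p = below_p,
    reptrfrac_p = rtf_p,
    below_class = classify(below_p),
    reptrfrac_class = classify(rtf_p),
    maximal = !is.na(below_p) & below_p < under_p &
      !is.na(rtf_p) & rtf_p > over_p
  )
  structure(
    list(
      report = report,
      shuffle_counts = setNames(as.data.frame(counts), motifs),
      shuffle_reptrfrac = setNames(as.data.frame(rtfs), motifs),
      orf_id = orf_id,
      n_codons = length(codons),
      n_shuffles = as.integer(n_shuffles),
      seed = as.integer(seed)
    ),
    class = "cdur_result"
  )
}

#' Run the under-representation test over a set of ORFs
#'
#' @param cds A data frame with columns `orf_id` and `seq`.
#' @param ... Passed on to [cdur_test()].
#' @param seed Master seed; one sub-seed per ORF is derived from it.
#' @return A tibble of per-ORF, per-motif reports (rows of
#'   [tidy.cdur_result()]).
#' @export
cdur_batch <- function(cds, ..., seed = 1L) {
  stopifnot(all(c("orf_id", "seq") %in% names(cds)))
  withr::local_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, nrow(cds))
  purrr::map2_dfr(seq_len(nrow(cds)), sub_seeds, function(i, s) {
    tidy(cdur_test(cds$seq[i], ..., seed = s, orf_id = cds$orf_id[i]))
  })
}

#' @describeIn cdur_test Per-motif report as a tibble: observed count and
#'   repTrFrac, permutation p-values (`below_p`, `reptrfrac_p`),
#'   classifications and the `maximal` flag.
#' @param x A `cdur_result` object.
#' @method tidy cdur_result
#' @export
tidy.cdur_result <- function(x, ...) x$report

#' @describeIn cdur_test One-row summary: sequence size, shuffle count and
#'   how many motifs are under-represented or maximal.
#' @method glance cdur_result
#' @export
glance.cdur_result <- function(x, ...) {
  tibble(
    orf_id = x$orf_id,
    n_codons = x$n_codons,
    n_shuffles = x$n_shuffles,
    n_motifs = nrow(x$report),
    n_under = sum(x$report$below_class == "under", na.rm = TRUE),
    n_maximal = sum(x$report$maximal),
    seed = x$seed
  )
}

#' @describeIn cdur_test Shuffle-null histograms of the motif count with the
#'   observed count marked, one facet per motif.
#' @param object A `cdur_result` object.
#' @param ... Unused.
#' @method autoplot cdur_result
#' @export
autoplot.cdur_result <- function(object, ...) {
  null_df <- tidyr::pivot_longer(
    as_tibble(object$shuffle_counts),
    dplyr::everything(),
    names_to = "motif", values_to = "count"
  )
  obs_df <- object$report[, c("motif", "observed_count")]
  ggplot2::ggplot(null_df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      data = obs_df,
      ggplot2::aes(xintercept = .data$observed_count),
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::facet_wrap(~motif, scales = "free") +
    ggplot2::labs(
      x = "motif count in shuffled sequence", y = "shuffles",
      title = sprintf(
        "Permutation null vs observed (%s, %d shuffles)",
        object$orf_id, object$n_shuffles
      )
    ) +
    ggplot2::theme_minimal()
}

#' Aggregate under-representation calls by group
#'
#' Summarises a batch of per-ORF motif reports per group label (for example,
#' the viral host class): the percentage of ORFs under-represented in the
#' count metric, over-represented in repTrFrac, and maximal.
#'
#' @param reports A tibble of per-ORF reports ([cdur_batch()] output).
#' @param groups Mapping of `orf_id` to a label: a data frame with columns
#'   `orf_id` and `label`, or a named character vector. Every report
#'   `orf_id` must be labelled; labels with no reports yield zero-count
#'   rows.
#' @return A tibble with one row per (label, motif): `n_orfs`, `pct_under`,
#'   `pct_over_reptrfrac`, `pct_maximal`.
#' @export
aggregate_by_group <- function(reports, groups) {
  if (!is.data.frame(groups)) {
    groups <- tibble(orf_id = names(groups), label = unname(groups))
  }
  stopifnot(all(c("orf_id", "label") %in% names(groups)))
  missing_ids <- setdiff(unique(reports$orf_id), groups$orf_id)
  if (length(missing_ids)) {
    abort(
      sprintf("unlabelled orf_id(s): %s", paste(head(missing_ids, 5), collapse = ", ")),
      class = "viromics_input_error"
    )
  }
  labelled <- dplyr::inner_join(reports, groups, by = "orf_id")
  all_cells <- tidyr::expand_grid(
    label = unique(groups$label),
    motif = unique(reports$motif)
  )
  stats <- labelled |>
    group_by(.data$label, .data$motif) |>
    summarise(
      n_orfs = dplyr::n(),
      pct_under = 100 * mean(.data$below_class == "under", na.rm = TRUE),
      pct_over_reptrfrac = 100 * mean(.data$reptrfrac_class == "over", na.rm = TRUE),
      pct_maximal = 100 * mean(.data$maximal),
      .groups = "drop"
    )
  all_cells |>
    left_join(stats, by = c("label", "motif")) |>
    mutate(
      n_orfs = tidyr::replace_na(.data$n_orfs, 0L),
      pct_under = tidyr::replace_na(.data$pct_under, 0),
      pct_over_reptrfrac = tidyr::replace_na(.data$pct_over_reptrfrac, 0),
      pct_maximal = tidyr::replace_na(.data$pct_maximal, 0)
    ) |>
    arrange(.data$label, .data$motif)
}
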
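# Viral-candidate decision cascade: evidence filtering from external search
# tables, host-genome subtraction, redundancy clustering and completeness
# classification. BLAST and HMMER are consumed as tabular output; they are
# never executed here.

#' PFAM accessions of viral RNA-dependent RNA polymerase domains
#'
#' The conserved replicative enzyme of RNA viruses; a single domain hit to
#' one of these models is independent evidence that a contig is viral.
#' @export
VRDRP_PFAM <- c("PF00680", "PF00978", "PF00998", "PF02123", "PF07925", "PF04197")

#' Read BLAST tabular output (outfmt 6)
#'
#' @param path Path to a 12-column BLAST tabular file
#'   (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore`).
#' @return A tibble with the standard columns plus `query_id`, `subject_id`,
#'   `evalue`, `source = "blastp"` and an empty `domain_acc`, ready for
#'   [filter_evidence()].
#' @export
read_blast_tab <- function(path) {
  cols <- c(
    "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  df <- utils::read.table(path,
    sep = "\t", col.names = cols, comment.char = "#",
    colClasses = c(
      "character", "character", rep("numeric", 2), rep("integer", 6),
      "numeric", "numeric"
    )
  )
  as_tibble(df) |>
    mutate(
      query_id = .data$qseqid, subject_id = .data$sseqid,
      source = "blastp", domain_acc = NA_character_
    )
}

#' Read HMMER per-domain tabular output (domtblout)
#'
#' @param path Path to a `--domtblout` file from `hmmsearch`/`hmmscan`
#'   run with profile HMMs as queries against protein sequences.
#' @return A tibble with `query_id` (the searched protein), `domain_acc`
#'   (PFAM accession, version suffix stripped), `domain_name`, `evalue`
#'   (per-domain independent E-value) and `source = "hmmer"`.
#' @export
read_hmmer_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(
      query_id = character(), subject_id = character(),
      domain_acc = character(), domain_name = character(),
      evalue = numeric(), source = character()
    ))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  tibble(
    query_id = vapply(fields, `[[`, character(1), 1L),
    subject_id = vapply(fields, `[[`, character(1), 4L),
    domain_acc = sub("\\.\\d+$", "", vapply(fields, `[[`, character(1), 5L)),
    domain_name = vapply(fields, `[[`, character(1), 4L),
    evalue = as.numeric(vapply(fields, `[[`, character(1), 13L)),
    source = "hmmer"
  )
}

#' Filter candidate queries by search evidence
#'
#' A query is kept through either of two routes: at least `min_hits`
#' distinct BLASTP alignments (counted per query-subject pair, so HSP
#' fragmentation does not inflate the tally) at `evalue <= evalue_cutoff`,
#' or at least one HMMER hit to a viral RdRp domain model at
#' `evalue <= domain_cutoff`. The hit-count rule applies to the BLASTP route
#' only.
#'
#' @param hits A data frame of evidence with columns `query_id`,
#'   `subject_id`, `evalue`, `source` (`"blastp"` or `"hmmer"`) and
#'   `domain_acc` (PFAM accession for HMMER rows).
#' @param evalue_cutoff BLASTP E-value cutoff.
#' @param min_hits Minimal number of distinct BLASTP hits.
#' @param domain_cutoff HMMER domain E-value cutoff.
#' @param vrdrp_accessions PFAM accessions accepted as RdRp evidence.
#' @return A tibble with `query_id` and its evidence `route` (`"blastp"`,
#'   `"vrdrp"` or `"both"`), one row per kept query.
#' @export
filter_evidence <- function(hits, evalue_cutoff = 1e-50, min_hits = 5L,
                            domain_cutoff = 1e-5,
                            vrdrp_accessions = VRDRP_PFAM) {
  stopifnot(all(c("query_id", "evalue", "source") %in% names(hits)))
  if (!"subject_id" %in% names(hits)) hits$subject_id <- NA_character_
  if (!"domain_acc" %in% names(hits)) hits$domain_acc <- NA_character_
  blast_kept <- hits |>
    filter(.data$source == "blastp", .data$evalue <= evalue_cutoff) |>
    distinct(.data$query_id, .data$subject_id) |>
    count(.data$query_id) |>
    filter(.data$n >= min_hits) |>
    dplyr::pull(.data$query_id)
  rdrp_kept <- hits |>
    filter(
      .data$source == "hmmer",
      sub("\\.\\d+$", "", .data$domain_acc) %in% vrdrp_accessions,
      .data$evalue <= domain_cutoff
    ) |>
    dplyr::pull(.data$query_id) |>
    unique()
  tibble(query_id = union(blast_kept, rdrp_kept)) |>
    mutate(route = dplyr::case_when(
      .data$query_id %in% blast_kept & .data$query_id %in% rdrp_kept ~ "both",
      .data$query_id %in% blast_kept ~ "blastp",
      TRUE ~ "vrdrp"
    )) |>
    arrange(.data$query_id)
}

#' Remove candidates matching the host genome
#'
#' @param candidates Kept queries: a character vector of ids or a data frame
#'   with a `query_id` column (e.g. [filter_evidence()] output).
#' @param host_hits Data frame of host-genome search hits with `query_id`
#'   and `evalue`.
#' @param evalue_cutoff Hits at or below this E-value disqualify a
#'   candidate.
#' @return The candidates with host-matching queries removed, in the same
#'   form as the input.
#' @export
subtract_host <- function(candidates, host_hits, evalue_cutoff = 1e-5) {
  matched <- if (is.null(host_hits) || nrow(host_hits) == 0L) {
    character(0)
  } else {
    unique(host_hits$query_id[host_hits$evalue <= evalue_cutoff])
  }
  if (is.data.frame(candidates)) {
    filter(candidates, !.data$query_id %in% matched)
  } else {
    setdiff(candidates, matched)
  }
}

#' Global pairwise sequence identity
#'
#' Identity of a global (Needleman-Wunsch) alignment, defined as the number
#' of identically matched positions divided by the length of the shorter
#' sequence — the denominator convention of greedy redundancy clusterers.
#'
#' @param a,b Amino-acid (or nucleotide) sequences as single strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 4, type = "global"
  )
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Greedy identity clustering of protein sequences
#'
#' Longest-first greedy clustering: sequences are sorted by decreasing
#' length (ties broken lexicographically) and each sequence joins the
#' earliest-founded cluster whose representative it matches at
#' `threshold` identity ([pairwise_identity()]), otherwise it founds a new
#' cluster. Deterministic for a given input set.
#'
#' @param seqs Named character vector of sequences (names become sequence
#'   ids; unnamed input is labelled `seq1..n`).
#' @param threshold Identity threshold for joining a cluster.
#' @return A tibble with one row per sequence: `seq_id`, `length`,
#'   `cluster` (integer, in founding order), `representative` (seq_id of
#'   the cluster representative) and `is_representative`.
#' @export
#' @examples
#' cluster_by_identity(c(a = "MKVLAEQT", b = "MKVLAEQT", c = "WYWYWYWY"))
cluster_by_identity <- function(seqs, threshold = 0.90) {
  if (length(seqs) == 0L) {
    abort("no sequences to cluster", class = "viromics_input_error")
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), seqs)
  seqs <- seqs[ord]
  reps <- integer(0) # indices (into sorted seqs) of representatives
  cluster <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    assigned <- 0L
    for (k in seq_along(reps)) {
      if (pairwise_identity(seqs[[i]], seqs[[reps[k]]]) >= threshold) {
        assigned <- k
        break
      }
    }
    if (assigned == 0L) {
      reps <- c(reps, i)
      assigned <- length(reps)
    }
    cluster[i] <- assigned
  }
  tibble(
    seq_id = names(seqs),
    length = nchar(unname(seqs)),
    cluster = cluster,
    representative = names(seqs)[reps[cluster]],
    is_representative = seq_along(seqs) %in% reps
  )
}

#' Classify viral genome completeness
#'
#' A candidate genome is `nearly_complete` when it is a single contig longer
#' than `min_length` nucleotides that encodes at least one complete ORF;
#' otherwise it is `partial`.
#'
#' @param candidates A data frame with columns `contig_id` and `length`,
#'   and either a logical `has_complete_orf` column or nothing if `orfs`
#'   is supplied.
#' @param orfs Optional ORF table ([find_orfs()] output) used to derive
#'   `has_complete_orf` per contig.
#' @param min_length Length threshold in nucleotides (strictly greater
#'   than).
#' @return The input tibble with a `completeness` column
#'   (`"nearly_complete"` or `"partial"`).
#' @export
classify_completeness <- function(candidates, orfs = NULL, min_length = 5000L) {
  candidates <- as_tibble(candidates)
  if (!"has_complete_orf" %in% names(candidates)) {
    if (is.null(orfs)) {
      abort("supply either a has_complete_orf column or an `orfs` table",
        class = "viromics_input_error"
      )
    }
    complete_ids <- unique(orfs$contig_id[orfs$complete])
    candidates$has_complete_orf <- candidates$contig_id %in% complete_ids
  }
  mutate(candidates, completeness = ifelse(
    .data$length > min_length & .data$has_complete_orf,
    "nearly_complete", "partial"
  ))
}

#' Screen contigs for viral candidates
#'
#' End-to-end decision cascade over a set of contigs: ORF prediction,
#' evidence filtering ([filter_evidence()]), host-genome subtraction
#' ([subtract_host()]), redundancy clustering of the longest predicted
#' protein per kept contig ([cluster_by_identity()]), completeness
#' classification ([classify_completeness()]) and polyA-tail detection
#' ([detect_polya()]).
#'
#' @param contigs Named character vector of contig sequences. Evidence
#'   `query_id`s must use the contig names.
#' @param hits Evidence table for [filter_evidence()].
#' @param host_hits Optional host-genome hit table for [subtract_host()].
#' @param min_orf_codons,evalue_cutoff,min_hits,domain_cutoff,host_cutoff,
#'   cluster_threshold,min_length Stage parameters; see the stage functions.
#' @return A tibble with one row per kept contig: evidence route, ORF
#'   summary, completeness class, polyA flag and cluster assignment.
#' @export
screen_candidates <- function(contigs, hits, host_hits = NULL,
                              min_orf_codons = 100L,
                              evalue_cutoff = 1e-50, min_hits = 5L,
                              domain_cutoff = 1e-5, host_cutoff = 1e-5,
                              cluster_threshold = 0.90,
                              min_length = 5000L) {
  kept <- filter_evidence(hits,
    evalue_cutoff = evalue_cutoff,
    min_hits = min_hits, domain_cutoff = domain_cutoff
  )
  if (!is.null(host_hits)) kept <- subtract_host(kept, host_hits, host_cutoff)
  kept <- filter(kept, .data$query_id %in% names(contigs))
  if (nrow(kept) == 0L) {
    return(tibble(
      contig_id = character(), length = integer(), route = character(),
      n_orfs = integer(), has_complete_orf = logical(),
      completeness = character(), polya = logical(),
      cluster = integer(), representative = character()
    ))
  }
  contigs <- contigs[kept$query_id]
  orfs <- find_orfs(contigs, min_codons = min_orf_codons)
  cand <- tibble(
    contig_id = kept$query_id,
    length = nchar(unname(contigs)),
    route = kept$route
  ) |>
    left_join(
      orfs |> group_by(.data$contig_id) |>
        summarise(n_orfs = n(), has_complete_orf = any(.data$complete)),
      by = "contig_id"
    ) |>
    mutate(
      n_orfs = tidyr::replace_na(.data$n_orfs, 0L),
      has_complete_orf = tidyr::replace_na(.data$has_complete_orf, FALSE)
    ) |>
    classify_completeness(min_length = min_length) |>
    mutate(polya = vapply(contigs, detect_polya, logical(1)))

  # cluster the longest predicted protein of each contig with >= 1 ORF
  best <- orfs |>
    group_by(.data$contig_id) |>
    arrange(desc(.data$n_codons), .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  if (nrow(best) > 0L) {
    cl <- cluster_by_identity(
      setNames(best$protein, best$contig_id),
      threshold = cluster_threshold
    ) |>
      select(contig_id = "seq_id", "cluster", "representative")
    cand <- left_join(cand, cl, by = "contig_id")
  } else {
    cand$cluster <- NA_integer_
    cand$representative <- NA_character_
  }
  cand
}
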
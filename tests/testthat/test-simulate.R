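test_that("gen_cds builds ATG-initiated, stop-terminated CDSs of 3*n_codons nt", {
  for (n in c(2L, 3L, 50L, 100L)) {
    s <- gen_cds(n, seed = n)
    expect_equal(nchar(s), 3L * n)
    expect_equal(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% c("TAA", "TAG", "TGA"))
    if (n > 2L) {
      internal <- substring(s, seq(4, nchar(s) - 3, by = 3), seq(6, nchar(s), by = 3))
      expect_false(any(head(internal, -1) %in% c("TAA", "TAG", "TGA")))
    }
  }
  expect_identical(gen_cds(100, seed = 1), gen_cds(100, seed = 1))
  expect_false(identical(gen_cds(100, seed = 1), gen_cds(100, seed = 2)))
})

test_that("codon usage must be a normalizable sense-codon distribution", {
  expect_error(gen_cds(10, codon_usage = c(TAA = 1)), class = "viromics_config_error")
  expect_error(gen_cds(10, codon_usage = c(AAA = -1, AAC = 2)),
    class = "viromics_config_error"
  )
  s <- gen_cds(10, codon_usage = c(AAA = 1), seed = 3)
  expect_equal(substr(s, 4, 27), strrep("AAA", 8))
})

test_that("gen_depleted_cds rearranges the gen_cds draw without touching
           protein or base composition", {
  for (seed in 1:5) {
    null_seq <- gen_cds(200, seed = seed)
    dep <- gen_depleted_cds(200, motif = "TA", strength = 1, seed = seed)
    expect_identical(gen_depleted_cds(200, "TA", 0, seed = seed), null_seq)
    expect_lte(count_motif(dep, "TA"), count_motif(null_seq, "TA"))
    expect_identical(
      as.character(Biostrings::translate(Biostrings::DNAString(dep))),
      as.character(Biostrings::translate(Biostrings::DNAString(null_seq)))
    )
    expect_identical(
      sort(strsplit(dep, "")[[1]]),
      sort(strsplit(null_seq, "")[[1]])
    )
  }
  expect_identical(
    gen_depleted_cds(100, "AA", 1, seed = 9),
    gen_depleted_cds(100, "AA", 1, seed = 9)
  )
})

test_that("edited pileup honours edit_rate = 0 and error_rate = 0", {
  ref <- gen_cds(200, seed = 5)
  pu <- gen_edited_pileup(ref, sim_config(seed = 1, coverage = 20, edit_rate = 0))
  expect_equal(nrow(pu$truth), 0L)
  ref_chars <- strsplit(ref, "")[[1]]
  mismatches <- mapply(function(s, p) {
    sum(strsplit(s, "")[[1]] != ref_chars[p:(p + nchar(s) - 1)])
  }, pu$alignments$seq, pu$alignments$pos)
  expect_true(all(mismatches == 0))
  expect_true(all(pu$alignments$nm == 0))
})

test_that("edited-site count is binomial around edit_rate * #A and truth
           frequencies equal realised alternate fractions", {
  ref <- gen_cds(3400, seed = 8) # ~10 kb
  cfg <- sim_config(seed = 2, coverage = 100, edit_rate = 0.05)
  pu <- gen_edited_pileup(ref, cfg)
  n_a <- sum(strsplit(ref, "")[[1]][-1] == "A")
  expect_gt(nrow(pu$truth), n_a * 0.05 - 4 * sqrt(n_a * 0.05))
  expect_lt(nrow(pu$truth), n_a * 0.05 + 4 * sqrt(n_a * 0.05))
  # recompute realised fractions from the alignments themselves
  starts <- pu$alignments$pos
  ends <- starts + nchar(pu$alignments$seq) - 1L
  for (i in seq_len(min(nrow(pu$truth), 25L))) {
    p <- pu$truth$pos[i]
    covering <- which(starts <= p & ends >= p)
    bases <- substr(pu$alignments$seq[covering], p - starts[covering] + 1L,
      p - starts[covering] + 1L
    )
    expect_equal(mean(bases == "G"), pu$truth$frequency[i])
  }
})

test_that("a fixed seed reproduces the SAM file byte for byte", {
  ref <- gen_cds(150, seed = 4)
  cfg <- sim_config(seed = 11, coverage = 15)
  f1 <- tempfile(fileext = ".sam")
  f2 <- tempfile(fileext = ".sam")
  write_sam(gen_edited_pileup(ref, cfg), f1)
  write_sam(gen_edited_pileup(ref, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a reference without eligible A sites warns and yields empty truth", {
  expect_warning(
    pu <- gen_edited_pileup(strrep("C", 120), sim_config(seed = 1, coverage = 10)),
    "no eligible A"
  )
  expect_equal(nrow(pu$truth), 0L)
})

test_that("small-RNA library counts follow expression weights in
           degradation mode", {
  orfs <- tibble::tibble(
    orf_id = c("o1", "o2", "o3"),
    seq = vapply(1:3, function(i) gen_cds(100, seed = i), character(1)),
    weight = c(1, 2, 4)
  )
  lib <- gen_srna_library(orfs, sim_config(
    seed = 3, n_fragments = 7000,
    srna_mode = "degradation"
  ))
  counts <- table(factor(lib$orf_id, levels = orfs$orf_id))
  expected <- 7000 * orfs$weight / sum(orfs$weight)
  expect_true(all(abs(counts - expected) < 4 * sqrt(expected)))
})

test_that("dicer21 fragments concentrate on 20-22 nt and all modes stay
           inside 15-50 nt", {
  orfs <- tibble::tibble(
    orf_id = "o1", seq = gen_cds(100, seed = 1), weight = 1
  )
  for (mode in c("degradation", "dicer21", "piwi30")) {
    lib <- gen_srna_library(orfs, sim_config(
      seed = 5, n_fragments = 2000,
      srna_mode = mode, srna_size_sd = 1
    ))
    expect_true(all(lib$length >= 15 & lib$length <= 50))
    expect_true(all(nchar(lib$seq) == lib$length))
  }
  lib21 <- gen_srna_library(orfs, sim_config(
    seed = 6, n_fragments = 2000,
    srna_mode = "dicer21", srna_size_sd = 1
  ))
  expect_gte(mean(lib21$length >= 20 & lib21$length <= 22), 0.8)
})

test_that("degenerate small-RNA configurations are rejected or empty", {
  orfs <- tibble::tibble(orf_id = "o1", seq = gen_cds(50, seed = 1), weight = 0)
  expect_error(gen_srna_library(orfs, sim_config(seed = 1)),
    class = "viromics_config_error"
  )
  orfs$weight <- 1
  empty <- gen_srna_library(orfs, sim_config(seed = 1, n_fragments = 0))
  expect_equal(nrow(empty), 0L)
})
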
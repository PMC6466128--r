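test_that("CDS validation strips the terminal stop and rejects malformed
           input", {
  expect_equal(strip_and_validate_cds("ATGAAATAA"), c("ATG", "AAA"))
  expect_equal(strip_and_validate_cds("ATGTGA"), "ATG")
  expect_error(strip_and_validate_cds("ATGAA"), class = "viromics_input_error")
  expect_error(strip_and_validate_cds("ATGTAAAAA"), class = "viromics_input_error")
})

test_that("third-position shuffling preserves translation, length and base
           multiset on random CDSs", {
  set.seed(7)
  for (rep in 1:20) {
    s <- gen_cds(sample(30:150, 1), seed = rep)
    cod <- strip_and_validate_cds(s)
    aa0 <- paste(Biostrings::GENETIC_CODE[cod], collapse = "")
    bases0 <- sort(strsplit(paste(cod, collapse = ""), "")[[1]])
    for (k in 1:20) {
      sh <- shuffle_third_positions(cod)
      expect_equal(paste(Biostrings::GENETIC_CODE[sh], collapse = ""), aa0)
      expect_equal(sort(strsplit(paste(sh, collapse = ""), "")[[1]]), bases0)
    }
  }
})

test_that("exchangeable third bases are actually exchanged; singleton groups
           are fixed", {
  # two Lys codons: both orders of the third bases {A, G} must be reachable
  outcomes <- vapply(
    1:50,
    function(s) paste(shuffle_third_positions(c("AAA", "AAG"), seed = s), collapse = " "),
    character(1)
  )
  expect_setequal(unique(outcomes), c("AAA AAG", "AAG AAA"))
  # Met and Trp are single-codon amino acids: identity permutation always
  for (s in 1:10) {
    expect_equal(shuffle_third_positions(c("ATG", "TGG"), seed = s), c("ATG", "TGG"))
  }
})

test_that("motif counting handles overlap, degeneracy and the empty case", {
  expect_equal(count_motif("AATAA", "AA"), 2L)
  expect_equal(count_motif("AATAA", "TA"), 1L)
  expect_equal(count_motif("AATAA", "WA"), 3L)
  expect_equal(count_motif("", "TA"), 0L)
  set.seed(3)
  for (rep in 1:30) {
    s <- random_dna(300)
    for (m in c("AA", "CA", "GA", "TA", "WA")) {
      expect_equal(count_motif(s, m), oracle_count_motif(s, m))
    }
  }
})

test_that("repTrFrac matches hand-derived genetic-code cases", {
  # "ATGAAA": AA at (4,5): AAA->AGA Lys->Arg nonsyn; at (5,6): AAA->AAG syn
  expect_equal(reptrfrac(c("ATG", "AAA"), "AA"), 0.5)
  expect_true(is.na(reptrfrac(c("ATG", "CCC"), "TA")))
  # single GA occurrence at a fourfold-degenerate third position: GGA->GGG syn
  expect_equal(reptrfrac(c("ATG", "GGA"), "GA"), 0)
})

test_that("the fast permutation path equals the public string functions", {
  set.seed(11)
  motifs <- c("AA", "CA", "GA", "TA", "WA")
  for (rep in 1:15) {
    cod <- strip_and_validate_cds(gen_cds(sample(20:100, 1), seed = 100 + rep))
    prep <- viromics:::cdur_prepare(cod, motifs)
    sh <- shuffle_third_positions(cod, seed = rep)
    t3 <- substr(sh, 3, 3)
    for (m in motifs) {
      v <- viromics:::cdur_eval(prep, t3, m)
      expect_equal(v[1], count_motif(sh, m))
      rt <- reptrfrac(sh, m)
      if (is.na(rt)) expect_true(is.na(v[2])) else expect_equal(v[2], rt)
    }
  }
})

test_that("cdur_test is bit-reproducible and flags maximal
           under-representation by the 0.05/0.95 rule", {
  s <- gen_cds(120, seed = 21)
  r1 <- cdur_test(s, n_shuffles = 200, seed = 5)
  r2 <- cdur_test(s, n_shuffles = 200, seed = 5)
  expect_identical(tidy(r1), tidy(r2))
  rep <- tidy(r1)
  expect_identical(
    rep$maximal,
    !is.na(rep$below_p) & rep$below_p < 0.05 &
      !is.na(rep$reptrfrac_p) & rep$reptrfrac_p > 0.95
  )
  expect_identical(rep$below_class[rep$below_p < 0.05 & !is.na(rep$below_p)] |>
    unique() |> setdiff("under"), character(0))
})

test_that("a CDS of single-codon amino acids yields identical shuffles and
           below_p of zero under the strict-less rule", {
  s <- paste(rep(c("ATG", "TGG"), 10), collapse = "")
  r <- tidy(cdur_test(s, motifs = "TA", n_shuffles = 50, seed = 1))
  expect_equal(r$below_p, 0)
})

test_that("strongly TA-depleted sequences are called under-represented", {
  r <- tidy(cdur_test(gen_depleted_cds(300, "TA", 1, seed = 31),
    motifs = "TA", n_shuffles = 500, seed = 8
  ))
  expect_lt(r$below_p, 0.05)
  expect_equal(r$below_class, "under")
})

test_that("group aggregation computes per-label percentages and keeps empty
           labels", {
  reports <- tibble::tibble(
    orf_id = paste0("o", 1:10),
    motif = "TA",
    below_class = rep(c("under", "neutral"), c(4, 6)),
    reptrfrac_class = rep(c("over", "neutral"), c(2, 8)),
    maximal = rep(c(TRUE, FALSE), c(2, 8))
  )
  groups <- tibble::tibble(
    orf_id = c(paste0("o", 1:10), "unused"),
    label = c(rep("virus", 10), "empty_class")
  )
  agg <- aggregate_by_group(reports, groups)
  virus <- agg[agg$label == "virus", ]
  expect_equal(virus$pct_under, 40)
  expect_equal(virus$pct_maximal, 20)
  empty <- agg[agg$label == "empty_class", ]
  expect_equal(empty$n_orfs, 0L)
  expect_equal(empty$pct_under, 0)
  expect_error(
    aggregate_by_group(reports, groups[-1, ]),
    class = "viromics_input_error"
  )
})
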
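rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

test_that("pair merging reconstructs short inserts and drops non-overlapping
           pairs", {
  insert <- substr(gen_cds(30, seed = 3), 5, 24) # 20 nt insert, read-through
  merged <- merge_pairs(insert, rc(insert))
  expect_equal(merged$seq, insert)
  expect_equal(merged$length, 20L)

  # long insert with a 30 nt overlap between 60 nt reads
  long_insert <- substr(gen_cds(60, seed = 4), 1, 90)
  r1 <- substr(long_insert, 1, 60)
  r2 <- rc(substr(long_insert, 31, 90))
  out <- merge_pairs(r1, r2)
  expect_equal(out$seq, long_insert)
  expect_equal(out$overlap, 30L)

  no_overlap <- merge_pairs(strrep("A", 20), strrep("A", 20)) # mate rc is poly-T
  expect_equal(nrow(no_overlap), 0L)
  expect_equal(attr(no_overlap, "n_dropped"), 1L)
  expect_error(merge_pairs(c("ACGT", "ACGT"), "ACGT"),
    class = "viromics_input_error"
  )
})

test_that("merging simulated read-through pairs recovers every fragment", {
  orfs <- tibble::tibble(orf_id = "o1", seq = gen_cds(100, seed = 6), weight = 1)
  lib <- gen_srna_library(orfs, sim_config(seed = 9, n_fragments = 200))
  merged <- merge_pairs(lib$seq, vapply(lib$seq, rc, character(1)))
  expect_equal(nrow(merged), nrow(lib))
  expect_equal(merged$seq, lib$seq)
})

test_that("size profiles report mode, band fractions and exclusions", {
  p21 <- size_profile(rep(21L, 50))
  expect_equal(p21$mode_length, 21L)
  expect_equal(p21$frac_20_22, 1)

  mix <- size_profile(rep(c(30L, 21L), c(70, 30)))
  expect_equal(mix$mode_length, 30L)
  expect_equal(mix$frac_29_30, 0.7)
  expect_equal(mix$frac_20_22, 0.3)

  with_out <- size_profile(c(rep(21L, 5), 51L, 14L))
  expect_equal(with_out$n_excluded, 2L)
  expect_equal(sum(tidy(with_out)$count) + with_out$n_excluded, 7L)
  expect_warning(size_profile(c(51L, 60L)), "no fragments")
})

test_that("fragment matching finds both strands and equals brute-force
           substring search", {
  target <- c(contig1 = gen_cds(700, seed = 12))
  k21 <- substr(target[[1]], 101, 121)
  mm <- match_fragments(c(k21, rc(k21)), target)
  expect_equal(nrow(mm$matches), 2L)
  expect_setequal(mm$matches$strand, c("+", "-"))
  expect_equal(mm$per_target$n_fragments, 2L)

  set.seed(21)
  frags <- c(
    vapply(1:30, function(i) { # half real subsequences, half random
      s <- sample(1:(nchar(target) - 20), 1)
      substr(target[[1]], s, s + 20)
    }, character(1)),
    vapply(1:30, function(i) random_dna(21), character(1))
  )
  mine <- match_fragments(frags, target)
  brute <- vapply(frags, function(f) {
    grepl(f, target[[1]], fixed = TRUE) || grepl(rc(f), target[[1]], fixed = TRUE)
  }, logical(1))
  expect_equal(
    sort(unique(mine$matches$fragment_id)),
    sort(paste0("frag", which(brute)))
  )
})

test_that("per-ORF fragment counts follow ORF intervals", {
  contig <- c(v1 = gen_cds(400, seed = 14))
  orfs <- find_orfs(contig, min_codons = 300)
  frag <- substr(contig[[1]], orfs$start + 10, orfs$start + 31)
  mm <- match_fragments(frag, contig, orfs = orfs)
  expect_equal(mm$per_orf$srna_count, 1L)
  expect_equal(mm$per_orf$orf_id, orfs$orf_id)
})

test_that("degradation diagnostics: proportional counts give r-squared one,
           independent counts stay under the permutation null", {
  prop <- tibble::tibble(expression = c(1, 2, 4, 8, 16), srna_count = c(10, 20, 40, 80, 160))
  expect_equal(degradation_test(prop)$r_squared, 1)

  set.seed(31)
  indep <- tibble::tibble(
    expression = runif(20, 1, 100),
    srna_count = rpois(20, 50)
  )
  obs <- degradation_test(indep)$r_squared
  null95 <- quantile(replicate(200, {
    degradation_test(dplyr::mutate(indep, srna_count = sample(srna_count)))$r_squared
  }), 0.95)
  expect_lt(obs, null95)

  expect_error(degradation_test(prop[1:2, ]), class = "viromics_input_error")
  expect_error(
    degradation_test(tibble::tibble(expression = c(1, 2, 3), srna_count = c(5, 5, 5))),
    class = "viromics_input_error"
  )
})

test_that("library modes separate: degradation tracks expression, dicer21
           does not and is 20-22 nt enriched", {
  orfs <- tibble::tibble(
    orf_id = paste0("o", 1:6),
    seq = vapply(1:6, function(i) gen_cds(150, seed = 40 + i), character(1)),
    weight = c(1, 2, 5, 10, 20, 40)
  )
  deg <- gen_srna_library(orfs, sim_config(
    seed = 51, n_fragments = 6000,
    srna_mode = "degradation"
  ))
  per_orf <- function(lib) {
    dplyr::count(lib, orf_id, name = "srna_count") |>
      dplyr::right_join(orfs[, c("orf_id", "weight")], by = "orf_id") |>
      dplyr::mutate(
        srna_count = tidyr::replace_na(srna_count, 0L),
        expression = weight * 1000
      )
  }
  expect_gte(degradation_test(per_orf(deg))$r_squared, 0.95)

  dic <- gen_srna_library(orfs, sim_config(
    seed = 52, n_fragments = 6000,
    srna_mode = "dicer21", srna_size_sd = 1
  ))
  expect_lte(degradation_test(per_orf(dic))$r_squared, 0.5)
  expect_gte(glance(size_profile(dic))$frac_20_22, 0.8)
  expect_equal(glance(size_profile(dic))$mode_length, 21L)

  piw <- gen_srna_library(orfs, sim_config(
    seed = 53, n_fragments = 4000,
    srna_mode = "piwi30", srna_size_sd = 1
  ))
  expect_equal(glance(size_profile(piw))$mode_length, 30L)
})
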
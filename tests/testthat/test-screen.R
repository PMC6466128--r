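blastp_hits <- function(query, n, evalue, subjects = paste0("s", seq_len(n))) {
  tibble::tibble(
    query_id = query, subject_id = subjects, evalue = evalue,
    source = "blastp", domain_acc = NA_character_
  )
}

test_that("evidence filtering applies the five-hit BLASTP rule and the RdRp
           domain route", {
  hits <- dplyr::bind_rows(
    blastp_hits("kept5", 5, 1e-60),
    blastp_hits("dropped4", 4, 1e-200),
    blastp_hits("weak", 6, 1e-40), # above the 1e-50 cutoff
    tibble::tibble(
      query_id = "rdrp_only", subject_id = "PF00680", evalue = 1e-7,
      source = "hmmer", domain_acc = "PF00680.12"
    ),
    tibble::tibble(
      query_id = "wrong_domain", subject_id = "PF00001", evalue = 1e-9,
      source = "hmmer", domain_acc = "PF00001"
    )
  )
  kept <- filter_evidence(hits)
  expect_setequal(kept$query_id, c("kept5", "rdrp_only"))
  expect_equal(kept$route[kept$query_id == "rdrp_only"], "vrdrp")
})

test_that("repeated HSPs against one subject do not inflate the hit count", {
  hits <- blastp_hits("q", 6, 1e-80, subjects = rep("same_subject", 6))
  expect_equal(nrow(filter_evidence(hits)), 0L)
})

test_that("adding evidence never removes candidates and relaxing the cutoff
           never shrinks the kept set", {
  set.seed(13)
  base <- dplyr::bind_rows(lapply(1:8, function(i) {
    blastp_hits(paste0("q", i), sample(3:7, 1), 10^-sample(45:80, 1))
  }))
  kept0 <- filter_evidence(base)$query_id
  extra <- dplyr::bind_rows(base, blastp_hits("q9", 6, 1e-70))
  expect_true(all(kept0 %in% filter_evidence(extra)$query_id))
  kept_relaxed <- filter_evidence(base, evalue_cutoff = 1e-40)$query_id
  expect_true(all(kept0 %in% kept_relaxed))
})

test_that("host subtraction removes matched candidates only", {
  cands <- c("v1", "v2", "v3")
  host <- tibble::tibble(query_id = c("v1", "v3"), evalue = c(1e-30, 1e-3))
  expect_equal(subtract_host(cands, host), c("v2", "v3")) # 1e-3 above cutoff
  expect_equal(subtract_host(cands, host[0, ]), cands)
  kept_df <- tibble::tibble(query_id = cands, route = "blastp")
  expect_equal(subtract_host(kept_df, host)$query_id, c("v2", "v3"))
})

test_that("identity clustering respects the 0.90 boundary", {
  a <- strrep("MKVLAEQTHW", 10)
  mutate_at <- function(s, idx, to = "A") {
    v <- strsplit(s, "")[[1]]
    v[idx] <- to
    paste(v, collapse = "")
  }
  b_same <- a
  b_90 <- mutate_at(a, seq(3, by = 10, length.out = 10)) # 90/100 identity
  b_89 <- mutate_at(a, seq(3, by = 9, length.out = 11), to = "G") # 89/100
  expect_equal(max(cluster_by_identity(c(x = a, y = b_same))$cluster), 1L)
  expect_equal(max(cluster_by_identity(c(x = a, y = b_90))$cluster), 1L)
  expect_equal(max(cluster_by_identity(c(x = a, y = b_89))$cluster), 2L)
})

test_that("greedy clustering equals the all-pairs oracle on random protein
           sets", {
  set.seed(5)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  for (rep in 1:4) {
    seqs <- vapply(1:12, function(i) {
      paste(sample(aas, sample(30:60, 1), replace = TRUE), collapse = "")
    }, character(1))
    # include some near-duplicates so clusters actually form
    seqs <- c(seqs, substr(seqs[1], 1, 40), seqs[2])
    names(seqs) <- paste0("p", seq_along(seqs))
    mine <- cluster_by_identity(seqs, threshold = 0.8)
    oracle <- oracle_greedy_clusters(seqs, threshold = 0.8)
    expect_equal(mine$cluster, oracle)
  }
})

test_that("completeness classification is exact on the boundary grid", {
  grid <- tidyr::expand_grid(
    length = c(4999L, 5001L),
    has_complete_orf = c(TRUE, FALSE)
  )
  grid$contig_id <- paste0("c", seq_len(nrow(grid)))
  out <- classify_completeness(grid)
  expect_equal(
    out$completeness,
    ifelse(out$length > 5000 & out$has_complete_orf, "nearly_complete", "partial")
  )
  expect_equal(sum(out$completeness == "nearly_complete"), 1L)
})

test_that("screen_candidates chains evidence, ORFs, clustering and polyA", {
  v1 <- paste0(gen_cds(1800, seed = 1), strrep("A", 30)) # > 5 kb, polyA
  v2 <- gen_cds(400, seed = 2)
  contigs <- c(virus_big = v1, virus_small = v2, host_like = gen_cds(400, seed = 3))
  hits <- dplyr::bind_rows(
    blastp_hits("virus_big", 5, 1e-70),
    blastp_hits("virus_small", 5, 1e-70),
    blastp_hits("host_like", 5, 1e-70)
  )
  host_hits <- tibble::tibble(query_id = "host_like", evalue = 1e-20)
  out <- screen_candidates(contigs, hits, host_hits = host_hits)
  expect_setequal(out$contig_id, c("virus_big", "virus_small"))
  big <- out[out$contig_id == "virus_big", ]
  expect_equal(big$completeness, "nearly_complete")
  expect_true(big$polya)
  expect_equal(out$completeness[out$contig_id == "virus_small"], "partial")
})
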
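# Seed-and-extend search: exact, sparse shifted-seed, pigeonhole approximate.

test_that("part_decode reports the decoding state after p characters", {
  idx <- toy_index(k = 3)
  # kMA0 entry "CGT" (start 1): the SNP at position 3 is passed, flagged absent
  tx0 <- reconstruct_kmers(idx, 0)
  e <- which(tx0 == "CGT")
  pd <- part_decode(idx, 0, e, 3)
  expect_equal(pd$vtList, 1L)
  expect_equal(pd$evList, 0L)
  expect_equal(pd$pos_curr, 4L)
  # kMA1 entry "GAA" (start 2): SNP introduced
  tx1 <- reconstruct_kmers(idx, 1)
  e <- which(tx1 == "GAA")
  pd <- part_decode(idx, 1, e, 3)
  expect_equal(pd$vtList, 1L)
  expect_equal(pd$evList, 1L)
  expect_equal(pd$pos_curr, 5L)
  # an entry with no variants in range: empty lists
  e <- which(tx0 == "ACG")[1]
  pd <- part_decode(idx, 0, e, 3)
  expect_equal(length(pd$vtList), 0L)
  expect_equal(pd$pos_curr, 3L)
})

test_that("toy exact search matches the hand-computed records", {
  idx <- toy_index(k = 3)
  r <- exact_search(idx, "ACG", min_seed = 1)
  expect_equal(r$pre, c(0L, 4L))
  expect_equal(r$haplotype_count, c(2L, 2L))
  r <- exact_search(idx, "GAA", min_seed = 1)
  expect_equal(r$pre, 2L)
  expect_equal(r$hap_idx[[1]], 1L)        # R = 10
  r <- exact_search(idx, "GTA", min_seed = 1)
  expect_equal(r$hap_idx[[1]], 2L)        # reference path, R = 01
  r <- exact_search(idx, "GAAC", min_seed = 1)
  expect_equal(r$pre, 2L)
  expect_equal(r$hap_idx[[1]], 1L)
  # N in the pattern never matches
  expect_equal(nrow(exact_search(idx, "ANG", min_seed = 1)), 0L)
})

test_that("patterns shorter than the minimum seed are refused", {
  idx <- toy_index(k = 3)
  expect_error(search_patterns(idx, "ACG", min_seed = 8),
               "shorter than the minimum seed length")
  expect_equal(nrow(search_patterns(idx, "ACG", min_seed = 1)), 2L)
})

test_that("pigeonhole_split partitions by floor arithmetic", {
  s <- pigeonhole_split(150, 3)
  expect_equal(s$start, c(0L, 37L, 74L, 111L))
  expect_equal(unique(s$length), 37L)
  s <- pigeonhole_split(10, 0)
  expect_equal(s$start, 0L); expect_equal(s$length, 10L)
  expect_error(pigeonhole_split(3, 3), "too short")
})

test_that("pigeonhole soundness: one segment is always error-free", {
  set.seed(20)
  for (i in 1:200) {
    m <- sample(30:200, 1)
    q <- sample(1:5, 1)
    if (m < q + 1) next
    s <- pigeonhole_split(m, q)
    errs <- sample(m, q)  # q planted substitutions (1-based positions)
    in_seg <- vapply(seq_len(nrow(s)), function(j)
      any(errs > s$start[j] & errs <= s$start[j] + s$length[j]), logical(1))
    expect_true(any(!in_seg))
  }
})

test_that("toy approximate search reports per-path minimum mismatches", {
  idx <- toy_index(k = 3)
  r <- approximate_search(idx, "GTA", q = 1, min_seed = 1)
  r <- r[order(r$mismatches), ]
  expect_equal(r$mismatches, c(0L, 1L))
  expect_equal(r$hap_idx[[1]], 2L)  # exact on the reference path
  expect_equal(r$hap_idx[[2]], 1L)  # 1 mismatch at the SNP
  # budget 0 loses the mismatching path
  r0 <- exact_search(idx, "GTTC", min_seed = 1)
  expect_equal(nrow(r0), 0L)
  r1 <- approximate_search(idx, "GTTC", q = 1, min_seed = 1)
  expect_true(all(r1$mismatches == 1L))
})

test_that("oracle equivalence holds on random collections (exact and approximate)", {
  for (seed in 201:203) {
    coll <- rand_collection(seed, ref_len = 2500L, n_samples = 4L)
    idx <- build_index(coll$fasta, coll$vcf,
                       params = index_params(k = 25, lut_width = 8))
    qs <- generate_query_set(coll, 25, rng_seed = seed + 1,
                             err_range = c(0L, 3L))
    want3 <- oracle_scan(coll, qs, q = 3)
    for (q in c(0L, 2L, 3L)) {
      got <- expand_matches(search_patterns(idx, qs, q = q))
      want <- want3[want3$mismatches <= q, , drop = FALSE]
      rep <- equivalence_check(got, want)
      expect_true(rep$pass, label = sprintf("seed %d q %d", seed, q))
    }
    unlink(coll$dir, recursive = TRUE)
  }
})

test_that("sparse and dense indexes give identical expanded answers", {
  coll <- rand_collection(301, ref_len = 2500L, n_samples = 4L)
  on.exit(unlink(coll$dir, recursive = TRUE))
  qs <- generate_query_set(coll, 20, rng_seed = 5, err_range = c(0L, 1L))
  dense <- build_index(coll$fasta, coll$vcf,
                       params = index_params(k = 25, lut_width = 8))
  g0 <- expand_matches(search_patterns(dense, qs, q = 1))
  for (d in c(2L, 3L, 8L)) {
    sp <- build_index(coll$fasta, coll$vcf,
                      params = index_params(k = 25, lut_width = 8, sparsity = d))
    gd <- expand_matches(search_patterns(sp, qs, q = 1))
    expect_identical(gd, g0, label = paste("d =", d))
  }
})

test_that("mismatch budgets are monotone: results for q contain those for q-1", {
  coll <- rand_collection(302, ref_len = 2000L, n_samples = 3L)
  on.exit(unlink(coll$dir, recursive = TRUE))
  idx <- build_index(coll$fasta, coll$vcf,
                     params = index_params(k = 25, lut_width = 8))
  qs <- generate_query_set(coll, 10, rng_seed = 6, err_range = c(0L, 3L))
  prev <- NULL
  for (q in 0:3) {
    g <- expand_matches(search_patterns(idx, qs, q = q))
    key <- paste(g$query_id, g$chrom, g$pre, g$offset, g$hap)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("self-sampled patterns are always recovered in their source haplotype", {
  coll <- rand_collection(303, ref_len = 2000L, n_samples = 3L)
  on.exit(unlink(coll$dir, recursive = TRUE))
  idx <- build_index(coll$fasta, coll$vcf,
                     params = index_params(k = 25, lut_width = 8))
  qs <- generate_query_set(coll, 30, rng_seed = 7, err_range = c(0L, 0L))
  got <- expand_matches(search_patterns(idx, qs, q = 0))
  for (i in seq_len(nrow(qs))) {
    hit <- got[got$query_id == qs$id[i] & got$chrom == qs$chrom[i] &
                 got$pre == qs$pre[i] & got$offset == qs$offset[i] &
                 got$hap == qs$hap[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$mismatches, 0L)
  }
})

test_that("aggregate_matches merges only identical-evidence records", {
  idx <- toy_index(k = 3)
  r <- exact_search(idx, "ACG", min_seed = 1)
  dup <- rbind(r, r)
  agg <- aggregate_matches(dup)
  expect_equal(nrow(agg), nrow(r))
  expect_equal(nrow(aggregate_matches(r[0, ])), 0L)
  # same position, different evidence: two records survive aggregation
  r2 <- search_patterns(idx, data.frame(id = "p", seq = "ACG"), min_seed = 1)
  expect_equal(nrow(aggregate_matches(r2)), nrow(r2))
})

test_that("reverse-complement search finds minus-strand occurrences", {
  idx <- toy_index(k = 3)
  r <- search_patterns(idx, data.frame(id = "x", seq = "CGT"), rc = TRUE,
                       min_seed = 1)
  expect_true(any(r$query_id == "x"))       # CGT occurs forward
  expect_true(any(r$query_id == "x/rc"))    # ACG = revcomp(CGT) occurs too
})
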
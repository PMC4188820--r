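# k-mer enumeration, categorization, presence filtering, subarray assembly,
# sparsification and interval lookup.

toy_parts <- function() {
  tf <- toy_files()
  on.exit(unlink(tf$dir, recursive = TRUE))
  fa <- read_fasta(tf$fasta)
  vc <- read_vcf_min(tf$vcf, fa$chrom_table)
  vd <- build_variant_database(normalize_variants(vc, fa$ref, fa$chrom_table))
  occ <- build_occurrence_matrix(vc, vd$variants)
  list(fa = fa, vc = vc, vd = vd, occ = occ)
}

test_that("toy enumeration yields the expected subarray counts and texts", {
  idx <- toy_index(k = 3)
  sizes <- vapply(idx$kma, function(s) length(s$pos_ref), integer(1))
  expect_equal(sizes, c(5L, 3L, 0L, 0L))
  expect_equal(reconstruct_kmers(idx, 0), c("ACG", "ACG", "CGT", "GTA", "TAC"))
  expect_equal(reconstruct_kmers(idx, 1), c("AAC", "CGA", "GAA"))
  expect_equal(idx$kma[[2]]$pos_ref, c(3L, 1L, 2L))  # starts of AAC/CGA/GAA
})

test_that("insertion-internal k-mer starts carry 1-based offsets", {
  p <- toy_parts()
  # add an INS "GG" before position 2 by rebuilding the database by hand
  vd <- make_vd(data.frame(kind = c("INS"), pos = 2L, del_len = 0L,
                           ins_seq = "GG"))
  params <- index_params(k = 3, lut_width = 2)
  cands <- enumerate_kmer_paths(p$fa$ref, p$fa$chrom_table, vd, params)
  ins_cands <- which(cands$offset > 0L)
  expect_setequal(cands$offset[ins_cands], c(1L, 2L))
  expect_true(all(cands$pos_ref[ins_cands] == 2L))
  # the post-insertion window is present as an anchored entry with (INS, 1)
  anch <- which(cands$offset == 0L & cands$pos_ref == 2L & cands$ev_len == 1L &
                cands$ev_flag[cands$ev_ptr + 1L] == 1L)
  expect_true(length(anch) >= 1L)
  expect_equal(cands$text[anch[1]], "GTA")
})

test_that("categorization follows consecutiveness, E_max and offsets", {
  cands <- list(pos_ref = c(0L, 0L, 0L, 0L), offset = c(0L, 0L, 1L, 0L),
                ev_ptr = c(0L, 0L, 3L, 4L), ev_len = c(0L, 3L, 1L, 2L),
                ev_vt = c(5L, 6L, 7L, 5L, 5L, 9L),
                ev_flag = c(1L, 0L, 1L, 1L, 1L, 1L))
  p16 <- index_params(k = 12, E_max = 16, lut_width = 4)
  expect_equal(categorize_entries(cands, p16), c(0L, 1L, 2L, 3L))
  p1 <- index_params(k = 12, E_max = 1, lut_width = 4)
  expect_equal(categorize_entries(cands, p1), c(0L, 3L, 2L, 3L))
})

test_that("presence filter keeps only combinations some haplotype carries", {
  p <- toy_parts()
  params <- index_params(k = 3, lut_width = 2)
  cands <- enumerate_kmer_paths(p$fa$ref, p$fa$chrom_table, p$vd, params)

  filter_counts <- function(occ_bits) {
    occ <- matrix(occ_bits, 1)
    keep <- presence_filter(cands, occ, p$vd, params)
    c(ref_kept = sum(keep[cands$ev_len == 0L &
                            cands$pos_ref %in% 1:3]),
      alt_kept = sum(keep[cands$ev_len > 0L]))
  }
  # occ = 10: both present-path and absent-path candidates kept
  both <- filter_counts(c(TRUE, FALSE))
  expect_gt(both[["ref_kept"]], 0); expect_gt(both[["alt_kept"]], 0)
  # occ = 11: reference-path candidates overlapping the SNP dropped
  allc <- filter_counts(c(TRUE, TRUE))
  expect_equal(allc[["ref_kept"]], 0); expect_gt(allc[["alt_kept"]], 0)
  # occ = 00: present-path candidates dropped
  none <- filter_counts(c(FALSE, FALSE))
  expect_equal(none[["alt_kept"]], 0); expect_gt(none[["ref_kept"]], 0)
})

test_that("build_kmer_array sorts, deduplicates and its LUT equals binary search", {
  idx <- toy_index(k = 3)
  for (cc in 0:3) {
    tx <- reconstruct_kmers(idx, cc)
    expect_false(is.unsorted(tx))
  }
  # lut interval for every 2-mer prefix equals the binary-search interval
  tx0 <- reconstruct_kmers(idx, 0)
  sub <- idx$kma[[1]]
  expect_equal(sub$lut_width, 2L)
  for (pfx_i in 0:15) {
    pfx <- paste(c("A", "C", "G", "T")[c(pfx_i %/% 4, pfx_i %% 4) + 1L],
                 collapse = "")
    lo <- sub$lut[pfx_i + 1L]; hi <- sub$lut[pfx_i + 2L]
    expect_equal(lo, sum(substr(tx0, 1, 2) < pfx))
    expect_equal(hi, sum(substr(tx0, 1, 2) <= pfx))
  }
  # duplicates from different enumeration orders collapse to one entry
  key0 <- paste(tx0, sub$pos_ref, sub$offset)
  expect_false(any(duplicated(key0)))
})

test_that("sparsify keeps multiples of d plus DEL/INS-anchored entries", {
  idx <- toy_index(k = 3)
  params <- idx$params
  sp <- sparsify(idx$kma, 2L, idx, params)
  expect_equal(sp[[1]]$pos_ref, c(0L, 4L, 2L))  # starts {0,2,4} (text order)
  # kMA1 keeps only the even start; the SNP-initial entry at start 3 is not
  # a DEL/INS and is dropped
  expect_equal(sp[[2]]$pos_ref, 2L)
  # d = 1 is the identity
  expect_identical(sparsify(idx$kma, 1L, idx, params), idx$kma)
  # entry counts are non-increasing in d; subarrays 2 and 3 invariant
  coll <- rand_collection(77, ref_len = 1500L, n_samples = 2L)
  on.exit(unlink(coll$dir, recursive = TRUE))
  prev <- c(Inf, Inf)
  for (d in c(1L, 2L, 4L, 8L)) {
    id <- build_index(coll$fasta, coll$vcf,
                      params = index_params(k = 12, lut_width = 4, sparsity = d))
    n01 <- vapply(id$kma[1:2], function(s) length(s$pos_ref), integer(1))
    n23 <- vapply(id$kma[3:4], function(s) length(s$pos_ref), integer(1))
    expect_true(all(n01 <= prev))
    if (d == 1L) base23 <- n23 else expect_equal(n23, base23)
    prev <- n01
  }
})

test_that("interval_lookup finds exactly the prefix-matching entries", {
  idx <- toy_index(k = 3)
  iv <- interval_lookup(idx, 0, "ACG")
  expect_equal(iv, c(1L, 2L))              # two ACG entries (starts 0 and 4)
  expect_equal(interval_lookup(idx, 0, "GAA")[2] -
               interval_lookup(idx, 0, "GAA")[1] + 1L, 0L)  # empty
  iv1 <- interval_lookup(idx, 1, "GAA")
  expect_equal(iv1[2] - iv1[1] + 1L, 1L)
  # single-character seed: all entries beginning with A
  ivA <- interval_lookup(idx, 0, "A")
  tx <- reconstruct_kmers(idx, 0)
  expect_equal(ivA[1]:ivA[2], which(substr(tx, 1, 1) == "A"))
  # linear-scan oracle over random seeds on a random collection
  coll <- rand_collection(88, ref_len = 1200L, n_samples = 2L)
  on.exit(unlink(coll$dir, recursive = TRUE))
  id <- build_index(coll$fasta, coll$vcf,
                    params = index_params(k = 12, lut_width = 4))
  set.seed(1)
  for (cc in 0:3) {
    tx <- reconstruct_kmers(id, cc)
    if (!length(tx)) next
    for (i in 1:20) {
      L <- sample(1:12, 1)
      seed <- if (runif(1) < 0.7)
        substr(tx[sample(length(tx), 1)], 1, L)
      else paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
      iv <- interval_lookup(id, cc, seed)
      want <- which(substr(tx, 1, nchar(seed)) == seed)
      got <- if (iv[2] >= iv[1]) iv[1]:iv[2] else integer()
      expect_equal(got, want)
    }
  }
})

test_that("every kept entry resolves to a non-empty haplotype set", {
  coll <- rand_collection(55, ref_len = 1500L, n_samples = 3L)
  on.exit(unlink(coll$dir, recursive = TRUE))
  idx <- build_index(coll$fasta, coll$vcf,
                     params = index_params(k = 12, lut_width = 4))
  st <- idx$bv
  for (cc in 0:3) {
    sub <- idx$kma[[cc + 1]]
    for (e in seq_along(sub$pos_ref)) {
      pd <- part_decode(idx, cc, e, idx$params$k)
      expect_true(any(resolve_haplotypes(st, pd$vtList, pd$evList)),
                  label = sprintf("subarray %d entry %d", cc, e))
    }
  }
})

test_that("path explosion triggers the guard with a diagnostic", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", strrep("ACGT", 10)), f)
  fa <- read_fasta(f)
  df <- data.frame(kind = "SNP", pos = 0:19, del_len = 1L,
                   ins_seq = rep(c("C", "G", "T", "A"), 5))
  vd <- make_vd(df)
  params <- index_params(k = 20, lut_width = 4, path_cap = 100)
  expect_error(enumerate_kmer_paths(fa$ref, fa$chrom_table, vd, params),
               "path explosion")
  unlink(f)
})
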
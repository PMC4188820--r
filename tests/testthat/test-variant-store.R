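# Reference packing, variant normalization, database lookups, and
# path-conditional forward/backward decoding.

test_that("pack/unpack is the identity with random access", {
  r <- pack_reference("ACGTN")
  expect_equal(r$length, 5L)
  expect_equal(ref_chars(r, 4, 1), "N")
  expect_equal(ref_chars(r, 0, 5), "ACGTN")
  expect_equal(pack_reference("")$length, 0L)
  expect_error(ref_chars(r, 5, 1), "out of bounds")
  expect_error(pack_reference("ACGX"), "invalid character 'X'")

  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 501, replace = TRUE),
             collapse = "")
  p <- pack_reference(s)
  for (i in 1:20) {
    st <- sample.int(501, 1) - 1L
    n <- sample.int(501 - st, 1)
    expect_equal(ref_chars(p, st, n), substr(s, st + 1, st + n))
  }
})

test_that("normalize_variants classifies by the shared-anchor convention", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "AACGTACG"), f)
  fa <- read_fasta(f)
  vf <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1"), collapse = "\t"))
  line <- function(pos, ref, alt, gt = "1|0")
    paste(c("chr1", pos, ".", ref, alt, ".", ".", ".", "GT", gt), collapse = "\t")
  writeLines(c(hdr, line(2, "AC", "A"), line(2, "ACGT", "AGG"),
               line(4, "G", "GTT"), line(5, "T", "A,C")), vf)
  v <- read_vcf_min(vf, fa$chrom_table)
  vars <- normalize_variants(v, fa$ref, fa$chrom_table)
  expect_equal(vars$kind, c("DEL", "SV", "INS", "SNP", "SNP"))
  expect_equal(vars$pos, c(2L, 2L, 4L, 4L, 4L))     # 0-based effect positions
  expect_equal(vars$del_len, c(1L, 3L, 0L, 1L, 1L))
  expect_equal(vars$ins_seq, c("", "GG", "TT", "A", "C"))
  expect_equal(vars$allele, c(1L, 1L, 1L, 1L, 2L))  # multiallelic split

  writeLines(c(hdr, line(2, "AG", "A")), vf)  # REF disagrees with reference
  v <- read_vcf_min(vf, fa$chrom_table)
  expect_error(normalize_variants(v, fa$ref, fa$chrom_table),
               "REF allele mismatch at chr1:2")
  writeLines(c(hdr, line(2, "AC", "GT")), vf)  # no shared anchor
  v <- read_vcf_min(vf, fa$chrom_table)
  expect_error(normalize_variants(v, fa$ref, fa$chrom_table), "anchor")
  unlink(c(f, vf))
})

test_that("first_variant_at_or_after agrees with a linear scan", {
  vd <- make_vd(data.frame(kind = c("SNP", "DEL", "SNP", "SNP"),
                           pos = c(2L, 5L, 5L, 9L),
                           del_len = c(1L, 2L, 1L, 1L),
                           ins_seq = c("A", "", "C", "G")))
  expect_equal(first_variant_at_or_after(vd, 5), 2L)
  expect_equal(first_variant_at_or_after(vd, 10), 5L)  # past the end
  expect_equal(first_variant_at_or_after(vd, 0), 1L)
  for (pos in 0:12) {
    lin <- which(vd$variants$pos >= pos)
    expect_equal(first_variant_at_or_after(vd, pos),
                 if (length(lin)) min(lin) else vd$n + 1L)
  }
})

test_that("spanning_deletions uses the open interval and nests correctly", {
  vd <- make_vd(data.frame(kind = c("DEL"), pos = 2L, del_len = 2L,
                           ins_seq = ""))
  expect_equal(spanning_deletions(vd, 3), 1L)   # 2 < 3 < 4
  expect_equal(spanning_deletions(vd, 2), integer())  # start not spanned
  expect_equal(spanning_deletions(vd, 4), integer())  # end not spanned

  vd2 <- make_vd(data.frame(kind = c("DEL", "DEL"), pos = c(0L, 2L),
                            del_len = c(6L, 2L), ins_seq = c("", "")))
  expect_equal(spanning_deletions(vd2, 3), c(1L, 2L))
  # brute-force interval check on a random database
  set.seed(7)
  n <- 30L
  df <- data.frame(kind = "DEL", pos = sort(sample(0:200, n)),
                   del_len = sample(1:9, n, replace = TRUE), ins_seq = "")
  vdr <- make_vd(df)
  for (pos in sample(0:210, 40)) {
    brute <- which(vdr$variants$pos < pos &
                   pos < vdr$variants$pos + vdr$variants$del_len)
    expect_equal(spanning_deletions(vdr, pos), brute)
  }
})

test_that("decode_forward applies deletions, insertions and substitutions", {
  ref <- pack_reference("AACGTT")
  vd_del <- make_vd(data.frame(kind = "DEL", pos = 2L, del_len = 2L, ins_seq = ""))
  expect_equal(decode_forward(ref, vd_del, 1, 3, path = 1L), "ATT")
  vd_ins <- make_vd(data.frame(kind = "INS", pos = 2L, del_len = 0L, ins_seq = "GG"))
  expect_equal(decode_forward(ref, vd_ins, 1, 4, path = 1L), "AGGC")
  vd_snp <- make_vd(data.frame(kind = "SNP", pos = 2L, del_len = 1L, ins_seq = "G"))
  expect_equal(decode_forward(ref, vd_snp, 1, 3), "ACG")  # absent: identity
  expect_equal(decode_forward(ref, vd_snp, 1, 3, path = 1L), "AGG")
  # running past the end flags the short result
  r <- decode_forward(ref, vd_del, 4, 4, path = 1L)
  expect_equal(as.character(r), "TT")
  expect_true(attr(r, "hit_end"))
})

test_that("decode_backward mirrors decode_forward through deletions and insertions", {
  ref <- pack_reference("AACGTT")
  vd_del <- make_vd(data.frame(kind = "DEL", pos = 2L, del_len = 2L, ins_seq = ""))
  expect_equal(decode_backward(ref, vd_del, 4, 2, path = 1L), "AA")
  vd <- make_vd(data.frame(kind = "SNP", pos = 0L, del_len = 1L, ins_seq = "C"))
  expect_equal(decode_backward(ref, vd, 3, 3), "AAC")
  vd_ins <- make_vd(data.frame(kind = "INS", pos = 2L, del_len = 0L, ins_seq = "GG"))
  expect_equal(decode_backward(ref, vd_ins, 2, 2, path = 1L, end_offset = 1L),
               "AG")  # ref char 1 then the first inserted char
  r <- decode_backward(ref, vd_ins, 1, 5)
  expect_equal(as.character(r), "A")
  expect_true(attr(r, "hit_begin"))
})

test_that("forward decode reproduces explicitly constructed haplotypes; backward agrees", {
  for (seed in 1:3) {
    coll <- rand_collection(seed + 600, ref_len = 1200L, n_samples = 3L,
                            snp_rate = 0.02, del_rate = 0.005,
                            ins_rate = 0.005, sv_rate = 0.002)
    fa <- read_fasta(coll$fasta)
    vc <- read_vcf_min(coll$vcf, fa$chrom_table)
    vd <- build_variant_database(normalize_variants(vc, fa$ref, fa$chrom_table))
    for (h in seq_along(coll$hap_names)) {
      path <- which(coll$occ[, h])
      dec <- decode_haplotype(coll, h)[[1]]
      got <- decode_forward(fa$ref, vd, 0, nchar(dec$text) + 10L, path = path,
                            chrom_table = fa$chrom_table)
      expect_equal(as.character(got), dec$text)
    }
    # backward equals the reverse-read suffix of forward (ref-char ends)
    set.seed(seed)
    h <- sample(length(coll$hap_names), 1L)
    path <- which(coll$occ[, h])
    full <- decode_forward(fa$ref, vd, 0, 10000L, path = path,
                           chrom_table = fa$chrom_table)
    dec <- decode_haplotype(coll, h)[[1]]
    ref_ends <- which(dec$offset == 0L)
    ref_ends <- ref_ends[ref_ends >= 5L]
    for (i in 1:10) {
      ei <- sample(ref_ends, 1L)   # window ending before a ref char
      n <- sample.int(min(ei - 1L, 40L), 1L)
      want <- substr(dec$text, ei - n, ei - 1L)
      got <- decode_backward(fa$ref, vd, dec$pre[ei], n, path = path)
      expect_equal(as.character(got), want)
    }
    unlink(coll$dir, recursive = TRUE)
  }
})
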
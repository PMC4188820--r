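# Fixtures built in code: the two-haplotype toy collection (reference
# ACGTACG with one SNP T->A at chr1:4, carried by haplotype 1 only) and
# small random collections.

toy_files <- function(dir = tempfile("toy")) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "r.fa")
  vcf <- file.path(dir, "v.vcf")
  writeLines(c(">chr1", "ACGTACG"), fa)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=7>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    paste(c("chr1", "4", ".", "T", "A", ".", ".", ".", "GT", "1|0"),
          collapse = "\t")), vcf)
  list(fasta = fa, vcf = vcf, dir = dir)
}

toy_index <- function(k = 3L, sparsity = 1L, E_max = 16L) {
  tf <- toy_files()
  on.exit(unlink(tf$dir, recursive = TRUE))
  build_index(tf$fasta, tf$vcf,
              params = index_params(k = k, sparsity = sparsity, E_max = E_max,
                                    lut_width = 2L, min_seed = 1L))
}

# a small in-memory variant database over a given reference string
make_vd <- function(df) {
  df$ins_seq <- as.character(df$ins_seq)
  df$vcf_chrom <- "chr1"
  df$vcf_pos <- df$pos + 1L
  df$record <- seq_len(nrow(df))
  df$allele <- 1L
  build_variant_database(df)
}

rand_collection <- function(seed, ref_len = 3000L, n_samples = 4L, ...) {
  generate_collection(collection_spec(ref_len = ref_len,
                                      n_samples = n_samples,
                                      rng_seed = seed, ...))
}

expanded_key <- function(df) {
  paste(df$query_id, df$chrom, df$pre, df$offset, df$hap, df$mismatches,
        sep = "|")
}
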
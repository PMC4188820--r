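# hapfind

Searching a *collection* of genomes — a reference plus the phased variants
of many individuals — for all occurrences of a DNA pattern is the core step
of aligning reads against a population rather than a single genome.
`hapfind` builds a variant-aware k-mer index over such a collection and
answers **locate queries, exact or with up to q mismatches**, reporting for
every occurrence its reference-anchored position *and the exact set of
haploid genomes that carry it*. The collection is never materialized: the
index is built straight from the FASTA reference and a phased VCF, for
anyone who needs population-resolved pattern lookup (read anchoring,
probe/primer uniqueness, allele-specific sequence queries) on desk-scale
regions.

## The method in brief

The collection is the implicit set of haplotype sequences
`H = {h₁, …, h_{2n}}` defined by reference `R`, variant database
`V = {v_i = (type, pos, del_len, ins)}` and per-variant presence
bit-vectors `BV_i ∈ {0,1}^{2n}`. The index enumerates every k-mer of every
`h ∈ H` as a *decoding recipe* — a reference start plus an evidence list
`E = ((v_{i₁}, e₁), (v_{i₂}, e₂), …)`, `e_j ∈ {0,1}` flagging each
influencing variant present or absent — kept only if some haplotype carries
exactly that combination, and stores the recipes in four lexicographically
sorted subarrays with lookup tables (pure-reference / consecutive-evidence
/ insertion-internal / irregular). A query of length `m` is answered
seed-and-extend: locate the seed (prefix of length `min(m, k)`) by binary
search, decode each hit forward along every consistent variant path, and at
the pattern end resolve the accumulated evidence against the bit-vectors,

```
R ← 1^{2n};  for (v, e) in E:  R ← R & (e ? BV_v : ~BV_v)
```

reporting `(pre, R)` whenever `R ≠ 0`. For `q` mismatches the pattern is
split into `q+1` segments of length `⌊m/(q+1)⌋` — by pigeonhole one is
error-free — each searched exactly and extended bidirectionally under the
mismatch budget. A sparse mode keeps only every `d`-th entry of the two big
subarrays (plus entries anchored on a deletion/insertion) and recovers the
rest through `d` shifted seeds with leftward decoding. Bit-vectors are
compressed through a dictionary of unique 192-bit chunks; per-variant rows
decompress on the fly.

## A worked example

```r
library(hapfind)
coll <- generate_collection(collection_spec(ref_len = 4000L, n_samples = 4L,
                                            rng_seed = 7L))
idx <- build_index(coll$fasta, coll$vcf,
                   params = index_params(k = 25, lut_width = 8))
idx
#> <hapfind_index> k = 25  sparsity = 1
#>   reference: 4000 bp in 1 chromosome(s); 59 variants; 8 haplotypes
#>   subarray sizes: 3901 / 998 / 32 / 10
#>   bit-vector dictionary: 25 chunks of 192 bits

qs <- generate_query_set(coll, 3, len_range = c(60L, 80L),
                         err_range = c(1L, 1L), rng_seed = 9L)
search_patterns(idx, qs, q = 1)[, c("query_id", "chrom", "pre", "offset",
                                    "mismatches", "haplotype_count")]
#>  query_id chrom  pre offset mismatches haplotype_count
#>         1  chr1 1843      0          1               4
#>         2  chr1 3337      0          1               8
#>         3  chr1 3304      0          1               7
```

Each row is one occurrence: query 1 — an excerpt of haplotype `S001_2` with
one planted substitution — is found at preceding position 1843 of `chr1`
(the last reference character before the match; 0 would mean a chromosome
start), on a reference character (`offset` 0; a value `j ≥ 1` would mean
the match starts at the `j`-th character of an insertion), with 1 mismatch,
in 4 of the 8 haploid genomes (`S001_2,S002_1,S003_2,S004_2` — exactly the
carriers of the variant combination along that path). Query 2's window is
variant-free, so all 8 haplotypes contain it.

The same pipeline is scriptable:

```sh
Rscript inst/cli/hapfind.R build --ref ref.fa --vcf variants.vcf --k 30 --sparsity 1 --out idx.hfx
Rscript inst/cli/hapfind.R query --index idx.hfx --patterns reads.fq --format fastq \
        --max-mismatches 3 --out matches.tsv
Rscript inst/cli/hapfind.R selftest --grid small
```

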
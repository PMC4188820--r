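---
title: "Indexing a haplotype collection: the model behind hapfind"
author: "hapfind authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing a haplotype collection: the model behind hapfind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapfind)
```

## The problem and the representation

Modern genome repositories do not store a thousand genomes as a thousand
FASTA files. They store one reference genome plus a variant database: for
every site, the alternative alleles, and for every sample, a phased genotype
saying which alleles each of its two haploid chromosome sets carries. This
compact representation is sufficient to reconstruct every haplotype
sequence, and `hapfind` builds its search index directly from it — never
materializing the collection — while still answering the *locate* query
exactly: report every position (relative to the reference) where a pattern
occurs, together with the identity of every haploid genome that contains
that occurrence, in exact or `q`-mismatch (Hamming) matching.

Four structures make up the index:

* **REF** — the reference, 4 bits per character (A/C/G/T/N), chromosomes
  concatenated into one 0-based global coordinate space.
* **VD** — the variant database. Each VCF ALT becomes one typed variant:
  SNP, DEL, INS, or SV (a combined deletion + insertion). We store the
  *effect position* (first affected reference character; for an insertion
  the character before which it inserts), the deletion length and the
  inserted string, ordered by position with a coarse lookup table. A
  companion inverse-deletion list orders every DEL/SV by its *resulting*
  position `pos + del_len`, which is what leftward decoding needs.
* **BV** — one presence bit-vector per variant over all haploid genomes
  (2 per phased diploid sample), compressed through a dictionary of unique
  fixed-width chunks (192 bits by default, configurable): spatially close
  variant configurations repeat across individuals, so the vocabulary stays
  small while random access remains one table lookup per chunk.
* **kMA** — the k-mer array: every k-length string that occurs in *any*
  haplotype, stored not as text but as a decoding recipe — a reference
  start position plus an *evidence list* of (variant, present/absent) flags
  describing the path that produces it. Entries are split into four
  lexicographically sorted subarrays: pure-reference k-mers (position
  only), variant k-mers with consecutive evidence (≤ `E_max` flags),
  the same but starting inside an inserted sequence (with a 1-based
  offset), and everything else (explicit variant/flag pairs). A per-subarray
  lookup table over the leading characters narrows every binary search.

A k-mer candidate is kept only if at least one haploid genome actually
carries its exact variant combination (checked against BV); the pure
reference path at a position is kept only while some haplotype is
variant-free there. This *presence filter* is what keeps the array close to
the biological content of the collection rather than the combinatorial
closure of the variant database.

## Searching

Queries follow seed-and-extend. The seed is the pattern prefix of length
`p = min(|P|, k)`; it is located by LUT-narrowed binary search in each of
the four subarrays, comparing against k-mer text reconstructed on the fly.
Each hit is *partially decoded* — the cursor advances `p` characters along
the entry's stored path without re-comparing characters — and then extended
character by character to the end of the pattern. At every variant the
extension branches: introduce it (if its characters fit the pattern) or
skip it, flagging the evidence either way; a variant lying inside an
already-applied deletion is skipped silently unless it deletes beyond it.
When the pattern is exhausted, the evidence list is resolved against the
bit-vectors: starting from all-ones, AND each flagged-present variant's
vector and each flagged-absent variant's complement. An empty result kills
the path; otherwise `(position, haplotype set)` is reported. Deletions
*spanning* the match start are constrained absent — on a haplotype carrying
such a deletion the start character does not exist.

Reported coordinates follow the VCF-style anchor convention: `pre` is the
1-based position of the last reference character strictly before the match
(0 at a chromosome start), and matches starting inside an inserted sequence
carry the anchor's `pre` plus a 1-based offset into the insertion.

**Record canonicalization.** Several routes (dense seeds, shifted seeds,
different pigeonhole segments) can rediscover one occurrence. Every
completed path is therefore re-walked once from its match start along its
present-variant set, rebuilding the evidence list in canonical forward
order and recounting mismatches; records identical in (position, offset,
evidence) merge, keeping the minimum mismatch count. Variants anchored
exactly at the match start that cannot change the matched text — an
insertion ending at the start, a deletion ending at the start — are left
unconstrained, so equivalent routes produce literally the same record. The
per-haplotype expansion of the results (the unit every equivalence test
compares) is unaffected by this merging.

**Sparse mode.** With sparsity `d > 1` the two largest subarrays keep only
entries whose reference start is a multiple of `d` — the sampled-suffix-
array idea — plus every entry beginning with a present DEL/INS/SV anchored
at its start (those entries are the only representation of windows that
start right after a deletion, or right after/inside an insertion, and they
cannot be recovered by shifting). The search then additionally looks up the
pattern substrings starting at offsets `1..d-1`, and verified hits are
decoded *leftward* to check the skipped prefix, using the inverse-deletion
list to jump over present deletions. Walking right from any match start,
each of `d` consecutive haplotype positions either advances one reference
character (so `d` consecutive start positions cover a multiple of `d`),
enters an insertion (unsampled subarray), or crosses a deletion (kept by
the anchor exception) — which is why the sampled index misses nothing.

**Approximate mode.** For `q` mismatches the pattern is split into `q + 1`
disjoint segments of length `floor(m/(q+1))`; by pigeonhole at least one
segment of any `q`-mismatch occurrence is error-free, so each segment is
searched exactly and extended in both directions under the global mismatch
budget (mismatches are forbidden inside the seeding segment itself —
occurrences with errors there are found through another segment). Pattern
characters outside A/C/G/T (for example N) never match anything, including
N in the collection. Insertions and deletions along a path are not errors —
they are alternative exact paths; the mismatch model is substitutions only,
and an inserted character mismatching the pattern consumes budget exactly
like a reference character.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 30 | maximum seed length; the single construction-time parameter of the dense scheme (typical useful range 25–45; longer seeds mean rarer hits but a larger array) |
| `sparsity` (`d`) | 1 | keep 1/`d` of the two big subarrays; queries probe `d` shifted seeds |
| `E_max` | 16 | flags-per-entry threshold separating the bit-vector subarrays from the explicit-pair subarray; placement only — answers are provably invariant (tested for `E_max` ∈ {1, 4, 16}) |
| `lut_width` | 12 | characters covered by each subarray's lookup table; the effective width is capped by `ceil(log4(2·entries))` so a toy index never allocates a 4^12 table |
| `chunk_bits` | 192 | bit-vector dictionary chunk width |
| `min_seed` | 8 | top-level queries shorter than this are refused (they flood the index with matches); pass `min_seed = 1` to accept anything |
| `path_cap`, `node_cap` | 2^20, 10^6 | guards against variant-path explosion during construction and extension; exceeded caps abort with a diagnostic rather than silently truncating |

## The synthetic generator and what passing tests mean

`generate_collection()` draws a uniform random reference (with optional N
runs), places SNPs (1/100 bp), deletions and insertions (1/1000 bp each),
and SVs (1/2000 bp) — about 10% of SNP sites are multiallelic — and assigns
phased genotypes with Beta(0.5, 1.5)-distributed carrier frequencies, so
most variants are rare and the chunk dictionary's sharing is actually
exercised. Genotype assignment keeps each haplotype a single unambiguous
path: no two carried variants share an effect position and no carried
variant starts strictly inside another carried deletion (overlaps *across*
haplotypes are allowed and exercise the path enumeration). Query sets are
mutated excerpts: uniform haplotype, start, and length (100–200 bp by
default), with 0–5 substitutions; N-containing excerpts are rejected.

Ground truth is a naive scan over the explicitly decoded haplotype strings
(via `Biostrings` pattern matching — machinery entirely independent of the
index), keeping every window within Hamming distance `q` together with the
projection of its first character. The acceptance suite asserts *exact
set equality* between the expanded index results and this oracle across
dozens of random collections (2–20 kb, 4–64 haplotypes) for `q` ∈ 0..5,
plus sparse/dense equality, k-mer-content completeness against brute-force
enumeration, store losslessness, pigeonhole soundness, serialization
fidelity, and byte-level determinism. Problem sizes (50/20/3 collections
with 200/100/50 queries for the exact/approximate/sparse properties;
10,000-variant × 500-haplotype matrices; 10,000 pigeonhole patterns) were
chosen as the smallest scales at which every code path — multi-chunk rows,
multiallelic sites, nested deletions, insertion-internal matches,
chromosome boundaries — occurs many times per run.

What passing does **not** show: the generator has uniform base composition,
no linkage structure, no mutation spectrum, and no sequencing-error model,
so the tests certify *correctness* of the combinatorics, not performance or
variant-calling realism on real cohorts. Real-data properties the model
does cover (phased diploids, multiallelic records, anchor-style VCF indels,
N runs) are generated deliberately.

## Numerical and design choices

* **Coordinates.** Internally everything is 0-based and global; the first
  affected character (not the VCF anchor) is the variant's position, which
  is the only convention under which the extension's cursor comparison
  `vt.pos = pos` is self-consistent for all four variant types. Reports
  convert back to per-chromosome 1-based preceding positions.
* **Offsets are 1-based.** A k-mer or match starting at the j-th inserted
  character carries offset `j`; offset 0 means a reference character. The
  projection of a SNP's alternative character is the reference position it
  replaces, offset 0.
* **k-mers never cross chromosome boundaries**, and k-mers shorter than `k`
  (truncated by a chromosome end) are not stored; patterns shorter than `k`
  are still found anywhere a full `k` window exists. k-mers beginning with
  N are filtered out; N elsewhere in a k-mer is kept and simply never
  matches a query character.
* **Shifted seeds probe all four subarrays.** Probing the insertion-offset
  subarray too is a completeness-safe superset at negligible cost.
* **Ties and duplicates.** Subarrays sort by (text, position, offset,
  evidence); exact duplicates are removed at build time. Query-side records
  deduplicate on (position, offset, canonical evidence).
* **Degenerate inputs.** Empty VCFs build a pure-reference index; empty
  evidence lists resolve to "present in every haploid genome"; a variant
  listed twice with conflicting flags resolves to the empty set with a
  trace message; all-zero occurrence rows are legal (the variant is then
  carried by nobody and every path requiring it is filtered).
* **Container.** The on-disk index is a versioned container (magic bytes,
  format version, length, Adler-32 checksum) around a serialized payload of
  all sections; round-trip query fidelity is the contract, bit-layout
  compatibility with any other tool is not.

## Known limitations

* Matching is Hamming only; edit-distance (indel-tolerant) matching is out
  of scope.
* A pattern shorter than `k` that occurs only within the last `k - 1`
  positions of a chromosome (or of a haplotype tail) cannot be seeded,
  because only full-length k-mers are stored. Queries at or above `k`
  characters — the intended regime — are unaffected.
* Construction enumerates variant paths exhaustively within each k-window;
  pathological densities (every position polymorphic) hit the `path_cap`
  guard rather than completing.
* Overlapping variants co-carried by one haplotype (which the generator
  never emits, matching the phased-VCF model) would make a haplotype an
  ambiguous path; the search's extension handles overlap *paths* by the
  delete-beyond rule and resolves them against the bit-vectors, which
  yields the empty set under this model.
* With `sparsity > 1` **and** mismatches, shifted seeds must still fit
  inside an error-free segment, so configurations where `d` approaches the
  segment length `floor(m/(q+1))` degrade; large `d` with `q > 3` triggers
  an advisory warning at query time.

## A worked round trip

```{r roundtrip}
coll <- generate_collection(collection_spec(ref_len = 4000L, n_samples = 4L,
                                            rng_seed = 7L))
idx <- build_index(coll$fasta, coll$vcf,
                   params = index_params(k = 25, lut_width = 8))
idx
qs <- generate_query_set(coll, 20, err_range = c(0L, 2L), rng_seed = 8L)
got <- expand_matches(search_patterns(idx, qs, q = 2))
want <- oracle_scan(coll, qs, q = 2)
equivalence_check(got, want)
```

The same loop over a (k, sparsity, q) grid is packaged as
`cmd_selftest()`.
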
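# The k-mer array: enumeration of every k-mer occurring on any variant path,
# categorization into the four subarrays, presence filtering, sorting, lookup
# tables, and sparsification.

#' Index construction parameters
#'
#' @param k maximum seed length (the single construction-time parameter of
#'   the basic scheme); default 30.
#' @param sparsity sampling step `d >= 1`; the two largest subarrays keep only
#'   entries whose reference start is a multiple of `d` (plus the entries
#'   beginning with a present DEL/INS/SV anchored at the start).
#' @param E_max maximum number of consecutive evidences kept in the
#'   bit-vector subarrays (entries needing more, or non-consecutive variant
#'   ids, go to the explicit-pair subarray). Placement only: answers are
#'   invariant to `E_max`.
#' @param lut_width number of leading characters indexed by each subarray's
#'   lookup table (effective width is capped so the table never dominates a
#'   small index).
#' @param chunk_bits bit-vector dictionary chunk width.
#' @param path_cap abort threshold for variant-path explosion per start.
#' @param node_cap abort threshold for extension nodes per seed hit.
#' @param min_seed minimum top-level query seed length accepted by the
#'   command-line query path.
#' @return validated parameter list.
#' @export
index_params <- function(k = 30L, sparsity = 1L, E_max = 16L, lut_width = 12L,
                         chunk_bits = 192L, path_cap = 2^20, node_cap = 1e6,
                         min_seed = 8L) {
  k <- as.integer(k); sparsity <- as.integer(sparsity)
  E_max <- as.integer(E_max); lut_width <- as.integer(lut_width)
  stopifnot(k >= 1L, sparsity >= 1L, E_max >= 1L, lut_width >= 1L,
            chunk_bits >= 1L)
  if (k < lut_width)
    stop("k (", k, ") must be >= lut_width (", lut_width, ")")
  list(k = k, sparsity = sparsity, E_max = E_max, lut_width = lut_width,
       chunk_bits = as.integer(chunk_bits), path_cap = path_cap,
       node_cap = node_cap, min_seed = as.integer(min_seed))
}

#' Enumerate all k-mer path candidates
#'
#' Walks every reference start, expanding every combination of variants that
#' influences the window (each path records its evidence list), plus one
#' candidate per internal offset of every insertion. k-mers beginning with
#' `N` are dropped and k-mers never cross a chromosome boundary. The pure
#' reference path at each start yields the category-0 candidate; its all-zero
#' evidence is reconstructed at query time rather than stored.
#'
#' @param ref `packed_reference`; @param chrom_table chromosome table.
#' @param vd `variant_db`; @param params from [index_params()].
#' @return candidate list: `text`, `pos_ref` (0-based), `offset` (1-based in
#'   insertion, 0 otherwise), flattened evidence arrays (`ev_*`, 0-based
#'   variant ids) and spanning-deletion arrays (`sp_*`) used by the presence
#'   filter.
#' @export
enumerate_kmer_paths <- function(ref, chrom_table, vd, params) {
  a <- vd_args(vd)
  cst <- c(chrom_table$global_start, ref$length)
  cpp_enumerate_kmers(ref$codes, ref$length, as.integer(cst),
                      a$pos, a$del_len, a$kind, a$ins, a$inv_res, a$inv_id,
                      a$max_del, params$k, params$path_cap)
}

#' Categorize candidates into the four subarrays
#'
#' Category 0: no evidence (pure reference). 1: consecutive variant ids,
#' at most `E_max` evidences, start on a reference character. 2: as 1 but
#' starting inside an insertion. 3: everything else (non-consecutive ids or
#' more than `E_max` evidences).
#'
#' @param cands candidate list from [enumerate_kmer_paths()].
#' @param params from [index_params()].
#' @return integer vector of categories (0--3).
#' @export
categorize_entries <- function(cands, params) {
  n <- length(cands$pos_ref)
  cat <- integer(n)
  for (i in seq_len(n)) {
    len <- cands$ev_len[i]
    if (len == 0L) { cat[i] <- 0L; next }
    ids <- cands$ev_vt[(cands$ev_ptr[i] + 1L):(cands$ev_ptr[i] + len)]
    consec <- (max(ids) - min(ids) + 1L) == len
    small <- len <= params$E_max
    if (consec && small) cat[i] <- if (cands$offset[i] > 0L) 2L else 1L
    else cat[i] <- 3L
  }
  cat
}

#' Presence-filter candidates
#'
#' A candidate is kept only if at least one haploid genome carries exactly
#' its flagged variant combination, with spanning deletions (and, for the
#' pure-reference candidates, every variant starting inside the window)
#' required absent. Applies to all four categories.
#'
#' @param cands candidate list; @param occ occurrence matrix (or a
#'   `chunk_dict`, decompressed on the fly); @param vd `variant_db`;
#'   @param params from [index_params()].
#' @return logical keep vector.
#' @export
presence_filter <- function(cands, occ, vd, params) {
  if (inherits(occ, "chunk_dict")) occ <- decompress_bitvectors(occ)
  cpp_presence_keep(occ, as.integer(vd$variants$pos),
                    as.integer(cands$pos_ref), as.integer(cands$offset),
                    as.integer(cands$ev_ptr), as.integer(cands$ev_len),
                    as.integer(cands$ev_vt), as.integer(cands$ev_flag),
                    as.integer(cands$sp_ptr), as.integer(cands$sp_len),
                    as.integer(cands$sp_vt), params$k)
}

# flatten a subset of candidates into a subarray structure (no lut yet)
cand_subset <- function(cands, idx) {
  ev_ptr <- integer(length(idx)); ev_len <- cands$ev_len[idx]
  ev_vt <- integer(sum(ev_len)); ev_flag <- integer(sum(ev_len))
  p <- 0L
  for (j in seq_along(idx)) {
    i <- idx[j]
    ev_ptr[j] <- p
    if (ev_len[j] > 0L) {
      src <- (cands$ev_ptr[i] + 1L):(cands$ev_ptr[i] + ev_len[j])
      ev_vt[(p + 1L):(p + ev_len[j])] <- cands$ev_vt[src]
      ev_flag[(p + 1L):(p + ev_len[j])] <- cands$ev_flag[src]
      p <- p + ev_len[j]
    }
  }
  first_vt <- ifelse(ev_len > 0L, ev_vt[ev_ptr + 1L], -1L)
  list(pos_ref = as.integer(cands$pos_ref[idx]),
       offset = as.integer(cands$offset[idx]),
       first_vt = as.integer(first_vt),
       ev_ptr = ev_ptr, ev_len = as.integer(ev_len),
       ev_vt = ev_vt, ev_flag = ev_flag)
}

# lookup table over the first `w` characters of the sorted texts
build_lut <- function(texts, w) {
  n <- length(texts)
  if (w < 1L) return(list(lut = integer(), lut_width = 0L))
  ids <- suppressWarnings(
    strtoi(chartr("ACGT", "0123", substr(texts, 1L, w)), base = 4L))
  ids[grepl("[^ACGT]", substr(texts, 1L, w))] <- NA_integer_
  ok <- which(!is.na(ids))
  f <- ids[ok]
  # first entry index (0-based) whose prefix id >= p, for p = 0..4^w
  cnt <- findInterval(seq.int(0L, 4^w) - 0.5, f)
  lut <- ifelse(cnt < length(ok), ok[cnt + 1L] - 1L, n)
  list(lut = as.integer(lut), lut_width = as.integer(w))
}

#' Assemble the four sorted k-mer subarrays
#'
#' Deduplicates candidates, sorts each subarray in lexicographic order of the
#' k-mer texts (ties by reference position, offset, first variant), and
#' builds a per-subarray lookup table over the leading characters (A/C/G/T
#' alphabet; entries with `N` in the prefix are reached by the binary-search
#' fallback).
#'
#' @param cands candidate list (already presence-filtered, or pass `keep`).
#' @param params from [index_params()].
#' @param keep optional logical filter from [presence_filter()].
#' @return list of 4 subarrays (`pos_ref`, `offset`, `first_vt`, flattened
#'   evidence, `lut`, `lut_width`), in category order 0--3.
#' @export
build_kmer_array <- function(cands, params, keep = NULL) {
  n <- length(cands$pos_ref)
  idx <- if (is.null(keep)) seq_len(n) else which(keep)
  cat <- categorize_entries(cands, params)
  evkey <- vapply(seq_len(n), function(i) {
    if (cands$ev_len[i] == 0L) return("")
    r <- (cands$ev_ptr[i] + 1L):(cands$ev_ptr[i] + cands$ev_len[i])
    paste(cands$ev_vt[r], cands$ev_flag[r], sep = ":", collapse = ",")
  }, character(1L))
  out <- vector("list", 4L)
  for (cc in 0:3) {
    sel <- idx[cat[idx] == cc]
    if (length(sel)) {
      o <- order(cands$text[sel], cands$pos_ref[sel], cands$offset[sel],
                 evkey[sel], method = "radix")
      sel <- sel[o]
      dup <- duplicated(data.frame(t = cands$text[sel], p = cands$pos_ref[sel],
                                   o = cands$offset[sel], e = evkey[sel]))
      sel <- sel[!dup]
    }
    sub <- cand_subset(cands, sel)
    w_eff <- min(params$lut_width,
                 max(1L, ceiling(log(max(2L * length(sel), 4L), base = 4L))))
    lt <- build_lut(cands$text[sel], w_eff)
    sub$lut <- lt$lut
    sub$lut_width <- lt$lut_width
    out[[cc + 1L]] <- sub
  }
  out
}

#' Sparsify the k-mer subarrays
#'
#' Keeps, in subarrays 0 and 1, only entries whose k-mer reference start is a
#' multiple of `d`; subarray 1 additionally keeps every entry that begins
#' with a present DEL/INS/SV anchored exactly at the start. Subarrays 2 and 3
#' are unchanged; `d = 1` is the identity. Lookup tables are rebuilt.
#'
#' @param kma list of 4 subarrays; @param d sparsity; @param index_like a
#'   `hapfind_index` or list providing `ref`, `chrom_table`, `vd` (needed to
#'   reconstruct texts for the rebuilt lookup tables); @param params
#'   parameters.
#' @return sparsified subarray list.
#' @export
sparsify <- function(kma, d, index_like, params) {
  d <- as.integer(d)
  stopifnot(d >= 1L)
  if (d == 1L) return(kma)
  vd <- index_like$vd
  for (cc in 0:1) {
    sub <- kma[[cc + 1L]]
    n <- length(sub$pos_ref)
    if (!n) next
    keep <- (sub$pos_ref %% d) == 0L
    if (cc == 1L) {
      fv <- sub$first_vt
      anchored <- fv >= 0L &
        sub$ev_flag[sub$ev_ptr + 1L] == 1L &
        vd$variants$pos[fv + 1L] == sub$pos_ref &
        vd$variants$kind[fv + 1L] != "SNP" &
        sub$offset == 0L
      keep <- keep | anchored
    }
    idx <- which(keep)
    cs <- cand_subset(list(pos_ref = sub$pos_ref, offset = sub$offset,
                           ev_ptr = sub$ev_ptr, ev_len = sub$ev_len,
                           ev_vt = sub$ev_vt, ev_flag = sub$ev_flag), idx)
    cs$lut <- integer()
    cs$lut_width <- 0L
    texts <- subarray_texts(index_like, cs, params$k)
    lt <- build_lut(texts, if (sub$lut_width > 0L) sub$lut_width else params$lut_width)
    cs$lut <- lt$lut
    cs$lut_width <- lt$lut_width
    kma[[cc + 1L]] <- cs
  }
  kma
}

# reconstruct the k-mer texts of a subarray (decoding recipes -> sequence)
subarray_texts <- function(index_like, sub, L) {
  a <- vd_args(index_like$vd)
  cst <- c(index_like$chrom_table$global_start, index_like$ref$length)
  cpp_entry_texts(index_like$ref$codes, index_like$ref$length, as.integer(cst),
                  a$pos, a$del_len, a$kind, a$ins, a$inv_res, a$inv_id,
                  a$max_del, sub, as.integer(L))
}

#' Reconstruct the k-mer texts of one subarray of an index
#'
#' @param index a `hapfind_index`; @param subarray 0--3.
#' @return character vector (lexicographically non-decreasing).
#' @export
reconstruct_kmers <- function(index, subarray) {
  subarray_texts(index, index$kma[[subarray + 1L]], index$params$k)
}

#' Locate the entry interval whose k-mers start with a seed
#'
#' LUT-narrowed binary search over the reconstructed k-mer texts; returns the
#' maximal interval of entries having `seed` as a prefix (empty interval if
#' none).
#'
#' @param index a `hapfind_index`; @param subarray 0--3; @param seed seed
#'   string (1 to k characters).
#' @return integer `c(l, r)`: 1-based inclusive bounds, `r < l` when empty.
#' @export
interval_lookup <- function(index, subarray, seed) {
  stopifnot(nchar(seed) >= 1L, nchar(seed) <= index$params$k)
  a <- vd_args(index$vd)
  cst <- c(index$chrom_table$global_start, index$ref$length)
  iv <- cpp_interval_lookup(index$ref$codes, index$ref$length, as.integer(cst),
                            a$pos, a$del_len, a$kind, a$ins, a$inv_res,
                            a$inv_id, a$max_del, index$kma[[subarray + 1L]],
                            seed)
  c(iv[1L] + 1L, iv[2L])
}

#' Build a hapfind index
#'
#' Reads the reference and VCF, normalizes and orders the variants, builds
#' the occurrence bit-vectors and their chunk dictionary, enumerates and
#' filters all k-mer paths, assembles the four sorted subarrays with lookup
#' tables, and sparsifies if requested.
#'
#' @param fasta reference FASTA path.
#' @param vcf phased VCF path.
#' @param ... parameters forwarded to [index_params()] (`k`, `sparsity`,
#'   `E_max`, `lut_width`, `chunk_bits`, ...).
#' @param params alternatively, a ready-made [index_params()] list.
#' @return a `hapfind_index`.
#' @export
build_index <- function(fasta, vcf, ..., params = index_params(...)) {
  fa <- read_fasta(fasta)
  vc <- read_vcf_min(vcf, fa$chrom_table)
  raw_variants <- normalize_variants(vc, fa$ref, fa$chrom_table)
  vd <- build_variant_database(raw_variants)
  occ <- build_occurrence_matrix(vc, vd$variants)
  bv <- compress_bitvectors(occ, params$chunk_bits)
  cands <- enumerate_kmer_paths(fa$ref, fa$chrom_table, vd, params)
  keep <- presence_filter(cands, occ, vd, params)
  kma <- build_kmer_array(cands, params, keep = keep)
  idx <- structure(
    list(version = 1L, params = params, chrom_table = fa$chrom_table,
         ref = fa$ref, vd = vd, bv = bv, hap_names = colnames(occ),
         occ = occ, kma = kma),
    class = "hapfind_index")
  if (params$sparsity > 1L)
    idx$kma <- sparsify(idx$kma, params$sparsity, idx, params)
  idx
}

#' @export
print.hapfind_index <- function(x, ...) {
  cat("<hapfind_index> k =", x$params$k, " sparsity =", x$params$sparsity,
      "\n  reference:", x$ref$length, "bp in", nrow(x$chrom_table),
      "chromosome(s);", x$vd$n, "variants;", length(x$hap_names),
      "haplotypes\n  subarray sizes:",
      paste(vapply(x$kma, function(s) length(s$pos_ref), integer(1L)),
            collapse = " / "),
      "\n  bit-vector dictionary:", ncol(x$bv$vocab), "chunks of",
      x$bv$chunk_bits, "bits\n")
  invisible(x)
}
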
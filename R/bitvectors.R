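# Per-variant haplotype occurrence bit-vectors, chunk-dictionary compression,
# and evidence-list resolution into result haplotype sets.

#' Build the variant occurrence matrix
#'
#' Row `v`, bit `h` is 1 iff haploid genome `h` carries variant `v`. For a
#' phased diploid sample `s` (1-based), haplotype `2s-1` takes the left GT
#' allele and `2s` the right; GT allele value `a > 0` sets the bit of the
#' variant normalized from ALT allele `a` of that record.
#'
#' @param vcf result of [read_vcf_min()].
#' @param variants data.frame from [normalize_variants()] *after* database
#'   ordering (rows must correspond to the final variant ids).
#' @return logical matrix (variants x haplotypes) with haplotype names
#'   `<sample>_1` / `<sample>_2` as column names.
#' @export
build_occurrence_matrix <- function(vcf, variants) {
  samples <- vcf$samples
  nh <- 2L * length(samples)
  hap_names <- if (length(samples))
    as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  else character()
  occ <- matrix(FALSE, nrow(variants), nh,
                dimnames = list(NULL, hap_names))
  if (!length(samples) || !nrow(variants)) return(occ)
  gt <- vcf$gt
  nalt <- vapply(strsplit(vcf$records$alt, ",", fixed = TRUE), length, integer(1L))
  left <- right <- matrix(0L, nrow(gt), ncol(gt))
  for (j in seq_len(ncol(gt))) {
    parts <- strsplit(gt[, j], "|", fixed = TRUE)
    left[, j] <- as.integer(vapply(parts, `[`, character(1L), 1L))
    right[, j] <- as.integer(vapply(parts, `[`, character(1L), 2L))
  }
  if (any(left > nalt) || any(right > nalt)) {
    bad <- which(left > nalt | right > nalt, arr.ind = TRUE)[1L, ]
    stop(sprintf("GT allele index exceeds ALT count in record %d, sample %s",
                 bad[1L], samples[bad[2L]]))
  }
  for (i in seq_len(nrow(variants))) {
    rec <- variants$record[i]
    a <- variants$allele[i]
    occ[i, ] <- as.vector(rbind(left[rec, ] == a, right[rec, ] == a))
  }
  occ
}

#' Compress occurrence bit-vectors through a chunk dictionary
#'
#' Rows are zero-padded to a multiple of `chunk_bits`, split into chunks, and
#' each chunk replaced by the id of its pattern in a vocabulary of unique
#' chunks -- spatially close variant configurations are often shared across
#' individuals, so few distinct chunks occur. Lossless.
#'
#' @param occ logical matrix (variants x haplotypes).
#' @param chunk_bits chunk width in bits (default 192).
#' @return a `chunk_dict` store.
#' @export
compress_bitvectors <- function(occ, chunk_bits = 192L) {
  stopifnot(chunk_bits >= 1L)
  nv <- nrow(occ)
  nh <- ncol(occ)
  ncheck <- max(nh, 1L)
  nchunk <- as.integer(ceiling(ncheck / chunk_bits))
  padded <- matrix(FALSE, nv, nchunk * chunk_bits)
  if (nh) padded[, seq_len(nh)] <- occ
  # one row per (variant, chunk): nv*nchunk x chunk_bits
  pieces <- vector("list", nchunk)
  for (cix in seq_len(nchunk)) {
    cols <- ((cix - 1L) * chunk_bits + 1L):(cix * chunk_bits)
    pieces[[cix]] <- padded[, cols, drop = FALSE]
  }
  allchunks <- do.call(rbind, pieces)  # (chunk index varies slowest)
  keys <- if (nrow(allchunks))
    do.call(paste0, as.data.frame(allchunks + 0L))
  else character()
  vocab_keys <- unique(keys)
  tok <- matrix(match(keys, vocab_keys), nv, nchunk)
  first <- match(vocab_keys, keys)
  vocab <- t(allchunks[first, , drop = FALSE])  # chunk_bits x V
  structure(
    list(n_haplotypes = nh, chunk_bits = as.integer(chunk_bits),
         vocab = vocab, tokens = tok,
         hap_names = colnames(occ)),
    class = "chunk_dict"
  )
}

#' @export
print.chunk_dict <- function(x, ...) {
  cat("<chunk_dict>", nrow(x$tokens), "variants x", x$n_haplotypes,
      "haplotypes;", ncol(x$vocab), "unique", paste0(x$chunk_bits, "-bit"),
      "chunks,", ncol(x$tokens), "token(s)/variant\n")
  invisible(x)
}

#' Fetch one variant's haplotype bit-vector
#'
#' Decompresses the row on the fly from its dictionary tokens.
#'
#' @param store a `chunk_dict`.
#' @param variant_id 1-based variant id.
#' @return logical vector of length `n_haplotypes`.
#' @export
variant_vector <- function(store, variant_id) {
  if (variant_id < 1L || variant_id > nrow(store$tokens))
    stop("variant id ", variant_id, " out of range")
  bits <- as.vector(store$vocab[, store$tokens[variant_id, ]])
  bits[seq_len(store$n_haplotypes)]
}

#' Decompress the full occurrence matrix
#'
#' @param store a `chunk_dict`.
#' @return logical matrix (variants x haplotypes).
#' @export
decompress_bitvectors <- function(store) {
  nv <- nrow(store$tokens)
  occ <- matrix(FALSE, nv, store$n_haplotypes)
  if (!is.null(store$hap_names)) colnames(occ) <- store$hap_names
  nh <- store$n_haplotypes
  for (cix in seq_len(ncol(store$tokens))) {
    lo <- (cix - 1L) * store$chunk_bits + 1L
    hi <- min(cix * store$chunk_bits, nh)
    if (lo > hi) break
    block <- t(store$vocab[seq_len(hi - lo + 1L), store$tokens[, cix], drop = FALSE])
    occ[, lo:hi] <- block
  }
  occ
}

#' Resolve an evidence list into a haplotype set
#'
#' Starts from all ones (an empty evidence list means the sequence is present
#' in every haploid genome) and ANDs each listed variant's bit-vector when
#' flagged present, its complement when flagged absent. A variant listed
#' twice with conflicting flags is a contradiction: the empty set is returned
#' and a trace message emitted.
#'
#' @param store a `chunk_dict`.
#' @param vtList integer vector of variant ids (1-based).
#' @param evList parallel 0/1 flags (1 = introduced).
#' @return logical haplotype set of length `n_haplotypes`.
#' @export
resolve_haplotypes <- function(store, vtList, evList) {
  stopifnot(length(vtList) == length(evList))
  R <- rep(TRUE, store$n_haplotypes)
  if (length(vtList)) {
    dup <- duplicated(vtList)
    if (any(dup)) {
      for (v in unique(vtList[dup])) {
        if (length(unique(evList[vtList == v])) > 1L) {
          message("contradictory evidence for variant ", v,
                  ": empty haplotype set")
          return(rep(FALSE, store$n_haplotypes))
        }
      }
    }
    for (i in seq_along(vtList)) {
      bits <- variant_vector(store, vtList[i])
      R <- R & (if (evList[i]) bits else !bits)
    }
  }
  R
}
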
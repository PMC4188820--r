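# Seed-and-extend search: exact matching, the sparse shifted-seed variant,
# and pigeonhole-partitioned approximate matching.

#' Split a pattern into pigeonhole segments
#'
#' For a pattern of length `m` searched with at most `q` mismatches, at least
#' one of the `q + 1` disjoint consecutive segments of length
#' `floor(m / (q + 1))` is error-free and can serve as an exact seed.
#' Trailing remainder characters belong to no segment; they are still checked
#' during extension.
#'
#' @param m pattern length; @param q maximum mismatches.
#' @return data.frame with `start` (0-based) and `length`.
#' @export
pigeonhole_split <- function(m, q) {
  stopifnot(m >= 1L, q >= 0L)
  L <- m %/% (q + 1L)
  if (L < 1L) stop("pattern too short for q = ", q,
                   " (needs at least ", q + 1L, " characters)")
  data.frame(start = (0:q) * L, length = L)
}

#' Partially decode a k-mer entry
#'
#' Advances `p` characters from the entry's start along its stored evidence
#' path without character comparison (the seed is already known to match),
#' returning the decoding state: encountered variants with presence flags
#' (prefixed by the spanning deletions of the entry anchor, flagged absent),
#' the succeeding reference position and the next variant index.
#'
#' @param index a `hapfind_index`; @param subarray 0--3; @param entry 1-based
#'   entry index; @param p characters to decode (1..k).
#' @return list: `vtList` (1-based ids), `evList`, `pos_curr`, `vt_curr`
#'   (1-based), `text`, and the first-character projection `pre` / `offset`.
#' @export
part_decode <- function(index, subarray, entry, p) {
  sub <- index$kma[[subarray + 1L]]
  stopifnot(entry >= 1L, entry <= length(sub$pos_ref), p >= 1L,
            p <= index$params$k)
  a <- vd_args(index$vd)
  cst <- c(index$chrom_table$global_start, index$ref$length)
  r <- sub$ev_ptr[entry] + seq_len(sub$ev_len[entry])
  st <- cpp_part_decode(index$ref$codes, index$ref$length, as.integer(cst),
                        a$pos, a$del_len, a$kind, a$ins, a$inv_res, a$inv_id,
                        a$max_del, sub$pos_ref[entry], sub$offset[entry],
                        as.integer(sub$ev_vt[r]), as.integer(sub$ev_flag[r]),
                        as.integer(p))
  list(vtList = st$vtList + 1L, evList = st$evList,
       pos_curr = st$pos_curr, vt_curr = st$vt_curr + 1L,
       text = st$text, pre = st$pre, offset = st$offset_out)
}

#' Search patterns in an indexed collection
#'
#' Locate queries with up to `q` mismatches, via the seed-and-extend scheme:
#' the pattern (or each pigeonhole segment, for `q > 0`) is located exactly
#' in the four k-mer subarrays, partially decoded, extended rightward to the
#' pattern end and leftward to the pattern start along every consistent
#' variant path, and each completed path is resolved against the genotype
#' bit-vectors. For a sparse index, seeds shifted by `1..d-1` positions are
#' additionally searched and verified by leftward decoding. Matches are
#' deduplicated by (position, offset, evidence), keeping the minimum mismatch
#' count.
#'
#' @param index a `hapfind_index`.
#' @param patterns character vector, or data.frame with `id` and `seq`
#'   columns (from [read_patterns()]).
#' @param q maximum mismatches (0 = exact).
#' @param rc also search the reverse complement of each pattern (reported
#'   with `/rc` appended to the query id).
#' @param min_seed refuse patterns shorter than this (default taken from the
#'   index parameters; pass 1 to accept any length).
#' @return data.frame of match records: `query_id`, `chrom`, `pre` (1-based
#'   preceding position; 0 at a chromosome start), `offset` (1-based inside
#'   an insertion, 0 otherwise), `mismatches`, `haplotype_count`,
#'   `haplotypes` (comma-joined names), plus list columns `hap_idx` (integer
#'   haplotype indices) and `evidence` (two-column matrices id/flag,
#'   1-based ids).
#' @export
search_patterns <- function(index, patterns, q = 0L, rc = FALSE,
                            min_seed = NULL) {
  if (is.data.frame(patterns)) {
    ids <- as.character(patterns$id)
    seqs <- toupper(patterns$seq)
  } else {
    seqs <- toupper(as.character(patterns))
    ids <- as.character(seq_along(seqs))
  }
  if (is.null(min_seed)) min_seed <- index$params$min_seed
  short <- nchar(seqs) < min_seed
  if (any(short))
    stop("pattern(s) ", paste(ids[short], collapse = ", "),
         " shorter than the minimum seed length (", min_seed,
         "); such queries flood the index with matches")
  if (rc) {
    ids <- c(ids, paste0(ids, "/rc"))
    seqs <- c(seqs, revcomp(seqs))
  }
  a <- vd_args(index$vd)
  cst <- c(index$chrom_table$global_start, index$ref$length)
  res <- cpp_search_batch(index$ref$codes, index$ref$length, as.integer(cst),
                          a$pos, a$del_len, a$kind, a$ins, a$inv_res,
                          a$inv_id, a$max_del, index$kma, index$occ, seqs,
                          as.integer(q), index$params$sparsity,
                          index$params$k, index$params$node_cap)
  n <- length(res$query)
  cidx <- findInterval(res$pre, index$chrom_table$global_start)
  ev <- vector("list", n)
  hap <- vector("list", n)
  for (i in seq_len(n)) {
    r <- res$ev_ptr[i] + seq_len(res$ev_len[i])
    ev[[i]] <- cbind(id = res$ev_vt[r] + 1L, flag = res$ev_flag[r])
    hap[[i]] <- which(res$haps[i, ])
  }
  out <- data.frame(
    query_id = ids[res$query],
    chrom = index$chrom_table$name[cidx],
    pre = res$pre - index$chrom_table$global_start[cidx],
    offset = res$offset,
    mismatches = res$mismatches,
    haplotype_count = vapply(hap, length, integer(1L)),
    stringsAsFactors = FALSE
  )
  out$haplotypes <- vapply(hap, function(h)
    paste(index$hap_names[h], collapse = ","), character(1L))
  out$hap_idx <- I(hap)
  out$evidence <- I(ev)
  out[order(out$query_id, out$chrom, out$pre, out$offset), , drop = FALSE]
}

#' @rdname search_patterns
#' @export
exact_search <- function(index, patterns, ...) {
  search_patterns(index, patterns, q = 0L, ...)
}

#' @rdname search_patterns
#' @export
approximate_search <- function(index, patterns, q, ...) {
  search_patterns(index, patterns, q = q, ...)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

#' Aggregate (deduplicate) match records
#'
#' Canonical key: (query, chromosome, preceding position, offset, sorted
#' evidence pairs). Duplicates are merged keeping the minimum mismatch count
#' and the union of haplotype sets; output is sorted by (query, chromosome,
#' position, offset). Records with the same position but different evidence
#' stay separate.
#'
#' @param records match data.frame(s) as returned by [search_patterns()].
#' @return deduplicated data.frame.
#' @export
aggregate_matches <- function(records) {
  if (!nrow(records)) return(records)
  key <- vapply(seq_len(nrow(records)), function(i) {
    e <- records$evidence[[i]]
    o <- order(e[, 1L])
    paste(records$query_id[i], records$chrom[i], records$pre[i],
          records$offset[i],
          paste(e[o, 1L], e[o, 2L], sep = ":", collapse = ","),
          sep = "|")
  }, character(1L))
  grp <- split(seq_len(nrow(records)), key)
  keep <- vapply(grp, function(ix) ix[which.min(records$mismatches[ix])],
                 integer(1L))
  out <- records[sort(keep), , drop = FALSE]
  for (ix in grp) {
    if (length(ix) > 1L) {
      tgt <- ix[which.min(records$mismatches[ix])]
      row <- which(sort(keep) == tgt)
      u <- sort(unique(unlist(records$hap_idx[ix])))
      out$hap_idx[[row]] <- u
      out$haplotype_count[row] <- length(u)
    }
  }
  rownames(out) <- NULL
  out
}

#' Expand match records into per-haplotype tuples
#'
#' The unit of comparison against the naive-scan oracle: one row per
#' (query, chromosome, preceding position, offset, haplotype), keeping the
#' minimum mismatch count over all records containing the tuple.
#'
#' @param records match data.frame from [search_patterns()].
#' @return data.frame `query_id`, `chrom`, `pre`, `offset`, `hap` (1-based
#'   haplotype index), `mismatches`.
#' @export
expand_matches <- function(records) {
  if (!nrow(records)) {
    return(data.frame(query_id = character(), chrom = character(),
                      pre = integer(), offset = integer(), hap = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  reps <- vapply(records$hap_idx, length, integer(1L))
  df <- data.frame(
    query_id = rep(records$query_id, reps),
    chrom = rep(records$chrom, reps),
    pre = rep(records$pre, reps),
    offset = rep(records$offset, reps),
    hap = unlist(records$hap_idx),
    mismatches = rep(records$mismatches, reps),
    stringsAsFactors = FALSE
  )
  key <- paste(df$query_id, df$chrom, df$pre, df$offset, df$hap, sep = "|")
  best <- tapply(df$mismatches, key, min)
  df <- df[!duplicated(key), , drop = FALSE]
  df$mismatches <- as.integer(best[paste(df$query_id, df$chrom, df$pre,
                                         df$offset, df$hap, sep = "|")])
  df <- df[order(df$query_id, df$chrom, df$pre, df$offset, df$hap), , drop = FALSE]
  rownames(df) <- NULL
  df
}
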
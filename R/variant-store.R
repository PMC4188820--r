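# Reference packing, variant normalization, and the variant database
# (VD + inverse-deletion list) with path-conditional decoding.

KIND_LEVELS <- c("SNP", "DEL", "INS", "SV")

#' Pack a nucleotide sequence into 4-bit codes
#'
#' @param sequence character scalar over A/C/G/T/N (uppercase).
#' @return A `packed_reference` object supporting random access via
#'   [ref_chars()].
#' @export
pack_reference <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  structure(
    list(codes = cpp_pack_ref(sequence), length = nchar(sequence)),
    class = "packed_reference"
  )
}

#' Random access into a packed reference
#'
#' @param ref a `packed_reference`.
#' @param start 0-based global start position.
#' @param n number of characters.
#' @return character scalar of length `n`.
#' @export
ref_chars <- function(ref, start, n) {
  cpp_unpack_ref(ref$codes, ref$length, as.integer(start), as.integer(n))
}

#' @export
print.packed_reference <- function(x, ...) {
  cat("<packed_reference> length", x$length, "\n")
  invisible(x)
}

#' Normalize raw VCF records into typed variants
#'
#' Splits multiallelic records and classifies each ALT against its REF by the
#' shared-anchor convention: equal length-1 alleles give a SNP; a longer REF
#' sharing the anchor base gives a DEL; a longer ALT sharing the anchor an
#' INS; and both sides extending past the anchor an SV (`del_len = |REF| - 1`,
#' `ins_seq` = ALT minus anchor). `effect_pos` is the 0-based global position
#' of the first affected character: the POS itself for a SNP, anchor + 1 for
#' DEL/INS/SV.
#'
#' @param vcf result of [read_vcf_min()].
#' @param ref a `packed_reference` (REF alleles are checked against it).
#' @param chrom_table chromosome table from [read_fasta()].
#' @return data.frame with one row per (record, ALT): `kind`, `pos` (0-based
#'   global effect position), `del_len`, `ins_seq`, `vcf_chrom`, `vcf_pos`,
#'   `record`, `allele` (ALT index within the record).
#' @export
normalize_variants <- function(vcf, ref, chrom_table) {
  rec <- vcf$records
  n <- nrow(rec)
  out <- vector("list", n)
  gstart <- stats::setNames(chrom_table$global_start, chrom_table$name)
  for (i in seq_len(n)) {
    chrom <- rec$chrom[i]
    pos0 <- rec$pos[i] - 1L + gstart[[chrom]]   # 0-based global position of REF[1]
    refa <- rec$ref[i]
    have <- ref_chars(ref, pos0, nchar(refa))
    if (!identical(have, refa)) {
      stop(sprintf(
        "REF allele mismatch at %s:%d: VCF has '%s', reference has '%s'",
        chrom, rec$pos[i], refa, have))
    }
    alts <- strsplit(rec$alt[i], ",", fixed = TRUE)[[1]]
    rows <- lapply(seq_along(alts), function(a) {
      alta <- alts[a]
      if (grepl("[^ACGT]", alta))
        stop(sprintf("unsupported ALT allele '%s' at %s:%d (explicit A/C/G/T sequences only)",
                     alta, chrom, rec$pos[i]))
      nr <- nchar(refa); na <- nchar(alta)
      if (nr == 1L && na == 1L) {
        data.frame(kind = "SNP", pos = pos0, del_len = 1L, ins_seq = alta,
                   stringsAsFactors = FALSE)
      } else if (substr(refa, 1L, 1L) != substr(alta, 1L, 1L)) {
        stop(sprintf("record at %s:%d has no shared anchor base (REF %s, ALT %s); pre-normalize the VCF",
                     chrom, rec$pos[i], refa, alta))
      } else if (na == 1L) {
        data.frame(kind = "DEL", pos = pos0 + 1L, del_len = nr - 1L,
                   ins_seq = "", stringsAsFactors = FALSE)
      } else if (nr == 1L) {
        data.frame(kind = "INS", pos = pos0 + 1L, del_len = 0L,
                   ins_seq = substr(alta, 2L, na), stringsAsFactors = FALSE)
      } else {
        data.frame(kind = "SV", pos = pos0 + 1L, del_len = nr - 1L,
                   ins_seq = substr(alta, 2L, na), stringsAsFactors = FALSE)
      }
    })
    rows <- do.call(rbind, rows)
    rows$vcf_chrom <- chrom
    rows$vcf_pos <- rec$pos[i]
    rows$record <- i
    rows$allele <- seq_along(alts)
    out[[i]] <- rows
  }
  v <- if (n) do.call(rbind, out) else
    data.frame(kind = character(), pos = integer(), del_len = integer(),
               ins_seq = character(), vcf_chrom = character(),
               vcf_pos = integer(), record = integer(), allele = integer(),
               stringsAsFactors = FALSE)
  # deletions must not run past their chromosome
  if (nrow(v)) {
    ce <- chrom_end_of(chrom_table, v$pos)
    bad <- which(v$pos + v$del_len > ce)
    if (length(bad))
      stop(sprintf("variant at %s:%d extends past its chromosome end",
                   v$vcf_chrom[bad[1]], v$vcf_pos[bad[1]]))
  }
  v
}

chrom_end_of <- function(chrom_table, pos) {
  ends <- chrom_table$global_start + chrom_table$length
  idx <- findInterval(pos, chrom_table$global_start)
  ends[idx]
}

#' Build the variant database
#'
#' Orders variants by (effect position, input order), attaches a coarse
#' position lookup table, and derives the inverse-deletion list (every DEL/SV
#' keyed by its resulting position `pos + del_len`) used for leftward
#' decoding.
#'
#' @param variants data.frame from [normalize_variants()].
#' @param lookup_step bucket width of the position lookup table.
#' @return A `variant_db` object.
#' @export
build_variant_database <- function(variants, lookup_step = 64L) {
  ord <- order(variants$pos, seq_len(nrow(variants)), method = "radix")
  v <- variants[ord, , drop = FALSE]
  rownames(v) <- NULL
  n <- nrow(v)
  isdel <- v$kind %in% c("DEL", "SV")
  invdel <- data.frame(
    id = which(isdel),
    res = v$pos[isdel] + v$del_len[isdel]
  )
  invdel <- invdel[order(invdel$res, invdel$id, method = "radix"), , drop = FALSE]
  rownames(invdel) <- NULL
  max_del <- if (any(isdel)) max(v$del_len[isdel]) else 0L
  # coarse lookup: first variant index (1-based) at or after each bucket start
  maxpos <- if (n) max(v$pos) else 0L
  nbuck <- maxpos %/% lookup_step + 2L
  first <- findInterval((seq_len(nbuck) - 1L) * lookup_step - 0.5, v$pos) + 1L
  structure(
    list(variants = v, invdel = invdel, max_del = as.integer(max_del),
         lookup = list(step = as.integer(lookup_step), first = as.integer(first)),
         n = n),
    class = "variant_db"
  )
}

#' @export
print.variant_db <- function(x, ...) {
  cat("<variant_db>", x$n, "variants (",
      paste(sprintf("%s: %d", KIND_LEVELS, tabulate(match(x$variants$kind, KIND_LEVELS), 4L)),
            collapse = ", "), ")\n")
  invisible(x)
}

# C++-facing pieces of a variant_db
vd_args <- function(vd) {
  v <- vd$variants
  list(
    pos = as.integer(v$pos),
    del_len = as.integer(v$del_len),
    kind = as.integer(match(v$kind, KIND_LEVELS) - 1L),
    ins = as.character(v$ins_seq),
    inv_res = as.integer(vd$invdel$res),
    inv_id = as.integer(vd$invdel$id - 1L),
    max_del = as.integer(vd$max_del)
  )
}

#' First variant at or after a reference position
#'
#' Uses the coarse position lookup to bound a binary search, as the database
#' is ordered by effect position.
#'
#' @param vd a `variant_db`.
#' @param pos 0-based global reference position.
#' @return 1-based index of the first variant with effect position `>= pos`;
#'   `vd$n + 1` if there is none.
#' @export
first_variant_at_or_after <- function(vd, pos) {
  stopifnot(pos >= 0)
  b <- pos %/% vd$lookup$step + 1L
  lo <- if (b <= length(vd$lookup$first)) vd$lookup$first[b] else vd$n + 1L
  p <- vd$variants$pos
  while (lo <= vd$n && p[lo] < pos) lo <- lo + 1L
  lo
}

#' Deletions spanning a reference position
#'
#' A DEL/SV spans `pos` when `effect_pos < pos < effect_pos + del_len`
#' (a deletion starting exactly at `pos` does not span it). Found by scanning
#' the inverse-deletion list over resulting positions in
#' `(pos, pos + max_del]`.
#'
#' @param vd a `variant_db`.
#' @param pos 0-based global reference position.
#' @return integer vector of 1-based variant indices, ascending.
#' @export
spanning_deletions <- function(vd, pos) {
  if (vd$max_del <= 0L || nrow(vd$invdel) == 0L) return(integer())
  res <- vd$invdel$res
  lo <- findInterval(pos, res) + 1L  # first res > pos
  ids <- integer()
  i <- lo
  while (i <= length(res) && res[i] <= pos + vd$max_del) {
    v <- vd$invdel$id[i]
    if (vd$variants$pos[v] < pos) ids <- c(ids, v)
    i <- i + 1L
  }
  sort(ids)
}

#' Decode haplotype sequence rightward along a variant path
#'
#' Applies exactly the variants in `path` (1-based indices into the database)
#' in effect-position order, starting at reference position `start`. Variants
#' lying wholly inside an already-applied deletion are skipped; one deleting
#' beyond it is applied from the current point, mirroring the extension
#' semantics of the search.
#'
#' @param ref `packed_reference`; @param vd `variant_db`.
#' @param start 0-based global start; @param n characters wanted.
#' @param path integer vector of present variant ids (1-based).
#' @param chrom_table optional chromosome table; decoding never crosses the
#'   chromosome end (a shorter string with attribute `hit_end = TRUE` is
#'   returned instead).
#' @return character scalar (possibly shorter than `n`).
#' @export
decode_forward <- function(ref, vd, start, n, path = integer(),
                           chrom_table = NULL) {
  cend <- if (is.null(chrom_table)) ref$length else chrom_end_of(chrom_table, start)
  p <- vd$variants$pos
  dl <- vd$variants$del_len
  ins <- vd$variants$ins_seq
  present <- rep(FALSE, vd$n)
  present[path] <- TRUE
  out <- character(0)
  pos <- start
  vt <- first_variant_at_or_after(vd, start)
  count <- 0L
  while (count < n) {
    havev <- vt <= vd$n && p[vt] < cend
    if (!havev || p[vt] > pos) {
      if (pos >= cend) break
      nxt <- if (havev) p[vt] else cend
      take <- min(nxt - pos, n - count)
      out <- c(out, ref_chars(ref, pos, take))
      count <- count + take
      pos <- pos + take
      next
    }
    v <- vt
    if (p[v] == pos) {
      if (present[v]) {
        t <- min(nchar(ins[v]), n - count)
        if (t > 0L) out <- c(out, substr(ins[v], 1L, t))
        count <- count + t
        pos <- p[v] + dl[v]
      }
      vt <- v + 1L
      next
    }
    nw <- p[v] + dl[v]
    if (nw > pos && present[v]) {
      t <- min(nchar(ins[v]), n - count)
      if (t > 0L) out <- c(out, substr(ins[v], 1L, t))
      count <- count + t
      pos <- nw
    }
    vt <- v + 1L
  }
  res <- paste(out, collapse = "")
  if (count < n) attr(res, "hit_end") <- TRUE
  res
}

#' Decode haplotype sequence leftward along a variant path
#'
#' Returns the `n` haplotype characters immediately left of `end` under the
#' given path, using the inverse-deletion list to jump over present
#' deletions. With `end_offset > 0` decoding starts inside the insertion of
#' the path variant anchored at `end`, after its `end_offset`-th inserted
#' character.
#'
#' @inheritParams decode_forward
#' @param end 0-based global position one past the last desired character.
#' @param end_offset 1-based offset into an insertion at `end` (0 = none).
#' @return character scalar, left-to-right (possibly shorter than `n`, with
#'   attribute `hit_begin = TRUE`).
#' @export
decode_backward <- function(ref, vd, end, n, path = integer(), end_offset = 0L,
                            chrom_table = NULL) {
  cbeg <- if (is.null(chrom_table)) 0L else {
    idx <- findInterval(max(end - 1L, 0L), chrom_table$global_start)
    chrom_table$global_start[max(idx, 1L)]
  }
  p <- vd$variants$pos
  dl <- vd$variants$del_len
  ins <- vd$variants$ins_seq
  present <- rep(FALSE, vd$n)
  present[path] <- TRUE
  res_pos <- p + dl
  out <- character(0)  # collected right-to-left
  count <- 0L
  b <- end
  ins_v <- 0L
  ins_o <- 0L
  if (end_offset > 0L) {
    cand <- path[p[path] == end & nchar(ins[path]) >= end_offset]
    if (!length(cand)) stop("end_offset given but no present insertion anchored at `end`")
    ins_v <- cand[1L]
    ins_o <- as.integer(end_offset)
    present[ins_v] <- FALSE  # consumed
  }
  while (count < n) {
    if (ins_v > 0L) {
      if (ins_o == 0L) { b <- p[ins_v]; ins_v <- 0L; next }
      out <- c(out, substr(ins[ins_v], ins_o, ins_o))
      count <- count + 1L
      ins_o <- ins_o - 1L
      next
    }
    # a present variant ending exactly at b? (highest database index first)
    ending <- which(present & res_pos == b)
    if (length(ending)) {
      v <- max(ending)
      if (nchar(ins[v]) > 0L) { ins_v <- v; ins_o <- nchar(ins[v]) }
      else b <- p[v]
      present[v] <- FALSE  # consumed
      next
    }
    if (b <= cbeg) break
    out <- c(out, ref_chars(ref, b - 1L, 1L))
    count <- count + 1L
    b <- b - 1L
  }
  res <- paste(rev(out), collapse = "")
  if (count < n) attr(res, "hit_begin") <- TRUE
  res
}
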
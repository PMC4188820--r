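# Synthetic collections (reference + phased VCF), mutated-excerpt query sets,
# and the brute-force naive-scan oracle that defines ground truth for every
# equivalence test.

#' Specification of a synthetic collection
#'
#' Defaults emulate the study conditions of the verification harness: SNPs at
#' 1/100 bp, deletions and insertions at 1/1000 bp each (1/500 combined),
#' structural variants (long deletion + insertion) at 1/2000 bp, phased
#' diploid samples, and a skewed allele-frequency distribution (most variants
#' rare) so the chunk dictionary's sharing is exercised.
#'
#' @param ref_len per-chromosome lengths (bp).
#' @param n_samples diploid samples (haplotypes = 2x).
#' @param snp_rate,del_rate,ins_rate,sv_rate expected variants per base.
#' @param max_indel_len maximum DEL/INS length; @param max_sv_len maximum SV
#'   deletion/insertion length.
#' @param af_shape `"skewed"` (Beta(0.5, 1.5)) or `"uniform"` carrier
#'   frequencies.
#' @param n_runs,n_run_len number and length of `N` runs per chromosome.
#' @param rng_seed integer seed; the same seed reproduces byte-identical
#'   output files.
#' @return a `collection_spec` list.
#' @export
collection_spec <- function(ref_len = 10000L, n_samples = 8L,
                            snp_rate = 1 / 100, del_rate = 1 / 1000,
                            ins_rate = 1 / 1000, sv_rate = 1 / 2000,
                            max_indel_len = 10L, max_sv_len = 20L,
                            af_shape = c("skewed", "uniform"),
                            n_runs = 0L, n_run_len = 5L, rng_seed = 1L) {
  af_shape <- match.arg(af_shape)
  stopifnot(all(ref_len >= 1L), n_samples >= 1L, snp_rate >= 0, del_rate >= 0,
            ins_rate >= 0, sv_rate >= 0, max_indel_len >= 1L, max_sv_len >= 1L)
  structure(list(ref_len = as.integer(ref_len),
                 n_samples = as.integer(n_samples),
                 snp_rate = snp_rate, del_rate = del_rate,
                 ins_rate = ins_rate, sv_rate = sv_rate,
                 max_indel_len = as.integer(max_indel_len),
                 max_sv_len = as.integer(max_sv_len), af_shape = af_shape,
                 n_runs = as.integer(n_runs), n_run_len = as.integer(n_run_len),
                 rng_seed = as.integer(rng_seed)),
            class = "collection_spec")
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Generate a synthetic collection
#'
#' Draws a uniform random reference (with optional `N` runs), places typed
#' variants, assigns phased genotypes with per-variant carrier frequencies,
#' and writes standard FASTA and VCF files. Genotype assignment keeps every
#' haplotype a single unambiguous path: two variants never share an effect
#' position on one haplotype, and no carried variant starts strictly inside
#' another carried deletion.
#'
#' @param spec a [collection_spec()].
#' @param dir output directory (created if needed).
#' @return a `collection` object: file paths, chromosome table, reference
#'   sequences, the truth variant table (database order), occurrence matrix
#'   and haplotype names.
#' @export
generate_collection <- function(spec, dir = tempfile("coll")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$rng_seed)
  nchrom <- length(spec$ref_len)
  cnames <- paste0("chr", seq_len(nchrom))
  nh <- 2L * spec$n_samples

  seqs <- character(nchrom)
  allvar <- list()
  for (ci in seq_len(nchrom)) {
    len <- spec$ref_len[ci]
    s <- strsplit(rand_seq(len), "", fixed = TRUE)[[1L]]
    if (spec$n_runs > 0L && len > 4L * spec$n_run_len) {
      for (r in seq_len(spec$n_runs)) {
        st <- sample.int(len - spec$n_run_len, 1L)
        s[st:(st + spec$n_run_len - 1L)] <- "N"
      }
    }
    ok_anchor <- which(s != "N")  # positions usable as anchors/footprints

    draw_pos <- function(count, need_left_anchor, max_len) {
      # effect positions (0-based local) whose REF footprint avoids N
      cand <- ok_anchor - 1L
      if (need_left_anchor) {
        cand <- cand[cand >= 1L]
        cand <- cand[s[cand] != "N"]  # s[cand] is the anchor character
      }
      cand <- cand[cand + max_len <= len]
      if (count > length(cand))
        stop("cannot place ", count, " variants on chromosome ", cnames[ci],
             " without conflicts; lower the rates")
      if (count == 0L) integer() else sort(sample(cand, count))
    }

    n_snp <- rbinom(1L, len, spec$snp_rate)
    n_del <- rbinom(1L, len, spec$del_rate)
    n_ins <- rbinom(1L, len, spec$ins_rate)
    n_sv <- rbinom(1L, len, spec$sv_rate)

    vlist <- list()
    p <- draw_pos(n_snp, FALSE, 1L)
    if (length(p)) {
      nalt <- 1L + (runif(length(p)) < 0.1)  # ~10% multiallelic sites
      vlist$snp <- data.frame(kind = "SNP", pos_local = p, del_len = 1L,
                              ins_len = 0L, nalt = nalt)
    }
    p <- draw_pos(n_del, TRUE, spec$max_indel_len)
    if (length(p)) {
      dl <- sample.int(spec$max_indel_len, length(p), replace = TRUE)
      dl <- pmin(dl, len - p)
      vlist$del <- data.frame(kind = "DEL", pos_local = p, del_len = dl,
                              ins_len = 0L, nalt = 1L)
    }
    p <- draw_pos(n_ins, TRUE, 0L)
    if (length(p)) {
      il <- sample.int(spec$max_indel_len, length(p), replace = TRUE)
      vlist$ins <- data.frame(kind = "INS", pos_local = p, del_len = 0L,
                              ins_len = il, nalt = 1L)
    }
    p <- draw_pos(n_sv, TRUE, spec$max_sv_len)
    if (length(p)) {
      dl <- pmin(sample.int(spec$max_sv_len, length(p), replace = TRUE), len - p)
      il <- sample.int(spec$max_sv_len, length(p), replace = TRUE)
      vlist$sv <- data.frame(kind = "SV", pos_local = p, del_len = dl,
                             ins_len = il, nalt = 1L)
    }
    v <- if (length(vlist)) do.call(rbind, vlist) else
      data.frame(kind = character(), pos_local = integer(),
                 del_len = integer(), ins_len = integer(), nalt = integer())
    if (nrow(v)) {
      # one VCF record per row; records sorted by VCF POS, creation order
      v$vcf_pos <- ifelse(v$kind == "SNP", v$pos_local + 1L, v$pos_local)
      v <- v[order(v$vcf_pos, seq_len(nrow(v)), method = "radix"), , drop = FALSE]
      v$chrom <- cnames[ci]
      v$chrom_i <- ci
    }
    seqs[ci] <- paste(s, collapse = "")
    allvar[[ci]] <- v
  }

  chrom_table <- data.frame(name = cnames,
                            global_start = cumsum(c(0L, spec$ref_len[-nchrom])),
                            length = spec$ref_len, stringsAsFactors = FALSE)
  recs <- do.call(rbind, allvar[vapply(allvar, nrow, integer(1L)) > 0L])
  if (is.null(recs))
    recs <- data.frame(kind = character(), pos_local = integer(),
                       del_len = integer(), ins_len = integer(),
                       nalt = integer(), vcf_pos = integer(),
                       chrom = character(), chrom_i = integer())

  # expand records into variants (allele order within record), draw alleles
  exp <- list()
  for (i in seq_len(nrow(recs))) {
    ci <- recs$chrom_i[i]
    s <- substring(seqs[ci], recs$pos_local[i] + 1L, recs$pos_local[i] + 1L)
    for (a in seq_len(recs$nalt[i])) {
      kind <- recs$kind[i]
      ins_seq <- if (kind == "SNP") {
        sample(setdiff(c("A", "C", "G", "T"), s), 1L)
      } else if (recs$ins_len[i] > 0L) rand_seq(recs$ins_len[i]) else ""
      exp[[length(exp) + 1L]] <- data.frame(
        kind = kind,
        pos = chrom_table$global_start[ci] + recs$pos_local[i],
        del_len = if (kind == "INS") 0L else recs$del_len[i] + (kind == "SNP") * 0L,
        ins_seq = ins_seq, record = i, allele = a, chrom_i = ci,
        stringsAsFactors = FALSE)
    }
  }
  vars <- if (length(exp)) do.call(rbind, exp) else
    data.frame(kind = character(), pos = integer(), del_len = integer(),
               ins_seq = character(), record = integer(), allele = integer(),
               chrom_i = integer(), stringsAsFactors = FALSE)
  # multiallelic SNP alts must differ from each other too
  if (nrow(vars)) {
    dup <- duplicated(vars[, c("record", "ins_seq")]) & vars$kind == "SNP"
    while (any(dup)) {
      for (i in which(dup)) {
        ci <- vars$chrom_i[i]
        rc <- substring(seqs[ci],
                        vars$pos[i] - chrom_table$global_start[ci] + 1L,
                        vars$pos[i] - chrom_table$global_start[ci] + 1L)
        taken <- vars$ins_seq[vars$record == vars$record[i]]
        free <- setdiff(c("A", "C", "G", "T"), c(rc, taken))
        vars$ins_seq[i] <- if (length(free)) sample(free, 1L) else free[1L]
      }
      dup <- duplicated(vars[, c("record", "ins_seq")]) & vars$kind == "SNP"
    }
  }
  # database order: (effect position, expansion order)
  ord <- order(vars$pos, seq_len(nrow(vars)), method = "radix")
  vars <- vars[ord, , drop = FALSE]
  rownames(vars) <- NULL
  nv <- nrow(vars)

  af <- if (nv == 0L) numeric() else if (spec$af_shape == "skewed")
    rbeta(nv, 0.5, 1.5) else runif(nv)

  # genotype assignment: per-haplotype path consistency
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  hap_names <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  occ <- matrix(FALSE, nv, nh, dimnames = list(NULL, hap_names))
  cur_end <- rep(-1L, nh)
  last_pos <- rep(-1L, nh)
  for (i in seq_len(nv)) {
    want <- runif(nh) < af[i]
    okh <- want & vars$pos[i] >= cur_end & vars$pos[i] != last_pos
    occ[i, ] <- okh
    cur_end[okh] <- pmax(cur_end[okh], vars$pos[i] + vars$del_len[i])
    last_pos[okh] <- vars$pos[i]
  }

  # write FASTA
  fasta <- file.path(dir, "reference.fa")
  fa_lines <- unlist(lapply(seq_len(nchrom), function(ci) {
    body <- substring(seqs[ci], seq(1L, nchar(seqs[ci]), 60L),
                      pmin(seq(1L, nchar(seqs[ci]), 60L) + 59L, nchar(seqs[ci])))
    c(paste0(">", cnames[ci]), body)
  }))
  writeLines(fa_lines, fasta)

  # write VCF (records in recs order == sorted by chrom, POS, creation)
  vcf <- file.path(dir, "variants.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", cnames, spec$ref_len),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  lines <- character(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    ci <- recs$chrom_i[i]
    loc <- recs$pos_local[i]
    gs <- chrom_table$global_start[ci]
    vi <- which(vars$record == i)  # in database order; map allele -> variant
    vi <- vi[order(vars$allele[vi])]
    refseq <- seqs[ci]
    if (recs$kind[i] == "SNP") {
      posf <- loc + 1L
      refa <- substring(refseq, posf, posf)
      alts <- vars$ins_seq[vi]
    } else {
      posf <- loc  # 1-based anchor position (= 0-based effect position)
      anchor <- substring(refseq, posf, posf)
      refa <- paste0(anchor, substring(refseq, loc + 1L, loc + recs$del_len[i]))
      alts <- paste0(anchor, vars$ins_seq[vi])
    }
    gtl <- integer(nh)
    for (a in seq_along(vi)) gtl[occ[vi[a], ]] <- a
    gts <- paste(gtl[seq(1L, nh, 2L)], gtl[seq(2L, nh, 2L)], sep = "|")
    lines[i] <- paste(c(recs$chrom[i], posf, ".", refa,
                        paste(alts, collapse = ","), ".", ".", ".", "GT", gts),
                      collapse = "\t")
  }
  writeLines(c(hdr, lines), vcf)

  structure(list(fasta = fasta, vcf = vcf, dir = dir, spec = spec,
                 chrom_table = chrom_table, ref_seqs = seqs,
                 variants = vars, occ = occ, hap_names = hap_names,
                 cache = new.env(parent = emptyenv())),
            class = "collection")
}

#' @export
print.collection <- function(x, ...) {
  cat("<collection>", sum(x$chrom_table$length), "bp,",
      nrow(x$chrom_table), "chromosome(s),", nrow(x$variants), "variants,",
      length(x$hap_names), "haplotypes\n  files:", x$fasta, "/", x$vcf, "\n")
  invisible(x)
}

#' Decode one haplotype with its reference projection
#'
#' Applies exactly the variants carried by haplotype `h`, left to right. The
#' projection records, for every emitted character, the preceding reference
#' position (0-based within the chromosome, i.e. the 1-based count of
#' reference characters before it) and the 1-based insertion offset
#' (0 for reference characters) -- the match-record coordinate convention.
#'
#' @param collection a `collection`; @param h 1-based haplotype index.
#' @return list with one element per chromosome: `chrom`, `text`, `pre`,
#'   `offset`.
#' @export
decode_haplotype <- function(collection, h) {
  key <- paste0("hap", h)
  if (!is.null(collection$cache[[key]])) return(collection$cache[[key]])
  stopifnot(h >= 1L, h <= length(collection$hap_names))
  out <- vector("list", nrow(collection$chrom_table))
  for (ci in seq_len(nrow(collection$chrom_table))) {
    gs <- collection$chrom_table$global_start[ci]
    len <- collection$chrom_table$length[ci]
    refseq <- collection$ref_seqs[ci]
    sel <- which(collection$occ[, h] & collection$variants$chrom_i == ci)
    v <- collection$variants[sel, , drop = FALSE]
    texts <- character(0); pres <- list(); offs <- list()
    cur <- 0L
    for (i in seq_len(nrow(v))) {
      p0 <- v$pos[i] - gs
      if (p0 < cur)
        stop("conflicting present variants on haplotype ", h,
             " at local position ", p0)
      if (p0 > cur) {
        texts <- c(texts, substring(refseq, cur + 1L, p0))
        pres[[length(pres) + 1L]] <- cur:(p0 - 1L)
        offs[[length(offs) + 1L]] <- rep(0L, p0 - cur)
      }
      il <- nchar(v$ins_seq[i])
      if (il > 0L) {
        texts <- c(texts, v$ins_seq[i])
        pres[[length(pres) + 1L]] <- rep(p0, il)
        offs[[length(offs) + 1L]] <-
          if (v$kind[i] == "SNP") 0L else seq_len(il)
      }
      cur <- p0 + v$del_len[i]
    }
    if (cur < len) {
      texts <- c(texts, substring(refseq, cur + 1L, len))
      pres[[length(pres) + 1L]] <- cur:(len - 1L)
      offs[[length(offs) + 1L]] <- rep(0L, len - cur)
    }
    out[[ci]] <- list(chrom = collection$chrom_table$name[ci],
                      text = paste(texts, collapse = ""),
                      pre = as.integer(unlist(pres)),
                      offset = as.integer(unlist(offs)))
  }
  collection$cache[[key]] <- out
  out
}

# cached DNAStringSet over all (haplotype, chromosome) texts, plus the raw
# bytes and projections of each subject
hap_subject_set <- function(collection) {
  if (!is.null(collection$cache$subject_set))
    return(collection$cache$subject_set)
  subj <- list()
  meta <- list()
  for (h in seq_along(collection$hap_names)) {
    dec <- decode_haplotype(collection, h)
    for (d in dec) {
      subj[[length(subj) + 1L]] <- d$text
      meta[[length(meta) + 1L]] <-
        list(hap = h, chrom = d$chrom, raw = charToRaw(d$text),
             pre = d$pre, offset = d$offset)
    }
  }
  out <- list(set = Biostrings::DNAStringSet(unlist(subj)), meta = meta)
  collection$cache$subject_set <- out
  out
}

#' Naive-scan oracle
#'
#' Brute-force ground truth: every window of every decoded haplotype within
#' Hamming distance `q` of the pattern, reported with the projection of its
#' first character. A pattern `N` mismatches everything. The scan is
#' independent of the index machinery (it runs on explicitly decoded
#' haplotype strings).
#'
#' @param collection a `collection`.
#' @param patterns character vector or data.frame with `id`/`seq`.
#' @param q maximum Hamming distance.
#' @return data.frame `query_id`, `chrom`, `pre`, `offset`, `hap`,
#'   `mismatches` (minimum per tuple).
#' @export
oracle_scan <- function(collection, patterns, q = 0L) {
  if (is.data.frame(patterns)) {
    ids <- as.character(patterns$id); seqs <- toupper(patterns$seq)
  } else {
    seqs <- toupper(as.character(patterns))
    ids <- as.character(seq_along(seqs))
  }
  ss <- hap_subject_set(collection)
  rows <- list()
  nraw <- charToRaw("N")
  for (pi in seq_along(seqs)) {
    P <- seqs[pi]
    m <- nchar(P)
    praw <- charToRaw(P)
    has_n <- any(praw == nraw)
    starts_by_subj <- if (!has_n) {
      mi <- Biostrings::vmatchPattern(P, ss$set, max.mismatch = q)
      Biostrings::startIndex(mi)
    } else {
      lapply(ss$meta, function(sj)  # fallback: check every window
        seq_len(max(length(sj$raw) - m + 1L, 0L)))
    }
    for (si in seq_along(ss$meta)) {
      sj <- ss$meta[[si]]
      for (st in starts_by_subj[[si]]) {
        if (st < 1L || st + m - 1L > length(sj$raw)) next
        sub <- sj$raw[st:(st + m - 1L)]
        mism <- sum(praw != sub) + if (has_n) sum(praw == nraw & sub == nraw) else 0L
        if (mism <= q) {
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = ids[pi], chrom = sj$chrom, pre = sj$pre[st],
            offset = sj$offset[st], hap = sj$hap, mismatches = as.integer(mism),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(), chrom = character(),
                      pre = integer(), offset = integer(), hap = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$query_id, df$chrom, df$pre, df$offset, df$hap), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Generate a query set of mutated haplotype excerpts
#'
#' Each pattern is an excerpt of uniform random length from a uniform random
#' haplotype and start, with `e` substitutions (each to a different base) at
#' distinct positions, `e` uniform in `err_range`. Excerpts containing `N`
#' are rejected and redrawn.
#'
#' @param collection a `collection`.
#' @param n number of patterns.
#' @param len_range,err_range inclusive integer ranges.
#' @param rng_seed integer seed.
#' @param path optional output file; @param format `"txt"`, `"fasta"` or
#'   `"fastq"`.
#' @return data.frame `id`, `seq`, plus provenance columns `hap`, `chrom`,
#'   `start` (1-based within the haplotype text), `pre`, `offset`, `errors`.
#' @export
generate_query_set <- function(collection, n, len_range = c(100L, 200L),
                               err_range = c(0L, 5L), rng_seed = 1L,
                               path = NULL, format = c("txt", "fasta", "fastq")) {
  format <- match.arg(format)
  set.seed(rng_seed)
  nh <- length(collection$hap_names)
  out <- vector("list", n)
  tries <- 0L
  i <- 1L
  while (i <= n) {
    if ((tries <- tries + 1L) > 100L * n + 100L)
      stop("query rejection loop exceeded its bound (N-free excerpts too rare?)")
    h <- sample.int(nh, 1L)
    dec <- decode_haplotype(collection, h)
    ci <- sample.int(length(dec), 1L)
    txt <- dec[[ci]]$text
    len <- sample(len_range[1L]:len_range[2L], 1L)
    if (nchar(txt) < len) next
    st <- sample.int(nchar(txt) - len + 1L, 1L)
    ex <- substring(txt, st, st + len - 1L)
    if (grepl("N", ex, fixed = TRUE)) next
    e <- sample(err_range[1L]:err_range[2L], 1L)
    if (e > 0L) {
      ppos <- sample.int(len, e)
      chars <- strsplit(ex, "", fixed = TRUE)[[1L]]
      for (p in ppos)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      ex <- paste(chars, collapse = "")
    }
    out[[i]] <- data.frame(id = as.character(i), seq = ex, hap = h,
                           chrom = dec[[ci]]$chrom, start = st,
                           pre = dec[[ci]]$pre[st],
                           offset = dec[[ci]]$offset[st],
                           errors = e, stringsAsFactors = FALSE)
    i <- i + 1L
  }
  df <- do.call(rbind, out)
  if (!is.null(path)) {
    lines <- switch(format,
      txt = df$seq,
      fasta = as.vector(rbind(paste0(">", df$id), df$seq)),
      fastq = as.vector(rbind(paste0("@", df$id), df$seq, "+",
                              strrep("I", nchar(df$seq)))))
    writeLines(lines, path)
  }
  df
}

#' Check index results against the oracle
#'
#' Both sides are expanded to (query, chromosome, preceding position, offset,
#' haplotype) tuples with minimum mismatch counts; the check passes iff the
#' symmetric difference is empty and every shared tuple agrees on its
#' mismatch count.
#'
#' @param index_expanded result of [expand_matches()].
#' @param oracle_expanded result of [oracle_scan()].
#' @return an `equiv_report`: `pass`, `missing` (oracle-only tuples), `extra`
#'   (index-only), `wrong_mismatches`.
#' @export
equivalence_check <- function(index_expanded, oracle_expanded) {
  keyof <- function(d) paste(d$query_id, d$chrom, d$pre, d$offset, d$hap,
                             sep = "|")
  ki <- keyof(index_expanded)
  ko <- keyof(oracle_expanded)
  missing <- oracle_expanded[!(ko %in% ki), , drop = FALSE]
  extra <- index_expanded[!(ki %in% ko), , drop = FALSE]
  shared <- intersect(ki, ko)
  mi <- index_expanded$mismatches[match(shared, ki)]
  mo <- oracle_expanded$mismatches[match(shared, ko)]
  wrong <- which(mi != mo)
  wrong_df <- if (length(wrong))
    cbind(oracle_expanded[match(shared[wrong], ko), , drop = FALSE],
          index_mismatches = mi[wrong])
  else oracle_expanded[0, , drop = FALSE]
  structure(list(pass = nrow(missing) == 0L && nrow(extra) == 0L &&
                   length(wrong) == 0L,
                 missing = missing, extra = extra,
                 wrong_mismatches = wrong_df),
            class = "equiv_report")
}

#' @export
print.equiv_report <- function(x, ...) {
  cat("<equiv_report>", if (x$pass) "PASS" else "FAIL",
      "| missing:", nrow(x$missing), " extra:", nrow(x$extra),
      " wrong mismatch counts:", nrow(x$wrong_mismatches), "\n")
  invisible(x)
}
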
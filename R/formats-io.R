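# External formats: FASTA, minimal VCF, pattern files, the TSV match report,
# and the versioned index container.

#' Read a reference genome from FASTA
#'
#' Chromosomes are concatenated into one global 0-based coordinate space;
#' lowercase is mapped to uppercase. Only A/C/G/T/N are accepted.
#'
#' @param path FASTA file (one or more records).
#' @return list with `ref` (a [pack_reference()] object) and `chrom_table`
#'   (data.frame `name`, `global_start` (0-based), `length`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(lines)))
    stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[which(nzchar(lines))[1L]])
    stop("line 1: FASTA must start with a '>' header")
  # validate the alphabet with line numbers before parsing
  seq_lines <- which(!hdr & nzchar(lines))
  for (i in seq_lines) {
    bad <- regexpr("[^ACGTNacgtn]", lines[i])
    if (bad > 0L)
      stop(sprintf("line %d: non-nucleotide character '%s' in sequence",
                   i, substr(lines[i], bad, bad)))
  }
  set <- Biostrings::readBStringSet(path)
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms)) {
    dup <- nms[duplicated(nms)][1L]
    first_line <- which(hdr)[match(dup, nms)]
    stop(sprintf("duplicate chromosome name '%s' (record starting near line %d)",
                 dup, first_line))
  }
  seqs <- toupper(as.character(set))
  lens <- nchar(seqs)
  if (any(lens == 0L)) stop("FASTA record '", nms[lens == 0L][1L], "' is empty")
  chrom_table <- data.frame(
    name = nms,
    global_start = cumsum(c(0L, lens[-length(lens)])),
    length = lens,
    stringsAsFactors = FALSE
  )
  rownames(chrom_table) <- NULL
  list(ref = pack_reference(paste(seqs, collapse = "")),
       chrom_table = chrom_table)
}

#' Read the minimal subset of a VCF
#'
#' Retains only CHROM/POS/REF/ALT and the phased GT of every sample -- the
#' fields sufficient to reconstruct each haplotype sequence. Multiallelic
#' records are passed through intact (split later by
#' [normalize_variants()]).
#'
#' Preconditions enforced as hard errors: records sorted by (chromosome order
#' in `chrom_table`, position); all genotypes phased (`|` separator, no
#' missing alleles); chromosomes known; positions within the chromosome.
#'
#' @param path VCF 4.x file (plain text).
#' @param chrom_table chromosome table from [read_fasta()].
#' @return list with `records` (data.frame `chrom`, `pos` (1-based), `ref`,
#'   `alt` comma-joined), `gt` (character matrix records x samples, e.g.
#'   `"0|1"`) and `samples`.
#' @export
read_vcf_min <- function(path, chrom_table) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n <- nrow(fix)
  samples <- colnames(v@gt)[-1L]
  if (is.null(samples)) samples <- character()
  if (n == 0L) {
    return(list(records = data.frame(chrom = character(), pos = integer(),
                                     ref = character(), alt = character(),
                                     stringsAsFactors = FALSE),
                gt = matrix(character(), 0L, length(samples),
                            dimnames = list(NULL, samples)),
                samples = samples))
  }
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  unknown <- !(chrom %in% chrom_table$name)
  if (any(unknown))
    stop("VCF record on unknown chromosome '", chrom[unknown][1L], "'")
  corder <- match(chrom, chrom_table$name)
  if (is.unsorted(order(corder, pos)) ||
      any(diff(corder) < 0L) || any(diff(pos)[diff(corder) == 0L] < 0L))
    stop("VCF records are not sorted by (chromosome, position)")
  over <- pos > chrom_table$length[corder]
  if (any(over))
    stop(sprintf("VCF position %d exceeds the length of chromosome %s",
                 pos[over][1L], chrom[over][1L]))
  gtfmt <- if (ncol(v@gt) >= 1L) v@gt[, 1L] else rep("GT", n)
  gt_field <- function(x, fmt) {
    i <- match("GT", strsplit(fmt, ":", fixed = TRUE)[[1L]])
    if (is.na(i)) stop("VCF record without a GT field")
    vapply(strsplit(x, ":", fixed = TRUE), function(p) p[i], character(1L))
  }
  gt <- matrix("", n, length(samples), dimnames = list(NULL, samples))
  if (length(samples)) {
    for (j in seq_along(samples))
      gt[, j] <- gt_field(as.character(v@gt[, j + 1L]), gtfmt)
  }
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype ('/' separator) found; phased GT required")
  if (any(grepl("\\.", gt)))
    stop("missing genotype ('.') found; complete phased GT required")
  if (!all(grepl("^[0-9]+\\|[0-9]+$", gt)))
    stop("malformed GT field '", gt[!grepl("^[0-9]+\\|[0-9]+$", gt)][1L], "'")
  list(records = data.frame(chrom = chrom, pos = pos,
                            ref = toupper(as.character(fix[, "REF"])),
                            alt = toupper(as.character(fix[, "ALT"])),
                            stringsAsFactors = FALSE),
       gt = gt, samples = samples)
}

#' Read query patterns
#'
#' @param path pattern file.
#' @param format `"txt"` (one pattern per line, ids by line number),
#'   `"fasta"` or `"fastq"` (qualities read and discarded).
#' @return data.frame with `id` and `seq` (uppercased; `N` retained).
#' @export
read_patterns <- function(path, format = c("txt", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("pattern file not found: ", path)
  if (format == "txt") {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    if (any(!keep))
      warning(sum(!keep), " empty line(s) skipped in ", path)
    data.frame(id = as.character(which(keep)),
               seq = toupper(trimws(lines[keep])),
               stringsAsFactors = FALSE)
  } else if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    data.frame(id = sub("\\s.*$", "", names(set)),
               seq = toupper(as.character(set)), stringsAsFactors = FALSE)
  } else {
    # structural validation (4-line records, matching quality length) before
    # handing the file to the Biostrings parser; qualities are discarded
    lines <- readLines(path, warn = FALSE)
    if (length(lines) %% 4L != 0L ||
        !all(startsWith(lines[seq(1L, length(lines), 4L)], "@")) ||
        !all(startsWith(lines[seq(3L, length(lines), 4L)], "+")) ||
        any(nchar(lines[seq(2L, length(lines), 4L)]) !=
            nchar(lines[seq(4L, length(lines), 4L)])))
      stop("malformed FASTQ file ", path,
           " (4-line records with equal sequence/quality lengths expected)")
    set <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq"),
      error = function(e) stop("malformed FASTQ file ", path, ": ",
                               conditionMessage(e)))
    data.frame(id = sub("\\s.*$", "", names(set)),
               seq = toupper(as.character(set)), stringsAsFactors = FALSE)
  }
}

#' Write a TSV match report
#'
#' One row per match record: `pattern_id`, `chrom`, `preceding_pos` (1-based;
#' 0 at a chromosome start), `insertion_offset`, `mismatches`,
#' `haplotype_count` and the comma-joined haplotype ids
#' (`<sample>_1` / `<sample>_2`). A header-only file is written for an empty
#' result set; records differing in evidence are never silently merged.
#'
#' @param matches match data.frame from [search_patterns()].
#' @param path output file.
#' @export
write_matches <- function(matches, path) {
  df <- data.frame(
    pattern_id = matches$query_id,
    chrom = matches$chrom,
    preceding_pos = matches$pre,
    insertion_offset = matches$offset,
    mismatches = matches$mismatches,
    haplotype_count = matches$haplotype_count,
    haplotype_ids = matches$haplotypes,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# index container
# ---------------------------------------------------------------------------

INDEX_MAGIC <- charToRaw("HAPFINDX")
INDEX_FORMAT_VERSION <- 1L

#' Save / load an index
#'
#' The container is versioned (magic bytes, format version, payload length,
#' Adler-32 checksum) and holds every index section: packed reference,
#' chromosome table, variant database + inverse-deletion list, compressed
#' bit-vector dictionary, the four k-mer subarrays with lookup tables, and
#' the construction parameters. Round-trip fidelity (identical query answers
#' before and after) is the contract.
#'
#' @param index a `hapfind_index` from [build_index()].
#' @param path file path.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "hapfind_index"))
  payload <- serialize(index[setdiff(names(index), "occ")], NULL, xdr = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(INDEX_MAGIC, con)
  writeBin(as.integer(INDEX_FORMAT_VERSION), con, size = 4L, endian = "big")
  writeBin(as.numeric(length(payload)), con, size = 8L, endian = "big")
  writeBin(cpp_checksum(payload), con, size = 8L, endian = "big")
  writeBin(payload, con)
  invisible(path)
}

#' @rdname save_index
#' @return `load_index()` returns the restored `hapfind_index` (the
#'   decompressed occurrence-matrix cache is rebuilt).
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = length(INDEX_MAGIC))
  if (!identical(magic, INDEX_MAGIC))
    stop("not a hapfind index: ", path)
  ver <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (!length(ver) || ver != INDEX_FORMAT_VERSION)
    stop("unsupported index format version: ", if (length(ver)) ver else "<missing>")
  len <- readBin(con, "numeric", n = 1L, size = 8L, endian = "big")
  chk <- readBin(con, "numeric", n = 1L, size = 8L, endian = "big")
  if (!length(len) || !length(chk)) stop("truncated index file: ", path)
  payload <- readBin(con, "raw", n = len)
  if (length(payload) != len) stop("truncated index file: ", path)
  if (!identical(cpp_checksum(payload), chk))
    stop("index checksum mismatch (corrupt file): ", path)
  obj <- unserialize(payload)
  class(obj) <- "hapfind_index"
  obj$occ <- decompress_bitvectors(obj$bv)
  obj
}
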
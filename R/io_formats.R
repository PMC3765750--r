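#' @name io_formats
#' @title File formats used by the pipeline
#'
#' @description
#' The pipeline touches four external formats:
#'
#' * **Per-cytosine methylation tables**: whitespace-delimited text, one row
#'   per cytosine site, with columns `chrom`, `pos`, `strand` (`+`/`-`),
#'   `context` (`CG`, `CHG` or `CHH`), `coverage` (reads covering the site)
#'   and `ratio` (methylated reads / coverage, `NA` when coverage is 0).
#'   This is the per-site report emitted by bisulfite aligners'
#'   methylation-extraction step; other tools' output maps onto it by
#'   reordering columns (`col_names`).
#' * **Target region files**: 3+ column text (`chrom`, `start`, `end`),
#'   BED-style 0-based half-open by default.
#' * **Softmasked reference FASTA**: lowercase marks repeat-masked bases;
#'   case is preserved on read.
#' * **FASTQ** in Sanger (Phred+33) or Illumina-1.3 (Phred+64) encoding.
#'
#' Internally every coordinate is 0-based and intervals are half-open
#' `[start, end)`; readers normalise and writers restore the declared
#' external convention.
NULL

METHYL_COLS <- c("chrom", "pos", "strand", "context", "coverage", "ratio")
CONTEXTS <- c("CG", "CHG", "CHH")

#' Construct and validate a per-cytosine methylation table
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based site positions.
#' @param strand `"+"` or `"-"` per site.
#' @param context `"CG"`, `"CHG"` or `"CHH"` per site.
#' @param coverage non-negative integer read counts.
#' @param ratio methylation ratio in `[0, 1]`; must be `NA` exactly when
#'   `coverage` is 0 ("no data" is never serialised as 0).
#' @return A `data.frame` with class `methyl_table`.
#' @export
methyl_table <- function(chrom, pos, strand, context, coverage, ratio) {
  tbl <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    strand = as.character(strand), context = as.character(context),
    coverage = as.integer(coverage), ratio = as.numeric(ratio),
    stringsAsFactors = FALSE
  )
  validate_methyl_table(tbl)
}

validate_methyl_table <- function(tbl, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) sprintf("row %d", i) else sprintf("line %d", lines[i])
  }
  bad <- which(is.na(tbl$pos))
  if (length(bad))
    stop("non-integer position at ", where(bad[1]), call. = FALSE)
  bad <- which(!tbl$strand %in% c("+", "-"))
  if (length(bad))
    stop("invalid strand '", tbl$strand[bad[1]], "' at ", where(bad[1]),
         call. = FALSE)
  bad <- which(!tbl$context %in% CONTEXTS)
  if (length(bad))
    stop("unknown context token '", tbl$context[bad[1]], "' at ",
         where(bad[1]), " (expected CG, CHG or CHH)", call. = FALSE)
  bad <- which(is.na(tbl$coverage) | tbl$coverage < 0L)
  if (length(bad))
    stop("coverage must be a non-negative integer at ", where(bad[1]),
         call. = FALSE)
  bad <- which(!is.na(tbl$ratio) & (tbl$ratio < 0 | tbl$ratio > 1))
  if (length(bad))
    stop("methylation ratio outside [0,1] at ", where(bad[1]), call. = FALSE)
  bad <- which(tbl$coverage == 0L & !is.na(tbl$ratio))
  if (length(bad))
    stop("site with coverage 0 must have ratio NA at ", where(bad[1]),
         call. = FALSE)
  bad <- which(tbl$coverage > 0L & is.na(tbl$ratio))
  if (length(bad))
    stop("covered site with undefined ratio at ", where(bad[1]),
         call. = FALSE)
  class(tbl) <- c("methyl_table", "data.frame")
  tbl
}

#' Read a per-cytosine methylation-ratio table
#'
#' Reads whitespace-delimited per-site methylation reports. If the first
#' line names the columns (contains `chrom`), columns are matched by name in
#' any order; otherwise `col_names` declares the column order, defaulting to
#' `chrom pos strand context coverage ratio`. Positions are normalised to
#' the internal 0-based convention.
#'
#' @param path input file.
#' @param coord_base coordinate base of the `pos` column in the file: `1`
#'   (default, typical for per-site reports) or `0`.
#' @param col_names column order for headerless files; any permutation of
#'   `chrom pos strand context coverage ratio`. Ignored when the file has a
#'   header.
#' @return A [methyl_table] in file order.
#' @export
read_methyl_table <- function(path, coord_base = 1, col_names = NULL) {
  stopifnot(coord_base %in% c(0, 1))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L && grepl("\\bchrom\\b", first)
  nfield <- count.fields(path, comment.char = "")
  if (length(nfield) == 0L || (has_header && length(nfield) == 1L)) {
    tbl <- methyl_table(character(), integer(), character(), character(),
                        integer(), numeric())
    return(tbl)
  }
  names_used <- if (has_header) {
    strsplit(trimws(first), "[ \t]+")[[1]]
  } else {
    col_names %||% METHYL_COLS
  }
  if (!setequal(names_used, METHYL_COLS))
    stop("methylation table must provide columns ",
         paste(METHYL_COLS, collapse = ", "), "; got: ",
         paste(names_used, collapse = ", "), call. = FALSE)
  body_lines <- seq_along(nfield)
  if (has_header) body_lines <- body_lines[-1L]
  bad <- body_lines[nfield[body_lines] != length(names_used)]
  if (length(bad))
    stop("missing columns at line ", bad[1], ": expected ",
         length(names_used), " fields, found ", nfield[bad[1]],
         call. = FALSE)
  raw <- read.table(path, header = FALSE, skip = as.integer(has_header),
                    col.names = names_used, colClasses = "character",
                    na.strings = "NA", stringsAsFactors = FALSE)
  lines <- body_lines
  pos <- suppressWarnings(as.integer(raw$pos))
  coverage <- suppressWarnings(as.integer(raw$coverage))
  ratio <- suppressWarnings(as.numeric(raw$ratio))
  bad <- which(!is.na(raw$ratio) & is.na(ratio))
  if (length(bad))
    stop("unparseable ratio '", raw$ratio[bad[1]], "' at line ",
         lines[bad[1]], call. = FALSE)
  tbl <- data.frame(chrom = raw$chrom, pos = pos - as.integer(coord_base),
                    strand = raw$strand, context = raw$context,
                    coverage = coverage, ratio = ratio,
                    stringsAsFactors = FALSE)
  validate_methyl_table(tbl, lines = lines)
}

#' Write a per-cytosine methylation-ratio table
#'
#' Inverse of [read_methyl_table()]: emits a header line and one row per
#' site, with positions shifted to `coord_base` and undefined ratios
#' (coverage 0) serialised as `NA`.
#'
#' @param tbl a [methyl_table].
#' @param path output file.
#' @param coord_base coordinate base to write positions in (default 1).
#' @return `path`, invisibly.
#' @export
write_methyl_table <- function(tbl, path, coord_base = 1) {
  stopifnot(coord_base %in% c(0, 1))
  tbl <- validate_methyl_table(as.data.frame(tbl))
  out <- tbl
  out$pos <- out$pos + as.integer(coord_base)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(METHYL_COLS, collapse = "\t"), con)
  if (nrow(out))
    write.table(out[METHYL_COLS], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a target-region file
#'
#' Reads 3+ column region files (`chrom`, `start`, `end`, optional label).
#' The default interpretation is BED-style 0-based half-open; files using
#' 1-based fully-closed coordinates are converted with
#' `format = "one_based"`.
#'
#' @param path input file (tab- or space-delimited; lines starting with
#'   `#` or a `chrom` header line are skipped).
#' @param format `"bed0"` (0-based half-open, default) or `"one_based"`
#'   (1-based inclusive).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `label`
#'   (internal 0-based half-open), in file order. Overlaps are permitted.
#' @export
read_targets <- function(path, format = c("bed0", "one_based")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  all_lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", all_lines) &
    !grepl("^\\s*chrom\\b", all_lines)
  lines <- which(keep)
  if (!length(lines))
    return(target_regions(character(), integer(), integer()))
  fields <- strsplit(trimws(all_lines[lines]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1]
    stop("target file needs 3 columns (chrom, start, end); line ",
         lines[i], " has ", nf[i], call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  label <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("non-integer coordinate at line ", lines[bad[1]], call. = FALSE)
  if (format == "one_based") {
    start <- start - 1L   # [start, end] 1-based -> [start-1, end) 0-based
  }
  bad <- which(start < 0L | start >= end)
  if (length(bad))
    stop("invalid region (need 0 <= start < end) at line ", lines[bad[1]],
         call. = FALSE)
  target_regions(chrom, start, end, label)
}

#' Construct a target-region table (0-based half-open)
#'
#' @param chrom,start,end region coordinates, `0 <= start < end`.
#' @param label optional identifiers.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @export
target_regions <- function(chrom, start, end, label = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start) | is.na(end) | start < 0L | start >= end))
    stop("invalid region: need 0 <= start < end", call. = FALSE)
  data.frame(chrom = as.character(chrom), start = start, end = end,
             label = rep_len(as.character(label), length(chrom)),
             stringsAsFactors = FALSE)
}

#' Write a target-region file
#'
#' @param regions a target-region `data.frame` (see [target_regions()]).
#' @param path output file.
#' @param format output convention, as in [read_targets()].
#' @return `path`, invisibly.
#' @export
write_targets <- function(regions, path, format = c("bed0", "one_based")) {
  format <- match.arg(format)
  out <- regions[c("chrom", "start", "end")]
  if (format == "one_based") out$start <- out$start + 1L
  if (!all(is.na(regions$label))) out$label <- regions$label
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, na = ".")
  invisible(path)
}

#' Read a (softmasked) reference FASTA
#'
#' Case is preserved: lowercase bases mark repeat/low-complexity regions
#' (UCSC-style softmasking) and drive the `%low_count` repeat metric.
#'
#' @param path FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (!length(x)) stop("empty FASTA: ", path, call. = FALSE)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  if (any(nchar(seqs) == 0L))
    stop("zero-length sequence in FASTA: ", path, call. = FALSE)
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad))
    stop("non-ACGTN character in sequence ", names(seqs)[bad][1],
         call. = FALSE)
  seqs
}

#' Write a reference FASTA preserving case
#'
#' @param ref named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path, width = 70L) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(ref), path,
                              width = as.integer(width))
  invisible(path)
}

fastq_offset <- c(sanger = 33L, illumina = 64L)

#' Construct a set of sequencing reads
#'
#' @param id read identifiers.
#' @param seq read sequences over `A,C,G,T,N`.
#' @param qual list of integer Phred quality vectors, one per read, each the
#'   same length as its sequence, values in `[0, 93]`.
#' @return List with class `fastq_reads` and elements `id`, `seq`, `qual`.
#' @export
fastq_reads <- function(id, seq, qual) {
  id <- as.character(id); seq <- toupper(as.character(seq))
  qual <- lapply(qual, as.integer)
  if (length(id) != length(seq) || length(seq) != length(qual))
    stop("id, seq and qual must have equal length", call. = FALSE)
  if (any(nchar(seq) != lengths(qual)))
    stop("sequence and quality lengths differ", call. = FALSE)
  if (length(qual) && (min(unlist(qual), 93L) < 0L || max(unlist(qual), 0L) > 93L))
    stop("Phred scores must lie in [0, 93]", call. = FALSE)
  if (any(grepl("[^ACGTN]", seq)))
    stop("read sequences must be over A,C,G,T,N", call. = FALSE)
  structure(list(id = id, seq = seq, qual = qual), class = "fastq_reads")
}

#' @export
length.fastq_reads <- function(x) length(x$id)

#' @export
print.fastq_reads <- function(x, ...) {
  cat("fastq_reads:", length(x), "reads\n")
  invisible(x)
}

subset_reads <- function(reads, i) {
  fastq_reads(reads$id[i], reads$seq[i], reads$qual[i])
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @param encoding quality encoding: `"sanger"` (Phred+33) or `"illumina"`
#'   (Illumina 1.3+, Phred+64).
#' @return A [fastq_reads] object.
#' @export
read_fastq <- function(path, encoding = c("sanger", "illumina")) {
  encoding <- match.arg(encoding)
  off <- fastq_offset[[encoding]]
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  qual_str <- as.character(S4Vectors::mcols(x)$qualities)
  qual <- lapply(qual_str, function(q) utf8ToInt(q) - off)
  mins <- vapply(qual, function(q) if (length(q)) min(q) else 0L, 0)
  if (any(mins < 0)) {
    other <- setdiff(names(fastq_offset), encoding)
    stop("quality character below the ", encoding, " offset (", off,
         ") in read ", which(mins < 0)[1],
         "; is this file ", other, "-encoded?", call. = FALSE)
  }
  fastq_reads(sub("\\s.*$", "", names(x)), as.character(x), qual)
}

#' Write a FASTQ file
#'
#' @param reads a [fastq_reads] object.
#' @param path output file.
#' @param encoding quality encoding, as in [read_fastq()].
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, encoding = c("sanger", "illumina")) {
  encoding <- match.arg(encoding)
  off <- fastq_offset[[encoding]]
  quals <- vapply(reads$qual,
                  function(q) if (length(q)) intToUtf8(q + off) else "", "")
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(reads$seq), reads$id), path,
    format = "fastq", qualities = Biostrings::BStringSet(quals))
  invisible(path)
}
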
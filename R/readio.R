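#' Read a FASTQ file
#'
#' Parses plain or gzip-compressed 4-line FASTQ records. Qualities are
#' retained but not used for any downstream filtering (the assay applies no
#' quality filter). A malformed record aborts with an error naming the
#' 1-based index of the offending record.
#'
#' @param path FASTQ file (`.gz` handled transparently).
#' @return `data.frame` with columns `read_id` (the token before the first
#'   whitespace, without the leading `@`), `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L)
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  if (n %% 4L != 0L)
    stop(sprintf("malformed FASTQ: record %d is truncated", n %/% 4L + 1L))
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(qual))
  if (length(bad))
    stop(sprintf("malformed FASTQ: record %d is invalid", bad[1L]))
  data.frame(
    read_id = sub("\\s.*$", "", sub("^@", "", hdr)),
    sequence = toupper(seqs),
    quality = qual,
    stringsAsFactors = FALSE
  )
}

#' Write a FASTQ file
#'
#' @param reads `data.frame` with columns `read_id`, `sequence` and
#'   optionally `quality` (defaults to constant `I`).
#' @param path Output path; a `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  qual <- if ("quality" %in% names(reads)) reads$quality
          else vapply(nchar(reads$sequence),
                      function(k) strrep("I", k), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, open = "wt")
         else file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  out <- rbind(paste0("@", reads$read_id), reads$sequence, "+", qual)
  writeLines(as.vector(out), con)
  invisible(path)
}

#' Extract the identifier+tag region from reads
#'
#' Returns the `id_length + tag_length` substring starting at the schema's
#' `read_offset`; reads too short to cover the region yield `NA`.
#'
#' @param sequences Character vector of read sequences.
#' @param schema A `barcode_schema`.
#' @return Character vector of regions (`NA` for short reads).
#' @export
extract_region <- function(sequences, schema) {
  stopifnot(inherits(schema, "barcode_schema"))
  len <- region_length(schema)
  start <- schema$read_offset + 1L
  out <- substr(sequences, start, start + len - 1L)
  out[nchar(sequences) < schema$read_offset + len] <- NA_character_
  out
}

#' Assign reads to proteins by their identifier segment
#'
#' Compares the first `id_length` bases of each region against the schema's
#' identifier table by Hamming distance. A read is assigned to the unique
#' identifier within `max_mismatch`; if no identifier qualifies, or two tie
#' at the minimum distance, the read is unassigned (`NA`).
#'
#' @param regions Character vector of identifier+tag regions (`NA` allowed).
#' @param schema A `barcode_schema`.
#' @param max_mismatch Maximum tolerated identifier mismatches (0 or 1;
#'   default 1 — with a minimum pairwise identifier distance of 3 this is
#'   always unambiguous).
#' @return `data.frame` with columns `protein` (name or `NA`) and
#'   `id_mismatches` (`NA` when unassigned).
#' @export
assign_protein <- function(regions, schema, max_mismatch = 1L) {
  stopifnot(inherits(schema, "barcode_schema"), max_mismatch %in% c(0L, 1L))
  n <- length(regions)
  protein <- rep(NA_character_, n)
  mism <- rep(NA_integer_, n)
  ok <- !is.na(regions)
  if (any(ok)) {
    idseg <- substr(regions[ok], 1L, schema$id_length)
    mat <- .char_matrix(idseg)
    ids <- schema$identifiers
    dm <- matrix(0L, nrow = nrow(ids), ncol = ncol(mat))
    for (j in seq_len(nrow(ids)))
      dm[j, ] <- .hamming_to_one(mat, utf8ToInt(ids$tag[j]))
    dmin <- apply(dm, 2L, min)
    nmin <- colSums(dm == rep(dmin, each = nrow(ids)))
    hit <- dmin <= max_mismatch & nmin == 1L
    best <- apply(dm, 2L, which.min)
    p <- rep(NA_character_, sum(ok))
    m <- rep(NA_integer_, sum(ok))
    p[hit] <- ids$name[best[hit]]
    m[hit] <- as.integer(dmin[hit])
    protein[ok] <- p
    mism[ok] <- m
  }
  data.frame(protein = protein, id_mismatches = mism, stringsAsFactors = FALSE)
}

#' Extract counting tags and count fixed-base mismatches
#'
#' Splits off the counting-tag segment of each region and counts how many of
#' the pattern's fixed positions disagree. Reads with one or more fixed-base
#' mismatches are excluded from molecule counting downstream.
#'
#' @param regions Character vector of identifier+tag regions (`NA` allowed).
#' @param schema A `barcode_schema`.
#' @return `data.frame` with columns `counting_tag` and `fixed_mismatches`.
#' @export
check_fixed_bases <- function(regions, schema) {
  stopifnot(inherits(schema, "barcode_schema"))
  n <- length(regions)
  tag <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n)
  ok <- !is.na(regions)
  if (any(ok)) {
    tg <- substr(regions[ok], schema$id_length + 1L, region_length(schema))
    tag[ok] <- tg
    mm[ok] <- fixed_base_mismatches(tg, schema$pattern)
  }
  data.frame(counting_tag = tag, fixed_mismatches = mm,
             stringsAsFactors = FALSE)
}

#' Demultiplex reads into per-read tag observations
#'
#' Runs region extraction, protein assignment and the fixed-base filter over
#' a read table, producing one observation per read. A read passes the filter
#' iff it is assigned to a protein and its counting tag matches every fixed
#' base.
#'
#' @param reads `data.frame` from [read_fastq()] (columns `read_id`,
#'   `sequence`).
#' @param schema A `barcode_schema`.
#' @param max_mismatch Identifier mismatch tolerance, see [assign_protein()].
#' @return `data.frame` with columns `read_id`, `protein`, `id_mismatches`,
#'   `counting_tag`, `fixed_mismatches`, `passed_filter`, `reason`
#'   (`"short_read"`, `"unassigned"`, `"fixed_base"` or `NA` when passed).
#' @export
demultiplex <- function(reads, schema, max_mismatch = 1L) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence") %in% names(reads)))
  regions <- extract_region(reads$sequence, schema)
  asg <- assign_protein(regions, schema, max_mismatch = max_mismatch)
  fb <- check_fixed_bases(regions, schema)
  passed <- !is.na(asg$protein) & !is.na(fb$fixed_mismatches) &
    fb$fixed_mismatches == 0L
  reason <- rep(NA_character_, nrow(reads))
  reason[!passed & is.na(regions)] <- "short_read"
  reason[!passed & !is.na(regions) & is.na(asg$protein)] <- "unassigned"
  reason[!passed & !is.na(regions) & !is.na(asg$protein)] <- "fixed_base"
  data.frame(
    read_id = reads$read_id,
    protein = asg$protein,
    id_mismatches = asg$id_mismatches,
    counting_tag = fb$counting_tag,
    fixed_mismatches = fb$fixed_mismatches,
    passed_filter = passed,
    reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Write / read an observation table
#'
#' Tab-separated serialization of the [demultiplex()] output.
#' @param observations Observation `data.frame`.
#' @param path TSV path.
#' @export
write_observations <- function(observations, path) {
  utils::write.table(observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(read_id = "character",
                                         counting_tag = "character"))
  df$passed_filter <- as.logical(df$passed_filter)
  df
}
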
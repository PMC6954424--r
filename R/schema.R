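DNA_BASES <- c("A", "C", "G", "T")

# Default 31-bp amplification arms. Placeholder PCR-handle sequences: the arms
# flank the counted region and never enter demultiplexing or counting, so any
# fixed pair of primer-binding sequences serves; override in the schema config
# to match a real oligo design.
DEFAULT_ARM5 <- "ACACGACGCTCTTCCGATCTGTGACTGGAGT"
DEFAULT_ARM3 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGT"

.check_dna <- function(x, allow_n = FALSE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  grepl(sprintf("^[%s]*$", alphabet), x)
}

# character -> integer matrix (nchar x n), for vectorised Hamming distances
.char_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(integer(0), nrow = 0L, ncol = 0L))
  n <- unique(nchar(x))
  if (length(n) != 1L) stop("sequences have inconsistent lengths")
  vapply(x, function(s) utf8ToInt(s), integer(n), USE.NAMES = FALSE)
}

.hamming_to_one <- function(mat, v) {
  # distances from each column of `mat` to the single encoded sequence `v`
  if (ncol(mat) == 0L) return(integer(0))
  colSums(mat != v)
}

#' Counting-tag pattern
#'
#' Describes the semi-random molecule-counting tag: a string over A/C/G/T/N
#' where N marks a random base and a literal base marks a fixed (invariant)
#' position. The default assay design uses a 30-bp tag with 24 random and 6
#' fixed bases (A, C, T, G, A, C), one fixed base after every four random
#' bases.
#'
#' @param pattern Character scalar over `A`, `C`, `G`, `T`, `N`.
#' @return An object of class `counting_tag_pattern` with elements `pattern`,
#'   `length`, `fixed_positions` (1-based), `fixed_bases`, `n_fixed`,
#'   `n_random`.
#' @examples
#' p <- default_counting_pattern()
#' p$fixed_bases   # A C T G A C
#' @export
counting_tag_pattern <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) > 0L)
  if (!.check_dna(pattern, allow_n = TRUE))
    stop("pattern may only contain A, C, G, T, N")
  chars <- strsplit(pattern, "")[[1]]
  fixed <- which(chars != "N")
  structure(
    list(
      pattern = pattern,
      length = nchar(pattern),
      fixed_positions = fixed,
      fixed_bases = chars[fixed],
      n_fixed = length(fixed),
      n_random = sum(chars == "N")
    ),
    class = "counting_tag_pattern"
  )
}

#' @rdname counting_tag_pattern
#' @export
default_counting_pattern <- function() {
  counting_tag_pattern("NNNNANNNNCNNNNTNNNNGNNNNANNNNC")
}

#' Protein identifier table
#'
#' Builds the table of fixed protein-identifier barcodes. Each row names one
#' protein by a short fixed DNA tag (8 bp in the default design). Roles:
#' `"assay"` for proteins measured in the experiment, `"control"` for
#' negative-control proteins (e.g. the tag-only construct), `"unused"` for
#' barcodes absent from the assay, whose read counts define the sequencing
#' noise floor.
#'
#' @param tag Character vector of DNA identifier sequences (equal lengths).
#' @param name Character vector of protein labels (unique).
#' @param role Character vector, each one of `"assay"`, `"control"`,
#'   `"unused"`. Recycled if scalar.
#' @return A `data.frame` with columns `tag`, `name`, `role`.
#' @export
protein_identifiers <- function(tag, name, role = "assay") {
  stopifnot(is.character(tag), is.character(name))
  if (length(role) == 1L) role <- rep(role, length(tag))
  stopifnot(length(tag) == length(name), length(role) == length(tag))
  if (!all(role %in% c("assay", "control", "unused")))
    stop("role must be one of 'assay', 'control', 'unused'")
  if (anyDuplicated(name)) stop("protein names must be unique")
  data.frame(tag = toupper(tag), name = name, role = role,
             stringsAsFactors = FALSE)
}

#' Barcode schema
#'
#' Declarative layout of the barcode oligonucleotide: two amplification arms
#' flanking an identifier + counting-tag region. The default design is a
#' 100-bp oligo (31 + 8 + 30 + 31) of which the 38-bp identifier+tag region is
#' sequenced within a 76-bp read.
#'
#' @param identifiers `data.frame` from [protein_identifiers()].
#' @param pattern A [counting_tag_pattern()]; default is the 24-random /
#'   6-fixed 30-mer.
#' @param arm5,arm3 Amplification-arm sequences (equal length; defaults are
#'   31-bp placeholder PCR handles).
#' @param read_offset 0-based offset of the identifier+tag region within the
#'   sequenced read (default 0: the read starts at the identifier).
#' @param min_id_distance Minimum pairwise Hamming distance required among
#'   identifier tags (design-validation threshold, default 3, which makes
#'   1-mismatch demultiplexing unambiguous).
#' @return An object of class `barcode_schema`.
#' @examples
#' sch <- example_schema()
#' sch$id_length + sch$tag_length                       # 38-bp region
#' sch$id_length + sch$tag_length + 2 * sch$amp_arm_length  # 100-bp oligo
#' @export
barcode_schema <- function(identifiers,
                           pattern = default_counting_pattern(),
                           arm5 = DEFAULT_ARM5,
                           arm3 = DEFAULT_ARM3,
                           read_offset = 0L,
                           min_id_distance = 3L) {
  stopifnot(is.data.frame(identifiers),
            all(c("tag", "name", "role") %in% names(identifiers)))
  if (!inherits(pattern, "counting_tag_pattern"))
    pattern <- counting_tag_pattern(pattern)
  id_length <- unique(nchar(identifiers$tag))
  if (length(id_length) != 1L)
    stop("identifier tags must all have the same length")
  structure(
    list(
      id_length = as.integer(id_length),
      tag_length = pattern$length,
      amp_arm_length = as.integer(nchar(arm5)),
      amp_arm_count = 2L,
      arm5 = toupper(arm5),
      arm3 = toupper(arm3),
      identifiers = identifiers,
      pattern = pattern,
      read_offset = as.integer(read_offset),
      min_id_distance = as.integer(min_id_distance)
    ),
    class = "barcode_schema"
  )
}

#' @export
print.barcode_schema <- function(x, ...) {
  cat(sprintf(
    "barcode_schema: %d-bp identifier + %d-bp counting tag (%d random / %d fixed), %d x %d-bp arms => %d-bp oligo, %d-bp counted region\n",
    x$id_length, x$tag_length, x$pattern$n_random, x$pattern$n_fixed,
    x$amp_arm_count, x$amp_arm_length, oligo_length(x), region_length(x)))
  cat(sprintf("identifiers: %d (%s)\n", nrow(x$identifiers),
              paste(sprintf("%d %s", table(x$identifiers$role),
                            names(table(x$identifiers$role))), collapse = ", ")))
  invisible(x)
}

#' Schema length arithmetic
#'
#' `region_length()` is the length of the sequenced identifier+tag region;
#' `oligo_length()` the length of the full synthesized oligo.
#' @param schema A `barcode_schema`.
#' @export
region_length <- function(schema) schema$id_length + schema$tag_length

#' @rdname region_length
#' @export
oligo_length <- function(schema)
  schema$id_length + schema$tag_length + schema$amp_arm_count * schema$amp_arm_length

#' Validate a barcode schema
#'
#' Checks every design invariant and returns a report of violations; the
#' schema is valid iff the report has zero rows. Validation is side-effect
#' free and callers decide whether to abort.
#'
#' Checks: identifier alphabet, equal identifier lengths, uniqueness, minimum
#' pairwise Hamming distance, valid roles, pattern alphabet, arm alphabet and
#' equal arm lengths, and non-negative read offset.
#'
#' @param schema A `barcode_schema`.
#' @return A `data.frame` with columns `check` and `message`, one row per
#'   violation.
#' @export
validate_schema <- function(schema) {
  stopifnot(inherits(schema, "barcode_schema"))
  bad <- list()
  note <- function(check, message)
    bad[[length(bad) + 1L]] <<- data.frame(check = check, message = message,
                                           stringsAsFactors = FALSE)
  ids <- schema$identifiers
  if (!all(.check_dna(ids$tag)))
    note("identifier_alphabet", "identifier tags contain non-ACGT characters")
  if (length(unique(nchar(ids$tag))) > 1L)
    note("identifier_length", "identifier tags have unequal lengths")
  else if (unique(nchar(ids$tag)) != schema$id_length)
    note("identifier_length", "identifier tag length differs from id_length")
  dup <- ids$tag[duplicated(ids$tag)]
  if (length(dup))
    note("duplicate_identifier",
         sprintf("duplicate identifier tag(s): %s", paste(unique(dup), collapse = ", ")))
  if (!all(ids$role %in% c("assay", "control", "unused")))
    note("identifier_role", "roles must be assay/control/unused")
  if (nrow(ids) >= 2L && all(.check_dna(ids$tag)) &&
      length(unique(nchar(ids$tag))) == 1L && !length(dup)) {
    mat <- .char_matrix(ids$tag)
    dmin <- Inf
    for (i in seq_len(ncol(mat) - 1L)) {
      d <- .hamming_to_one(mat[, -seq_len(i), drop = FALSE], mat[, i])
      dmin <- min(dmin, d)
    }
    if (dmin < schema$min_id_distance)
      note("identifier_distance",
           sprintf("minimum pairwise identifier distance %d < required %d",
                   dmin, schema$min_id_distance))
  }
  if (!.check_dna(schema$pattern$pattern, allow_n = TRUE))
    note("pattern_alphabet", "counting pattern contains invalid characters")
  if (schema$pattern$length != schema$tag_length)
    note("pattern_length", "pattern length differs from tag_length")
  if (!all(.check_dna(c(schema$arm5, schema$arm3))))
    note("arm_alphabet", "amplification arms contain non-ACGT characters")
  if (nchar(schema$arm5) != nchar(schema$arm3))
    note("arm_length", "5' and 3' arms have unequal lengths")
  else if (nchar(schema$arm5) != schema$amp_arm_length)
    note("arm_length", "arm length differs from amp_arm_length")
  if (schema$read_offset < 0L)
    note("read_offset", "read_offset must be non-negative")
  if (length(bad)) do.call(rbind, bad)
  else data.frame(check = character(0), message = character(0),
                  stringsAsFactors = FALSE)
}

#' Assemble a full barcode oligo
#'
#' Concatenates arm5 + identifier + counting tag + arm3. The tag must match
#' the schema's counting pattern exactly at every fixed position.
#'
#' @param schema A `barcode_schema`.
#' @param protein Protein name or identifier tag present in the schema.
#' @param tag Counting-tag sequence of length `tag_length`.
#' @return The assembled oligo sequence (length [oligo_length()]).
#' @export
assemble_oligo <- function(schema, protein, tag) {
  stopifnot(inherits(schema, "barcode_schema"),
            is.character(protein), length(protein) == 1L,
            is.character(tag), length(tag) == 1L)
  ids <- schema$identifiers
  row <- which(ids$name == protein | ids$tag == protein)
  if (length(row) != 1L) stop(sprintf("unknown protein '%s'", protein))
  tag <- toupper(tag)
  if (nchar(tag) != schema$tag_length)
    stop(sprintf("counting tag must have length %d", schema$tag_length))
  if (!.check_dna(tag)) stop("counting tag contains non-ACGT characters")
  mm <- fixed_base_mismatches(tag, schema$pattern)
  if (mm > 0L)
    stop(sprintf("counting tag mismatches %d fixed base(s) of the pattern", mm))
  paste0(schema$arm5, ids$tag[row], tag, schema$arm3)
}

#' Count fixed-base mismatches of counting tags against a pattern
#'
#' @param tags Character vector of tag sequences (length = pattern length).
#' @param pattern A [counting_tag_pattern()].
#' @return Integer vector: number of fixed positions at which each tag
#'   disagrees with the pattern.
#' @export
fixed_base_mismatches <- function(tags, pattern) {
  stopifnot(inherits(pattern, "counting_tag_pattern"))
  if (length(tags) == 0L) return(integer(0))
  if (any(nchar(tags) != pattern$length))
    stop("tags must have the pattern's length")
  if (pattern$n_fixed == 0L) return(integer(length(tags)))
  fixed_int <- utf8ToInt(paste(pattern$fixed_bases, collapse = ""))
  mat <- .char_matrix(tags)
  as.integer(colSums(mat[pattern$fixed_positions, , drop = FALSE] != fixed_int))
}

#' Draw random counting tags
#'
#' Fills the N positions of the pattern with bases drawn uniformly from
#' {A,C,G,T}; fixed positions are set exactly. Uses R's session RNG, so the
#' draw is deterministic after `set.seed()`.
#'
#' @param pattern A [counting_tag_pattern()].
#' @param n Number of tags to draw.
#' @return Character vector of `n` tags, each passing the fixed-base check.
#' @export
random_counting_tag <- function(pattern, n = 1L) {
  stopifnot(inherits(pattern, "counting_tag_pattern"), n >= 0L)
  if (n == 0L) return(character(0))
  chars <- strsplit(pattern$pattern, "")[[1]]
  out <- matrix(rep(chars, n), nrow = pattern$length)
  n_free <- pattern$n_random
  if (n_free > 0L) {
    free <- which(chars == "N")
    out[free, ] <- sample(DNA_BASES, n_free * n, replace = TRUE)
  }
  apply(out, 2L, paste, collapse = "")
}

#' Generate an example schema with randomly designed identifiers
#'
#' Greedily picks identifier tags with pairwise Hamming distance at least
#' `min_id_distance`, mirroring the default assay design: a set of assay
#' proteins, a tag-only negative control, and a block of unused barcodes for
#' the noise floor.
#'
#' @param n_assay,n_control,n_unused Numbers of identifiers per role.
#' @param id_length Identifier length (default 8).
#' @param seed Integer seed for the identifier draw.
#' @param ... Passed on to [barcode_schema()].
#' @return A valid `barcode_schema`.
#' @export
example_schema <- function(n_assay = 4L, n_control = 1L, n_unused = 8L,
                           id_length = 8L, seed = 20L, ...) {
  n <- n_assay + n_control + n_unused
  tags <- withr_seed(seed, {
    picked <- character(0)
    mat <- NULL
    guard <- 0L
    while (length(picked) < n) {
      cand <- paste(sample(DNA_BASES, id_length, replace = TRUE), collapse = "")
      ok <- TRUE
      if (length(picked)) {
        d <- .hamming_to_one(mat, utf8ToInt(cand))
        ok <- min(d) >= 3L
      }
      if (ok) {
        picked <- c(picked, cand)
        mat <- .char_matrix(picked)
      }
      guard <- guard + 1L
      if (guard > 100000L) stop("could not design identifier set")
    }
    picked
  })
  names <- c(sprintf("protein%02d", seq_len(n_assay)),
             sprintf("control%02d", seq_len(n_control)),
             sprintf("unused%02d", seq_len(n_unused)))
  roles <- c(rep("assay", n_assay), rep("control", n_control),
             rep("unused", n_unused))
  barcode_schema(protein_identifiers(tags, names, roles), ...)
}

# evaluate `expr` under a temporary seed without disturbing the session RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Read and write schema configurations
#'
#' The schema is serialized as a YAML file holding the pattern, arms, offsets
#' and either an inline identifier table or the (relative) path of a
#' tab-separated identifier table with columns `tag`, `name`, `role`.
#'
#' @param path YAML config path.
#' @param schema A `barcode_schema`.
#' @param identifiers_file Optional file name for the identifier TSV written
#'   next to the YAML; if `NULL` the table is inlined in the YAML.
#' @return `read_schema_config()` returns a `barcode_schema`;
#'   `write_schema_config()` returns `path` invisibly.
#' @export
read_schema_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ids <- if (!is.null(cfg$identifiers_file)) {
    utils::read.delim(file.path(dirname(path), cfg$identifiers_file),
                      stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(cfg$identifiers, function(x)
      data.frame(tag = x$tag, name = x$name, role = x$role,
                 stringsAsFactors = FALSE)))
  }
  barcode_schema(
    protein_identifiers(ids$tag, ids$name, ids$role),
    pattern = counting_tag_pattern(cfg$pattern),
    arm5 = cfg$arm5, arm3 = cfg$arm3,
    read_offset = cfg$read_offset %||% 0L,
    min_id_distance = cfg$min_id_distance %||% 3L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_schema_config
#' @export
write_schema_config <- function(schema, path, identifiers_file = NULL) {
  stopifnot(inherits(schema, "barcode_schema"))
  cfg <- list(
    pattern = schema$pattern$pattern,
    arm5 = schema$arm5, arm3 = schema$arm3,
    read_offset = schema$read_offset,
    min_id_distance = schema$min_id_distance
  )
  if (is.null(identifiers_file)) {
    cfg$identifiers <- lapply(seq_len(nrow(schema$identifiers)), function(i)
      as.list(schema$identifiers[i, c("tag", "name", "role")]))
  } else {
    cfg$identifiers_file <- identifiers_file
    utils::write.table(schema$identifiers,
                       file.path(dirname(path), identifiers_file),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}
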
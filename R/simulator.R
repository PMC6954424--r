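#' Simulation configuration
#'
#' Describes a synthetic barcoded-protein sequencing experiment: per-protein
#' true molecule numbers, a PCR branching process with per-duplication
#' substitution errors, uniform amplicon sampling, and per-read sequencing
#' substitution errors.
#'
#' Default error model: `pcr_efficiency` 0.8 per cycle over 8 effective
#' cycles (enough branching to produce realistic read-count skew across
#' molecules while keeping the amplicon pool around 100x the molecule
#' number), `pcr_error_rate` 1e-5 substitutions per base per duplication
#' (high-fidelity polymerase order of magnitude), `seq_error_rate` 1e-3
#' substitutions per base (short-read platform order of magnitude).
#'
#' @param schema A `barcode_schema`.
#' @param molecules Named integer vector: true molecule count per protein
#'   name (names must exist in the schema).
#' @param pcr_cycles Number of amplification cycles.
#' @param pcr_efficiency Per-cycle duplication probability of each amplicon.
#' @param pcr_error_rate Substitutions per base per duplication event,
#'   applied to the identifier+tag region of each new copy.
#' @param seq_error_rate Substitutions per base applied to each emitted read.
#' @param reads_out Number of reads to sample (with replacement) from the
#'   amplicon pool; ignored in exhaustive mode.
#' @param unassigned_fraction Fraction of reads whose identifier segment is
#'   replaced by a random identifier-length sequence (emulates foreign or
#'   corrupt amplicons).
#' @param read_length Emitted read length (default 76).
#' @param exhaustive If `TRUE`, emit every amplicon exactly once instead of
#'   sampling; guarantees coverage of every molecule (used for exact-limit
#'   checks).
#' @param seed Integer seed; the simulation is fully deterministic given the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(schema, molecules, pcr_cycles = 8L,
                       pcr_efficiency = 0.8, pcr_error_rate = 1e-5,
                       seq_error_rate = 1e-3, reads_out = NULL,
                       unassigned_fraction = 0, read_length = 76L,
                       exhaustive = FALSE, seed = 1L) {
  stopifnot(inherits(schema, "barcode_schema"),
            length(molecules) > 0L, !is.null(names(molecules)),
            all(molecules >= 0L),
            pcr_efficiency >= 0, pcr_efficiency <= 1,
            pcr_error_rate >= 0, pcr_error_rate <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1,
            unassigned_fraction >= 0, unassigned_fraction <= 1)
  unknown <- setdiff(names(molecules), schema$identifiers$name)
  if (length(unknown))
    stop(sprintf("molecule counts name proteins absent from the schema: %s",
                 paste(unknown, collapse = ", ")))
  if (!exhaustive && is.null(reads_out))
    stop("reads_out is required unless exhaustive = TRUE")
  structure(list(schema = schema, molecules = molecules,
                 pcr_cycles = as.integer(pcr_cycles),
                 pcr_efficiency = pcr_efficiency,
                 pcr_error_rate = pcr_error_rate,
                 seq_error_rate = seq_error_rate,
                 reads_out = if (is.null(reads_out)) NULL else as.integer(reads_out),
                 unassigned_fraction = unassigned_fraction,
                 read_length = as.integer(read_length),
                 exhaustive = isTRUE(exhaustive),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# substitution mutagenesis: each sequence acquires Binomial(L, rate) errors
# at distinct positions, each to a uniformly chosen different base
.mutate_seqs <- function(seqs, rate) {
  n <- length(seqs)
  if (n == 0L) return(list(seq = seqs, n_errors = integer(0)))
  if (rate <= 0) return(list(seq = seqs, n_errors = integer(n)))
  L <- nchar(seqs)
  k <- stats::rbinom(n, L, rate)
  for (i in which(k > 0L)) {
    s <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(L[i], k[i])
    for (p in pos) s[p] <- sample(DNA_BASES[DNA_BASES != s[p]], 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  list(seq = seqs, n_errors = as.integer(k))
}

#' Simulate a barcoded-protein sequencing experiment
#'
#' Emulates the generative process behind the assay: (1) each true molecule
#' receives a distinct counting tag drawn from the schema's pattern
#' (collisions re-drawn, so ground truth is collision-free by construction);
#' (2) each molecule's identifier+tag region is amplified by a
#' Galton-Watson branching process, every duplication independently
#' introducing substitutions at `pcr_error_rate` per base; (3) `reads_out`
#' amplicons are sampled uniformly with replacement (or every amplicon once
#' in exhaustive mode); (4) each read is assembled to `read_length` bases
#' (3' arm appended, `A`-padded if needed, prefixed by the arm-5' tail when
#' `read_offset > 0`) and acquires sequencing substitutions at
#' `seq_error_rate` per base; (5) a fraction `unassigned_fraction` of reads
#' has its identifier replaced by a random sequence.
#'
#' @param config A [sim_config()].
#' @return List with `reads` (a `data.frame` usable with [write_fastq()]:
#'   `read_id`, `sequence`, `quality`) and `truth`, an object of class
#'   `sim_truth`: list with `molecules` (`protein`, `molecule_index`, `tag`)
#'   and `reads` (`read_id`, `protein`, `molecule_index`, `n_pcr_errors`,
#'   `n_seq_errors`, `scrambled_id`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  schema <- config$schema
  mols <- config$molecules[config$molecules > 0L]
  if (length(mols) == 0L)
    stop("no molecules to simulate: all configured counts are zero")
  withr_seed(config$seed, {
    # (1) ground-truth molecules with globally distinct counting tags
    total <- sum(mols)
    tags <- random_counting_tag(schema$pattern, total)
    guard <- 0L
    while (anyDuplicated(tags)) {
      dup <- which(duplicated(tags))
      tags[dup] <- random_counting_tag(schema$pattern, length(dup))
      guard <- guard + 1L
      if (guard > 1000L) stop("tag space too small for requested molecules")
    }
    proteins <- rep(names(mols), mols)
    truth_mol <- data.frame(
      protein = proteins,
      molecule_index = sequence(unname(mols)),
      tag = tags, stringsAsFactors = FALSE)
    ids <- schema$identifiers
    id_of <- stats::setNames(ids$tag, ids$name)
    region <- paste0(id_of[proteins], tags)

    # (2) PCR branching process over the identifier+tag region
    amp_region <- region
    amp_mol <- seq_len(total)
    amp_err <- integer(total)
    for (cyc in seq_len(config$pcr_cycles)) {
      dup <- stats::runif(length(amp_region)) < config$pcr_efficiency
      if (any(dup)) {
        mut <- .mutate_seqs(amp_region[dup], config$pcr_error_rate)
        amp_region <- c(amp_region, mut$seq)
        amp_mol <- c(amp_mol, amp_mol[dup])
        amp_err <- c(amp_err, amp_err[dup] + mut$n_errors)
      }
    }

    # (3) sample reads from the amplicon pool
    sel <- if (config$exhaustive) seq_along(amp_region)
           else sample.int(length(amp_region), config$reads_out,
                           replace = TRUE)
    n_reads <- length(sel)

    # (4) assemble full reads and apply sequencing errors
    prefix <- if (schema$read_offset > 0L)
      substr(schema$arm5,
             schema$amp_arm_length - schema$read_offset + 1L,
             schema$amp_arm_length) else ""
    raw <- paste0(prefix, amp_region[sel], schema$arm3)
    short <- nchar(raw) < config$read_length
    if (any(short))
      raw[short] <- paste0(raw[short],
                           strrep("A", config$read_length - nchar(raw[short])))
    raw <- substr(raw, 1L, config$read_length)
    seqd <- .mutate_seqs(raw, config$seq_error_rate)

    # (5) identifier scrambling
    scram <- stats::runif(n_reads) < config$unassigned_fraction
    out_seq <- seqd$seq
    if (any(scram)) {
      k <- sum(scram)
      rnd <- vapply(seq_len(k), function(i)
        paste(sample(DNA_BASES, schema$id_length, replace = TRUE),
              collapse = ""), character(1))
      tmp <- out_seq[scram]
      substr(tmp, schema$read_offset + 1L,
             schema$read_offset + schema$id_length) <- rnd
      out_seq[scram] <- tmp
    }

    read_id <- sprintf("read%06d", seq_len(n_reads))
    reads <- data.frame(read_id = read_id, sequence = out_seq,
                        quality = strrep("I", config$read_length),
                        stringsAsFactors = FALSE)
    truth_reads <- data.frame(
      read_id = read_id,
      protein = truth_mol$protein[amp_mol[sel]],
      molecule_index = truth_mol$molecule_index[amp_mol[sel]],
      n_pcr_errors = amp_err[sel],
      n_seq_errors = seqd$n_errors,
      scrambled_id = scram,
      stringsAsFactors = FALSE)
    truth <- structure(list(molecules = truth_mol, reads = truth_reads,
                            config = config),
                       class = "sim_truth")
    list(reads = reads, truth = truth)
  })
}

#' Compare pipeline output against simulation ground truth
#'
#' @param truth A `sim_truth` from [simulate_experiment()].
#' @param table A `molecule_count_table` from [count_molecules()].
#' @param observations Optional observation table from [demultiplex()] on
#'   the simulated reads, enabling read-level metrics.
#' @return An object of class `recovery_report`: list with `per_protein`
#'   (`protein`, `true_molecules`, `estimated_molecules`, `abs_error`,
#'   `rel_error`) and, when observations are supplied, `demux_accuracy`
#'   (fraction of unscrambled reads assigned to their true protein),
#'   `unassigned_fraction` (fraction of reads left unassigned) and
#'   `filter_exclusion_rate` (fraction of assigned reads removed by the
#'   fixed-base filter).
#' @export
recovery_report <- function(truth, table, observations = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  true_counts <- table(truth$molecules$protein)
  prot <- table$protein[table$protein %in% names(true_counts)]
  tc <- as.integer(true_counts[prot])
  est <- table$molecule_count[match(prot, table$protein)]
  per <- data.frame(protein = prot, true_molecules = tc,
                    estimated_molecules = est,
                    abs_error = abs(est - tc),
                    rel_error = abs(est - tc) / pmax(tc, 1L),
                    stringsAsFactors = FALSE)
  out <- list(per_protein = per)
  if (!is.null(observations)) {
    m <- merge(observations, truth$reads, by = "read_id",
               suffixes = c("", ".true"))
    clean <- !m$scrambled_id
    out$demux_accuracy <- mean(!is.na(m$protein[clean]) &
                                 m$protein[clean] == m$protein.true[clean])
    out$unassigned_fraction <- mean(is.na(m$protein))
    assigned <- !is.na(m$protein)
    out$filter_exclusion_rate <-
      if (any(assigned)) mean(!m$passed_filter[assigned]) else NA_real_
  }
  class(out) <- "recovery_report"
  out
}
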
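#' Run the full counting-and-calling pipeline
#'
#' Chains [read_fastq()] -> [demultiplex()] -> [count_molecules()] and, when
#' an assay sheet is supplied, noise-floor estimation and [call_ppi()] /
#' [summarize_screen()]. The result equals the composition of the
#' individually invoked stages with identical parameters; a run manifest
#' records versions, input digests, parameters and per-stage tallies.
#'
#' The assay sheet is a `data.frame` (or TSV path) with columns `protein`,
#' `set` (one of `PRS`, `RRS`, `control`) and `control_of` (for PRS/RRS rows,
#' the name of the matched negative-control protein whose signal is the
#' background for rule 2).
#'
#' @param fastq Path to a FASTQ file (or a read `data.frame`).
#' @param schema A `barcode_schema` or path to a schema YAML config.
#' @param assay_sheet Optional assay sheet (`data.frame` or TSV path).
#' @param params A [cluster_params()].
#' @param max_mismatch Identifier mismatch tolerance (see [assign_protein()]).
#' @param min_reads Minimum-signal threshold for calling (default 10).
#' @param call_on Signal used for the calls: `"reads"` (default) or
#'   `"molecules"`.
#' @param out_dir Optional directory; when given, observation, count-table
#'   and call TSVs plus a JSON manifest are written there.
#' @return List with `observations`, `count_table`, `floor`, `calls`,
#'   `screen` (when the sheet defines PRS and RRS sets) and `manifest`.
#' @export
run_pipeline <- function(fastq, schema, assay_sheet = NULL,
                         params = cluster_params(), max_mismatch = 1L,
                         min_reads = 10, call_on = c("reads", "molecules"),
                         out_dir = NULL) {
  call_on <- match.arg(call_on)
  t0 <- Sys.time()
  if (is.character(schema)) schema <- read_schema_config(schema)
  viol <- validate_schema(schema)
  if (nrow(viol))
    stop(sprintf("stage schema: invalid schema: %s",
                 paste(viol$message, collapse = "; ")))
  fastq_path <- NULL
  reads <- if (is.character(fastq)) { fastq_path <- fastq; read_fastq(fastq) }
           else fastq
  observations <- demultiplex(reads, schema, max_mismatch = max_mismatch)
  count_table <- count_molecules(observations, schema, params)

  floor <- NULL
  calls <- NULL
  screen <- NULL
  if (!is.null(assay_sheet)) {
    sheet <- if (is.character(assay_sheet))
      utils::read.delim(assay_sheet, stringsAsFactors = FALSE)
    else assay_sheet
    stopifnot(all(c("protein", "set") %in% names(sheet)))
    floor <- noise_floor(count_table, on = call_on)
    sig_col <- if (call_on == "reads") "assigned_reads" else "molecule_count"
    signal <- stats::setNames(count_table[[sig_col]], count_table$protein)
    test <- sheet[sheet$set %in% c("PRS", "RRS"), , drop = FALSE]
    if (nrow(test)) {
      ctrl <- signal[test$control_of]
      ctrl[is.na(ctrl)] <- 0
      calls <- cbind(test[, c("protein", "set")],
                     call_ppi(signal[test$protein], ctrl, floor = floor,
                              min_reads = min_reads))
      rownames(calls) <- NULL
      if (any(test$set == "PRS") && any(test$set == "RRS"))
        screen <- summarize_screen(calls$call[calls$set == "PRS"] == "positive",
                                   calls$call[calls$set == "RRS"] == "positive")
    }
  }

  manifest <- list(
    tool = "halobarcode",
    version = as.character(utils::packageVersion("halobarcode")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = if (!is.null(fastq_path))
      list(fastq = unname(tools::md5sum(fastq_path))) else list(),
    parameters = list(distance = params$distance, metric = params$metric,
                      linkage = params$linkage, max_mismatch = max_mismatch,
                      min_reads = min_reads, call_on = call_on),
    tallies = list(
      raw_reads = nrow(reads),
      assigned_reads = sum(!is.na(observations$protein)),
      filtered_reads = sum(observations$passed_filter),
      unassigned_reads = sum(is.na(observations$protein)),
      molecules = sum(count_table$molecule_count)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_observations(observations, file.path(out_dir, "observations.tsv"))
    write_count_table(count_table, file.path(out_dir, "count_table.tsv"))
    if (!is.null(calls))
      utils::write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(observations = observations, count_table = count_table,
       floor = floor, calls = calls, screen = screen, manifest = manifest)
}
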
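#' Sequencing noise floor from unused barcodes
#'
#' Read counts mapping to barcodes that are not part of the assay measure the
#' sequencing background (index hopping, synthesis cross-contamination,
#' mis-demultiplexing). Signals below mean + 3 SD of those counts are treated
#' as background noise. SD uses the sample (n-1) denominator.
#'
#' @param count_table A `molecule_count_table` (or `data.frame` with columns
#'   `role` and the chosen signal column).
#' @param on Which signal the floor is computed on: `"reads"` (default,
#'   assigned reads) or `"molecules"`.
#' @return An object of class `noise_floor`: list with `mean`, `sd`,
#'   `threshold` (= mean + 3 sd), `n` and `on`.
#' @export
noise_floor <- function(count_table, on = c("reads", "molecules")) {
  on <- match.arg(on)
  col <- if (on == "reads") "assigned_reads" else "molecule_count"
  x <- count_table[[col]][count_table$role == "unused"]
  if (length(x) < 2L)
    stop("noise floor undefined: need at least 2 unused identifiers")
  m <- mean(x)
  s <- stats::sd(x)
  structure(list(mean = m, sd = s, threshold = m + 3 * s,
                 n = length(x), on = on),
            class = "noise_floor")
}

#' @export
print.noise_floor <- function(x, ...) {
  cat(sprintf("noise floor (%s): mean %.3g, sd %.3g, threshold mean+3sd = %.3g (n = %d unused barcodes)\n",
              x$on, x$mean, x$sd, x$threshold, x$n))
  invisible(x)
}

#' Call a protein-protein interaction positive or negative
#'
#' Conjunction of three rules, each individually recorded: (1) `min_reads` —
#' prey signal at least `min_reads` (below 10 reads a pair is negative);
#' (2) `control_exceed` — prey signal strictly greater than the matched
#' negative-control (tag-only protein) signal; (3) `noise_floor` — prey
#' signal at or above the unused-barcode mean + 3 SD threshold. A pair is
#' positive iff all three hold. A pair failing only the noise-floor rule is
#' labelled `background_noise`; any other failure is `negative`.
#'
#' @param prey_reads,control_reads Non-negative numeric vectors (recycled to
#'   common length).
#' @param floor A [noise_floor()], or `NULL` to disable rule (3).
#' @param min_reads Minimum signal (default 10).
#' @return `data.frame` with columns `prey_reads`, `control_reads`, `call`
#'   (`"positive"`, `"negative"`, `"background_noise"`), and logical rule
#'   columns `rule_min_reads`, `rule_control_exceed`, `rule_noise_floor`
#'   (TRUE = rule satisfied). Attribute `thresholds` records the thresholds
#'   used.
#' @export
call_ppi <- function(prey_reads, control_reads, floor = NULL, min_reads = 10) {
  n <- max(length(prey_reads), length(control_reads))
  prey <- rep_len(prey_reads, n)
  ctrl <- rep_len(control_reads, n)
  stopifnot(all(prey >= 0), all(ctrl >= 0))
  thr <- if (is.null(floor)) 0 else floor$threshold
  r_min <- prey >= min_reads
  r_ctl <- prey > ctrl          # "exceeded" is strict: ties are negative
  r_nf <- prey >= thr
  call <- ifelse(r_min & r_ctl & r_nf, "positive",
                 ifelse(r_min & r_ctl & !r_nf, "background_noise", "negative"))
  out <- data.frame(prey_reads = prey, control_reads = ctrl, call = call,
                    rule_min_reads = r_min, rule_control_exceed = r_ctl,
                    rule_noise_floor = r_nf, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- list(min_reads = min_reads, noise_floor = thr)
  out
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Computes the exact two-tailed p-value by hypergeometric enumeration with
#' the point-probability rule: with both margins fixed, sum the probabilities
#' of every admissible table whose point probability does not exceed that of
#' the observed table (within relative tolerance 1e-7). This is the
#' convention of the common online calculators and of `stats::fisher.test`.
#'
#' @param a,b,c,d Cell counts of the table `[[a, b], [c, d]]`.
#' @return The two-tailed p-value.
#' @examples
#' fisher_exact_two_tailed(7, 9, 1, 15)  # 0.0373
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) stop("all-zero table: p undefined")
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  x <- max(0, col1 - row2):min(col1, row1)
  probs <- stats::dhyper(x, row1, row2, col1)
  p_obs <- stats::dhyper(a, row1, row2, col1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Summarize a reference-set interaction screen
#'
#' Counts positives in a positive reference set (PRS: literature-supported
#' interacting pairs) and a random reference set (RRS: pairs with no reported
#' interaction), and compares the two positivity rates with a two-tailed
#' Fisher's exact test.
#'
#' @param prs_calls,rrs_calls Either [call_ppi()] results or character/logical
#'   vectors of calls (`"positive"`/`TRUE` counts as positive).
#' @return An object of class `screen_summary`: list with `prs_positive`,
#'   `prs_total`, `rrs_positive`, `rrs_total`, `prs_rate`, `rrs_rate`,
#'   `p_two_tailed`.
#' @export
summarize_screen <- function(prs_calls, rrs_calls) {
  as_pos <- function(x) {
    if (is.data.frame(x)) x <- x$call
    if (is.logical(x)) x else x == "positive"
  }
  prs <- as_pos(prs_calls)
  rrs <- as_pos(rrs_calls)
  if (!length(prs) || !length(rrs)) stop("call lists must be non-empty")
  a <- sum(prs); b <- sum(!prs); c_ <- sum(rrs); d <- sum(!rrs)
  structure(list(
    prs_positive = a, prs_total = length(prs),
    rrs_positive = c_, rrs_total = length(rrs),
    prs_rate = a / length(prs), rrs_rate = c_ / length(rrs),
    p_two_tailed = fisher_exact_two_tailed(a, b, c_, d)
  ), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("PRS: %d/%d positive (%.1f%%)\nRRS: %d/%d positive (%.1f%%)\nFisher exact (two-tailed): p = %.4g\n",
              x$prs_positive, x$prs_total, 100 * x$prs_rate,
              x$rrs_positive, x$rrs_total, 100 * x$rrs_rate,
              x$p_two_tailed))
  invisible(x)
}

#' Call an immunoprecipitation dilution series
#'
#' For a barcoded-antigen pulldown assayed across an antibody dilution
#' ladder: replicate-barcode reads are summed per dilution; a dilution step
#' is positive iff its summed signal strictly exceeds the matched
#' background-control sum (tag-only barcoded protein); for positive steps the
#' specificity ratio is the signal divided by the signal obtained after
#' immunoprecipitation with the reference serum. The detection limit is the
#' largest dilution factor still called positive.
#'
#' @param assay `data.frame` with columns `dilution` (numeric dilution
#'   factor) and `reads`; multiple rows per dilution are the replicate
#'   barcodes and are summed.
#' @param control Same structure: matched background-control reads. A
#'   dilution missing from `control` is uncallable (`NA` call).
#' @param serum_reference Same structure: reference-serum reads, used for the
#'   specificity ratio (optional; `NULL` gives `NA` ratios).
#' @return An object of class `ip_series`: `data.frame` with columns
#'   `dilution`, `reads_sum`, `control_sum`, `serum_sum`, `call`,
#'   `specificity_ratio` (defined only for positive steps), plus attribute
#'   `detection_limit` (largest positive dilution, `NA` if none).
#' @export
call_ip_series <- function(assay, control, serum_reference = NULL) {
  stopifnot(all(c("dilution", "reads") %in% names(assay)),
            all(c("dilution", "reads") %in% names(control)))
  sum_by <- function(df) tapply(df$reads, df$dilution, sum)
  s <- sum_by(assay)
  ctl <- sum_by(control)
  ser <- if (is.null(serum_reference)) NULL else sum_by(serum_reference)
  dil <- sort(unique(assay$dilution))
  key <- as.character(dil)
  reads_sum <- as.numeric(s[key])
  control_sum <- as.numeric(ctl[key])
  serum_sum <- if (is.null(ser)) rep(NA_real_, length(dil))
               else as.numeric(ser[key])
  call <- ifelse(is.na(control_sum), NA_character_,
                 ifelse(reads_sum > control_sum, "positive", "negative"))
  ratio <- ifelse(!is.na(call) & call == "positive" & !is.na(serum_sum) &
                    serum_sum > 0, reads_sum / serum_sum, NA_real_)
  out <- data.frame(dilution = dil, reads_sum = reads_sum,
                    control_sum = control_sum, serum_sum = serum_sum,
                    call = call, specificity_ratio = ratio,
                    stringsAsFactors = FALSE)
  pos <- out$dilution[!is.na(out$call) & out$call == "positive"]
  attr(out, "detection_limit") <- if (length(pos)) max(pos) else NA_real_
  class(out) <- c("ip_series", "data.frame")
  out
}
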
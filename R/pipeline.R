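#' Staged reduction plan
#'
#' One row per stage: the clustering cutoff, the number of presort passes and
#' blocked-diagonal blocks, alignment cycles per condensation and the span.
#' [default_plan()] is the staged protocol with cutoffs falling 90 to 50 in
#' steps of 10 and multi-pass presorts of 8/4/2/1/1 passes (and blocks),
#' which shifts the early load onto the fast presort.
#'
#' @param cutoff vector of non-increasing stage cutoffs (0-100).
#' @param presort_passes presort passes per stage.
#' @param presort_blocks blocked-diagonal block count per stage.
#' @param align_cycles alignment cycles per condensation (mini-alignment size
#'   is bounded by `2^align_cycles`).
#' @param span maximum order separation compared during condensation.
#' @return a `stage_plan` data frame.
#' @export
stage_plan <- function(cutoff, presort_passes = 1L, presort_blocks = 1L,
                       align_cycles = 3L, span = 50L) {
  if (is.unsorted(rev(cutoff))) stop("stage cutoffs must be non-increasing")
  df <- data.frame(cutoff = cutoff,
                   presort_passes = as.integer(presort_passes),
                   presort_blocks = as.integer(presort_blocks),
                   align_cycles = as.integer(align_cycles),
                   span = as.integer(span))
  class(df) <- c("stage_plan", "data.frame")
  df
}

#' @rdname stage_plan
#' @export
default_plan <- function() {
  stage_plan(cutoff = c(90, 80, 70, 60, 50),
             presort_passes = c(8L, 4L, 2L, 1L, 1L),
             presort_blocks = c(8L, 4L, 2L, 1L, 1L))
}

condense_and_select <- function(records, acfg, table, user_bias) {
  minis <- condense_once(records, acfg)
  reps <- lapply(minis, select_representative, table = table,
                 user_bias = user_bias)
  out <- do.call(rbind, reps)
  class(out) <- c("seq_records", "data.frame")
  rownames(out) <- NULL
  out
}

#' Run a staged reduction schedule
#'
#' For each stage: presort (with the stage's pass and block counts), condense
#' order-adjacent sequences above the stage cutoff into mini-alignments, and
#' select one representative per mini-alignment. After the last stage the
#' floor cutoff is iterated (at most `max_floor_cycles` times) until the
#' collection stops shrinking or falls to `stop_at` sequences; finally the
#' survivors are multiply aligned with [final_align()].
#'
#' @param records a [seq_records] frame.
#' @param plan a [stage_plan()]; [default_plan()] by default.
#' @param stop_at stop once this many sequences (or fewer) remain; 0 reduces
#'   as far as the cutoffs allow.
#' @param presort_cfg a [presort_config()] (its `n_blocks` is overridden per
#'   stage).
#' @param align_cfg an [align_config()] (its `cutoff`, `span` and
#'   `n_iterations` are overridden per stage).
#' @param table a [penalty_table()].
#' @param user_bias optional named per-code bias vector (see
#'   [annotation_penalty()]).
#' @param final run the final multiple alignment.
#' @param final_floor cutoff floor of the final alignment.
#' @param max_floor_cycles cap on repeat cycles at the floor cutoff.
#' @param count_subfam also report the per-stage subfamily count (adjacency
#'   at the stage cutoff); costs one adjacent scan per stage.
#' @param verbose log per-stage counts to standard error.
#' @return a `mulsel_run`: list with `records` (the reduced collection),
#'   `report` (per-stage data frame: cutoff, seconds, sequences,
#'   subfamilies), and `msa` (a `family_msa`, or `NULL` when `final =
#'   FALSE`).
#' @export
run_schedule <- function(records, plan = default_plan(), stop_at = 0L,
                         presort_cfg = presort_config(),
                         align_cfg = align_config(),
                         table = penalty_table(), user_bias = NULL,
                         final = TRUE, final_floor = 25,
                         max_floor_cycles = 10L, count_subfam = TRUE,
                         verbose = FALSE) {
  stopifnot(nrow(plan) >= 1)
  report <- NULL
  note <- function(stage, cutoff, secs) {
    sf <- if (count_subfam) count_subfamilies(records, cutoff, align_cfg) else NA
    report <<- rbind(report, data.frame(
      stage = stage, cutoff = cutoff, seconds = round(secs, 2),
      sequences = nrow(records), subfamilies = sf))
    if (verbose)
      message(sprintf("stage %s (cutoff %g): %d sequences, %s subfamilies, %.2fs",
                      stage, cutoff, nrow(records), as.character(sf), secs))
  }
  for (st in seq_len(nrow(plan))) {
    if (nrow(records) <= stop_at) break
    t0 <- proc.time()["elapsed"]
    pcfg <- presort_cfg
    pcfg$n_blocks <- plan$presort_blocks[st]
    acfg <- align_cfg
    acfg$cutoff <- plan$cutoff[st]
    acfg$span <- plan$span[st]
    acfg$n_iterations <- plan$align_cycles[st]
    records <- presort(records, pcfg, passes = plan$presort_passes[st])
    records <- condense_and_select(records, acfg, table, user_bias)
    note(as.character(plan$cutoff[st]), plan$cutoff[st],
         proc.time()["elapsed"] - t0)
  }
  # iterate at the floor cutoff until nothing more is removed
  acfg <- align_cfg
  acfg$cutoff <- plan$cutoff[nrow(plan)]
  acfg$span <- plan$span[nrow(plan)]
  acfg$n_iterations <- plan$align_cycles[nrow(plan)]
  pcfg <- presort_cfg
  pcfg$n_blocks <- 1L
  for (cyc in seq_len(max_floor_cycles)) {
    if (nrow(records) <= stop_at) break
    t0 <- proc.time()["elapsed"]
    n0 <- nrow(records)
    records <- presort(records, pcfg, passes = 1L)
    records <- condense_and_select(records, acfg, table, user_bias)
    note(sprintf("%g.%d", acfg$cutoff, cyc), acfg$cutoff,
         proc.time()["elapsed"] - t0)
    if (nrow(records) == n0) break
  }
  msa <- NULL
  if (final) {
    t0 <- proc.time()["elapsed"]
    msa <- final_align(records, align_cfg, from = acfg$cutoff,
                       floor = final_floor)
    records <- msa$records
    note("final", final_floor, proc.time()["elapsed"] - t0)
  }
  structure(list(records = records, report = report, msa = msa),
            class = "mulsel_run")
}

#' @export
print.mulsel_run <- function(x, ...) {
  cat("staged reduction run\n")
  print(x$report, row.names = FALSE)
  if (!is.null(x$msa))
    cat(sprintf("final: %d sequences in %d families\n",
                nrow(x$records), x$msa$n_families))
  invisible(x)
}

#' Batched reduction of very large inputs
#'
#' Each batch is reduced independently down to the stages at or above
#' `merge_cutoff` (batches share no state, so they can be processed in
#' parallel or on separate machines), the selected representatives are
#' concatenated, and the union is run through the remaining lower-cutoff
#' stages.
#'
#' @param batches list of [seq_records] frames or FASTA file paths.
#' @param plan a [stage_plan()].
#' @param merge_cutoff batches are reduced through all stages with cutoff at
#'   or above this value before being combined.
#' @param ... passed on to [run_schedule()].
#' @return a `mulsel_run` for the combined collection.
#' @export
run_batched <- function(batches, plan = default_plan(), merge_cutoff = 70,
                        ...) {
  stopifnot(length(batches) >= 1)
  batches <- lapply(batches, function(b)
    if (is.character(b)) read_fasta(b) else b)
  if (any(vapply(batches, nrow, 1L) == 0)) stop("empty batch")
  pre <- plan[plan$cutoff >= merge_cutoff, , drop = FALSE]
  post <- plan[plan$cutoff < merge_cutoff, , drop = FALSE]
  if (nrow(post) == 0) post <- plan[nrow(plan), , drop = FALSE]
  reduced <- lapply(batches, function(b) {
    if (nrow(pre) == 0) return(b)
    run_schedule(b, pre, final = FALSE, ...)$records
  })
  union <- do.call(rbind, reduced)
  class(union) <- c("seq_records", "data.frame")
  rownames(union) <- NULL
  run_schedule(union, post, ...)
}

#' Trim an external alignment to its query sequence
#'
#' Deletes all alignment columns that are gapped in the query, drops
#' sequences whose remaining gap fraction against the query exceeds
#' `max_gap_frac` (default 0.25), and de-gaps the survivors. This is the
#' standard preparation of a large search alignment before reduction.
#'
#' @param alignment a gapped [seq_records] frame of equal length.
#' @param query_code code of the query sequence (must be present).
#' @param max_gap_frac maximum tolerated gap fraction.
#' @return de-gapped [seq_records] frame of the survivors.
#' @export
trim_to_query <- function(alignment, query_code, max_gap_frac = 0.25) {
  at <- which(alignment$code == query_code)
  if (length(at) != 1) stop("query '", query_code, "' absent from alignment")
  if (length(unique(nchar(alignment$residues))) != 1)
    stop("ragged alignment")
  chars <- strsplit(alignment$residues, "")
  keep_col <- chars[[at]] != "-"
  gap_frac <- vapply(chars, function(x) mean(x[keep_col] == "-"), 1.0)
  out <- alignment[gap_frac <= max_gap_frac, , drop = FALSE]
  out$residues <- degap(vapply(chars[gap_frac <= max_gap_frac],
                               function(x) paste(x[keep_col], collapse = ""),
                               ""))
  rownames(out) <- NULL
  out
}
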
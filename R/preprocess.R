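#' Discard barcodes with too few pre-induction reads
#'
#' Barcodes with fewer than `min_pre_reads` reads in the pre-induction
#' sample are discarded and excluded from downstream analysis.  The
#' pre-induction requirement is evaluated against the pre samples of the
#' table's own channel; with several replicates the default demands the
#' minimum in every replicate's pre sample (`per_replicate = "all"`),
#' since replicates are independent transformations analysed pairwise.
#' `per_replicate = "any"` instead keeps a barcode seen adequately in at
#' least one replicate.
#'
#' @param table a barcode- or guide-level `count_table`.
#' @param design a [screen_design]; its pre-condition samples that appear
#'   in `table` define the filter columns.
#' @param min_pre_reads minimum pre-induction read count (published
#'   screens use 5).
#' @param per_replicate `"all"` or `"any"` across replicate pre samples.
#' @param pre_condition which condition is "pre-induction"; defaults to
#'   the design's baseline condition.
#' @return The filtered `count_table` (all samples retained, rows
#'   dropped), with attribute `dropped` listing removed row ids.
#' @export
filter_low_pre <- function(table, design, min_pre_reads = 5L,
                           per_replicate = c("all", "any"),
                           pre_condition = design$baseline_condition) {
  per_replicate <- match.arg(per_replicate)
  stopifnot(inherits(table, "count_table"), inherits(design, "screen_design"))
  samp <- design$samples
  pre_ids <- samp$sample_id[samp$condition == pre_condition]
  pre_ids <- intersect(pre_ids, colnames(table$counts))
  if (length(pre_ids) == 0L)
    stop_ciber("design has no '%s' sample among the table's columns", pre_condition)
  pre <- table$counts[, pre_ids, drop = FALSE]
  keep <- if (per_replicate == "all") apply(pre >= min_pre_reads, 1, all)
          else apply(pre >= min_pre_reads, 1, any)
  out <- count_table(table$counts[keep, , drop = FALSE], table$level)
  attr(out, "dropped") <- rownames(table$counts)[!keep]
  out
}

#' Sum barcode counts to guide level
#'
#' Counts are summed for each guide across its independent barcodes,
#' within channel and sample.  Per-sample totals over retained barcodes
#' are conserved exactly.
#'
#' @param table a barcode-level `count_table`.
#' @param map a [barcode_map] covering every row of `table`.
#' @return A guide-level `count_table` with attribute `n_barcodes_used`
#'   (named integer vector per guide).  If the table mixes channels the
#'   rows are summed per (guide, channel) pair with ids
#'   `"<guide>.<channel>"`; single-channel tables keep plain guide ids.
#' @export
aggregate_to_guides <- function(table, map) {
  stopifnot(inherits(table, "count_table"), inherits(map, "barcode_map"))
  if (table$level != "barcode") stop_ciber("table is already at guide level")
  idx <- match(rownames(table$counts), map$barcode)
  if (anyNA(idx)) {
    missing <- rownames(table$counts)[is.na(idx)]
    stop_ciber("barcode(s) absent from map: %s",
               paste(utils::head(missing, 5), collapse = ", "))
  }
  chans <- unique(map$channel[idx])
  group <- if (length(chans) > 1L)
    paste(map$guide_id[idx], map$channel[idx], sep = ".")
  else map$guide_id[idx]
  summed <- rowsum(table$counts, group)
  out <- count_table(summed, level = "guide")
  attr(out, "n_barcodes_used") <- c(table(group))[rownames(summed)]
  out
}

#' Pair reporter and normalizer counts per guide and sample cell
#'
#' Aligns two guide-level tables on their shared guides and the design's
#' (replicate, condition) grid, yielding the matched count pairs the
#' ratio model consumes.  Guides missing from either channel are dropped
#' and reported.
#'
#' @param reporter,normalizer guide-level `count_table`s for the reporter
#'   channel and the chosen normalizer channel (matched-promoter RNA or
#'   DNA).
#' @param design a [screen_design]; its reporter rows and
#'   `normalizer_channel` rows locate the sample columns.
#' @return list with `R`, `N` (guides x samples matrices, columns named
#'   `"<condition>_r<replicate>"`), `totals_R`, `totals_N` (per-sample
#'   channel totals computed before guide alignment), `replicate`,
#'   `condition` (per column), and `dropped_guides`.
#' @export
build_ratio_input <- function(reporter, normalizer, design) {
  stopifnot(inherits(reporter, "count_table"), inherits(normalizer, "count_table"),
            inherits(design, "screen_design"))
  samp <- design$samples
  rep_samp <- samp[samp$channel == "reporter", , drop = FALSE]
  nrm_samp <- samp[samp$channel == design$normalizer_channel, , drop = FALSE]
  rep_samp <- rep_samp[rep_samp$sample_id %in% colnames(reporter$counts), , drop = FALSE]
  nrm_samp <- nrm_samp[nrm_samp$sample_id %in% colnames(normalizer$counts), , drop = FALSE]
  key <- function(d) paste0(d$condition, "_r", d$replicate)
  shared <- intersect(key(rep_samp), key(nrm_samp))
  if (length(shared) == 0L)
    stop_ciber("no shared (replicate, condition) cells between channels")
  rep_samp <- rep_samp[match(shared, key(rep_samp)), ]
  nrm_samp <- nrm_samp[match(shared, key(nrm_samp)), ]

  guides <- intersect(rownames(reporter$counts), rownames(normalizer$counts))
  if (length(guides) == 0L) stop_ciber("no overlapping guides between channels")
  dropped <- union(setdiff(rownames(reporter$counts), guides),
                   setdiff(rownames(normalizer$counts), guides))

  R <- reporter$counts[guides, rep_samp$sample_id, drop = FALSE]
  N <- normalizer$counts[guides, nrm_samp$sample_id, drop = FALSE]
  totals_R <- colSums(reporter$counts[, rep_samp$sample_id, drop = FALSE])
  totals_N <- colSums(normalizer$counts[, nrm_samp$sample_id, drop = FALSE])
  colnames(R) <- colnames(N) <- shared
  names(totals_R) <- names(totals_N) <- shared
  list(R = R, N = N, totals_R = totals_R, totals_N = totals_N,
       replicate = rep_samp$replicate, condition = rep_samp$condition,
       dropped_guides = dropped)
}
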
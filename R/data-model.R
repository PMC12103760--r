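#' @keywords internal
"_PACKAGE"

CHANNELS <- c("reporter", "normalizer", "dna")
CONDITIONS <- c("pre", "post", "post_chx")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ciber <- function(...) stop(sprintf(...), call. = FALSE)

#' Construct a barcode map
#'
#' A barcode map links each expressed barcode sequence to the guide it is
#' paired with and the channel it reports (`reporter`, `normalizer`, or
#' `dna`).  In the dual-barcode design every guide carries one reporter and
#' one matched-promoter normalizer barcode; the `dna` channel carries the
#' template-abundance barcodes.
#'
#' @param barcode character vector of uppercase A/C/G/T sequences, all of
#'   the same length (25 nt in the reference library design).
#' @param guide_id character vector of guide identifiers (opaque strings).
#' @param channel character vector, each one of `"reporter"`,
#'   `"normalizer"`, `"dna"`.
#' @return A `data.frame` of class `barcode_map` with columns `barcode`,
#'   `guide_id`, `channel` and attribute `barcode_length`.
#' @details Invariants enforced: a barcode sequence maps to exactly one
#'   (guide, channel); all barcodes share one length and the DNA alphabet;
#'   every guide with a reporter barcode also has a normalizer barcode.
#' @export
barcode_map <- function(barcode, guide_id, channel) {
  barcode <- toupper(as.character(barcode))
  guide_id <- as.character(guide_id)
  channel <- as.character(channel)
  if (length(barcode) != length(guide_id) || length(barcode) != length(channel))
    stop_ciber("barcode, guide_id and channel must have equal length")
  if (length(barcode) == 0L) stop_ciber("barcode map is empty")
  bad <- grepl("[^ACGT]", barcode)
  if (any(bad))
    stop_ciber("barcode(s) with characters outside A/C/G/T: %s",
               paste(utils::head(barcode[bad], 3), collapse = ", "))
  len <- unique(nchar(barcode))
  if (length(len) != 1L)
    stop_ciber("all barcodes must share one length (found lengths %s)",
               paste(len, collapse = ", "))
  dup <- duplicated(barcode)
  if (any(dup))
    stop_ciber("duplicate barcode(s): %s",
               paste(unique(barcode[dup]), collapse = ", "))
  if (!all(channel %in% CHANNELS))
    stop_ciber("channel must be one of %s", paste(CHANNELS, collapse = "/"))
  rep_g <- unique(guide_id[channel == "reporter"])
  norm_g <- unique(guide_id[channel == "normalizer"])
  missing_norm <- setdiff(rep_g, norm_g)
  if (length(missing_norm))
    stop_ciber("guide(s) with a reporter but no normalizer barcode: %s",
               paste(utils::head(missing_norm, 5), collapse = ", "))
  out <- data.frame(barcode = barcode, guide_id = guide_id, channel = channel,
                    stringsAsFactors = FALSE)
  attr(out, "barcode_length") <- len
  class(out) <- c("barcode_map", "data.frame")
  out
}

#' Read / write a barcode map
#'
#' Plain TSV with a header row and columns `barcode`, `guide_id`,
#' `channel`; extra columns are tolerated and ignored.
#'
#' @param path file path.
#' @return `read_barcode_map()` returns a validated [barcode_map];
#'   `write_barcode_map()` returns `path` invisibly.
#' @export
read_barcode_map <- function(path) {
  df <- read_tsv_checked(path, c("barcode", "guide_id", "channel"))
  barcode_map(df$barcode, df$guide_id, df$channel)
}

#' @rdname read_barcode_map
#' @param map a [barcode_map].
#' @export
write_barcode_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("barcode", "guide_id", "channel")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop_ciber("file not found: %s", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop_ciber("cannot parse %s: %s", path, conditionMessage(e)))
  miss <- setdiff(required_cols, names(df))
  if (length(miss))
    stop_ciber("%s lacks required column(s): %s", path, paste(miss, collapse = ", "))
  df
}

#' Construct a count table
#'
#' A barcode-by-sample (or guide-by-sample) matrix of non-negative integer
#' read counts.  Column sums are the per-sample sequencing totals and are
#' conserved by guide-level aggregation.
#'
#' @param counts integer matrix with unique rownames (barcode or guide ids)
#'   and colnames (sample ids).
#' @param level `"barcode"` or `"guide"`.
#' @return A `count_table`: list with elements `counts` (integer matrix)
#'   and `level`.
#' @export
count_table <- function(counts, level = c("barcode", "guide")) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_ciber("count matrix needs row and column names")
  if (anyDuplicated(rownames(counts)))
    stop_ciber("duplicate row ids in count table")
  if (anyDuplicated(colnames(counts)))
    stop_ciber("duplicate sample ids in count table")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop_ciber("counts must be finite non-negative integers")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, level = level), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d %s rows x %d samples; total reads %s\n",
              nrow(x$counts), x$level, ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read / write a count table
#'
#' TSV with a first column of row identifiers (header `id`) followed by one
#' integer column per sample.  Round-trips losslessly; negative or
#' non-integer entries are rejected.
#'
#' @param path file path.
#' @param level row level of the stored table, `"barcode"` or `"guide"`.
#' @return `read_count_table()` returns a `count_table`;
#'   `write_count_table()` returns `path` invisibly.
#' @export
read_count_table <- function(path, level = c("barcode", "guide")) {
  level <- match.arg(level)
  df <- read_tsv_checked(path, "id")
  if (ncol(df) < 2L) stop_ciber("%s has no sample columns", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_ciber("%s has non-numeric count entries", path)
  rownames(m) <- df$id
  count_table(m, level)
}

#' @rdname read_count_table
#' @param table a `count_table`.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Describe the replicate / condition / channel layout of a screen
#'
#' @param samples data.frame with columns `sample_id`, `replicate`
#'   (integer), `condition` (one of `pre`, `post`, `post_chx`), `channel`
#'   (one of `reporter`, `normalizer`, `dna`).
#' @param baseline_condition,contrast_condition the two conditions being
#'   contrasted; the published screens use the pre-induction sample as the
#'   baseline (post-induction for the cycloheximide comparison).
#' @param normalizer_channel `"normalizer"` for matched-promoter RNA-to-RNA
#'   normalization or `"dna"` for conventional RNA-to-DNA.
#' @return A `screen_design` object.
#' @export
screen_design <- function(samples, baseline_condition = "pre",
                          contrast_condition = "post",
                          normalizer_channel = c("normalizer", "dna")) {
  normalizer_channel <- match.arg(normalizer_channel)
  need <- c("sample_id", "replicate", "condition", "channel")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop_ciber("design lacks column(s): %s", paste(miss, collapse = ", "))
  samples <- as.data.frame(samples)[, need]
  samples$replicate <- as.integer(samples$replicate)
  if (!all(samples$condition %in% CONDITIONS))
    stop_ciber("condition must be one of %s", paste(CONDITIONS, collapse = "/"))
  if (!all(samples$channel %in% CHANNELS))
    stop_ciber("channel must be one of %s", paste(CHANNELS, collapse = "/"))
  if (anyDuplicated(samples$sample_id))
    stop_ciber("duplicate sample_id in design")
  if (identical(baseline_condition, contrast_condition))
    stop_ciber("baseline and contrast conditions must differ")
  rep_cells <- samples[samples$channel == "reporter", c("replicate", "condition")]
  norm_cells <- samples[samples$channel == normalizer_channel,
                        c("replicate", "condition")]
  key <- function(d) paste(d$replicate, d$condition)
  missing_cells <- setdiff(key(rep_cells), key(norm_cells))
  if (length(missing_cells))
    stop_ciber("(replicate, condition) cell(s) present for reporter but not %s: %s",
               normalizer_channel, paste(missing_cells, collapse = "; "))
  structure(list(samples = samples,
                 baseline_condition = baseline_condition,
                 contrast_condition = contrast_condition,
                 normalizer_channel = normalizer_channel),
            class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf("screen_design: %d samples, %d replicates; %s vs %s (baseline), normalizer = %s\n",
              nrow(x$samples), length(unique(x$samples$replicate)),
              x$contrast_condition, x$baseline_condition, x$normalizer_channel))
  invisible(x)
}

#' Read a sample sheet into a screen design
#'
#' TSV with columns `sample_id`, `replicate`, `condition`, `channel`.
#'
#' @inheritParams screen_design
#' @param path file path.
#' @export
read_screen_design <- function(path, baseline_condition = "pre",
                               contrast_condition = "post",
                               normalizer_channel = c("normalizer", "dna")) {
  df <- read_tsv_checked(path, c("sample_id", "replicate", "condition", "channel"))
  screen_design(df, baseline_condition, contrast_condition,
                match.arg(normalizer_channel))
}

#' Guide-to-gene annotation
#'
#' @param guide_id,gene character vectors; each guide appears at most once,
#'   genes may be shared by several guides (the libraries average more than
#'   two guides per gene).
#' @return data.frame of class `guide_annotation`.
#' @export
guide_annotation <- function(guide_id, gene) {
  guide_id <- as.character(guide_id); gene <- as.character(gene)
  if (length(guide_id) != length(gene))
    stop_ciber("guide_id and gene must have equal length")
  if (anyDuplicated(guide_id))
    stop_ciber("duplicate guide_id in annotation")
  out <- data.frame(guide_id = guide_id, gene = gene, stringsAsFactors = FALSE)
  class(out) <- c("guide_annotation", "data.frame")
  out
}

#' @rdname guide_annotation
#' @param path TSV with columns `guide_id`, `gene`.
#' @export
read_guide_annotation <- function(path) {
  df <- read_tsv_checked(path, c("guide_id", "gene"))
  guide_annotation(df$guide_id, df$gene)
}
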
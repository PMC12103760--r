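#' Read layout for FASTQ emission
#'
#' Reads are `prefix + barcode + suffix` with independent per-base
#' substitution errors at `error_rate`; qualities are a constant
#' Phred+33 character.
#'
#' @param prefix fixed anchor sequence preceding the barcode (may be "").
#' @param suffix fixed sequence following the barcode (may be "").
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param quality_char single quality character written for every base.
#' @return A `read_layout` list.
#' @export
read_layout <- function(prefix = "ACGTACGTAC", suffix = "GATC",
                        error_rate = 0, quality_char = "I") {
  prefix <- toupper(prefix); suffix <- toupper(suffix)
  if (grepl("[^ACGT]", paste0(prefix, suffix, "A")))
    stop_ciber("prefix/suffix must be A/C/G/T")
  if (error_rate < 0 || error_rate >= 1)
    stop_ciber("error_rate must lie in [0, 1)")
  structure(list(prefix = prefix, suffix = suffix, error_rate = error_rate,
                 quality_char = quality_char),
            class = "read_layout")
}

inject_substitutions <- function(reads, error_rate) {
  if (error_rate == 0 || length(reads) == 0L) return(reads)
  alphabet <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(reads, ""))
  hit <- matrix(stats::runif(length(mat)) < error_rate, nrow(mat))
  if (any(hit)) {
    # substitute with one of the three other bases, uniformly
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    cur <- match(mat[hit], alphabet)
    mat[hit] <- alphabet[((cur - 1L + shift) %% 4L) + 1L]
  }
  apply(mat, 1, paste, collapse = "")
}

#' Emit simulated reads as FASTQ files
#'
#' Writes one FASTQ per sample column of a barcode-level count table:
#' each barcode contributes exactly its count in reads (before error
#' injection), read order is shuffled, substitution errors are injected
#' independently per base.  Inverse of [count_fastq] at error rate 0.
#'
#' @param counts barcode-level `count_table` (rows must appear in `map`).
#' @param map a [barcode_map].
#' @param layout a [read_layout].
#' @param dir output directory (created if needed).
#' @param seed integer seed controlling error injection and read order.
#' @return named character vector of written file paths (sample ids as
#'   names), suitable for [count_fastq].
#' @export
emit_fastq <- function(counts, map, layout = read_layout(), dir, seed = 1L) {
  stopifnot(inherits(counts, "count_table"), inherits(map, "barcode_map"))
  bl <- attr(map, "barcode_length") %||% nchar(map$barcode[1])
  if (any(!rownames(counts$counts) %in% map$barcode))
    stop_ciber("count rows absent from barcode map")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- character(0)
  for (s in colnames(counts$counts)) {
    cnt <- counts$counts[, s]
    reads <- rep(paste0(layout$prefix, rownames(counts$counts), layout$suffix),
                 times = cnt)
    if (length(reads)) reads <- sample(reads)
    reads <- inject_substitutions(reads, layout$error_rate)
    qual <- strrep(layout$quality_char, nchar(layout$prefix) + bl +
                     nchar(layout$suffix))
    path <- file.path(dir, paste0(s, ".fastq"))
    if (length(reads)) {
      rec <- rbind(paste0("@read", seq_along(reads)), reads, "+", qual)
      writeLines(as.vector(rec), path)
    } else writeLines(character(0), path)
    files[s] <- path
  }
  files
}
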
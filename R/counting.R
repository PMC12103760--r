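#' Barcode matching policy
#'
#' @param max_mismatches maximum Hamming distance (0, 1 or 2) between the
#'   extracted barcode window and a library barcode.  Library generation
#'   enforces a pairwise distance of at least 3, so one-mismatch
#'   assignment is unambiguous on generated libraries.
#' @param require_unique if `TRUE` (default) a window at equal minimal
#'   distance from two library barcodes is never assigned.
#' @param anchor fixed sequence immediately preceding the barcode slot;
#'   `""` puts the barcode at the start of the read.
#' @param anchor_max_mismatches mismatches tolerated when locating the
#'   anchor.
#' @return A `match_policy` list.
#' @export
match_policy <- function(max_mismatches = 1L, require_unique = TRUE,
                         anchor = "", anchor_max_mismatches = 1L) {
  if (!max_mismatches %in% 0:2)
    stop_ciber("max_mismatches must be 0, 1 or 2")
  anchor <- toupper(anchor)
  if (nchar(anchor) && grepl("[^ACGT]", anchor))
    stop_ciber("anchor must be A/C/G/T")
  structure(list(max_mismatches = as.integer(max_mismatches),
                 require_unique = isTRUE(require_unique),
                 anchor = anchor,
                 anchor_max_mismatches = as.integer(anchor_max_mismatches)),
            class = "match_policy")
}

# Index of a barcode map for repeated matching.  Exact lookups use a
# hashed environment; 1-neighbour lookups map every distance-1 variant to
# its barcode index, with collisions marked ambiguous (-1).
build_barcode_index <- function(map, max_mismatches) {
  exact <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(map))) exact[[map$barcode[i]]] <- i
  nb1 <- NULL
  if (max_mismatches >= 1L) {
    nb1 <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(nrow(map))) {
      for (s in hamming_neighbors(map$barcode[i])) {
        cur <- nb1[[s]]
        nb1[[s]] <- if (is.null(cur)) i else -1L
      }
    }
  }
  list(exact = exact, nb1 = nb1, map = map,
       barcode_length = attr(map, "barcode_length") %||% nchar(map$barcode[1]))
}

hamming_dist <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  if (length(av) != length(bv)) return(Inf)
  sum(av != bv)
}

# Match one barcode window against the index.  Returns the map row index,
# 0 for unmatched, -1 for ambiguous.
match_window <- function(window, idx, policy) {
  hit <- idx$exact[[window]]
  if (!is.null(hit)) return(hit)
  if (policy$max_mismatches == 0L) return(0L)
  hit <- idx$nb1[[window]]
  if (!is.null(hit)) {
    if (hit > 0L) return(hit)
    return(if (policy$require_unique) -1L else 0L)
  }
  if (policy$max_mismatches < 2L) return(0L)
  d <- vapply(idx$map$barcode, hamming_dist, numeric(1), b = window,
              USE.NAMES = FALSE)
  dmin <- min(d)
  if (dmin > policy$max_mismatches) return(0L)
  best <- which(d == dmin)
  if (length(best) > 1L) return(if (policy$require_unique) -1L else 0L)
  best
}

# Locate the anchor in a read; returns the 1-based position after the
# anchor (barcode start), or NA.  Position 1 is tried first (the layout
# used by the FASTQ emitter), then a sliding scan.
locate_anchor <- function(read, anchor, max_mm, barcode_length) {
  la <- nchar(anchor)
  if (la == 0L) return(1L)
  lr <- nchar(read)
  last <- lr - la - barcode_length + 1L
  if (last < 1L) return(NA_integer_)
  for (pos in seq_len(last)) {
    if (hamming_dist(substr(read, pos, pos + la - 1L), anchor) <= max_mm)
      return(pos + la)
  }
  NA_integer_
}

#' Match a single read against a barcode map
#'
#' Locates the anchor (tolerating `anchor_max_mismatches`), extracts the
#' barcode-length window that follows, and assigns the unique library
#' barcode within `max_mismatches` Hamming distance.  Ambiguity
#' (two barcodes at equal minimal distance) and failure are reported as
#' status, never as errors.
#'
#' @param read_sequence character read sequence.
#' @param map a [barcode_map].
#' @param policy a [match_policy].
#' @return list with `status` (`"matched"`, `"ambiguous"`,
#'   `"unmatched"`) and, when matched, `barcode`, `guide_id`, `channel`.
#' @export
match_read <- function(read_sequence, map, policy = match_policy()) {
  idx <- build_barcode_index(map, policy$max_mismatches)
  match_read_indexed(toupper(read_sequence), idx, policy)
}

match_read_indexed <- function(read, idx, policy) {
  bl <- idx$barcode_length
  start <- locate_anchor(read, policy$anchor, policy$anchor_max_mismatches, bl)
  if (is.na(start) || nchar(read) < start + bl - 1L)
    return(list(status = "unmatched"))
  window <- substr(read, start, start + bl - 1L)
  hit <- match_window(window, idx, policy)
  if (hit > 0L)
    return(list(status = "matched", barcode = idx$map$barcode[hit],
                guide_id = idx$map$guide_id[hit], channel = idx$map$channel[hit]))
  list(status = if (hit < 0L) "ambiguous" else "unmatched")
}

read_fastq_sequences <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con))
  n_lines <- 0L
  while (length(chunk <- readLines(con, 65536L))) n_lines <- n_lines + length(chunk)
  if (n_lines %% 4L != 0L)
    stop_ciber("truncated FASTQ record in %s (record %d incomplete)",
               path, n_lines %/% 4L + 1L)
  if (n_lines == 0L) return(character(0))
  reads <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop_ciber("cannot parse FASTQ %s: %s",
                                   path, conditionMessage(e)))
  as.character(reads)
}

#' Count barcodes in per-sample FASTQ files
#'
#' Every read is anchored, its barcode window extracted and matched
#' against the map under the policy; matched + ambiguous + unmatched
#' reads partition each sample's total exactly.  Identical read
#' sequences are matched once and tallied, so counting is independent of
#' read order.
#'
#' @param files named character vector: `sample_id -> FASTQ path`
#'   (plain or gzip).
#' @param map a [barcode_map].
#' @param policy a [match_policy].
#' @return list with `counts` (barcode-level `count_table`, one row per
#'   map barcode, one column per sample) and `report` (data.frame of
#'   total / matched / ambiguous / unmatched per sample).
#' @export
count_fastq <- function(files, map, policy = match_policy()) {
  if (is.null(names(files)) || any(names(files) == ""))
    stop_ciber("files must be a named vector (sample ids as names)")
  idx <- build_barcode_index(map, policy$max_mismatches)
  counts <- matrix(0L, nrow(map), length(files),
                   dimnames = list(map$barcode, names(files)))
  report <- data.frame(sample_id = names(files), total = 0L, matched = 0L,
                       ambiguous = 0L, unmatched = 0L, stringsAsFactors = FALSE)
  for (j in seq_along(files)) {
    reads <- read_fastq_sequences(files[[j]])
    report$total[j] <- length(reads)
    if (length(reads) == 0L) next
    tab <- table(reads)
    uniq <- names(tab)
    n_per <- as.integer(tab)
    hits <- integer(length(uniq))
    for (k in seq_along(uniq)) {
      m <- match_read_indexed(uniq[k], idx, policy)
      hits[k] <- switch(m$status, matched = match(m$barcode, map$barcode),
                        ambiguous = -1L, unmatched = 0L)
    }
    matched <- hits > 0L
    if (any(matched)) {
      add <- rowsum(n_per[matched], hits[matched])
      counts[as.integer(rownames(add)), j] <-
        counts[as.integer(rownames(add)), j] + add[, 1]
    }
    report$matched[j] <- sum(n_per[matched])
    report$ambiguous[j] <- sum(n_per[hits == -1L])
    report$unmatched[j] <- sum(n_per[hits == 0L])
  }
  list(counts = count_table(counts, "barcode"), report = report)
}
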
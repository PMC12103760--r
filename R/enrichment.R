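#' One-sided Fisher's exact test for overrepresentation
#'
#' Hypergeometric upper tail `P[X >= k]` for observing `k` hit genes in a
#' set of size `K`, with `n` hits among a universe of `N` genes —
#' computed by exact summation of the hypergeometric mass, no
#' approximation.
#'
#' @param k hits inside the set.
#' @param K set size.
#' @param n total hits.
#' @param N universe size.
#' @return the exact p-value.
#' @export
fisher_exact_one_sided <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop_ciber("inconsistent margins: k=%d K=%d n=%d N=%d", k, K, n, N)
  sum(stats::dhyper(k:min(K, n), m = K, n = N - K, k = n))
}

#' Gene-set overrepresentation with Bonferroni correction
#'
#' For each set, the one-sided Fisher's exact p of the hit/set overlap,
#' fold enrichment `(k/n)/(K/N)`, and the Bonferroni-corrected p over
#' the number of sets tested; a set is significant iff the corrected p
#' is below `alpha` (published analyses use 0.05).  The universe
#' defaults to all genes targeted by the guide library, which defines
#' the sampling frame.
#'
#' @param hit_genes character vector of significant genes (subset of
#'   `universe`).
#' @param gene_sets named list of character vectors.
#' @param universe character vector of all testable genes.
#' @param alpha significance level on the Bonferroni-corrected p.
#' @param alternative `"greater"` (overrepresentation, default) or
#'   `"two.sided"`.
#' @return data.frame sorted by p: `set`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p`, `p_bonferroni`, `significant`.
#' @export
overrepresentation <- function(hit_genes, gene_sets, universe, alpha = 0.05,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0L) stop_ciber("empty universe")
  if (length(gene_sets) == 0L) stop_ciber("no gene sets supplied")
  if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
    stop_ciber("gene_sets must be a named list")
  universe <- unique(universe)
  hit_genes <- unique(hit_genes)
  stray <- setdiff(hit_genes, universe)
  if (length(stray))
    stop_ciber("hit gene(s) outside the universe: %s",
               paste(utils::head(stray, 5), collapse = ", "))
  N <- length(universe); n <- length(hit_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(members)
    k <- length(intersect(members, hit_genes))
    p <- if (alternative == "greater") fisher_exact_one_sided(k, K, n, N)
    else stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                            alternative = "two.sided")$p.value
    fe <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
    data.frame(set = nm, k = k, K = K, n = n, N = N, fold_enrichment = fe,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * length(gene_sets))
  out$significant <- out$p_bonferroni < alpha
  out[order(out$p), , drop = FALSE]
}

#' Read gene sets from a GMT-like TSV
#'
#' One set per line: set name, description, then member genes, all
#' tab-separated.
#'
#' @param path file path.
#' @return named list of character gene vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_ciber("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop_ciber("line %d of %s has fewer than 3 fields", i, path)
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  sets
}
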
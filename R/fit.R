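#' Fit the moderated ratio model to a barcoded CRISPRi screen
#'
#' The central analysis: for every guide, the library-size-normalized
#' log2 reporter/normalizer ratio is formed per sample, the change of
#' that ratio between the baseline and contrast conditions is estimated
#' across biological replicates, per-guide variances are shrunk toward an
#' empirical-Bayes prior, and a moderated t-test with Benjamini-Hochberg
#' FDR calls significant guides at the screen's thresholds.
#'
#' With `design_mode = "paired"` (the default) the pre and post samples
#' of a replicate are treated as a pair — the model of the published
#' screens, where both samples come from the same culture — and the test
#' is a one-sample moderated t on the per-replicate ratio changes.
#' `"unpaired"` fits a two-group comparison of the per-sample log ratios
#' with a pooled variance, for count deposits whose replicate pairing is
#' unknown.
#'
#' @param reporter guide-level `count_table` of reporter-channel counts.
#' @param normalizer guide-level `count_table` of the normalizer channel
#'   chosen in `design` (matched-promoter RNA or DNA).
#' @param design a [screen_design].
#' @param annotation optional [guide_annotation] used by
#'   [summary.ciber_fit] and [gene_results].
#' @param q_threshold,lfc_threshold significance thresholds (published
#'   screens: q < 0.01 with |log2 fold change| > 1 or > 2).
#' @param pseudocount added to counts inside the log ratio.
#' @param q_floor display floor for adjusted p-values.
#' @param moderate logical; `FALSE` switches variance moderation off
#'   (`d0 = 0`, classical t-test).
#' @param center `"median"` (default) subtracts each sample's median
#'   log ratio from its column before differencing.  Sequencing at fixed
#'   depth makes counts compositional: if induced guides change total
#'   reporter output, every guide's raw ratio shifts by the same
#'   sample-level constant.  Median-of-ratios centering removes that
#'   shift under the standard assumption that most guides are
#'   phenotypically null.  `"none"` disables it.
#' @param design_mode `"paired"` or `"unpaired"`.
#' @param var_floor floor applied to per-guide variances.
#' @return An object of class `ciber_fit` with components
#'   `results` (per-guide data.frame: `guide_id`, `log2fc`,
#'   `mean_log_expr`, `t`, `p`, `q`, `q_display`, `significant`,
#'   `direction`), `moderation` (the [fit_moderation] object), `L`
#'   (log-ratio matrix), `D` (per-replicate ratio changes, paired mode),
#'   `design`, `thresholds`, `design_mode`, `dropped_guides`, `call`.
#' @seealso [coef.ciber_fit], [summary.ciber_fit], [plot.ciber_fit],
#'   [residuals.ciber_fit]
#' @examples
#' scr <- simulate_screen(simulation_config(n_guides = 100, depth = 1e5, seed = 42))
#' fit <- ciber_fit(scr$reporter, scr$normalizer, scr$design)
#' head(coef(fit))
#' summary(fit)
#' @export
ciber_fit <- function(reporter, normalizer, design, annotation = NULL,
                      q_threshold = 0.01, lfc_threshold = 1,
                      pseudocount = 0.5, q_floor = 1e-50,
                      moderate = TRUE,
                      center = c("median", "none"),
                      design_mode = c("paired", "unpaired"),
                      var_floor = 1e-8) {
  design_mode <- match.arg(design_mode)
  center <- match.arg(center)
  if (lfc_threshold < 0) stop_ciber("lfc_threshold must be non-negative")
  if (q_threshold <= 0 || q_threshold > 1) stop_ciber("q_threshold must lie in (0,1]")
  inp <- build_ratio_input(reporter, normalizer, design)

  L <- log_ratio(inp$R, inp$N,
                 total_R = rep(inp$totals_R, each = nrow(inp$R)),
                 total_N = rep(inp$totals_N, each = nrow(inp$N)),
                 pseudocount = pseudocount)
  dim(L) <- dim(inp$R); dimnames(L) <- dimnames(inp$R)
  if (center == "median")
    L <- sweep(L, 2, apply(L, 2, stats::median))

  base_cols <- which(inp$condition == design$baseline_condition)
  ctr_cols <- which(inp$condition == design$contrast_condition)
  if (!length(base_cols) || !length(ctr_cols))
    stop_ciber("design's baseline/contrast conditions not found among samples")

  if (design_mode == "paired") {
    reps <- intersect(inp$replicate[base_cols], inp$replicate[ctr_cols])
    if (length(reps) < 2L)
      stop_ciber("paired analysis needs >= 2 replicates with both conditions")
    bl <- L[, base_cols[match(reps, inp$replicate[base_cols])], drop = FALSE]
    ct <- L[, ctr_cols[match(reps, inp$replicate[ctr_cols])], drop = FALSE]
    grc <- guide_ratio_change(bl, ct)
    D <- ct - bl
    colnames(D) <- paste0("r", reps)
    n_eff <- length(reps)
  } else {
    nb <- length(base_cols); nc <- length(ctr_cols)
    if (nb + nc < 3L) stop_ciber("unpaired analysis needs >= 3 samples total")
    mb <- rowMeans(L[, base_cols, drop = FALSE])
    mc <- rowMeans(L[, ctr_cols, drop = FALSE])
    vb <- apply(L[, base_cols, drop = FALSE], 1, stats::var)
    vc <- apply(L[, ctr_cols, drop = FALSE], 1, stats::var)
    pooled <- ((nb - 1) * vb + (nc - 1) * vc) / (nb + nc - 2)
    grc <- data.frame(log2fc = mc - mb, s2 = pooled, df = nb + nc - 2L,
                      n_replicates = NA_integer_, row.names = rownames(L))
    D <- NULL
    # variance of (mc - mb) = pooled * (1/nb + 1/nc); reuse the paired-test
    # formula t = lfc / sqrt(s2_post / n_eff) with n_eff = 1/(1/nb + 1/nc)
    n_eff <- 1 / (1 / nb + 1 / nc)
  }

  mod <- if (moderate) fit_moderation(grc$s2, grc$df, var_floor = var_floor)
  else {
    s2f <- pmax(grc$s2, var_floor)
    structure(list(d0 = 0, s0_sq = NA_real_, s2 = s2f, df = grc$df,
                   s2_post = s2f, df_total = grc$df),
              class = "moderation_fit")
  }

  tst <- moderated_test(grc$log2fc, mod$s2_post, mod$df_total, n_eff)
  res <- data.frame(guide_id = rownames(L),
                    log2fc = grc$log2fc,
                    mean_log_expr = rowMeans(L),
                    s2 = grc$s2,
                    t = tst$t,
                    p = tst$p,
                    q = bh_fdr(tst$p),
                    row.names = NULL, stringsAsFactors = FALSE)
  nb_used <- attr(reporter, "n_barcodes_used")
  res$n_barcodes_used <- if (!is.null(nb_used))
    as.integer(nb_used[res$guide_id]) else NA_integer_
  res <- call_significant(res, q_threshold, lfc_threshold, q_floor)
  if (!is.null(annotation))
    res$gene <- annotation$gene[match(res$guide_id, annotation$guide_id)]

  structure(list(results = res, moderation = mod, L = L, D = D,
                 design = design, annotation = annotation,
                 thresholds = list(q = q_threshold, lfc = lfc_threshold,
                                   q_floor = q_floor),
                 design_mode = design_mode, n_eff = n_eff,
                 dropped_guides = inp$dropped_guides,
                 call = match.call()),
            class = "ciber_fit")
}

#' @export
print.ciber_fit <- function(x, ...) {
  cat("Moderated ratio model of a barcoded CRISPRi screen\n")
  cat(sprintf("  normalization: reporter / %s (%s)\n",
              x$design$normalizer_channel,
              if (x$design$normalizer_channel == "normalizer")
                "matched-promoter RNA-to-RNA" else "RNA-to-DNA"))
  cat(sprintf("  contrast: %s vs %s (baseline), %s design\n",
              x$design$contrast_condition, x$design$baseline_condition,
              x$design_mode))
  cat(sprintf("  guides tested: %d; prior: d0 = %.3g, s0^2 = %.3g\n",
              nrow(x$results), x$moderation$d0, x$moderation$s0_sq))
  cat(sprintf("  significant at q < %g, |log2fc| > %g: %d (%d up, %d down)\n",
              x$thresholds$q, x$thresholds$lfc, sum(x$results$significant),
              sum(x$results$direction == "up"),
              sum(x$results$direction == "down")))
  invisible(x)
}

#' Summarize a fitted screen
#'
#' @param object a [ciber_fit].
#' @param n number of top guides (by q) to display.
#' @param ... unused.
#' @return Invisibly, a list with the significant-guide table and, when
#'   an annotation is attached, the per-gene roll-up.
#' @export
summary.ciber_fit <- function(object, n = 10L, ...) {
  print(object)
  res <- object$results
  top <- res[order(res$q, -abs(res$log2fc)), ]
  top <- utils::head(top[, c("guide_id", "log2fc", "t", "p", "q_display",
                             "significant", "direction")], n)
  cat("\nTop guides:\n")
  print(top, row.names = FALSE, digits = 4)
  genes <- NULL
  if (!is.null(object$annotation)) {
    genes <- gene_results(object)
    sig_genes <- genes[genes$n_significant_guides > 0, , drop = FALSE]
    cat(sprintf("\nGenes with >= 1 significant guide: %d\n", nrow(sig_genes)))
  }
  invisible(list(top_guides = top, genes = genes))
}

#' @export
coef.ciber_fit <- function(object, ...) {
  stats::setNames(object$results$log2fc, object$results$guide_id)
}

#' Per-replicate residuals of the paired ratio model
#'
#' Paired mode only: `D_gr - log2fc_g`, the deviation of each
#' replicate's ratio change from the guide's estimate.
#'
#' @param object a [ciber_fit].
#' @param ... unused.
#' @export
residuals.ciber_fit <- function(object, ...) {
  if (is.null(object$D))
    stop_ciber("residuals are defined for the paired design mode only")
  sweep(object$D, 1, object$results$log2fc)
}

#' Volcano plot of a fitted screen
#'
#' log2 fold change against -log10 displayed q, with the screen's
#' thresholds drawn as dashed lines and significant guides highlighted.
#'
#' @param x a [ciber_fit].
#' @param ... passed to [graphics::plot].
#' @export
plot.ciber_fit <- function(x, ...) {
  res <- x$results
  graphics::plot(res$log2fc, -log10(res$q_display),
                 pch = 16, cex = 0.5,
                 col = ifelse(res$significant, "red3", "grey50"),
                 xlab = expression(log[2] ~ "fold change of reporter/normalizer ratio"),
                 ylab = expression(-log[10] ~ "q-value"), ...)
  graphics::abline(h = -log10(x$thresholds$q), lty = 2)
  graphics::abline(v = c(-1, 1) * x$thresholds$lfc, lty = 2)
  invisible(x)
}

#' Per-gene roll-up of a fitted screen
#'
#' @param fit a [ciber_fit] built with an annotation (or pass one here).
#' @param annotation optional [guide_annotation] overriding the fit's.
#' @return see [summarize_by_gene].
#' @export
gene_results <- function(fit, annotation = fit$annotation) {
  if (is.null(annotation)) stop_ciber("no guide annotation available")
  summarize_by_gene(fit$results, annotation)
}

#' Significant-guide table of a fitted screen
#'
#' @param fit a [ciber_fit].
#' @return rows of `fit$results` passing the thresholds, ordered by q.
#' @export
significant_guides <- function(fit) {
  res <- fit$results[fit$results$significant, , drop = FALSE]
  res[order(res$q, -abs(res$log2fc)), , drop = FALSE]
}

#' Write the guide result table as TSV
#'
#' @param fit a [ciber_fit].
#' @param path output file.
#' @export
write_results <- function(fit, path) {
  utils::write.table(fit$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
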
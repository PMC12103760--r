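#' Library-size-normalized log2 ratio of reporter to normalizer counts
#'
#' `L = log2[(R + pc) / total_R * 1e6] - log2[(N + pc) / total_N * 1e6]`.
#' The per-million scaling cancels in the ratio but keeps each term an
#' interpretable log2 counts-per-million; the 0.5 pseudocount stabilizes
#' low counts.  Doubling counts and totals together leaves L unchanged.
#'
#' @param R,N reporter and normalizer read counts (vectors recycle).
#' @param total_R,total_N per-sample totals for the two channels.
#' @param pseudocount added to each count before the log.
#' @return log2 ratio(s).
#' @export
log_ratio <- function(R, N, total_R, total_N, pseudocount = 0.5) {
  if (any(R < 0) || any(N < 0)) stop_ciber("counts must be non-negative")
  if (any(total_R <= 0) || any(total_N <= 0)) stop_ciber("totals must be positive")
  log2((R + pseudocount) / total_R * 1e6) - log2((N + pseudocount) / total_N * 1e6)
}

#' Per-guide paired ratio change across replicates
#'
#' For each guide the paired difference `D_r = L[contrast, r] -
#' L[baseline, r]` is formed per replicate; the effect estimate is
#' `mean(D_r)`, its sample variance `s2` carries `df = n_replicates - 1`.
#'
#' @param L_baseline,L_contrast numeric matrices, guides x replicates, of
#'   log2 ratios in the baseline and contrast conditions (columns aligned
#'   by replicate).
#' @return data.frame with `log2fc`, `s2`, `df`, `n_replicates` per row.
#' @export
guide_ratio_change <- function(L_baseline, L_contrast) {
  L_baseline <- as.matrix(L_baseline); L_contrast <- as.matrix(L_contrast)
  if (!identical(dim(L_baseline), dim(L_contrast)))
    stop_ciber("baseline and contrast matrices must be guides x replicates with equal dims")
  n_rep <- ncol(L_baseline)
  if (n_rep < 1L) stop_ciber("no replicates")
  D <- L_contrast - L_baseline
  lfc <- rowMeans(D)
  s2 <- if (n_rep >= 2L) apply(D, 1, stats::var) else rep(NA_real_, nrow(D))
  data.frame(log2fc = lfc, s2 = s2, df = n_rep - 1L, n_replicates = n_rep,
             row.names = rownames(D))
}

# Solve trigamma(x) = y by Newton iteration on 1/trigamma (monotone).
trigamma_inverse <- function(y) {
  out <- y
  ok <- is.finite(y) & y > 0
  out[!ok] <- NA_real_
  big <- ok & y > 1e7          # trigamma(x) ~ 1/x for tiny x
  out[big] <- 1 / sqrt(y[big])
  small <- ok & y < 1e-6       # trigamma(x) ~ 1/x + 1/(2x^2) for large x
  out[small] <- 1 / y[small]
  mid <- ok & !big & !small
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

#' Fit the empirical-Bayes variance prior
#'
#' Models the per-guide residual variances `s_g^2` (df `d_g`) as draws
#' from a scaled F about a prior `s0^2` with prior df `d0`, estimated by
#' moment-matching the log variances (the classical moderated-t prior
#' fit).  The moderated variance is the df-weighted shrinkage
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, which always lies
#' between `s_g^2` and `s0^2`; `d0 = 0` recovers the raw variances and
#' `d0 = Inf` forces every variance to `s0^2`.
#'
#' @param s2 per-guide sample variances.
#' @param df per-guide residual degrees of freedom (scalar or vector).
#' @param var_floor variances below this are raised to it before fitting;
#'   with two replicates exact zeros are common and uninformative.
#' @return A `moderation_fit`: list with `d0`, `s0_sq`, `s2_post`
#'   (moderated variances), `df_total = d0 + df`, and the inputs.
#' @export
fit_moderation <- function(s2, df, var_floor = 1e-8) {
  n <- length(s2)
  if (n < 2L) stop_ciber("need at least 2 variances to fit a prior")
  df <- rep_len(df, n)
  if (any(df < 1)) stop_ciber("all residual df must be >= 1")
  s2f <- pmax(s2, var_floor)
  if (all(s2 <= var_floor)) {
    warning("all variances at or below the floor; using d0 = Inf prior")
    fit <- list(d0 = Inf, s0_sq = var_floor)
  } else {
    z <- log(s2f)
    e <- z - digamma(df / 2) + log(df / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # no excess spread beyond sampling noise: infinite prior df, scale
      # at the mean observed variance (exact no-op when all s2 are equal)
      d0 <- Inf
      s0_sq <- mean(s2f)
    }
    fit <- list(d0 = d0, s0_sq = s0_sq)
  }
  s2_post <- if (is.infinite(fit$d0)) rep(fit$s0_sq, n)
             else (fit$d0 * fit$s0_sq + df * s2f) / (fit$d0 + df)
  structure(list(d0 = fit$d0, s0_sq = fit$s0_sq, s2 = s2f, df = df,
                 s2_post = s2_post, df_total = fit$d0 + df),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("moderation_fit: d0 = %.4g, s0^2 = %.4g over %d guides\n",
              x$d0, x$s0_sq, length(x$s2)))
  invisible(x)
}

#' Moderated paired t-test
#'
#' `t = log2fc / sqrt(s2_post / n_replicates)` referred to a Student t
#' with `d0 + df` degrees of freedom, two-sided.  With `d0 = 0` this is
#' exactly the classical paired t-test.
#'
#' @param log2fc effect estimates (mean paired difference).
#' @param s2_post moderated variances (see [fit_moderation]).
#' @param df_total total degrees of freedom `d0 + df`.
#' @param n_replicates number of paired differences averaged.
#' @return data.frame with columns `t` and `p`.
#' @export
moderated_test <- function(log2fc, s2_post, df_total, n_replicates) {
  if (any(s2_post <= 0)) stop_ciber("moderated variances must be positive")
  tstat <- log2fc / sqrt(s2_post / n_replicates)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  data.frame(t = tstat, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1.
#'
#' @param p p-values in \[0, 1\]; NaN is rejected.
#' @return q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p))) stop_ciber("NA/NaN p-values")
  if (any(p < 0 | p > 1)) stop_ciber("p-values outside [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Score guides as significant
#'
#' A guide is significant iff `q < q_threshold` and `|log2fc| >
#' lfc_threshold`.  The published screens use `q < 0.01` with a log2
#' fold-change threshold of 1 or 2 depending on the screen; adjusted
#' p-values below 1e-50 are floored at 1e-50 for display only.
#'
#' @param results data.frame with columns `log2fc` and `q`.
#' @param q_threshold,lfc_threshold significance thresholds.
#' @param q_floor display floor for q.
#' @return `results` with added columns `q_display`, `significant`,
#'   `direction` (`up`/`down`/`none`).
#' @export
call_significant <- function(results, q_threshold = 0.01, lfc_threshold = 1,
                             q_floor = 1e-50) {
  if (lfc_threshold < 0) stop_ciber("lfc_threshold must be non-negative")
  results$q_display <- pmax(results$q, q_floor)
  results$significant <- results$q < q_threshold &
    abs(results$log2fc) > lfc_threshold
  results$direction <- ifelse(!results$significant, "none",
                              ifelse(results$log2fc > 0, "up", "down"))
  attr(results, "thresholds") <- list(q = q_threshold, lfc = lfc_threshold,
                                      q_floor = q_floor)
  results
}

#' Roll guide results up to genes
#'
#' @param results a guide result data.frame with `guide_id`, `log2fc`,
#'   `q`, `significant`, `direction`.
#' @param annotation a [guide_annotation]; unannotated guides are
#'   reported under gene `NA` with a warning.
#' @return per-gene data.frame: `gene`, `n_guides`,
#'   `n_significant_guides`, `n_up`, `n_down`, `best_q`,
#'   `mean_log2fc_significant`.
#' @export
summarize_by_gene <- function(results, annotation) {
  gene <- annotation$gene[match(results$guide_id, annotation$guide_id)]
  if (any(is.na(gene) & results$significant))
    warning("significant guide(s) without annotation reported as gene NA")
  gene[is.na(gene)] <- "NA"
  split_idx <- split(seq_len(nrow(results)), gene)
  rows <- lapply(names(split_idx), function(g) {
    i <- split_idx[[g]]
    sig <- results$significant[i]
    data.frame(gene = g,
               n_guides = length(i),
               n_significant_guides = sum(sig),
               n_up = sum(results$direction[i] == "up"),
               n_down = sum(results$direction[i] == "down"),
               best_q = min(results$q[i]),
               mean_log2fc_significant =
                 if (any(sig)) mean(results$log2fc[i][sig]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$best_q), , drop = FALSE]
}
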
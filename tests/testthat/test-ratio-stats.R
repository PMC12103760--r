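test_that("log ratio arithmetic, symmetry, and scale invariance", {
  expect_equal(log_ratio(10, 10, 1000, 1000), 0)
  expect_equal(log_ratio(15, 3, 1e6, 1e6), log2(15.5 / 3.5))
  expect_error(log_ratio(-1, 3, 10, 10), "non-negative")
  expect_error(log_ratio(1, 3, 0, 10), "positive")
  # doubling counts and totals together leaves the ratio unchanged
  # (exact in the no-pseudocount limit)
  expect_equal(log_ratio(30, 6, 2e6, 2e6, pseudocount = 0),
               log_ratio(15, 3, 1e6, 1e6, pseudocount = 0))
})

test_that("paired ratio change reproduces hand-computed mean and variance", {
  L_base <- matrix(c(0, 0), 1)
  L_ctr <- matrix(c(2, 2), 1)
  out <- guide_ratio_change(L_base, L_ctr)
  expect_equal(out$log2fc, 2); expect_equal(out$s2, 0); expect_equal(out$df, 1L)

  out13 <- guide_ratio_change(matrix(c(0, 0), 1), matrix(c(1, 3), 1))
  expect_equal(out13$log2fc, 2)   # mean(1, 3)
  expect_equal(out13$s2, 2)       # var(1, 3)

  same <- matrix(rnorm(6), 3)
  id <- guide_ratio_change(same, same)
  expect_equal(id$log2fc, rep(0, 3))
})

test_that("moderation prior behaves at its analytic limits", {
  # all variances equal: prior sits at that variance, shrinkage is a no-op
  m <- fit_moderation(rep(0.5, 50), df = 4)
  expect_equal(m$s0_sq, 0.5, tolerance = 1e-6)
  expect_equal(m$s2_post, rep(0.5, 50), tolerance = 1e-6)

  # moderated variances always lie between the raw variance and the prior
  set.seed(61)
  s2 <- rchisq(200, 3) / 3
  m2 <- fit_moderation(s2, df = 2)
  lo <- pmin(m2$s2, m2$s0_sq); hi <- pmax(m2$s2, m2$s0_sq)
  expect_true(all(m2$s2_post >= lo - 1e-12 & m2$s2_post <= hi + 1e-12))

  # all-zero variances fall back to an infinite prior with a warning
  expect_warning(m3 <- fit_moderation(rep(0, 20), df = 1), "floor")
  expect_identical(m3$d0, Inf)
})

test_that("moderation recovers known prior parameters from simulated variances", {
  # s_g^2 = s0^2 * F(d_g, d0): scaled inverse-chi-square prior draws
  set.seed(71)
  d0 <- 4; s0_sq <- 2; d_g <- 4
  s2 <- s0_sq * rf(5000, d_g, d0)
  m <- fit_moderation(s2, df = d_g)
  expect_lt(abs(m$d0 - d0) / d0, 0.2)
  expect_lt(abs(m$s0_sq - s0_sq) / s0_sq, 0.1)
})

test_that("moderation agrees with the reference empirical-Bayes implementation", {
  set.seed(81)
  s2 <- 0.8 * rf(800, 2, 6)
  m <- fit_moderation(s2, df = 2)
  sq <- limma::squeezeVar(s2, df = 2)
  expect_equal(m$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(m$s0_sq, sq$var.prior, tolerance = 0.05)
  expect_equal(m$s2_post, sq$var.post, tolerance = 0.05)
})

test_that("moderated test with d0 = 0 equals the classical paired t-test", {
  D <- c(1, 3)
  lfc <- mean(D); s2 <- var(D)
  out <- moderated_test(lfc, s2, df_total = 1, n_replicates = 2)
  ref <- t.test(D)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(out$p, ref$p.value, tolerance = 1e-12)

  # zero effect gives t = 0, p = 1; p is symmetric under sign flip
  z <- moderated_test(0, 1, 5, 2)
  expect_equal(z$t, 0); expect_equal(z$p, 1)
  a <- moderated_test(1.3, 0.4, 7, 2); b <- moderated_test(-1.3, 0.4, 7, 2)
  expect_equal(a$p, b$p)
  expect_error(moderated_test(1, 0, 5, 2), "positive")
})

test_that("BH q-values match the step-up definition and p.adjust", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.1, NA)), "NA")
  expect_error(bh_fdr(c(0.1, 1.2)), "outside")
  set.seed(91)
  for (i in 1:25) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_identical(q, bh_stepup_oracle(p))
    # q is non-decreasing in the rank of p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("significance calls honour thresholds, direction, and the display floor", {
  res <- data.frame(guide_id = c("a", "b", "c", "d"),
                    log2fc = c(2.5, 1.5, -3, 0.2),
                    q = c(0.009, 0.009, 1e-80, 0.5))
  out <- call_significant(res, q_threshold = 0.01, lfc_threshold = 2)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$direction, c("up", "none", "down", "none"))
  expect_equal(out$q_display[3], 1e-50)   # display floor
  expect_equal(out$q[3], 1e-80)           # raw q untouched
  expect_error(call_significant(res, lfc_threshold = -1), "non-negative")
})

test_that("gene roll-up equals a brute-force group-by", {
  ann <- guide_annotation(sprintf("g%02d", 1:10),
                          rep(c("GCN4", "URA3", "HIS3", "NAM7", "UPF3"), each = 2))
  set.seed(95)
  res <- data.frame(guide_id = sprintf("g%02d", 1:10),
                    log2fc = rnorm(10, 0, 2), q = runif(10)^2)
  res <- call_significant(res, q_threshold = 0.05, lfc_threshold = 1)
  out <- summarize_by_gene(res, ann)
  for (g in out$gene) {
    rows <- res[ann$gene[match(res$guide_id, ann$guide_id)] == g, ]
    expect_equal(out$n_guides[out$gene == g], nrow(rows))
    expect_equal(out$n_significant_guides[out$gene == g], sum(rows$significant))
    expect_equal(out$best_q[out$gene == g], min(rows$q))
  }
  # one significant guide among two at the strict (lfc > 2) thresholds
  res2 <- data.frame(guide_id = c("g01", "g02"), log2fc = c(3, 0.1),
                     q = c(0.001, 0.5))
  res2 <- call_significant(res2, 0.01, 2)
  out2 <- summarize_by_gene(res2, ann)
  expect_equal(out2$n_significant_guides[out2$gene == "GCN4"], 1L)
})

test_that("type-I error is controlled on null screens", {
  fracs <- vapply(1:5, function(i) {
    scr <- simulate_screen(simulation_config(n_guides = 1000, depth = 2e5,
                                             seed = 200 + i,
                                             fraction_true_hits = 0,
                                             fraction_systemic = 0))
    fit <- ciber_fit(scr$reporter, scr$normalizer, scr$design)
    mean(fit$results$q < 0.01)
  }, numeric(1))
  expect_lte(mean(fracs), 0.02)
})

test_that("the fit object supports the standard S3 interface", {
  scr <- simulate_screen(simulation_config(n_guides = 120, depth = 1e5, seed = 17))
  ann <- guide_annotation(scr$truth$guide_id,
                          rep(sprintf("GENE%02d", 1:60), each = 2))
  fit <- ciber_fit(scr$reporter, scr$normalizer, scr$design, annotation = ann)
  expect_s3_class(fit, "ciber_fit")
  expect_named(coef(fit), scr$truth$guide_id)
  expect_output(print(fit), "Moderated ratio model")
  expect_output(s <- summary(fit), "Top guides")
  r <- residuals(fit)
  expect_equal(dim(r), c(120, 2))
  expect_equal(rowMeans(r), setNames(rep(0, 120), rownames(r)), tolerance = 1e-12)
  # q >= p and both in [0, 1]
  expect_true(all(fit$results$q >= fit$results$p - 1e-15))
  expect_true(all(fit$results$p >= 0 & fit$results$q <= 1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("unpaired mode reduces to the pooled two-group t on the log ratios", {
  scr <- simulate_screen(simulation_config(n_guides = 60, depth = 1e5, seed = 19,
                                           n_replicates = 3))
  fit <- ciber_fit(scr$reporter, scr$normalizer, scr$design,
                   design_mode = "unpaired", moderate = FALSE, center = "none")
  # cross-check one guide against t.test(var.equal = TRUE)
  L <- fit$L
  g <- rownames(L)[5]
  pre <- L[g, grep("^pre", colnames(L))]
  post <- L[g, grep("^post", colnames(L))]
  ref <- t.test(post, pre, var.equal = TRUE)
  i <- match(g, fit$results$guide_id)
  expect_equal(fit$results$t[i], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(fit$results$p[i], ref$p.value, tolerance = 1e-10)
})
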
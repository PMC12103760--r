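#' Configure a simulated dual-barcode CRISPRi screen
#'
#' The generative model mirrors the measurement process of a barcoded
#' CRISPRi expression-reporter screen.  Each guide `g` carries four log2
#' effects, all scaled by its knockdown efficiency `kappa_g`:
#' \describe{
#'   \item{`phenotype`}{`p_g`, change of reporter-only transcription upon
#'     induction — the signal the screen is designed to detect.}
#'   \item{`systemic`}{`s_g`, change applied equally to reporter and
#'     normalizer transcription (e.g. knockdown of core mRNA
#'     transcriptional machinery).  It cancels in the matched-promoter
#'     RNA-to-RNA ratio but not in the RNA-to-DNA ratio.}
#'   \item{`fitness`}{`f_g`, change in cell abundance over the induction
#'     window; carried identically by all three channels.}
#'   \item{`dna`}{`d_g`, change in per-cell template copy number; carried
#'     by DNA and, proportionally, both RNA channels.}
#' }
#' Latent per-guide cell abundance is log-normal; in `plasmid` mode a
#' log-normal copy number multiplies all channels and a fraction `phi` of
#' each guide's mass is re-assigned to a random other guide's barcodes
#' (cells that took up two library plasmids decouple barcode from guide).
#' Counts arise by gamma-perturbing the channel masses (overdispersion)
#' and drawing a multinomial at the configured depth per sample.
#'
#' @param n_guides number of guides.
#' @param n_replicates biological replicates (independent cultures).
#' @param depth sequencing depth per sample (reads).  Desk-scale default
#'   1e6; the published screens used more than 14 million reads per sample.
#' @param fraction_true_hits fraction of guides given a phenotype effect.
#' @param phenotype_effect_range magnitude range (log2) for phenotype
#'   effects, drawn uniformly with random sign.
#' @param fraction_systemic fraction of guides given a systemic effect.
#' @param systemic_effect_size magnitude (log2) of systemic effects,
#'   random sign.
#' @param fraction_fitness,fitness_effect_sd fraction of guides with a
#'   fitness effect and the SD (log2, mean 0) of those effects.
#' @param abundance_sd log-normal SD (natural log) of per-guide cell
#'   abundance, the library-representation skew.
#' @param copy_mode `"integrated"` (single-copy landing-pad integration:
#'   copy number is exactly 1 and `co_transformation_fraction` is forced
#'   to 0) or `"plasmid"` (episomal library with segregation noise).
#' @param copy_lognormal_sd log-normal SD of plasmid copy number
#'   (plasmid mode only).
#' @param co_transformation_fraction fraction `phi` of each guide's mass
#'   re-assigned to a random other guide's barcodes (plasmid mode only).
#' @param rho reporter/normalizer baseline expression ratio, linear scale.
#' @param overdispersion_shape gamma shape of the multiplicative count
#'   noise; larger is quieter, `Inf` disables it (pure multinomial).
#' @param knockdown_efficiency scalar in \[0,1\] scaling all four effects.
#' @param seed integer seed; fixes every draw (bit-reproducible runs).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_guides = 2000L,
                              n_replicates = 2L,
                              depth = 1e6,
                              fraction_true_hits = 0.05,
                              phenotype_effect_range = c(1, 3),
                              fraction_systemic = 0.05,
                              systemic_effect_size = 2,
                              fraction_fitness = 0,
                              fitness_effect_sd = 1,
                              abundance_sd = 0.5,
                              copy_mode = c("integrated", "plasmid"),
                              copy_lognormal_sd = 0.5,
                              co_transformation_fraction = 0.05,
                              rho = 1,
                              overdispersion_shape = 100,
                              knockdown_efficiency = 1,
                              seed = 1L) {
  copy_mode <- match.arg(copy_mode)
  if (copy_mode == "integrated") co_transformation_fraction <- 0
  cfg <- list(n_guides = as.integer(n_guides),
              n_replicates = as.integer(n_replicates),
              depth = depth,
              fraction_true_hits = fraction_true_hits,
              phenotype_effect_range = phenotype_effect_range,
              fraction_systemic = fraction_systemic,
              systemic_effect_size = systemic_effect_size,
              fraction_fitness = fraction_fitness,
              fitness_effect_sd = fitness_effect_sd,
              abundance_sd = abundance_sd,
              copy_mode = copy_mode,
              copy_lognormal_sd = copy_lognormal_sd,
              co_transformation_fraction = co_transformation_fraction,
              rho = rho,
              overdispersion_shape = overdispersion_shape,
              knockdown_efficiency = knockdown_efficiency,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_guides < 2L) stop_ciber("need at least 2 guides")
    if (n_replicates < 1L) stop_ciber("need at least 1 replicate")
    if (depth <= 0) stop_ciber("depth must be positive")
    fr <- c(fraction_true_hits, fraction_systemic, fraction_fitness,
            co_transformation_fraction)
    if (any(fr < 0 | fr > 1)) stop_ciber("fractions must lie in [0,1]")
    if (knockdown_efficiency < 0 || knockdown_efficiency > 1)
      stop_ciber("knockdown_efficiency must lie in [0,1]")
    if (abundance_sd < 0 || copy_lognormal_sd < 0)
      stop_ciber("log-normal SDs must be non-negative")
    if (rho <= 0) stop_ciber("rho must be positive")
    if (overdispersion_shape <= 0) stop_ciber("overdispersion_shape must be positive")
    if (copy_mode == "integrated" && co_transformation_fraction != 0)
      stop_ciber("integrated mode forces co_transformation_fraction = 0")
  })
  invisible(cfg)
}

#' Draw a guide-effect truth table from a simulation config
#'
#' @param config a [simulation_config].
#' @return data.frame with columns `guide_id`, `phenotype_effect`,
#'   `systemic_effect`, `fitness_effect`, `dna_effect`,
#'   `knockdown_efficiency`.  Null guides have all four effects zero.
#' @export
draw_guide_effects <- function(config) {
  n <- config$n_guides
  guide_id <- sprintf("guide%04d", seq_len(n))
  p <- s <- f <- d <- numeric(n)
  n_hit <- round(config$fraction_true_hits * n)
  if (n_hit > 0) {
    idx <- sample.int(n, n_hit)
    mag <- stats::runif(n_hit, config$phenotype_effect_range[1],
                        config$phenotype_effect_range[2])
    p[idx] <- mag * sample(c(-1, 1), n_hit, replace = TRUE)
  }
  n_sys <- round(config$fraction_systemic * n)
  if (n_sys > 0) {
    idx <- sample.int(n, n_sys)
    s[idx] <- config$systemic_effect_size * sample(c(-1, 1), n_sys, replace = TRUE)
  }
  n_fit <- round(config$fraction_fitness * n)
  if (n_fit > 0) {
    idx <- sample.int(n, n_fit)
    f[idx] <- stats::rnorm(n_fit, 0, config$fitness_effect_sd)
  }
  data.frame(guide_id = guide_id, phenotype_effect = p, systemic_effect = s,
             fitness_effect = f, dna_effect = d,
             knockdown_efficiency = config$knockdown_efficiency,
             stringsAsFactors = FALSE)
}

#' Simulate a dual-barcode CRISPRi screen
#'
#' Generates reporter-RNA, normalizer-RNA and DNA count tables for every
#' (replicate, condition) sample from one shared latent cell population
#' per sample, together with the ground-truth guide effects.  See
#' [simulation_config] for the latent model.
#'
#' @param config a [simulation_config].
#' @param truth optional externally supplied truth table in the format of
#'   [draw_guide_effects] (overrides the config's effect draws).
#' @return A `simulated_screen`: list with per-channel `count_table`s
#'   (`reporter`, `normalizer`, `dna`), the `truth` table, the
#'   [screen_design], and the config.
#' @export
simulate_screen <- function(config, truth = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  if (is.null(truth)) truth <- draw_guide_effects(config)
  n <- nrow(truth)
  if (n != config$n_guides)
    stop_ciber("truth table has %d guides, config says %d", n, config$n_guides)
  kap <- truth$knockdown_efficiency

  a <- if (config$abundance_sd > 0) stats::rlnorm(n, 0, config$abundance_sd) else rep(1, n)
  cpy <- if (config$copy_mode == "plasmid" && config$copy_lognormal_sd > 0)
    stats::rlnorm(n, 0, config$copy_lognormal_sd) else rep(1, n)
  base <- a * cpy

  growth <- 2^(kap * (truth$fitness_effect + truth$dna_effect))
  mass <- list(
    reporter = cbind(pre = base * config$rho,
                     post = base * config$rho *
                       2^(kap * (truth$phenotype_effect + truth$systemic_effect)) * growth),
    normalizer = cbind(pre = base,
                       post = base * 2^(kap * truth$systemic_effect) * growth),
    dna = cbind(pre = base, post = base * growth))
  if (any(!vapply(mass, function(m) all(is.finite(m)), logical(1))))
    stop_ciber("non-finite channel masses; effect sizes too extreme")

  phi <- config$co_transformation_fraction
  if (phi > 0) {
    # each guide donates phi of its mass to one random other guide's barcodes
    partner <- vapply(seq_len(n), function(i) sample(seq_len(n)[-i], 1L), integer(1))
    reassign <- function(m) {
      kept <- (1 - phi) * m
      for (j in seq_len(ncol(m))) {
        add <- tapply(phi * m[, j], partner, sum)
        kept[as.integer(names(add)), j] <- kept[as.integer(names(add)), j] + add
      }
      kept
    }
    mass <- lapply(mass, reassign)
  }

  conds <- c("pre", "post")
  samp_grid <- expand.grid(condition = conds,
                           replicate = seq_len(config$n_replicates),
                           stringsAsFactors = FALSE)
  sample_ids <- sprintf("%s_r%d", samp_grid$condition, samp_grid$replicate)

  draw_channel <- function(m) {
    out <- matrix(0L, n, nrow(samp_grid),
                  dimnames = list(truth$guide_id, sample_ids))
    for (k in seq_len(nrow(samp_grid))) {
      mu <- m[, samp_grid$condition[k]]
      noisy <- if (is.finite(config$overdispersion_shape))
        mu * stats::rgamma(n, shape = config$overdispersion_shape,
                           rate = config$overdispersion_shape)
      else mu
      out[, k] <- stats::rmultinom(1, size = config$depth, prob = noisy / sum(noisy))
    }
    count_table(out, level = "guide")
  }
  counts <- lapply(mass, draw_channel)

  samples <- do.call(rbind, lapply(CHANNELS, function(ch)
    data.frame(sample_id = sample_ids, replicate = samp_grid$replicate,
               condition = samp_grid$condition, channel = ch,
               stringsAsFactors = FALSE)))
  # per-channel tables share sample ids; design rows distinguish channels
  samples$sample_id <- paste(samples$channel, samples$sample_id, sep = ".")
  design <- screen_design(samples, baseline_condition = "pre",
                          contrast_condition = "post",
                          normalizer_channel = "normalizer")

  for (ch in CHANNELS)
    colnames(counts[[ch]]$counts) <- paste(ch, sample_ids, sep = ".")

  structure(list(reporter = counts$reporter, normalizer = counts$normalizer,
                 dna = counts$dna, truth = truth, design = design,
                 config = config),
            class = "simulated_screen")
}

#' @export
print.simulated_screen <- function(x, ...) {
  cat(sprintf("simulated_screen: %d guides, %d replicates, depth %g, %s mode\n",
              x$config$n_guides, x$config$n_replicates, x$config$depth,
              x$config$copy_mode))
  n_hit <- sum(x$truth$phenotype_effect != 0)
  n_sys <- sum(x$truth$systemic_effect != 0)
  cat(sprintf("  truth: %d phenotype hits, %d systemic guides\n", n_hit, n_sys))
  invisible(x)
}

#' Generate a synthetic barcode library for a set of guides
#'
#' Draws random barcodes (default 25 nt) for the reporter, normalizer and
#' dna channels of each guide, enforcing a minimum pairwise Hamming
#' distance of 3 across the whole library so that one-mismatch barcode
#' assignment is unambiguous.  Distance screening uses the shared
#' one-mismatch-neighbourhood test: two sequences within Hamming distance
#' 2 always share a 1-neighbour.
#'
#' @param guide_ids character vector of guide identifiers.
#' @param barcode_length barcode length in nt.
#' @param channels which channels receive a barcode per guide.
#' @return A [barcode_map].
#' @export
generate_barcode_library <- function(guide_ids, barcode_length = 25L,
                                     channels = CHANNELS) {
  n_needed <- length(guide_ids) * length(channels)
  bcs <- character(0)
  seen_neighbors <- new.env(hash = TRUE, parent = emptyenv())
  tries <- 0L
  while (length(bcs) < n_needed) {
    tries <- tries + 1L
    if (tries > 50L * n_needed) stop_ciber("cannot place distinct barcodes")
    cand <- paste(sample(c("A", "C", "G", "T"), barcode_length, replace = TRUE),
                  collapse = "")
    nb <- c(cand, hamming_neighbors(cand))
    if (any(vapply(nb, function(s) !is.null(seen_neighbors[[s]]), logical(1))))
      next
    for (s in nb) seen_neighbors[[s]] <- TRUE
    bcs <- c(bcs, cand)
  }
  barcode_map(bcs,
              rep(guide_ids, times = length(channels)),
              rep(channels, each = length(guide_ids)))
}

# all sequences at Hamming distance exactly 1
hamming_neighbors <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  alphabet <- c("A", "C", "G", "T")
  out <- character(0)
  for (i in seq_along(chars)) {
    for (b in setdiff(alphabet, chars[i])) {
      v <- chars; v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}
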
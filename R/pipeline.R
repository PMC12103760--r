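#' Run the full screen pipeline from a config
#'
#' Orchestrates simulate (or load) -> preprocess -> fit -> enrich, writing
#' every intermediate table plus a JSON run log (seed, thresholds,
#' normalization mode, package version) so any output can be regenerated
#' from the recorded config.  Deterministic stages are bit-identical
#' across re-runs with the same config.
#'
#' Config keys (YAML file or list): `seed` (mandatory), `out_dir`;
#' either `simulate:` (arguments of [simulation_config]) or `counts:`
#' with `reporter`, `normalizer`, `design` file paths; optional
#' `normalizer` (`"normalizer"`/`"dna"`), `design_mode`, `thresholds:`
#' (`q`, `lfc`), `min_pre_reads`, `annotation` (TSV path), `gene_sets`
#' (GMT-like TSV path).
#'
#' @param config path to a YAML config, or an equivalent named list.
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @return list with `fit` (the [ciber_fit]), `screen` (when
#'   simulated), `enrichment` (when gene sets were supplied), `paths`
#'   of written files, and the resolved `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) stop_ciber("config must set an explicit seed")
  out_dir <- out_dir %||% cfg$out_dir %||% stop_ciber("config must set out_dir")

  thr_q <- cfg$thresholds$q %||% 0.01
  thr_lfc <- cfg$thresholds$lfc %||% 1
  if (thr_lfc < 0) stop_ciber("config error: lfc threshold must be non-negative")
  if (thr_q <= 0 || thr_q > 1) stop_ciber("config error: q threshold must lie in (0,1]")
  norm_channel <- cfg$normalizer %||% "normalizer"
  if (!norm_channel %in% c("normalizer", "dna"))
    stop_ciber("config error: normalizer must be 'normalizer' or 'dna'")
  design_mode <- cfg$design_mode %||% "paired"
  min_pre <- cfg$min_pre_reads %||% 5L

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  screen <- NULL

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sc <- do.call(simulation_config, sim_args)
    screen <- simulate_screen(sc)
    reporter <- screen$reporter
    normalizer <- screen[[norm_channel]]
    design <- screen$design
    design$normalizer_channel <- norm_channel
    paths$truth <- file.path(out_dir, "truth.tsv")
    utils::write.table(screen$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (ch in c("reporter", "normalizer", "dna")) {
      paths[[paste0(ch, "_counts")]] <- file.path(out_dir, paste0(ch, "_counts.tsv"))
      write_count_table(screen[[ch]], paths[[paste0(ch, "_counts")]])
    }
  } else if (!is.null(cfg$counts)) {
    need <- c("reporter", "normalizer", "design")
    miss <- setdiff(need, names(cfg$counts))
    if (length(miss))
      stop_ciber("config counts: missing %s", paste(miss, collapse = ", "))
    reporter <- read_count_table(cfg$counts$reporter, level = cfg$counts$level %||% "guide")
    normalizer <- read_count_table(cfg$counts$normalizer, level = cfg$counts$level %||% "guide")
    design <- read_screen_design(cfg$counts$design,
                                 baseline_condition = cfg$baseline %||% "pre",
                                 contrast_condition = cfg$contrast %||% "post",
                                 normalizer_channel = norm_channel)
  } else stop_ciber("config must provide either 'simulate' or 'counts'")

  if (reporter$level == "barcode") {
    if (is.null(cfg$barcode_map)) stop_ciber("barcode-level counts need a barcode_map path")
    map <- read_barcode_map(cfg$barcode_map)
    reporter <- aggregate_to_guides(filter_low_pre(reporter, design, min_pre), map)
    normalizer <- aggregate_to_guides(filter_low_pre(normalizer, design, min_pre), map)
  }

  annotation <- if (!is.null(cfg$annotation)) read_guide_annotation(cfg$annotation)
  fit <- ciber_fit(reporter, normalizer, design, annotation = annotation,
                   q_threshold = thr_q, lfc_threshold = thr_lfc,
                   design_mode = design_mode)
  paths$results <- file.path(out_dir, "guide_results.tsv")
  write_results(fit, paths$results)

  enr <- NULL
  if (!is.null(cfg$gene_sets) && !is.null(annotation)) {
    sets <- read_gene_sets(cfg$gene_sets)
    hits <- unique(stats::na.omit(fit$results$gene[fit$results$significant]))
    enr <- overrepresentation(hits, sets, universe = unique(annotation$gene))
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(enr, paths$enrichment, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  log <- list(package_version = as.character(utils::packageVersion("ciberscreen")),
              seed = cfg$seed, q_threshold = thr_q, lfc_threshold = thr_lfc,
              normalizer_channel = norm_channel, design_mode = design_mode,
              min_pre_reads = min_pre,
              n_guides_tested = nrow(fit$results),
              n_significant = sum(fit$results$significant))
  paths$run_log <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE, pretty = TRUE)

  list(fit = fit, screen = screen, enrichment = enr, paths = paths, config = cfg)
}

#' Re-analyse a downloaded count deposit at published thresholds
#'
#' Runs the ratio analysis on a directory of flat-TSV barcode/guide
#' counts (the schema used for deposited raw counts: `reporter_counts.tsv`,
#' `normalizer_counts.tsv` or `dna_counts.tsv`, `design.tsv`) under both
#' the paired and unpaired design modes, since the deposit does not
#' record which the original analysis used, and reports significant
#' guide and gene counts for each.
#'
#' @param dir directory containing the deposit.
#' @param q_threshold,lfc_threshold published thresholds for the screen.
#' @param normalizer `"normalizer"` or `"dna"`.
#' @param annotation optional [guide_annotation].
#' @return data.frame with one row per design mode: `design_mode`,
#'   `n_guides_tested`, `n_significant`, `n_up`, `n_down`,
#'   `n_genes_significant` (NA without annotation).
#' @export
benchmark_counts <- function(dir, q_threshold = 0.01, lfc_threshold = 1,
                             normalizer = c("normalizer", "dna"),
                             annotation = NULL) {
  normalizer <- match.arg(normalizer)
  if (!dir.exists(dir)) stop_ciber("deposit directory not found: %s", dir)
  norm_file <- file.path(dir, paste0(
    if (normalizer == "dna") "dna" else "normalizer", "_counts.tsv"))
  need <- c(file.path(dir, "reporter_counts.tsv"), norm_file,
            file.path(dir, "design.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss))
    stop_ciber("deposit lacks expected file(s): %s",
               paste(basename(miss), collapse = ", "))
  reporter <- read_count_table(need[1], level = "guide")
  norm <- read_count_table(need[2], level = "guide")
  design <- read_screen_design(need[3], normalizer_channel = normalizer)
  rows <- lapply(c("paired", "unpaired"), function(mode) {
    fit <- tryCatch(
      ciber_fit(reporter, norm, design, annotation = annotation,
                q_threshold = q_threshold, lfc_threshold = lfc_threshold,
                design_mode = mode),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(design_mode = mode, n_guides_tested = NA_integer_,
                        n_significant = NA_integer_, n_up = NA_integer_,
                        n_down = NA_integer_, n_genes_significant = NA_integer_))
    res <- fit$results
    ng <- if (!is.null(annotation)) {
      gr <- gene_results(fit)
      sum(gr$n_significant_guides > 0)
    } else NA_integer_
    data.frame(design_mode = mode, n_guides_tested = nrow(res),
               n_significant = sum(res$significant),
               n_up = sum(res$direction == "up"),
               n_down = sum(res$direction == "down"),
               n_genes_significant = ng)
  })
  do.call(rbind, rows)
}
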
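# Small in-code fixtures shared across tests.

# n distinct barcodes of given length, deterministic
fixed_barcodes <- function(n, len = 25L, seed = 101) {
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    if (!cand %in% out) out <- c(out, cand)
  }
  out
}

tiny_map <- function(n_guides = 3, len = 25L, seed = 101,
                     channels = c("reporter", "normalizer")) {
  bcs <- fixed_barcodes(n_guides * length(channels), len, seed)
  barcode_map(bcs,
              rep(sprintf("g%02d", seq_len(n_guides)), times = length(channels)),
              rep(channels, each = n_guides))
}

# a 2-replicate pre/post design over the given channels, sample ids
# "<channel>.<condition>_r<rep>"
tiny_design <- function(n_rep = 2, channels = c("reporter", "normalizer", "dna"),
                        normalizer_channel = "normalizer") {
  grid <- expand.grid(condition = c("pre", "post"), replicate = seq_len(n_rep),
                      channel = channels, stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s.%s_r%d", grid$channel, grid$condition, grid$replicate)
  screen_design(grid, normalizer_channel = normalizer_channel)
}

# guide-level count table for one channel matching tiny_design ids
channel_table <- function(counts, channel, n_rep = 2) {
  ids <- as.vector(outer(c("pre", "post"), seq_len(n_rep),
                         function(co, r) sprintf("%s.%s_r%d", channel, co, r)))
  colnames(counts) <- ids
  count_table(counts, "guide")
}

# brute-force Hamming distance between equal-length strings
bf_hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# independent BH step-up implementation (oracle)
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- (n / seq_len(n)) * p[o]
  q_sorted <- rev(cummin(rev(ranked)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}
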
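test_that("read matching agrees with a brute-force Hamming scan", {
  map <- tiny_map(10, len = 12, seed = 7)
  policy <- match_policy(max_mismatches = 1, anchor = "")
  set.seed(8)
  # exact barcodes, 1-mutant barcodes, and random sequences
  mk_mut <- function(b) {
    chars <- strsplit(b, "")[[1]]
    i <- sample(length(chars), 1)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    paste(chars, collapse = "")
  }
  reads <- c(map$barcode[1:5],
             vapply(map$barcode[6:10], mk_mut, character(1)),
             replicate(20, paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                                 collapse = "")))
  for (r in reads) {
    got <- match_read(r, map, policy)
    d <- vapply(map$barcode, bf_hamming, numeric(1), a = r)
    dmin <- min(d)
    if (dmin > 1) {
      expect_equal(got$status, "unmatched")
    } else if (sum(d == dmin) > 1) {
      expect_equal(got$status, "ambiguous")
    } else {
      expect_equal(got$status, "matched")
      expect_equal(got$barcode, map$barcode[which.min(d)])
    }
  }
})

test_that("ambiguous windows equidistant from two barcodes are never assigned", {
  map <- barcode_map(c("AAAAAAAAAA", "AAAAAAAACC", "CCCCCCCCCC", "CCCCCCCCAA"),
                     c("g1", "g1", "g2", "g2"),
                     c("reporter", "normalizer", "reporter", "normalizer"))
  # distance 1 from both AAAAAAAAAA and AAAAAAAACC
  res <- match_read("AAAAAAAAAC", map, match_policy(max_mismatches = 1))
  expect_equal(res$status, "ambiguous")
  # exact match still wins over a 1-mismatch alternative
  res2 <- match_read("AAAAAAAAAA", map, match_policy(max_mismatches = 1))
  expect_equal(res2$guide_id, "g1")
})

test_that("anchored extraction finds the barcode behind a mismatched anchor", {
  map <- tiny_map(4, len = 10, seed = 3)
  policy <- match_policy(max_mismatches = 0, anchor = "ACGTACGTAC",
                         anchor_max_mismatches = 1)
  read <- paste0("ACGTACGAAC", map$barcode[2], "TT")  # anchor with 1 sub
  res <- match_read(read, map, policy)
  expect_equal(res$barcode, map$barcode[2])
  # read too short to hold anchor + barcode
  expect_equal(match_read("ACGT", map, policy)$status, "unmatched")
})

test_that("max_mismatches=2 assigns unique 2-mutants and flags ties", {
  map <- tiny_map(5, len = 15, seed = 12)
  pol2 <- match_policy(max_mismatches = 2)
  b <- map$barcode[3]
  chars <- strsplit(b, "")[[1]]
  chars[2] <- setdiff(c("A", "C", "G", "T"), chars[2])[1]
  chars[9] <- setdiff(c("A", "C", "G", "T"), chars[9])[1]
  mut2 <- paste(chars, collapse = "")
  d <- vapply(map$barcode, bf_hamming, numeric(1), a = mut2)
  expect_equal(sum(d <= 2), 1L)  # fixture sanity: unique at distance 2
  expect_equal(match_read(mut2, map, pol2)$barcode, b)
  expect_equal(match_read(mut2, map, match_policy(max_mismatches = 1))$status,
               "unmatched")
})

test_that("FASTQ counting partitions reads exactly and is order-independent", {
  map <- tiny_map(6, len = 12, seed = 20)
  set.seed(21)
  n <- 500
  reads <- c(sample(map$barcode, n * 0.8, replace = TRUE),
             replicate(n * 0.2, paste(sample(c("A", "C", "G", "T"), 12,
                                             replace = TRUE), collapse = "")))
  dir <- withr::local_tempdir()
  write_one <- function(rs, path) {
    rec <- rbind(paste0("@r", seq_along(rs)), rs, "+", strrep("I", nchar(rs)))
    writeLines(as.vector(rec), path)
  }
  f1 <- file.path(dir, "s1.fastq"); write_one(reads, f1)
  f2 <- file.path(dir, "s2.fastq"); write_one(rev(reads), f2)
  out <- count_fastq(c(s1 = f1, s2 = f2), map, match_policy(max_mismatches = 1))
  rep <- out$report
  expect_equal(rep$matched + rep$ambiguous + rep$unmatched, rep$total)
  expect_equal(rep$total, c(n, n))
  # shuffled file gives the identical count column
  expect_identical(out$counts$counts[, "s1"], out$counts$counts[, "s2"])
  # independent per-read dictionary-scan oracle
  oracle <- table(factor(reads, levels = map$barcode))
  expect_equal(unname(out$counts$counts[map$barcode, "s1"]),
               as.integer(oracle))
})

test_that("empty FASTQ yields an all-zero column with total 0", {
  map <- tiny_map(3, len = 10, seed = 5)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "empty.fastq")
  writeLines(character(0), f)
  out <- count_fastq(c(s = f), map)
  expect_true(all(out$counts$counts == 0))
  expect_equal(out$report$total, 0L)
})

test_that("truncated FASTQ records raise a parse error naming the file", {
  map <- tiny_map(3, len = 10, seed = 5)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "trunc.fastq")
  writeLines(c("@r1", "ACGTACGTAC", "+"), f)  # missing quality line
  expect_error(count_fastq(c(s = f), map), "trunc.fastq")
})

test_that("counting emitted FASTQ at error rate 0 inverts the simulator", {
  guides <- sprintf("guide%04d", 1:20)  # ids as emitted by simulate_screen
  map <- generate_barcode_library(guides, barcode_length = 25,
                                  channels = c("reporter", "normalizer"))
  cfg <- simulation_config(n_guides = 20, depth = 3000, seed = 33,
                           fraction_true_hits = 0.2)
  scr <- simulate_screen(cfg)
  rep_map <- map[map$channel == "reporter", ]
  # barcode-level counts: one reporter barcode per guide
  bc_counts <- scr$reporter$counts
  rownames(bc_counts) <- rep_map$barcode[match(guides, rep_map$guide_id)]
  bc_tab <- count_table(bc_counts, "barcode")
  layout <- read_layout(prefix = "ACGTACGTAC", suffix = "GA", error_rate = 0)
  files <- emit_fastq(bc_tab, map, layout, dir = withr::local_tempdir(), seed = 9)
  out <- count_fastq(files, map,
                     match_policy(max_mismatches = 0, anchor = layout$prefix))
  got <- out$counts$counts[rownames(bc_counts), colnames(bc_counts)]
  expect_identical(got, bc_counts)
  # and aggregation back to guides reproduces the simulated guide table
  agg <- aggregate_to_guides(count_table(got, "barcode"), map)
  expect_identical(agg$counts[guides, ], scr$reporter$counts[guides, ])
})

test_that("1-mismatch matching recovers most reads at 1% substitution error", {
  guides <- sprintf("g%03d", 1:100)
  map <- generate_barcode_library(guides, barcode_length = 25,
                                  channels = c("reporter", "normalizer"))
  rep_map <- map[map$channel == "reporter", ]
  set.seed(44)
  cnt <- matrix(rpois(100, 60), 100, 1,
                dimnames = list(rep_map$barcode, "s1"))
  bc_tab <- count_table(cnt, "barcode")
  layout <- read_layout(prefix = "ACGTACGTAC", suffix = "", error_rate = 0.01)
  files <- emit_fastq(bc_tab, map, layout, dir = withr::local_tempdir(), seed = 10)
  out <- count_fastq(files, map,
                     match_policy(max_mismatches = 1, anchor = layout$prefix,
                                  anchor_max_mismatches = 1))
  # P(<=1 substitution in 25 nt at 1%) ~ 0.974; anchor adds a little loss
  expect_gte(out$report$matched / out$report$total, 0.95)
})

test_that("emission with different seeds shuffles read order but not counts", {
  map <- tiny_map(5, len = 10, seed = 2)
  rep_map <- map[map$channel == "reporter", ]
  cnt <- matrix(5:9, 5, 1, dimnames = list(rep_map$barcode, "s1"))
  tab <- count_table(cnt, "barcode")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- emit_fastq(tab, map, read_layout(prefix = "", suffix = ""), d1, seed = 1)
  f2 <- emit_fastq(tab, map, read_layout(prefix = "", suffix = ""), d2, seed = 2)
  r1 <- readLines(f1[["s1"]]); r2 <- readLines(f2[["s1"]])
  seq1 <- r1[seq(2, length(r1), 4)]; seq2 <- r2[seq(2, length(r2), 4)]
  expect_false(identical(seq1, seq2))      # order differs
  expect_equal(sort(seq1), sort(seq2))     # marginal counts identical
})
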
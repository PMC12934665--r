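test_that("IR ratio formula, undefined marker and scale invariance", {
  expect_equal(compute_ir_ratio(5, 95), 0.05)
  expect_equal(compute_ir_ratio(0, 10), 0)
  expect_equal(compute_ir_ratio(10, 0), 1)
  expect_true(is.na(compute_ir_ratio(0, 0)))
  expect_error(compute_ir_ratio(-1, 5), "non-negative")
  set.seed(2)
  a <- runif(20, 0, 100); b <- runif(20, 0.1, 100); k <- runif(20, 0.1, 9)
  expect_equal(compute_ir_ratio(k * a, k * b), compute_ir_ratio(a, b))
})

test_that("detection filter keeps introns at >= 0.05 in at least one sample", {
  rec <- data.frame(
    intron_id = rep(c("i1", "i2", "i3", "i4"), each = 2),
    sample = rep(c("s1", "s2"), 4),
    intronic = c(4, 6, 4, 4, 5, 0, 0, 0),
    exonic = c(96, 94, 96, 96, 95, 100, 0, 0),
    stringsAsFactors = FALSE
  )
  kept <- apply_detection_filter(rec)
  expect_setequal(unique(kept$intron_id), c("i1", "i3"))  # 0.06; exactly 0.05
  expect_false("i2" %in% kept$intron_id)                  # 0.04 twice
  expect_false("i4" %in% kept$intron_id)                  # undefined ratios
  strict <- apply_detection_filter(rec, min_samples = 2L)
  expect_equal(unique(strict$intron_id), character(0))
})

test_that("differential IR delta, direction, and the pooled Fisher substitute", {
  rec <- data.frame(
    intron_id = "i1", sample = paste0("s", 1:4),
    condition = c("A", "A", "B", "B"),
    intronic = c(40, 44, 20, 24), exonic = c(60, 56, 80, 76),
    stringsAsFactors = FALSE
  )
  res <- differential_ir(rec, "A", "B")
  expect_equal(res$delta_ratio, 0.20)
  expect_equal(res$direction, "increased")
  expect_equal(res$test, "fisher_pooled")

  same <- rec
  same$intronic <- rep(c(30, 40), 2)
  same$exonic <- rep(c(70, 60), 2)
  res0 <- differential_ir(same, "A", "B")
  expect_equal(res0$delta_ratio, 0)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$direction, "unchanged")

  pooled <- data.frame(intron_id = "i1", sample = c("a", "b"),
                       condition = c("A", "B"),
                       intronic = c(50, 20), exonic = c(50, 80),
                       stringsAsFactors = FALSE)
  expect_equal(differential_ir(pooled, "A", "B")$p_value,
               brute_fisher_p(50, 50, 20, 80), tolerance = 1e-12)

  undef <- data.frame(intron_id = "i1", sample = c("a", "b"),
                      condition = c("A", "B"),
                      intronic = c(0, 5), exonic = c(0, 5),
                      stringsAsFactors = FALSE)
  expect_error(differential_ir(undef, "A", "B"), "undefined")
})

test_that("differential direction agrees with the pooled log-odds sign", {
  set.seed(9)
  for (i in 1:20) {
    rec <- data.frame(
      intron_id = "x", sample = paste0("s", 1:4),
      condition = c("A", "A", "B", "B"),
      intronic = round(runif(4, 5, 200)), exonic = round(runif(4, 5, 200)),
      stringsAsFactors = FALSE
    )
    res <- differential_ir(rec, "A", "B")
    a <- colSums(rec[rec$condition == "A", c("intronic", "exonic")])
    b <- colSums(rec[rec$condition == "B", c("intronic", "exonic")])
    lo <- log(a[1] / a[2]) - log(b[1] / b[2])
    if (res$direction != "unchanged" && lo != 0) {
      expect_equal(res$direction == "increased",
                   res$delta_ratio > 0)
    }
  }
})

test_that("binding annotation uses half-open overlap arithmetic", {
  introns <- data.frame(intron_id = c("i1", "i2", "i3", "i4"),
                        chrom = c("chr1", "chr1", "chr2", "chr1"),
                        start = c(100, 100, 100, 500),
                        end = c(200, 200, 200, 700),
                        strand = c("+", "+", "+", "-"),
                        stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(150, 200, 190),
                      end = c(160, 210, 300),
                      strand = c("+", "+", "+"),
                      stringsAsFactors = FALSE)
  ann <- annotate_binding(introns, peaks)
  # [100,200) x [150,160) overlaps; [100,200) x [200,210) abuts: no
  expect_equal(ann$bound, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(attr(ann, "n_bound"), 3L)
  expect_equal(ann$bound, brute_bound(introns, peaks))
  # stranded mode excludes the minus-strand intron's plus-strand peaks
  s <- annotate_binding(introns, peaks, stranded = TRUE)
  expect_false(s$bound[4])
  expect_error(
    annotate_binding(data.frame(intron_id = "bad", chrom = "chr1",
                                start = 10, end = 10), peaks),
    "bad")
})

test_that("binding annotation matches all-pairs brute force on random intervals", {
  set.seed(21)
  n <- 300
  mk <- function(n) {
    start <- sample(0:5000, n, replace = TRUE)
    data.frame(intron_id = sprintf("r%03d", seq_len(n)),
               chrom = sample(c("chr1", "chr2", "chr3"), n, replace = TRUE),
               start = start, end = start + sample(1:400, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  introns <- mk(n); peaks <- mk(n)
  for (mo in c(1L, 25L)) {
    ann <- annotate_binding(introns, peaks, min_overlap_bp = mo)
    expect_equal(ann$bound, brute_bound(introns, peaks, mo))
  }
  # the overlap relation is invariant to input ordering
  shuf <- peaks[sample(n), ]
  expect_equal(annotate_binding(introns, shuf)$bound,
               annotate_binding(introns, peaks)$bound)
})

test_that("BED round trip preserves 0-based half-open coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tpk1\t5\t+",
               "chr2\t0\t50\tpk2\t7\t-"), bed)
  df <- read_bed(bed)
  expect_equal(df$start, c(100, 0))
  expect_equal(df$end, c(200, 50))
  expect_equal(df$strand, c("+", "-"))
  expect_equal(df$name, c("pk1", "pk2"))
})

test_that("polypyrimidine-tract scoring counts C/T in the terminal window", {
  expect_equal(score_py_tract(strrep("T", 20)), 1)
  expect_equal(score_py_tract(strrep("AG", 10)), 0)
  expect_equal(score_py_tract("TTTTTTTTTTAGAGAGAGAG"), 0.5)
  # only the window immediately upstream of the 3' ss counts
  expect_equal(score_py_tract(paste0(strrep("A", 30), strrep("C", 20))), 1)
  expect_equal(score_py_tract(strrep("U", 20)), 1)
  expect_error(score_py_tract("NNNNNNNNNNNNNNNNNNNN"), "non-nucleotide")
  expect_error(score_py_tract("ACGT"), "shorter")
})
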
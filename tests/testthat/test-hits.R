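thr_lower <- function(threshold, replicate = 1:2) {
  data.frame(replicate = replicate, threshold = threshold, tail = "lower",
             fdr = 0.10, stringsAsFactors = FALSE)
}

test_that("guide qualification is strictly beyond the threshold", {
  d <- data.frame(guide_id = c("a", "b", "c"), replicate = 1L,
                  delta_pir = c(-30, -20, -10), stringsAsFactors = FALSE)
  q <- qualify_guides(d, thr_lower(-20, 1L))
  expect_equal(q$pass, c(TRUE, FALSE, FALSE))
})

test_that("the gene rule needs expression, two qualifying guides and half the guides", {
  flags <- function(passes_r1, passes_r2, n = 4) {
    data.frame(
      guide_id = rep(sprintf("g%d", seq_len(n)), 2),
      replicate = rep(1:2, each = n),
      delta_pir = -c(ifelse(seq_len(n) <= passes_r1, 30, 1),
                     ifelse(seq_len(n) <= passes_r2, 30, 1)),
      pass = c(seq_len(n) <= passes_r1, seq_len(n) <= passes_r2),
      stringsAsFactors = FALSE
    )
  }
  expect_true(call_gene(flags(3, 3), fpkm = 1.0)$is_hit)
  expect_false(call_gene(flags(1, 1), fpkm = 1.0)$is_hit)
  expect_false(call_gene(flags(4, 4), fpkm = 0.05)$is_hit)
  # passing in only one replicate is not enough
  expect_false(call_gene(flags(3, 1), fpkm = 1.0)$is_hit)
  # >= 2 qualifying but < 50% of guides with data
  expect_false(call_gene(flags(2, 2, n = 6), fpkm = 1.0)$is_hit)
  expect_warning(res <- call_gene(flags(3, 3), fpkm = NA), "FPKM")
  expect_true(is.na(res$is_hit))
})

test_that("pair-construct hits collapse onto single genes with merge rules", {
  calls <- data.frame(
    target_id = c("A", "B", "A|C", "B|D", "B|E"),
    category = c("single", "single", "pair", "pair", "pair"),
    gene_a = c("A", "B", "A", "B", "B"),
    gene_b = c(NA, NA, "C", "D", "E"),
    is_hit = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    mean_delta = c(-12, -3, -25, -18, -30),
    direction = "IR-promoting",
    stringsAsFactors = FALSE
  )
  out <- collapse_combinatorial(calls)
  # A: hit singly and via a pair -> single-gene evidence kept
  a <- out[out$gene == "A", ]
  expect_false(a$from_pair)
  expect_equal(a$mean_delta, -12)
  # B: not a hit singly, hit via two pairs -> stronger |mean_delta| kept
  b <- out[out$gene == "B", ]
  expect_true(b$from_pair)
  expect_equal(b$mean_delta, -30)
  # partner genes of hit pairs appear, flagged
  expect_true(all(c("C", "D", "E") %in% out$gene))
  expect_true(all(out$from_pair[out$gene %in% c("C", "D", "E")]))

  # no pair hits -> identity on single-gene hits
  only_single <- calls[calls$category == "single", ]
  expect_equal(collapse_combinatorial(only_single)$gene, "A")
})

test_that("hits rank ascending by cross-cell-line average with alphabetical ties", {
  h1 <- data.frame(gene = c("x", "y", "z"), mean_delta = c(-12, -40, -3),
                   stringsAsFactors = FALSE)
  expect_equal(rank_hits(h1)$gene, c("y", "x", "z"))
  h2 <- data.frame(gene = c("x", "w"), mean_delta = c(-8, -10),
                   stringsAsFactors = FALSE)
  r <- rank_hits(list(HAP1 = h1, RPE1 = h2))
  expect_equal(r$avg_delta[r$gene == "x"], -10)  # (-12 + -8) / 2
  expect_equal(r$gene[1], "y")                   # -40, one line only
  tie <- list(data.frame(gene = c("b", "a"), mean_delta = c(-10, -10),
                         stringsAsFactors = FALSE))
  expect_equal(rank_hits(tie)$gene, c("a", "b"))
})

test_that("fisher_overlap reports the sample odds ratio with edge rules", {
  universe <- sprintf("g%03d", 1:100)
  ov <- fisher_overlap(universe[1:10], universe[6:15], universe)
  expect_equal(c(ov$both, ov$a_only, ov$b_only, ov$neither),
               c(5, 5, 5, 85))
  expect_equal(ov$odds_ratio, 17)

  disjoint <- fisher_overlap(universe[1:5], universe[6:10], universe)
  expect_equal(disjoint$odds_ratio, 0)

  nested <- fisher_overlap(universe[1:5], universe[1:8], universe)
  expect_equal(nested$odds_ratio, Inf)

  expect_error(fisher_overlap(c("g001", "nope"), "g002", universe),
               "outside the universe")
})

test_that("fisher p agrees with stats::fisher.test and is swap-symmetric", {
  set.seed(4)
  for (i in 1:40) {
    cells <- as.integer(rmultinom(1, sample(10:120, 1), runif(4)))
    p <- fisher_p_two_sided(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2))$p.value
    expect_equal(p, ref, tolerance = 1e-10)
    expect_equal(fisher_p_two_sided(cells[1], cells[3], cells[2], cells[4]),
                 p, tolerance = 1e-12)
  }
})

test_that("making a guide's delta more extreme never unmakes a hit", {
  cfg <- tiny_config(n_genes = 20L, n_controls = 50L,
                     effect_map = c(gene0003 = -30, gene0011 = -30),
                     seed = 51L)
  scr <- simulate_screen(cfg)
  base <- screen_hits(scr$counts, scr$library, scr$fpkm)
  hit_guides <- scr$library$guide_id[scr$library$gene_a %in% base$hits$gene]
  pushed <- scr$counts
  sel <- pushed$guide_id %in% hit_guides
  pushed$ie[sel] <- 0L  # most extreme lower-tail outcome possible
  pushed$ee[sel] <- pushed$total[sel]
  again <- screen_hits(pushed, scr$library, scr$fpkm)
  expect_true(all(base$hits$gene %in% again$hits$gene))
})
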
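test_that("histogram Otsu agrees with EBImage's on full images", {
  set.seed(5)
  img <- matrix(c(rnorm(2000, 0.2, 0.03), rnorm(2000, 0.8, 0.03)), 40, 100)
  img <- pmin(pmax(img, 0), 1)
  ours <- irscreen:::otsu_threshold(as.vector(img))
  ref <- EBImage::otsu(EBImage::Image(img))
  # both thresholds must land in the inter-class gap and induce the same
  # foreground (the optimum is flat across empty histogram bins, so the
  # numeric values may sit anywhere within the gap)
  expect_identical(img > ours, img > ref)
  expect_equal(irscreen:::otsu_threshold(rep(3, 10)), 3)
})

test_that("nucleus segmentation finds disjoint bright disks and ignores blanks", {
  img <- matrix(5, 120, 120)
  centers <- list(c(25, 25), c(25, 90), c(85, 60))
  for (cc in centers) {
    img[irscreen:::.disk_mask(120, cc[1], cc[2], 12)] <- 200
  }
  labels <- segment_nuclei(img, min_area = 100)
  expect_equal(max(labels), 3)

  expect_warning(blank <- segment_nuclei(matrix(0, 50, 50)), "blank")
  expect_equal(max(blank), 0)

  # a disk touching the border is removed
  edge <- matrix(5, 120, 120)
  edge[irscreen:::.disk_mask(120, 3, 60, 12)] <- 200
  edge[irscreen:::.disk_mask(120, 60, 60, 12)] <- 200
  expect_equal(max(segment_nuclei(edge, min_area = 100)), 1)
})

test_that("recovered nuclei overlap the simulated ground truth", {
  cfg <- image_sim_config(n_cells = 5L, noise_sd = 1, seed = 3L)
  co <- simulate_cells(cfg)
  for (cell in co$cells) {
    labels <- segment_nuclei(cell$dapi)
    expect_equal(max(labels), 1)
    found <- labels > 0
    truth <- cell$truth$nucleus_mask
    jaccard <- sum(found & truth) / sum(found | truth)
    expect_gte(jaccard, 0.9)
  }
})

test_that("speckle segmentation stays inside nuclei and handles flat SON", {
  cfg <- image_sim_config(n_cells = 4L, noise_sd = 2, seed = 13L)
  co <- simulate_cells(cfg)
  for (cell in co$cells) {
    labels <- segment_nuclei(cell$dapi)
    sp <- segment_speckles(cell$son, labels)
    expect_true(all(labels[sp] > 0))  # speckles subset of nuclei
    area_true <- sum(cell$truth$speckle_mask)
    expect_lt(abs(sum(sp) - area_true) / area_true, 0.25)
  }
  # constant SON inside the (single) nucleus: no speckles, warning
  flat <- co$cells[[1]]
  labels <- segment_nuclei(flat$dapi)
  flat_son <- matrix(7, nrow(flat$son), ncol(flat$son))
  expect_warning(none <- segment_speckles(flat_son, labels), "constant SON")
  expect_false(any(none))
})

test_that("speckle ratio is a ratio of means with documented edge cases", {
  nucleus <- matrix(FALSE, 20, 20); nucleus[5:15, 5:15] <- TRUE
  speckle <- matrix(FALSE, 20, 20); speckle[8:10, 8:10] <- TRUE
  fish <- matrix(0, 20, 20)
  fish[nucleus] <- 100
  expect_equal(speckle_ratio(fish, nucleus, speckle), 1)
  fish[speckle] <- 200
  expect_equal(speckle_ratio(fish, nucleus, speckle), 2)
  # invariant to positive rescaling of the channel
  expect_equal(speckle_ratio(3.7 * fish, nucleus, speckle), 2)
  expect_true(is.na(speckle_ratio(fish, nucleus, matrix(FALSE, 20, 20))))
  expect_true(is.na(speckle_ratio(fish, speckle, speckle)))  # no nucleoplasm
})

test_that("positivity gating excludes background-level cells from summaries", {
  cfg <- image_sim_config(n_cells = 6L, fraction_diffuse = 0.5, seed = 23L)
  co <- simulate_cells(cfg)
  q <- quantify_cohort(co)
  # force one cell's FISH to background level: it must drop out
  dark <- co$cells[[1]]
  dark$fish <- matrix(cfg$positivity_floor, nrow(dark$fish), ncol(dark$fish)) +
    pmax(matrix(rnorm(length(dark$fish), sd = 2), nrow(dark$fish)), -9)
  qd <- quantify_image(dark$dapi, dark$son, dark$fish)
  all_q <- classify_cells(rbind(cbind(cell_id = 0L, qd), q))
  expect_equal(all_q$pattern[all_q$cell_id == 0L], "Unclassified")
  summ <- attr(all_q, "summary")
  expect_equal(summ$n_positive, 6L)
  expect_equal(summ$pct_speckle + summ$pct_diffused, 100)
  # uniform-FISH (ratio ~ 1) positive cells are Diffused at cutoff 1.5
  diffuse_truth <- which(vapply(co$cells, function(c)
    c$truth$pattern == "Diffused", logical(1)))
  expect_true(all(all_q$pattern[all_q$cell_id %in% diffuse_truth] ==
                    "Diffused"))
})

test_that("a two-arm enrichment experiment separates cleanly", {
  enriched <- simulate_cells(image_sim_config(n_cells = 8L,
                                              fish_enrichment = 3,
                                              seed = 31L))
  control <- simulate_cells(image_sim_config(n_cells = 8L,
                                             fish_enrichment = 1,
                                             seed = 32L))
  qa <- classify_cells(quantify_cohort(enriched))
  qb <- classify_cells(quantify_cohort(control))
  expect_gt(mean(qa$ratio) - mean(qb$ratio), 0)
  expect_gt(attr(qa, "summary")$pct_speckle - attr(qb, "summary")$pct_speckle,
            50)
})

test_that("multi-page TIFF round trip preserves channel order and scale", {
  co <- simulate_cells(image_sim_config(n_cells = 1L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".tif")
  write_cell_tiff(co$cells[[1]], path)
  back <- read_cell_tiff(path)
  expect_equal(names(back), c("dapi", "son", "fish"))
  for (ch in names(back)) {
    expect_lt(max(abs(back[[ch]] - co$cells[[1]][[ch]])), 1.5)
  }
})
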
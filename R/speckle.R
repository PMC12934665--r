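#' Otsu threshold of a set of intensity values
#'
#' Classic between-class-variance Otsu on a histogram of the supplied
#' values. Needed because the per-nucleus SON threshold must be computed
#' on an arbitrary pixel subset, not a whole image.
#'
#' @param values Numeric intensities.
#' @param levels Histogram resolution (default 256).
#' @return The threshold (foreground is `> threshold`).
#' @keywords internal
otsu_threshold <- function(values, levels = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = levels + 1L)
  h <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1L] + breaks[-(levels + 1L)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Segment nuclei from the DAPI channel
#'
#' Gaussian-smooths (sigma 2 px by default), thresholds globally by Otsu,
#' fills holes, removes components below `min_area` or touching the
#' image border, and labels the rest 1..N.
#'
#' @param dapi 2-D intensity matrix.
#' @param min_area Minimum nucleus area in pixels (default 200).
#' @param sigma Gaussian smoothing SD in pixels (default 2).
#' @return Integer label matrix (0 = background).
#' @export
segment_nuclei <- function(dapi, min_area = 200L, sigma = 2) {
  if (var(as.vector(dapi)) == 0) {
    warning("blank DAPI channel: no nuclei")
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(dapi), sigma = sigma))
  mx <- max(sm)
  thr <- EBImage::otsu(EBImage::Image(sm / mx)) * mx
  mask <- sm > thr
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  border <- unique(c(labels[1L, ], labels[nrow(labels), ],
                     labels[, 1L], labels[, ncol(labels)]))
  areas <- tabulate(labels[labels > 0])
  keep <- setdiff(which(areas >= min_area), border)
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

#' Segment speckles from the SON channel within segmented nuclei
#'
#' Per nucleus, thresholds the SON intensities of that nucleus's pixels
#' by Otsu; the foreground is intersected with the nucleus, so the
#' speckle mask is always a subset of the nuclei. A nucleus with constant
#' SON yields no speckles (with a warning).
#'
#' @param son 2-D intensity matrix.
#' @param nucleus_labels Label matrix from [segment_nuclei()].
#' @return Logical speckle mask.
#' @export
segment_speckles <- function(son, nucleus_labels) {
  mask <- matrix(FALSE, nrow(son), ncol(son))
  for (i in seq_len(max(nucleus_labels))) {
    inside <- nucleus_labels == i
    v <- son[inside]
    if (var(v) == 0) {
      warning("nucleus ", i, " has constant SON: no speckles")
      next
    }
    thr <- otsu_threshold(v)
    mask[inside] <- son[inside] > thr
  }
  mask
}

#' Speckle-to-nucleoplasm FISH intensity ratio of one nucleus
#'
#' Mean FISH intensity over the speckle pixels of the nucleus divided by
#' the mean over the nucleus-minus-speckles (nucleoplasm) pixels. The
#' ratio of means is area-independent.
#'
#' @param fish 2-D FISH intensity matrix.
#' @param nucleus_mask Logical mask of one nucleus.
#' @param speckle_mask Logical speckle mask.
#' @return The ratio, or `NA` when either pixel set is empty or the
#'   nucleoplasm mean is zero.
#' @export
speckle_ratio <- function(fish, nucleus_mask, speckle_mask) {
  sp <- nucleus_mask & speckle_mask
  np <- nucleus_mask & !speckle_mask
  if (!any(sp) || !any(np)) return(NA_real_)
  denom <- mean(fish[np])
  if (denom <= 0) return(NA_real_)
  mean(fish[sp]) / denom
}

#' Quantify FISH speckle enrichment for the nuclei of one image
#'
#' Runs the segmentation chain (nuclei from DAPI, speckles from SON) and
#' computes, per nucleus, the speckle ratio, the nuclear mean FISH and
#' the image background (non-nucleus) FISH statistics used by the
#' positivity gate.
#'
#' @param dapi,son,fish Channel matrices of identical dimensions.
#' @param min_area,sigma Passed to [segment_nuclei()].
#' @return Data frame with one row per nucleus: `nucleus`, `area`,
#'   `ratio`, `nuclear_mean`, `bg_mean`, `bg_sd`.
#' @export
quantify_image <- function(dapi, son, fish, min_area = 200L, sigma = 2) {
  stopifnot(identical(dim(dapi), dim(son)), identical(dim(dapi), dim(fish)))
  labels <- segment_nuclei(dapi, min_area, sigma)
  n <- max(labels)
  bg <- fish[labels == 0]
  if (n == 0L) {
    return(data.frame(nucleus = integer(0), area = integer(0),
                      ratio = numeric(0), nuclear_mean = numeric(0),
                      bg_mean = numeric(0), bg_sd = numeric(0)))
  }
  speckle <- segment_speckles(son, labels)
  rows <- lapply(seq_len(n), function(i) {
    nuc <- labels == i
    data.frame(nucleus = i, area = sum(nuc),
               ratio = speckle_ratio(fish, nuc, speckle),
               nuclear_mean = mean(fish[nuc]),
               bg_mean = mean(bg), bg_sd = sd(bg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantify a whole simulated cohort
#'
#' @param cohort A `cell_cohort` from [simulate_cells()], or a list of
#'   cells with `dapi`/`son`/`fish` matrices.
#' @param min_area,sigma Passed to [segment_nuclei()].
#' @return Data frame over all cells with a `cell_id` column prepended to
#'   the [quantify_image()] columns.
#' @export
quantify_cohort <- function(cohort, min_area = 200L, sigma = 2) {
  cells <- if (inherits(cohort, "cell_cohort")) cohort$cells else cohort
  rows <- lapply(seq_along(cells), function(i) {
    q <- quantify_image(cells[[i]]$dapi, cells[[i]]$son, cells[[i]]$fish,
                        min_area, sigma)
    if (nrow(q)) cbind(cell_id = i, q) else NULL
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gate positivity and classify localization patterns
#'
#' A cell is FISH-positive when its nuclear mean exceeds the image
#' background mean by more than `positivity_k` background SDs. Among
#' positive cells, a speckle ratio of at least `ratio_cutoff` is a
#' "Speckle" pattern, below it "Diffused"; non-positive cells (and
#' positive cells with an undefined ratio) are "Unclassified" and are
#' excluded from the summary denominators.
#'
#' @param quants Per-nucleus quantification from [quantify_cohort()] /
#'   [quantify_image()].
#' @param positivity_k Background-SD multiplier of the positivity gate
#'   (default 3).
#' @param ratio_cutoff Speckle/Diffused boundary on the ratio
#'   (default 1.5; an operational stand-in for by-eye classification).
#' @return `quants` with `positive` and `pattern` columns and attribute
#'   `summary`: a list with `n_positive`, `pct_speckle`, `pct_diffused`.
#' @export
classify_cells <- function(quants, positivity_k = 3, ratio_cutoff = 1.5) {
  quants$positive <- quants$nuclear_mean >
    quants$bg_mean + positivity_k * quants$bg_sd
  quants$pattern <- ifelse(
    !quants$positive | is.na(quants$ratio), "Unclassified",
    ifelse(quants$ratio >= ratio_cutoff, "Speckle", "Diffused")
  )
  classified <- quants$pattern %in% c("Speckle", "Diffused")
  n_pos <- sum(classified)
  if (n_pos == 0L) {
    warning("no positive cells: summary undefined")
    summ <- list(n_positive = 0L, pct_speckle = NA_real_,
                 pct_diffused = NA_real_)
  } else {
    summ <- list(
      n_positive = n_pos,
      pct_speckle = 100 * sum(quants$pattern == "Speckle") / n_pos,
      pct_diffused = 100 * sum(quants$pattern == "Diffused") / n_pos
    )
  }
  attr(quants, "summary") <- summ
  quants
}
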
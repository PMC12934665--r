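#' Percent intron retention
#'
#' `PIR = 100 * IE / (IE + EE)`, the percentage of deduplicated molecules
#' supporting intron retention.
#'
#' @param ie,ee Non-negative molecule counts (vectorized).
#' @return Numeric percent in `[0, 100]`.
#' @examples
#' compute_pir(90, 10)  # 90
#' compute_pir(7, 13)   # 35
#' @export
compute_pir <- function(ie, ee) {
  if (any(ie < 0) || any(ee < 0)) stop("counts must be non-negative")
  total <- ie + ee
  if (any(total == 0)) {
    stop("PIR undefined for ie + ee = 0; filter such guides first")
  }
  100 * ie / total
}

#' Estimate the intergenic-control PIR baseline
#'
#' Aggregates the control guides' PIR values of one replicate into the
#' baseline `PIR_intergenic` that anchors dPIR. The default is the median
#' (robust to dropout-affected controls); `mean` and `pooled`
#' (`100 * sum(ie) / sum(ie + ee)`, count-weighted) are available.
#'
#' @param control_counts Guide counts restricted to control guides, with
#'   columns `replicate`, `ie`, `ee`.
#' @param replicate Replicate to estimate.
#' @param method One of `"median"`, `"mean"`, `"pooled"`.
#' @return List of class `baseline_estimate`: `replicate`,
#'   `pir_intergenic`, `n_controls`, `method`.
#' @export
estimate_baseline <- function(control_counts, replicate,
                              method = c("median", "mean", "pooled")) {
  method <- match.arg(method)
  x <- control_counts[control_counts$replicate == replicate, , drop = FALSE]
  if (nrow(x) == 0L) stop("no control guides for replicate ", replicate)
  pir <- compute_pir(x$ie, x$ee)
  value <- switch(method,
    median = median(pir),
    mean = mean(pir),
    pooled = 100 * sum(x$ie) / sum(x$ie + x$ee)
  )
  structure(list(replicate = replicate, pir_intergenic = value,
                 n_controls = nrow(x), method = method),
            class = "baseline_estimate")
}

#' Guide dPIR against a control baseline
#'
#' `dPIR = PIR_guide - PIR_intergenic`; negative values mean the guide's
#' target normally promotes retention of the reporter intron.
#'
#' @param pir Numeric PIR values (percent) of one replicate.
#' @param baseline A [estimate_baseline()] result for the same replicate.
#' @param replicate Replicate of the `pir` values, checked against the
#'   baseline.
#' @return Numeric dPIR in percentage points.
#' @export
compute_delta <- function(pir, baseline, replicate = baseline$replicate) {
  stopifnot(inherits(baseline, "baseline_estimate"))
  if (!identical(as.integer(replicate), as.integer(baseline$replicate))) {
    stop("baseline was estimated for replicate ", baseline$replicate,
         ", not ", replicate)
  }
  pir - baseline$pir_intergenic
}

#' Per-guide PIR / dPIR table for all replicates
#'
#' Joins guide counts with the library, computes PIR, estimates the
#' control baseline per replicate, and attaches dPIR.
#'
#' @param counts Guide counts (`guide_id`, `replicate`, `ie`, `ee`).
#' @param library Guide library (for `category` and target annotation).
#' @param baseline_method Baseline aggregation, see [estimate_baseline()].
#' @return Data frame with `guide_id`, `replicate`, `category`,
#'   `target_id`, `gene_a`, `gene_b`, `ie`, `ee`, `total`, `pir`,
#'   `pir_intergenic`, `delta_pir`; the per-replicate baselines are in
#'   attribute `baselines`.
#' @export
pir_table <- function(counts, library, baseline_method = "median") {
  m <- match(counts$guide_id, library$guide_id)
  if (anyNA(m)) stop("counts contain guides absent from the library")
  tab <- data.frame(
    counts[c("guide_id", "replicate", "ie", "ee")],
    total = counts$ie + counts$ee,
    category = library$category[m],
    target_id = library$target_id[m],
    gene_a = library$gene_a[m],
    gene_b = library$gene_b[m],
    stringsAsFactors = FALSE
  )
  tab$pir <- compute_pir(tab$ie, tab$ee)
  reps <- sort(unique(tab$replicate))
  baselines <- lapply(reps, function(r) {
    estimate_baseline(tab[tab$category == "control", , drop = FALSE],
                      r, baseline_method)
  })
  names(baselines) <- as.character(reps)
  base_val <- vapply(baselines, `[[`, numeric(1), "pir_intergenic")
  tab$pir_intergenic <- base_val[as.character(tab$replicate)]
  tab$delta_pir <- tab$pir - tab$pir_intergenic
  attr(tab, "baselines") <- baselines
  tab
}

#' Empirical dPIR threshold at a control-based FDR
#'
#' The threshold at which the expected fraction of intergenic controls
#' falling strictly beyond it equals `fdr`. For the lower tail this is the
#' order statistic at index `ceiling(fdr * n)` of the sorted control
#' dPIRs; the upper tail uses index `ceiling((1 - fdr) * n)`. "Beyond" is
#' strict, so at most `fdr * n` controls exceed the threshold and ties at
#' the threshold never count as exceeding.
#'
#' @param control_deltas Numeric dPIR values of control guides (>= 10
#'   required; the empirical quantile is unstable below that).
#' @param fdr Target control exceedance rate in `(0, 1]` (default 0.10).
#' @param tail `"lower"` (retention-promoting regulators) or `"upper"`.
#' @return The threshold in percentage points.
#' @export
empirical_threshold <- function(control_deltas, fdr = 0.10,
                                tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  n <- length(control_deltas)
  if (n < 10L) stop("need at least 10 control deltas for a stable threshold")
  if (!is.numeric(fdr) || fdr <= 0 || fdr > 1) stop("fdr must be in (0, 1]")
  s <- sort(control_deltas)
  if (tail == "lower") s[ceiling(fdr * n)] else s[ceiling((1 - fdr) * n)]
}

#' Per-replicate empirical thresholds from a PIR table
#'
#' @param pir_tab Result of [pir_table()].
#' @param fdr Target control exceedance rate (default 0.10).
#' @param tail Tail of interest, see [empirical_threshold()].
#' @return Data frame `replicate`, `threshold`, `tail`, `fdr`.
#' @export
threshold_table <- function(pir_tab, fdr = 0.10, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  reps <- sort(unique(pir_tab$replicate))
  thr <- vapply(reps, function(r) {
    ctl <- pir_tab$delta_pir[pir_tab$category == "control" &
                               pir_tab$replicate == r]
    empirical_threshold(ctl, fdr, tail)
  }, numeric(1))
  data.frame(replicate = reps, threshold = thr, tail = tail, fdr = fdr,
             stringsAsFactors = FALSE)
}
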
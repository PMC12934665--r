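#' Flag guides exceeding the empirical dPIR threshold
#'
#' A guide-replicate entry passes when its dPIR is strictly beyond the
#' replicate's threshold in the stated tail (ties at the threshold do not
#' count). Only guide-replicate entries present in the input (i.e. that
#' survived the minimum-molecule filter) receive a flag.
#'
#' @param deltas Data frame with `guide_id`, `replicate`, `delta_pir`.
#' @param thresholds [threshold_table()] output (`replicate`, `threshold`,
#'   `tail`).
#' @return `deltas` with logical column `pass` added.
#' @export
qualify_guides <- function(deltas, thresholds) {
  m <- match(deltas$replicate, thresholds$replicate)
  if (anyNA(m)) stop("missing threshold for some replicate")
  thr <- thresholds$threshold[m]
  tail <- thresholds$tail[m]
  deltas$pass <- ifelse(tail == "lower", deltas$delta_pir < thr,
                        deltas$delta_pir > thr)
  deltas
}

#' Gene-level hit call for one target
#'
#' Applies the gene rule: a target is a hit when its expression clears
#' `min_fpkm`, and in every replicate at least `min_qualifying` guides
#' pass the dPIR threshold and the passing fraction (over guides with
#' data in that replicate) is at least `min_fraction`.
#'
#' @param flags Data frame for one target with `guide_id`, `replicate`,
#'   `delta_pir`, `pass` (from [qualify_guides()]).
#' @param fpkm The target's expression; `NA` leaves the call undetermined
#'   with a warning.
#' @param min_qualifying Minimum passing guides per replicate (default 2).
#' @param min_fraction Minimum passing fraction per replicate
#'   (default 0.5).
#' @param min_fpkm Expression floor (default 0.1).
#' @return One-row data frame: `fpkm`, `n_guides_with_data`,
#'   `min_qualifying_guides`, `min_fraction_exceeding`, `is_hit`,
#'   `mean_delta`, `direction`.
#' @export
call_gene <- function(flags, fpkm, min_qualifying = 2L, min_fraction = 0.5,
                      min_fpkm = 0.1) {
  if (nrow(flags) == 0L) stop("no guide data for this target")
  reps <- sort(unique(flags$replicate))
  n_data <- vapply(reps, function(r) sum(flags$replicate == r), integer(1))
  n_qual <- vapply(reps, function(r) sum(flags$pass[flags$replicate == r]),
                   integer(1))
  frac <- n_qual / n_data
  mean_delta <- mean(flags$delta_pir)
  guides_ok <- all(n_qual >= min_qualifying) && all(frac >= min_fraction)
  if (is.na(fpkm)) {
    warning("missing FPKM: hit call undetermined")
    hit <- NA
  } else {
    hit <- fpkm >= min_fpkm && guides_ok
  }
  data.frame(
    fpkm = fpkm,
    n_guides_with_data = length(unique(flags$guide_id)),
    min_qualifying_guides = min(n_qual),
    min_fraction_exceeding = min(frac),
    is_hit = hit,
    mean_delta = mean_delta,
    direction = if (mean_delta < 0) "IR-promoting" else "splicing-promoting",
    stringsAsFactors = FALSE
  )
}

#' Gene-level hit calls for a whole screen
#'
#' Qualifies guides against the per-replicate thresholds and applies
#' [call_gene()] per target (single genes and pair constructs alike).
#' Pair constructs use the minimum FPKM of their two genes.
#'
#' @param pir_tab [pir_table()] output.
#' @param thresholds [threshold_table()] output.
#' @param fpkm Data frame `gene`, `fpkm`.
#' @param min_qualifying,min_fraction,min_fpkm See [call_gene()].
#' @return Data frame with one row per target: `target_id`, `category`,
#'   `gene_a`, `gene_b` plus the [call_gene()] columns.
#' @export
call_genes <- function(pir_tab, thresholds, fpkm, min_qualifying = 2L,
                       min_fraction = 0.5, min_fpkm = 0.1) {
  targ <- pir_tab[pir_tab$category != "control", , drop = FALSE]
  if (nrow(targ) == 0L) {
    return(data.frame(target_id = character(0), category = character(0),
                      gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  targ <- qualify_guides(targ, thresholds)
  fpkm_of <- function(g) {
    v <- fpkm$fpkm[match(g, fpkm$gene)]
    if (length(v) == 0L) NA_real_ else v
  }
  pieces <- lapply(split(targ, targ$target_id), function(d) {
    fp <- if (d$category[1L] == "pair") {
      min(fpkm_of(d$gene_a[1L]), fpkm_of(d$gene_b[1L]))
    } else {
      fpkm_of(d$gene_a[1L])
    }
    cbind(
      data.frame(target_id = d$target_id[1L], category = d$category[1L],
                 gene_a = d$gene_a[1L], gene_b = d$gene_b[1L],
                 stringsAsFactors = FALSE),
      call_gene(d, fp, min_qualifying, min_fraction, min_fpkm)
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Collapse pair-construct hits into a single-gene hit list
#'
#' Every gene of a hit pair construct joins the single-gene hit list,
#' flagged `from_pair`. A gene hit both singly and via a pair keeps its
#' single-gene evidence; a gene hit via several pairs keeps the pair with
#' the stronger `|mean_delta|`.
#'
#' @param calls [call_genes()] output.
#' @return Data frame `gene`, `mean_delta`, `direction`, `from_pair`,
#'   restricted to hits, one row per gene.
#' @export
collapse_combinatorial <- function(calls) {
  hits <- calls[!is.na(calls$is_hit) & calls$is_hit, , drop = FALSE]
  single <- hits[hits$category == "single", , drop = FALSE]
  pair <- hits[hits$category == "pair", , drop = FALSE]
  out <- data.frame(gene = single$gene_a, mean_delta = single$mean_delta,
                    direction = single$direction,
                    from_pair = rep(FALSE, nrow(single)),
                    stringsAsFactors = FALSE)
  if (nrow(pair)) {
    pg <- data.frame(
      gene = c(pair$gene_a, pair$gene_b),
      mean_delta = rep(pair$mean_delta, 2L),
      direction = rep(pair$direction, 2L),
      from_pair = TRUE, stringsAsFactors = FALSE
    )
    pg <- pg[!(pg$gene %in% out$gene), , drop = FALSE]
    if (nrow(pg)) {
      pg <- pg[order(pg$gene, -abs(pg$mean_delta)), , drop = FALSE]
      pg <- pg[!duplicated(pg$gene), , drop = FALSE]
      out <- rbind(out, pg)
    }
  }
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank hits across cell lines by average dPIR
#'
#' Averages each gene's `mean_delta` over the cell lines in which it has
#' a value and orders ascending (strongest retention-promoting regulators
#' first), breaking ties alphabetically by gene.
#'
#' @param hit_tables Named list of per-cell-line hit tables
#'   (from [collapse_combinatorial()]), or a single table.
#' @return Data frame `gene`, `avg_delta`, `n_cell_lines`, ordered.
#' @export
rank_hits <- function(hit_tables) {
  if (is.data.frame(hit_tables)) hit_tables <- list(hit_tables)
  long <- do.call(rbind, lapply(hit_tables, function(h) {
    h[c("gene", "mean_delta")]
  }))
  avg <- tapply(long$mean_delta, long$gene, mean)
  n <- tapply(long$mean_delta, long$gene, length)
  out <- data.frame(gene = names(avg), avg_delta = as.numeric(avg),
                    n_cell_lines = as.integer(n), stringsAsFactors = FALSE)
  out <- out[order(out$avg_delta, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end hit calling from counts
#'
#' Convenience wrapper: PIR/dPIR table, per-replicate empirical
#' thresholds, gene calls, and the collapsed single-gene hit list.
#'
#' @param counts Guide counts (`guide_id`, `replicate`, `ie`, `ee`).
#' @param library Guide library.
#' @param fpkm Data frame `gene`, `fpkm`.
#' @param fdr Control exceedance rate (default 0.10).
#' @param tail Threshold tail (default `"lower"`).
#' @param baseline_method Control aggregation (default `"median"`).
#' @param min_qualifying,min_fraction,min_fpkm See [call_gene()].
#' @return List with `pir`, `thresholds`, `calls`, `hits`.
#' @export
screen_hits <- function(counts, library, fpkm, fdr = 0.10,
                        tail = c("lower", "upper"),
                        baseline_method = "median", min_qualifying = 2L,
                        min_fraction = 0.5, min_fpkm = 0.1) {
  tail <- match.arg(tail)
  pir <- pir_table(counts, library, baseline_method)
  thr <- threshold_table(pir, fdr, tail)
  calls <- call_genes(pir, thr, fpkm, min_qualifying, min_fraction,
                      min_fpkm)
  list(pir = pir, thresholds = thr, calls = calls,
       hits = collapse_combinatorial(calls))
}

#' Screen summary statistics from a guide-level dPIR table
#'
#' Re-derives the headline screen numbers from a long table of per-guide
#' dPIR values across cell lines: per-line gene-level hit counts, the
#' union and intersection over cell lines, and the Fisher's-exact overlap
#' between the first two cell lines. The table must contain the control
#' guides (category `control`) from which each line's thresholds are
#' re-estimated.
#'
#' @param deltas Data frame with columns `cell_line`, `guide_id`,
#'   `replicate`, `category`, `target_id`, `gene_a`, `gene_b`,
#'   `delta_pir`.
#' @param fpkm Data frame `cell_line`, `gene`, `fpkm` (or `gene`, `fpkm`
#'   applied to every line).
#' @param fdr,tail,... Passed to [threshold_table()] and [call_genes()].
#' @return List with `per_line` (named hit counts), `hits` (named list of
#'   hit tables), `n_union`, `n_intersection`, and `overlap`
#'   (an `overlap_result` for the first two lines, or NULL).
#' @export
screen_summary_from_deltas <- function(deltas, fpkm, fdr = 0.10,
                                       tail = "lower", ...) {
  lines <- sort(unique(deltas$cell_line))
  hits <- list()
  universes <- list()
  for (cl in lines) {
    d <- deltas[deltas$cell_line == cl, , drop = FALSE]
    thr <- data.frame(
      replicate = sort(unique(d$replicate)),
      tail = tail, fdr = fdr, stringsAsFactors = FALSE
    )
    thr$threshold <- vapply(thr$replicate, function(r) {
      empirical_threshold(
        d$delta_pir[d$category == "control" & d$replicate == r], fdr, tail)
    }, numeric(1))
    fp <- if ("cell_line" %in% names(fpkm)) {
      fpkm[fpkm$cell_line == cl, c("gene", "fpkm"), drop = FALSE]
    } else {
      fpkm
    }
    calls <- call_genes(d, thr, fp, ...)
    hits[[cl]] <- collapse_combinatorial(calls)
    universes[[cl]] <- unique(stats::na.omit(c(d$gene_a, d$gene_b)))
  }
  hit_genes <- lapply(hits, `[[`, "gene")
  overlap <- NULL
  if (length(lines) >= 2L) {
    universe <- intersect(universes[[1L]], universes[[2L]])
    overlap <- fisher_overlap(intersect(hit_genes[[1L]], universe),
                              intersect(hit_genes[[2L]], universe),
                              universe)
  }
  list(
    per_line = vapply(hit_genes, length, integer(1)),
    hits = hits,
    n_union = length(Reduce(union, hit_genes)),
    n_intersection = length(Reduce(intersect, hit_genes)),
    overlap = overlap
  )
}
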
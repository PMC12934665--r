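#' Intron-retention ratio
#'
#' `IR ratio = intronic / (intronic + exonic)` for an annotated intron.
#' A zero denominator yields `NA` (undefined, distinct from 0).
#'
#' @param intronic,exonic Non-negative abundances (vectorized).
#' @return Ratio in `[0, 1]`, `NA` where undefined.
#' @examples
#' compute_ir_ratio(5, 95)  # 0.05
#' @export
compute_ir_ratio <- function(intronic, exonic) {
  if (any(intronic < 0, na.rm = TRUE) || any(exonic < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative")
  }
  total <- intronic + exonic
  ifelse(total > 0, intronic / total, NA_real_)
}

#' Detection filter on IR records
#'
#' Retains an intron when its IR ratio is at least `min_ratio`
#' (inclusive) in at least `min_samples` samples; undefined ratios never
#' satisfy the criterion.
#'
#' @param records Long data frame `intron_id`, `sample`, `intronic`,
#'   `exonic` (an `ir_ratio` column is computed if absent).
#' @param min_ratio Detection floor (default 0.05).
#' @param min_samples Minimum qualifying samples (default 1).
#' @return The rows of `records` belonging to retained introns, with
#'   `ir_ratio` attached.
#' @export
apply_detection_filter <- function(records, min_ratio = 0.05,
                                   min_samples = 1L) {
  if (!"ir_ratio" %in% names(records)) {
    records$ir_ratio <- compute_ir_ratio(records$intronic, records$exonic)
  }
  ok <- !is.na(records$ir_ratio) & records$ir_ratio >= min_ratio
  n_ok <- tapply(ok, records$intron_id, sum)
  keep_ids <- names(n_ok)[n_ok >= min_samples]
  out <- records[records$intron_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Differential intron retention between two conditions
#'
#' For each intron, `delta_ratio` is the mean IR ratio in condition `a`
#' minus that in condition `b` (over samples with a defined ratio), with
#' direction from its sign. Significance is a two-sided Fisher's exact
#' test on the pooled, rounded `(intronic, exonic)` counts of the two
#' conditions -- a deliberate, explicitly tagged substitute for a
#' model-based differential test (output carries `test = "fisher_pooled"`
#' so results are never mistaken for one).
#'
#' @param records Long data frame `intron_id`, `sample`, `condition`,
#'   `intronic`, `exonic`.
#' @param condition_a,condition_b The two condition labels to compare
#'   (delta is `a - b`).
#' @return Data frame `intron_id`, `delta_ratio`, `direction`
#'   (`increased`/`decreased`/`unchanged`), `p_value`, `test`.
#' @export
differential_ir <- function(records, condition_a, condition_b) {
  stopifnot(all(c("intron_id", "condition", "intronic", "exonic") %in%
                  names(records)))
  records$ir_ratio <- compute_ir_ratio(records$intronic, records$exonic)
  per_intron <- function(d) {
    a <- d[d$condition == condition_a, , drop = FALSE]
    b <- d[d$condition == condition_b, , drop = FALSE]
    ra <- a$ir_ratio[!is.na(a$ir_ratio)]
    rb <- b$ir_ratio[!is.na(b$ir_ratio)]
    if (length(ra) == 0L || length(rb) == 0L) {
      stop("all IR ratios undefined in one condition for intron ",
           d$intron_id[1L])
    }
    delta <- mean(ra) - mean(rb)
    p <- fisher_p_two_sided(round(sum(a$intronic)), round(sum(a$exonic)),
                            round(sum(b$intronic)), round(sum(b$exonic)))
    data.frame(
      intron_id = d$intron_id[1L], delta_ratio = delta,
      direction = if (delta > 0) "increased" else if (delta < 0)
        "decreased" else "unchanged",
      p_value = p, test = "fisher_pooled", stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(split(records, records$intron_id), per_intron))
  rownames(out) <- NULL
  out
}

.validate_intervals <- function(df, what) {
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    id <- if ("intron_id" %in% names(df)) df$intron_id[bad[1L]] else
      if ("name" %in% names(df)) df$name[bad[1L]] else bad[1L]
    stop("malformed ", what, " interval (start >= end): ", id)
  }
}

.as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    s <- df$strand
    s[is.na(s) | !(s %in% c("+", "-"))] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

#' Flag introns overlapped by CLIP peaks
#'
#' Coordinates are 0-based half-open; an intron is bound when some peak
#' on the same chromosome (and strand, if `stranded`) overlaps it by at
#' least `min_overlap_bp` (`overlap = max(0, min(end) - max(start))`), so
#' half-open abutting intervals never overlap.
#'
#' @param introns Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), optionally `strand` and `intron_id`.
#' @param peaks Data frame of peak intervals, same conventions.
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @param stranded Require matching strands (default FALSE; peak files
#'   are often effectively unstranded after processing).
#' @return `introns` with logical column `bound` and attribute
#'   `n_bound`.
#' @export
annotate_binding <- function(introns, peaks, min_overlap_bp = 1L,
                             stranded = FALSE) {
  .validate_intervals(introns, "intron")
  .validate_intervals(peaks, "peak")
  hits <- GenomicRanges::countOverlaps(
    .as_granges(introns), .as_granges(peaks),
    minoverlap = min_overlap_bp, ignore.strand = !stranded
  )
  introns$bound <- hits > 0L
  attr(introns, "n_bound") <- sum(introns$bound)
  introns
}

#' Read a BED file as 0-based half-open intervals
#'
#' @param path BED3-6 path.
#' @return Data frame `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (0-based half-open coordinates).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) gr$score else NA_real_,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Pyrimidine content of a polypyrimidine-tract window
#'
#' Fraction of pyrimidines (C and T/U) in the `window` nucleotides
#' immediately upstream of a 3' splice site, given the sense-strand
#' sequence ending at the splice site. Purine-rich (low-scoring) tracts
#' are weak U2AF2 substrates.
#'
#' @param seq Sense-strand nucleotide string whose final base abuts the
#'   3' splice site; length >= `window`.
#' @param window Window size in nt (default 20).
#' @return Pyrimidine fraction in `[0, 1]`.
#' @examples
#' score_py_tract("TTTTTTTTTTAGAGAGAGAG")  # 0.5
#' @export
score_py_tract <- function(seq, window = 20L) {
  seq <- toupper(seq)
  if (nchar(seq) < window) stop("sequence shorter than the scoring window")
  tract <- substr(seq, nchar(seq) - window + 1L, nchar(seq))
  chars <- strsplit(tract, "")[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T", "U"))) {
    stop("non-nucleotide characters in sequence")
  }
  mean(chars %in% c("C", "T", "U"))
}
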
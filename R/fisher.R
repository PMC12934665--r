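# Two-sided Fisher's exact p for a 2x2 table, by direct summation of the
# hypergeometric distribution: all outcomes whose probability does not
# exceed the observed table's (with the conventional 1 + 1e-7 relative
# slack guarding against floating-point ties) contribute to p. Implemented
# over the whole support at once so sweeps across tables stay cheap.

FISHER_REL_SLACK <- 1 + 1e-7

#' Two-sided Fisher p-values over the full hypergeometric support
#'
#' For fixed margins (`r` successes in the universe of `n`, sample of size
#' `c`) returns the two-sided exact p for every feasible count `x` of the
#' top-left cell.
#'
#' @param r,c,n Row margin, column margin, universe size.
#' @return List with `support` (feasible `x`) and `p` (matching p-values).
#' @keywords internal
fisher_p_profile <- function(r, c, n) {
  lo <- max(0L, r + c - n)
  hi <- min(r, c)
  x <- lo:hi
  probs <- dhyper(x, c, n - c, r)
  cmp <- outer(probs, probs * FISHER_REL_SLACK, `<=`)
  list(support = x, p = pmin(as.numeric(probs %*% cmp), 1))
}

#' Two-sided Fisher's exact p for one 2x2 table
#'
#' @param both,a_only,b_only,neither Non-negative cell counts.
#' @return The two-sided p-value.
#' @export
fisher_p_two_sided <- function(both, a_only, b_only, neither) {
  cells <- c(both, a_only, b_only, neither)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  prof <- fisher_p_profile(both + a_only, both + b_only, sum(cells))
  prof$p[prof$support == both]
}

#' Overlap of two hit sets by Fisher's exact test
#'
#' Cross-tabulates membership in `hits_a` and `hits_b` over a gene
#' universe and reports the sample odds ratio
#' `(both * neither) / (a_only * b_only)` with the two-sided exact p.
#' The odds ratio is `Inf` when the denominator is zero with a positive
#' numerator and 0 when the numerator is zero with a positive denominator.
#'
#' @param hits_a,hits_b Character vectors of hit genes; must be subsets of
#'   `universe`.
#' @param universe Character vector of all eligible genes.
#' @return List of class `overlap_result`: `both`, `a_only`, `b_only`,
#'   `neither`, `odds_ratio`, `p_value`.
#' @examples
#' fisher_overlap(letters[1:10], letters[6:15], letters)
#' @export
fisher_overlap <- function(hits_a, hits_b, universe) {
  universe <- unique(universe)
  hits_a <- unique(hits_a)
  hits_b <- unique(hits_b)
  out_a <- setdiff(hits_a, universe)
  out_b <- setdiff(hits_b, universe)
  if (length(out_a) || length(out_b)) {
    stop("hit genes outside the universe: ",
         paste(c(out_a, out_b), collapse = ", "))
  }
  in_a <- universe %in% hits_a
  in_b <- universe %in% hits_b
  both <- sum(in_a & in_b)
  a_only <- sum(in_a & !in_b)
  b_only <- sum(!in_a & in_b)
  neither <- sum(!in_a & !in_b)
  num <- both * neither
  den <- a_only * b_only
  or <- if (den > 0) num / den else if (num > 0) Inf else NaN
  structure(list(both = both, a_only = a_only, b_only = b_only,
                 neither = neither, odds_ratio = or,
                 p_value = fisher_p_two_sided(both, a_only, b_only, neither)),
            class = "overlap_result")
}
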
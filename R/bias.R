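## Post-filter bias report: does the clan filter systematically remove
## families with longer branches (long-branch attraction) or with more
## compositionally heterogeneous taxa?  Standard rank-sum tests, reported as
## a convenience layer over the per-family statistics.

#' Compare kept and removed family sets for systematic biases
#'
#' Computes the per-family average branch length for both sets and, when
#' alignments are supplied, the per-family fraction of taxa failing the
#' compositional-heterogeneity test, then runs two-sided Wilcoxon rank-sum
#' tests between kept and removed.  Non-significant differences indicate the
#' clan filter is not merely selecting on branch length or composition.
#'
#' @param kept,removed non-empty lists of [gene_family()] records.
#' @param alignments optional named list of [aa_alignment()] objects keyed by
#'   family id, covering families in both sets.
#' @param alpha significance level recorded in the report (default 0.05).
#' @return an object of class `bias_report`: list with `branch_length`
#'   (per-set values, W statistic, p value) and, if alignments were given,
#'   `composition` in the same shape.
#' @export
bias_report <- function(kept, removed, alignments = NULL, alpha = 0.05) {
  if (!length(kept) || !length(removed)) {
    stop("both kept and removed sets must be non-empty", call. = FALSE)
  }
  abl <- function(records) {
    vapply(records, function(rec) avg_branch_length(rec$tree), numeric(1L))
  }
  bl_kept <- abl(kept)
  bl_removed <- abl(removed)
  wt <- wilcox.test(bl_kept, bl_removed, exact = FALSE)
  out <- list(
    alpha = alpha,
    branch_length = list(kept = bl_kept, removed = bl_removed,
                         statistic = unname(wt$statistic),
                         p_value = wt$p.value)
  )
  if (!is.null(alignments)) {
    frac <- function(records) {
      vapply(records, function(rec) {
        aln <- alignments[[rec$family_id]]
        if (is.null(aln)) {
          stop("no alignment for family ", rec$family_id, call. = FALSE)
        }
        composition_test(aln, alpha = alpha)$fraction_failing
      }, numeric(1L))
    }
    ck <- frac(kept)
    cr <- frac(removed)
    wc <- wilcox.test(ck, cr, exact = FALSE)
    out$composition <- list(kept = ck, removed = cr,
                            statistic = unname(wc$statistic),
                            p_value = wc$p.value)
  }
  structure(out, class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Bias report (kept vs removed families)\n")
  cat(sprintf("  average branch length: W = %.1f, p = %.4f\n",
              x$branch_length$statistic, x$branch_length$p_value))
  if (!is.null(x$composition)) {
    cat(sprintf("  composition failure fraction: W = %.1f, p = %.4f\n",
                x$composition$statistic, x$composition$p_value))
  }
  invisible(x)
}
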
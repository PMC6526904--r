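## Alignment-level curation screens: substitution saturation (sums of NJ
## branch lengths under uncorrected vs multiple-hit-corrected distances) and
## per-taxon compositional heterogeneity.

.GAPCHARS <- c("-", "X", ".", "?")

#' Read an aligned amino-acid FASTA file
#'
#' @param path path to an aligned FASTA file.
#' @return named character vector of upper-case sequences, all equal length,
#'   of class `aa_alignment`.
#' @export
read_alignment <- function(path) {
  x <- ape::read.FASTA(path, type = "AA")
  aln <- toupper(vapply(as.character(x), paste, character(1L), collapse = ""))
  aa_alignment(aln)
}

#' Construct an alignment block
#'
#' @param seqs named character vector of aligned amino-acid sequences
#'   (equal lengths; gaps `-`, unknowns `X`).
#' @return the validated vector with class `aa_alignment`.
#' @export
aa_alignment <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), length(seqs) >= 1L)
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences differ in length", call. = FALSE)
  }
  structure(seqs, class = "aa_alignment")
}

.aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Uncorrected (p) distance between two aligned sequences
#'
#' Proportion of differing positions among positions where both sequences
#' carry a residue (pairwise deletion of gaps and `X`).  Returns 0 with a
#' warning when no position is comparable.
#'
#' @param a,b aligned sequences of equal length.
#' @return a number in \[0, 1\].
#' @export
p_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  if (length(ca) != length(cb)) stop("length mismatch", call. = FALSE)
  ok <- !(ca %in% .GAPCHARS) & !(cb %in% .GAPCHARS)
  if (!any(ok)) {
    warning("no comparable sites; p-distance set to 0", call. = FALSE)
    return(0)
  }
  mean(ca[ok] != cb[ok])
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln an [aa_alignment()].
#' @return symmetric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  m <- .aln_matrix(aa_alignment(aln))
  n <- nrow(m)
  valid <- matrix(!(m %in% .GAPCHARS), nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      ok <- valid[i, ] & valid[j, ]
      d[i, j] <- d[j, i] <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
    }
  }
  d
}

#' Multiple-hit-corrected protein distance
#'
#' Kimura's protein correction d = -ln(1 - p - 0.2 p^2), a closed-form
#' stand-in for a model-based (e.g. JTT) distance: it inflates large
#' p-distances to account for superimposed substitutions, which is exactly
#' what the saturation screen compares against.  Pairs beyond the correction
#' domain (p >= ~0.8541) are saturated; their distance is set to `cap` and
#' flagged in the `"saturated"` attribute.
#'
#' @param p p-distance(s) in \[0, 1\].
#' @param cap distance assigned to saturated pairs (default 5).
#' @return corrected distance(s), with logical attribute `"saturated"`.
#' @export
corrected_distance <- function(p, cap = 5) {
  stopifnot(all(p >= 0 & p <= 1))
  arg <- 1 - p - 0.2 * p^2
  sat <- arg <= 0
  d <- ifelse(sat, cap, -log(pmax(arg, .Machine$double.xmin)))
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()] (exact on additive matrices),
#' with the three-taxon case solved in closed form from the three pairwise
#' equations.  Negative estimated branch lengths are clamped to zero; the
#' total clamped deficit is stored in the `"clamped"` attribute.
#'
#' @param d symmetric distance matrix with at least 3 labelled rows.
#' @return an unrooted `phylo` object.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 labels", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (nrow(d) == 3L) {
    v <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    clamped <- sum(pmin(v, 0))
    v <- pmax(v, 0)
    lab <- rownames(d)
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                                        lab[1L], v[1L], lab[2L], v[2L],
                                        lab[3L], v[3L]))
    attr(tr, "clamped") <- clamped
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  attr(tr, "clamped") <- sum(tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  tr
}

#' Saturation statistic of one alignment
#'
#' Builds NJ trees from the p-distance matrix and from the corrected-distance
#' matrix, sums each tree's branch lengths, and reports both sums plus their
#' ratio.  Saturated alignments show corrected sums far exceeding p-distance
#' sums (ratio well above 1); for identical sequences both sums are 0 and the
#' ratio is defined as 1.
#'
#' @param aln an [aa_alignment()] with at least 3 sequences.
#' @param cap saturated-pair cap passed to [corrected_distance()].
#' @return a list with `sum_p`, `sum_corrected`, `ratio` and
#'   `n_saturated_pairs`.
#' @export
saturation_stat <- function(aln, cap = 5) {
  aln <- aa_alignment(aln)
  if (length(aln) < 3L) stop("need at least 3 sequences", call. = FALSE)
  pm <- p_distance_matrix(aln)
  cm <- corrected_distance(pm, cap = cap)
  sat <- attr(cm, "saturated")
  cm <- matrix(as.numeric(cm), nrow = nrow(pm), dimnames = dimnames(pm))
  diag(cm) <- 0
  sum_p <- sum(nj_tree(pm)$edge.length)
  sum_c <- sum(nj_tree(cm)$edge.length)
  list(sum_p = sum_p,
       sum_corrected = sum_c,
       ratio = if (sum_p == 0) 1 else sum_c / sum_p,
       n_saturated_pairs = sum(sat[upper.tri(sat)]))
}

#' Flag saturated gene families from their saturation ratios
#'
#' The visual outlier inspection of branch-length-sum plots is replaced by an
#' explicit rule: a family is flagged when its corrected/p ratio exceeds
#' median + k * MAD across families, or an absolute cap.
#'
#' @param stats data frame with columns `family_id` and `ratio` (at least 5
#'   rows for the robust rule).
#' @param k MAD multiplier (default 5; `Inf` disables).
#' @param cap absolute ratio cap (default 3; `Inf` disables).
#' @return character vector of flagged family ids.
#' @export
flag_saturated <- function(stats, k = 5, cap = 3) {
  stopifnot(is.data.frame(stats), all(c("family_id", "ratio") %in%
                                        names(stats)))
  if (nrow(stats) < 5L && is.finite(k)) {
    stop("need at least 5 families for the median + k*MAD rule", call. = FALSE)
  }
  r <- stats$ratio
  thr <- if (is.finite(k)) median(r) + k * mad(r) else Inf
  stats$family_id[r > thr | r > cap]
}

#' Per-taxon compositional-heterogeneity test
#'
#' For every sequence, a chi-square test of its amino-acid counts (gaps and
#' `X` excluded) against the alignment-wide residue frequencies, with degrees
#' of freedom equal to the number of residue states observed in that sequence
#' minus one (sparse residue usage in short alignments makes the full 19 df
#' anti-conservative).  Sequences with no comparable sites get `NA` with a
#' warning and are excluded from the failure fraction.
#'
#' @param aln an [aa_alignment()] with at least 2 sequences.
#' @param alpha significance level for the failure fraction (default 0.05).
#' @return a list with `p_values` (named over sequences), `fraction_failing`
#'   and `alpha`.
#' @export
composition_test <- function(aln, alpha = 0.05) {
  aln <- aa_alignment(aln)
  if (length(aln) < 2L) stop("need at least 2 sequences", call. = FALSE)
  m <- .aln_matrix(aln)
  keep <- !(m %in% .GAPCHARS)
  res <- m[keep]
  states <- sort(unique(res))
  f <- table(factor(res, levels = states))
  f <- as.numeric(f) / sum(f)
  p <- setNames(rep(NA_real_, nrow(m)), rownames(m))
  for (i in seq_len(nrow(m))) {
    ri <- m[i, !(m[i, ] %in% .GAPCHARS)]
    if (!length(ri)) {
      warning("sequence ", rownames(m)[i],
              " has no comparable sites; excluded", call. = FALSE)
      next
    }
    obs <- as.numeric(table(factor(ri, levels = states)))
    expd <- length(ri) * f
    use <- expd > 0
    stat <- sum((obs[use] - expd[use])^2 / expd[use])
    df <- sum(obs > 0) - 1L
    p[i] <- pchisq(stat, df = df, lower.tail = FALSE)
  }
  ok <- !is.na(p)
  list(p_values = p,
       fraction_failing = if (any(ok)) mean(p[ok] < alpha) else NA_real_,
       alpha = alpha)
}
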
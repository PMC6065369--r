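#' Volcano screen of a curated gene list
#'
#' Differential-expression screen across two sample groups (e.g. ER+ vs
#' ER- tumors). Per gene, the fold change is the ratio of group mean
#' intensities (reported as log2) and the p value comes from Welch's
#' two-sample comparison of log2 intensities. A gene is a hit when its
#' absolute fold change reaches \code{fc_threshold} (in either direction)
#' and its p value is at most \code{p_threshold}. No multiple-testing
#' correction is applied by default, matching the per-gene rule the
#' screen is built on; Benjamini-Hochberg adjustment is available behind
#' a flag.
#'
#' @param expr numeric matrix, genes (rows) x samples (columns), linear
#'   intensity scale, strictly positive.
#' @param groups factor or vector of two group labels, one per column;
#'   the first level is the numerator of the fold change. Each group
#'   needs at least 2 samples.
#' @param gene_list optional curated subset of rownames to screen;
#'   missing genes are reported in the \code{"missing_genes"} attribute.
#' @param fc_threshold fold-change hit threshold (default 2).
#' @param p_threshold p-value hit threshold (default 0.05).
#' @param fdr apply Benjamini-Hochberg adjustment before thresholding
#'   (default FALSE).
#' @param min_per_group minimum samples per group (default 10, mirroring
#'   the dataset inclusion rule; lower it for small designs).
#' @return Data frame sorted by descending significance: \code{gene},
#'   \code{log2_fc}, \code{p}, \code{hit}, \code{direction} (+1/-1/0),
#'   \code{degenerate} (TRUE when a gene had zero variance in both groups
#'   so no p value is defined; such genes are flagged, never silently
#'   dropped).
#' @export
volcano_screen <- function(expr, groups, gene_list = NULL,
                           fc_threshold = 2, p_threshold = 0.05,
                           fdr = FALSE, min_per_group = 10) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)))
    stop("expr must have gene names as rownames")
  if (any(expr <= 0)) stop("expression intensities must be positive")
  groups <- factor(groups)
  if (nlevels(groups) != 2 || length(groups) != ncol(expr))
    stop("groups must assign each sample to one of exactly two groups")
  tabg <- table(groups)
  if (any(tabg < 2)) stop("each group needs at least 2 samples")
  if (any(tabg < min_per_group))
    warning(sprintf("a group has fewer than %d samples", min_per_group))
  missing_genes <- character(0)
  if (!is.null(gene_list)) {
    missing_genes <- setdiff(gene_list, rownames(expr))
    expr <- expr[intersect(gene_list, rownames(expr)), , drop = FALSE]
  }
  ga <- groups == levels(groups)[1]
  lg <- log2(expr)
  res <- data.frame(gene = rownames(expr),
                    log2_fc = log2(rowMeans(expr[, ga, drop = FALSE]) /
                                   rowMeans(expr[, !ga, drop = FALSE])),
                    p = NA_real_, degenerate = FALSE)
  for (i in seq_len(nrow(expr))) {
    va <- lg[i, ga]; vb <- lg[i, !ga]
    if (stats::var(va) == 0 && stats::var(vb) == 0) {
      res$degenerate[i] <- TRUE
      next
    }
    res$p[i] <- stats::t.test(va, vb, var.equal = FALSE)$p.value
  }
  p_eff <- if (fdr) stats::p.adjust(res$p, method = "BH") else res$p
  res$hit <- !res$degenerate &
    abs(res$log2_fc) >= log2(fc_threshold) &
    !is.na(p_eff) & p_eff <= p_threshold
  res$direction <- sign(res$log2_fc) * (res$log2_fc != 0)
  res <- res[order(res$p, -abs(res$log2_fc), na.last = TRUE), ]
  rownames(res) <- NULL
  res <- res[, c("gene", "log2_fc", "p", "hit", "direction", "degenerate")]
  attr(res, "missing_genes") <- missing_genes
  attr(res, "thresholds") <- c(fc = fc_threshold, p = p_threshold)
  res
}

#' Cross-dataset recurrence tally of volcano hits
#'
#' Counts, for every gene, the number of independent datasets in which it
#' passed both volcano thresholds, and ranks genes by recurrence; ties in
#' recurrence are broken by mean -log10 p across the datasets in which
#' the gene was tested.
#'
#' @param results list of volcano result data frames from
#'   [volcano_screen()], one per dataset.
#' @return Data frame sorted by rank: \code{gene}, \code{recurrence},
#'   \code{n_datasets_tested}, \code{mean_neglog10_p}, \code{rank}.
#' @export
cross_dataset_tally <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  all_genes <- sort(unique(unlist(lapply(results, function(r) r$gene))))
  rec <- stats::setNames(integer(length(all_genes)), all_genes)
  nl10 <- stats::setNames(numeric(length(all_genes)), all_genes)
  ntest <- stats::setNames(integer(length(all_genes)), all_genes)
  for (r in results) {
    stopifnot(all(c("gene", "p", "hit") %in% names(r)))
    g <- as.character(r$gene)
    rec[g] <- rec[g] + as.integer(r$hit)
    ok <- !is.na(r$p)
    nl10[g[ok]] <- nl10[g[ok]] + (-log10(pmax(r$p[ok], 1e-300)))
    ntest[g] <- ntest[g] + as.integer(ok)
  }
  mean_nl10 <- ifelse(ntest > 0, nl10 / ntest, 0)
  out <- data.frame(gene = all_genes, recurrence = as.integer(rec),
                    n_datasets_tested = as.integer(ntest),
                    mean_neglog10_p = mean_nl10)
  out <- out[order(-out$recurrence, -out$mean_neglog10_p, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
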
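#' Linear fold change between two groups of log2 expression means
#'
#' @param mean_log2_a,mean_log2_b Group means on the log2 scale; group `a`
#'   is the feature-positive group.
#' @return `2^(mean_log2_a - mean_log2_b)`.
#' @export
#' @examples
#' compute_fold_change(6, 5) # 2
compute_fold_change <- function(mean_log2_a, mean_log2_b) {
  if (any(!is.finite(mean_log2_a)) || any(!is.finite(mean_log2_b)))
    .fail("fold change requires finite log2 means")
  2^(mean_log2_a - mean_log2_b)
}

#' Two-group differential test
#'
#' `"wilcoxon"` runs a two-sided rank-sum test; `"ttest"` a two-sided
#' two-sample t-test; `"auto"` applies the t-test only when both groups
#' pass a Shapiro normality check and a Bartlett homoscedasticity check
#' (both at p > 0.05), falling back to the rank-sum test otherwise.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 3).
#' @param method `"wilcoxon"`, `"ttest"` or `"auto"`.
#' @return The two-sided p-value, with attribute `"method"` recording the
#'   branch actually used.
#' @export
test_differential <- function(values_a, values_b,
                              method = c("wilcoxon", "ttest", "auto")) {
  method <- match.arg(method)
  if (length(values_a) < 3L || length(values_b) < 3L)
    .fail("each group needs at least 3 values")
  if (method == "auto") {
    normal <- tryCatch(
      stats::shapiro.test(values_a)$p.value > 0.05 &&
        stats::shapiro.test(values_b)$p.value > 0.05,
      error = function(e) FALSE)
    homosc <- normal && tryCatch(
      stats::bartlett.test(list(values_a, values_b))$p.value > 0.05,
      error = function(e) FALSE)
    method <- if (normal && homosc) "ttest" else "wilcoxon"
  }
  p <- if (method == "ttest") {
    if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
      warning("zero variance in both groups; p set to 1", call. = FALSE)
      1
    } else {
      stats::t.test(values_a, values_b)$p.value
    }
  } else {
    suppressWarnings(stats::wilcox.test(values_a, values_b)$p.value)
  }
  structure(p, method = method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: `q_i = min over {j : p_j >= p_i} of m * p_j /
#' rank_j`, clipped at 1 and monotone in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return The BH-adjusted q-values, in the input order.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    .fail("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

.direction_call <- function(fc, q, cfg) {
  ifelse(q < cfg$fdr & fc >= cfg$fc_up, "up",
         ifelse(q < cfg$fdr & fc <= cfg$fc_down, "down", "none"))
}

#' Screen lncRNAs for differential expression against a binary feature
#'
#' Per gene: linear fold change (feature-positive over feature-negative
#' mean on the log2 scale), two-group test p-value, BH q-value across the
#' tested genes, and a direction call requiring both the fold-change gate
#' (`>= fc_up` or `<= fc_down`) and `q < fdr`. Samples with a missing
#' label are excluded from this comparison.
#'
#' @param expr Numeric matrix, genes x samples (typically the lncRNA rows
#'   of the cohort).
#' @param labels Character/factor vector per sample; `positive` names the
#'   feature-positive level.
#' @param positive The feature-positive level of `labels`.
#' @param config A [lnchet_config()].
#' @param feature Label recorded in the output.
#' @return Data frame `gene`, `feature`, `n_pos`, `n_neg`, `fc`, `p`, `q`,
#'   `direction`, sorted by `q`.
#' @export
screen_binary_feature <- function(expr, labels, positive,
                                  config = lnchet_config(),
                                  feature = "feature") {
  if (length(labels) != ncol(expr))
    .fail("'labels' must have one value per sample")
  labels <- as.character(labels)
  keep <- !is.na(labels)
  expr <- expr[, keep, drop = FALSE]
  labels <- labels[keep]
  a <- labels == positive
  if (!any(a) || all(a))
    .fail("a group is empty after NA removal (feature '", feature, "')")
  xa <- expr[, a, drop = FALSE]
  xb <- expr[, !a, drop = FALSE]
  fc <- compute_fold_change(rowMeans(xa), rowMeans(xb))
  p <- vapply(seq_len(nrow(expr)), function(i)
    as.numeric(test_differential(xa[i, ], xb[i, ], config$test_method)),
    0)
  q <- adjust_bh(p)
  out <- data.frame(gene = rownames(expr), feature = feature,
                    n_pos = sum(a), n_neg = sum(!a),
                    fc = unname(fc), p = p, q = q,
                    direction = .direction_call(fc, q, config),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen lncRNAs for subtype-distinctive expression
#'
#' For each subtype the fold change compares the gene's mean in the focal
#' subtype to the unweighted mean of the per-subtype means of the
#' remaining subtypes; the p-value tests focal samples against the pooled
#' remaining samples. Gates are as in [screen_binary_feature()], with BH
#' applied within each subtype's gene family. Subtypes with fewer than 3
#' samples are excluded with a warning.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param subtype Character/factor of subtype labels per sample (NA
#'   samples are dropped).
#' @param config A [lnchet_config()].
#' @return Data frame with one row per (gene, subtype), columns as in
#'   [screen_binary_feature()] (`feature` holds the subtype).
#' @export
screen_subtype_distinctive <- function(expr, subtype,
                                       config = lnchet_config()) {
  subtype <- as.character(subtype)
  keep <- !is.na(subtype)
  expr <- expr[, keep, drop = FALSE]
  subtype <- subtype[keep]
  counts <- table(subtype)
  small <- names(counts)[counts < 3L]
  if (length(small)) {
    warning("subtype(s) with fewer than 3 samples excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !subtype %in% small
    expr <- expr[, keep, drop = FALSE]
    subtype <- subtype[keep]
  }
  lv <- sort(unique(subtype))
  if (length(lv) < 2L) .fail("need at least 2 subtypes with >= 3 samples")
  means <- vapply(lv, function(s)
    rowMeans(expr[, subtype == s, drop = FALSE]), numeric(nrow(expr)))
  if (nrow(expr) == 1L) means <- matrix(means, nrow = 1L,
                                        dimnames = list(rownames(expr), lv))
  res <- lapply(lv, function(s) {
    other <- setdiff(lv, s)
    mom <- rowMeans(means[, other, drop = FALSE]) # mean of the means
    fc <- compute_fold_change(means[, s], mom)
    focal <- subtype == s
    xf <- expr[, focal, drop = FALSE]
    xr <- expr[, !focal, drop = FALSE]
    p <- vapply(seq_len(nrow(expr)), function(i)
      as.numeric(test_differential(xf[i, ], xr[i, ], config$test_method)), 0)
    q <- adjust_bh(p)
    data.frame(gene = rownames(expr), feature = s,
               n_pos = sum(focal), n_neg = sum(!focal),
               fc = unname(fc), p = p, q = q,
               direction = .direction_call(fc, q, config),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$feature, out$q, out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
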
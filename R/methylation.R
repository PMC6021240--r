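#' Convert methylation beta-values to M-values
#'
#' `M = log2(beta / (1 - beta))`, strictly increasing on `(0, 1)`.
#'
#' @param beta Numeric vector or matrix of beta-values in `(0, 1)`.
#' @return M-values of the same shape.
#' @export
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8)) # -2, 0, 2
beta_to_m <- function(beta) {
  if (any(beta <= 0 | beta >= 1)) .fail("beta-values must lie in (0, 1)")
  log2(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m Numeric vector or matrix of M-values.
#' @export
m_to_beta <- function(m) 2^m / (1 + 2^m)

#' Filter methylation probes by quality and blacklists
#'
#' Removes sites whose detection p-value exceeds the threshold in any
#' sample (per-probe removal; set `mask_values = TRUE` to instead mask
#' individual failing values as NA and drop only all-NA sites), sites on
#' cross-reactive or SNP-containing blacklists, and sites on the sex
#' chromosomes. Removal counts per rule are recorded in the `"removed"`
#' attribute.
#'
#' @param beta Numeric matrix, sites x samples.
#' @param detection_p Optional matrix (same shape) or per-site vector of
#'   detection p-values.
#' @param cross_reactive,snp Character vectors of blacklisted site ids
#'   (unknown ids are ignored with a warning).
#' @param chrom Optional named character vector of per-site chromosomes
#'   (`chrX`/`chrY` sites are removed).
#' @param detection_threshold Detection p-value threshold.
#' @param mask_values Mask failing values instead of dropping the site.
#' @return The filtered beta matrix with attribute `"removed"`.
#' @export
filter_methylation_probes <- function(beta, detection_p = NULL,
                                      cross_reactive = character(),
                                      snp = character(), chrom = NULL,
                                      detection_threshold = 0.05,
                                      mask_values = FALSE) {
  sites <- rownames(beta)
  removed <- c(detection = 0L, cross_reactive = 0L, snp = 0L, sex_chrom = 0L)
  drop <- rep(FALSE, nrow(beta))
  if (!is.null(detection_p)) {
    fail <- if (is.matrix(detection_p)) detection_p > detection_threshold
            else matrix(detection_p > detection_threshold, nrow(beta),
                        ncol(beta))
    if (mask_values) {
      beta[fail] <- NA_real_
      bad <- rowSums(!is.na(beta)) == 0L
    } else {
      bad <- rowSums(fail) > 0L
    }
    removed["detection"] <- sum(bad & !drop)
    drop <- drop | bad
  }
  check_bl <- function(ids, rule) {
    unknown <- setdiff(ids, sites)
    if (length(unknown))
      warning(length(unknown), " unknown site id(s) in the ", rule,
              " blacklist ignored", call. = FALSE)
    bad <- sites %in% ids
    removed[rule] <<- sum(bad & !drop)
    drop <<- drop | bad
  }
  check_bl(cross_reactive, "cross_reactive")
  check_bl(snp, "snp")
  if (!is.null(chrom)) {
    bad <- sites %in% names(chrom)[chrom[sites] %in% c("chrX", "chrY", "X", "Y")]
    removed["sex_chrom"] <- sum(bad & !drop)
    drop <- drop | bad
  }
  out <- beta[!drop, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Call differentially methylated cytosines
#'
#' Per site: a two-sided t-test on M-values between the two groups, and
#' the absolute difference of the group median beta-values (delta-beta).
#' A site is called DM when `p < p_threshold` AND
#' `delta-beta > delta_beta`; the raw p-values are used by default (a BH
#' option is available).
#'
#' @param beta Numeric matrix, sites x samples, values in `(0, 1)`.
#' @param groups Factor/character with exactly two levels (one per
#'   sample), each with at least 3 samples.
#' @param p_threshold P-value threshold (default 0.05).
#' @param delta_beta Minimum absolute median beta difference (default
#'   0.2).
#' @param adjust Apply BH to the p-values before gating?
#' @return Data frame `site`, `p`, `delta_beta`, `call` (`DM`/`not-DM`).
#' @export
call_differential_methylation <- function(beta, groups, p_threshold = 0.05,
                                          delta_beta = 0.2, adjust = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) .fail("exactly two groups required")
  if (any(table(groups) < 3L)) .fail("each group needs at least 3 samples")
  g1 <- groups == levels(groups)[1L]
  m <- beta_to_m(beta)
  p <- vapply(seq_len(nrow(beta)), function(i) {
    a <- m[i, g1]; b <- m[i, !g1]
    if (stats::var(a) == 0 && stats::var(b) == 0) return(1)
    stats::t.test(a, b)$p.value
  }, 0)
  if (adjust) p <- adjust_bh(p)
  med1 <- apply(beta[, g1, drop = FALSE], 1L, stats::median)
  med2 <- apply(beta[, !g1, drop = FALSE], 1L, stats::median)
  db <- abs(med1 - med2)
  data.frame(site = rownames(beta), p = p, delta_beta = unname(db),
             call = ifelse(p < p_threshold & db > delta_beta, "DM", "not-DM"),
             stringsAsFactors = FALSE, row.names = NULL)
}
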
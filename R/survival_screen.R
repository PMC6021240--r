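#' Cox proportional-hazards fit for one gene
#'
#' Partial-likelihood fit (Efron ties) of relapse-free survival on a
#' single expression covariate, optionally adjusted for additional
#' covariates, with a Schoenfeld-residual proportional-hazards test on the
#' expression term.
#'
#' @param expr_gene Numeric expression vector (one value per sample).
#' @param time,event Right-censored follow-up (years) and event indicator.
#' @param covariates Optional data frame of adjustment covariates.
#' @return A list: `hr` (hazard ratio per unit of `expr_gene`), `loghr`,
#'   `p` (Wald), `ph_p` (proportional-hazards test on the expression
#'   term), `n`, `n_events`.
#' @export
fit_cox <- function(expr_gene, time, event, covariates = NULL) {
  keep <- !is.na(time) & !is.na(event) & !is.na(expr_gene)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  x <- expr_gene[keep]
  time <- time[keep]
  event <- event[keep]
  if (!length(x)) .fail("no usable samples for the Cox fit")
  if (sum(event) == 0) .fail("no events in the survival data")
  if (sum(event) < 10L)
    warning("fewer than 10 events; Cox estimates unstable", call. = FALSE)
  if (stats::var(x) == 0) .fail("degenerate covariate: expression is constant")
  df <- data.frame(time = time, event = event, x = x)
  if (!is.null(covariates)) df <- cbind(df, covariates[keep, , drop = FALSE])
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(setdiff(names(df), c("time", "event")),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  s <- summary(fit)
  ph_p <- tryCatch(survival::cox.zph(fit)$table["x", "p"],
                   error = function(e) NA_real_)
  list(hr = unname(s$coefficients["x", "exp(coef)"]),
       loghr = unname(s$coefficients["x", "coef"]),
       p = unname(s$coefficients["x", "Pr(>|z|)"]),
       ph_p = unname(ph_p), n = nrow(df), n_events = sum(event))
}

#' Per-lncRNA survival screen (univariate + multivariate Cox)
#'
#' Expression enters each model standardized per gene (z-score), so one
#' hazard-ratio threshold is comparable across genes. Per gene: a
#' univariate fit and a multivariate fit adjusted for KRAS status, MMR
#' status and disease stage (ordinal numeric). A direction is called only
#' when BOTH analyses satisfy the gates (`hr >= hr_up` or `hr <= hr_down`,
#' `p <= p_surv`) and the proportional-hazards check on the univariate
#' expression term is not rejected at `ph_alpha`. `HR < 1` (protective) is
#' labeled `RFS-positive`, `HR > 1` `RFS-negative`. The full follow-up is
#' used, with no time-window truncation.
#'
#' @param expr Numeric matrix, genes x samples (lncRNA rows).
#' @param clinical Clinical table with `rfs_time`, `rfs_event`, `kras`,
#'   `mmr`, `stage`; sample order must match `expr` columns.
#' @param config A [lnchet_config()].
#' @return Data frame `gene`, `hr_uni`, `p_uni`, `hr_multi`, `p_multi`,
#'   `ph_p`, `ph_fail`, `direction`.
#' @export
screen_survival <- function(expr, clinical, config = lnchet_config()) {
  need <- c("rfs_time", "rfs_event", "kras", "mmr", "stage")
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols))
    .fail("clinical table lacks column(s): ",
          paste(missing_cols, collapse = ", "))
  if (nrow(clinical) != ncol(expr))
    .fail("clinical table and expression matrix disagree on sample count")
  covs <- data.frame(kras = factor(clinical$kras),
                     mmr = factor(clinical$mmr),
                     stage = as.numeric(clinical$stage))
  time <- clinical$rfs_time
  event <- clinical$rfs_event
  rows <- lapply(rownames(expr), function(g) {
    x <- as.numeric(scale(expr[g, ]))
    uni <- fit_cox(x, time, event)
    multi <- fit_cox(x, time, event, covariates = covs)
    data.frame(gene = g, hr_uni = uni$hr, p_uni = uni$p,
               hr_multi = multi$hr, p_multi = multi$p,
               ph_p = uni$ph_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ph_fail <- !is.na(out$ph_p) & out$ph_p < config$ph_alpha
  both_up <- out$hr_uni >= config$hr_up & out$hr_multi >= config$hr_up
  both_dn <- out$hr_uni <= config$hr_down & out$hr_multi <= config$hr_down
  both_p <- out$p_uni <= config$p_surv & out$p_multi <= config$p_surv
  out$direction <- ifelse(out$ph_fail, "none",
                          ifelse(both_p & both_dn, "RFS-positive",
                                 ifelse(both_p & both_up, "RFS-negative",
                                        "none")))
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier table for a median-split of one gene's expression
#'
#' Convenience export mirroring per-gene survival displays: samples are
#' split at the median expression and a product-limit curve is computed
#' per half.
#'
#' @param expr_gene Numeric expression vector.
#' @param time,event Follow-up and event indicator.
#' @return Data frame `group` (`high`/`low`), `time`, `n_risk`, `surv`.
#' @export
km_median_split <- function(expr_gene, time, event) {
  keep <- !is.na(time) & !is.na(event) & !is.na(expr_gene)
  grp <- factor(ifelse(expr_gene[keep] > stats::median(expr_gene[keep]),
                       "high", "low"))
  fit <- survival::survfit(survival::Surv(time[keep], event[keep]) ~ grp)
  data.frame(group = rep(sub("^grp=", "", names(fit$strata)),
                         fit$strata),
             time = fit$time, n_risk = fit$n.risk, surv = fit$surv,
             stringsAsFactors = FALSE)
}
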
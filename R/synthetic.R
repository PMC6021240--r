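#' Parameters of a synthetic colorectal-tumor-like cohort
#'
#' Describes a cohort generated on the log2 scale with homoscedastic
#' Gaussian noise, categorical tumor features drawn at configurable
#' prevalences, six molecular subtypes, right-censored relapse-free
#' survival, and three kinds of planted ground truth:
#'
#' * `planted_shift` — per-gene log2 mean shifts between feature-positive
#'   and feature-negative samples (planted fold changes);
#' * `planted_cor` — lncRNAs wired to a gene set's latent factor so their
#'   Pearson correlation with every member mRNA is `weight * rho` in
#'   expectation (planted guilt-by-association signal);
#' * `planted_loghr` — lncRNAs loading on a latent prognostic factor that
#'   drives the proportional hazard, so each carries the stated marginal
#'   log hazard ratio per SD of expression.
#'
#' The reference dimensions mirror a 566-sample cohort profiled for 4898
#' lncRNAs and 14,851 mRNAs; tests and examples scale them down.
#'
#' @param n_samples,n_lncrna,n_mrna Cohort dimensions.
#' @param subtype_props Named probabilities for subtypes C1--C6 (sum 1).
#' @param prevalence Named list of feature-positive prevalences for
#'   `location` (distal), `mmr` (dMMR), `cimp` (pos), `cin` (high), and
#'   `braf`/`kras`/`tp53` (mut).
#' @param noise_sd Residual SD of log2 expression (homoscedastic).
#' @param baseline_range Range of per-gene baseline log2 means.
#' @param gene_sets Optional named list of mRNA-id sets (see
#'   [generate_gene_sets()]); required when `planted_cor` is non-empty.
#' @param planted_shift Data frame `gene`, `feature`, `shift` (log2).
#'   `feature` is a clinical feature name or a subtype `C1`..`C6`.
#' @param planted_cor Data frame `gene`, `set`, `rho`, `weight` (+1/-1).
#' @param planted_loghr Data frame `gene`, `loghr` (per SD of expression).
#' @param survival_loading Loading of planted survival genes on their
#'   latent prognostic factor (close to 1 keeps the marginal per-gene
#'   hazard near the planted value).
#' @param within_set_cor Pairwise correlation among members of non-wired
#'   gene sets (0 disables the shared factor).
#' @param base_hazard Baseline relapse hazard (events per year).
#' @param censor_max Administrative censoring horizon (years, uniform).
#' @param stage_props Probabilities of ordinal stages 1--4.
#' @return A validated list of class `"cohort_params"`.
#' @export
cohort_params <- function(n_samples = 566L, n_lncrna = 4898L, n_mrna = 14851L,
                          subtype_props = NULL,
                          prevalence = NULL,
                          noise_sd = 0.5,
                          baseline_range = c(4, 10),
                          gene_sets = NULL,
                          planted_shift = NULL,
                          planted_cor = NULL,
                          planted_loghr = NULL,
                          survival_loading = 0.95,
                          within_set_cor = 0,
                          base_hazard = 0.18,
                          censor_max = 10,
                          stage_props = c(0.2, 0.35, 0.35, 0.1)) {
  if (is.null(subtype_props))
    subtype_props <- stats::setNames(rep(1 / 6, 6), paste0("C", 1:6))
  if (is.null(prevalence))
    prevalence <- list(location = 0.55, mmr = 0.16, cimp = 0.21, cin = 0.55,
                       braf = 0.10, kras = 0.40, tp53 = 0.50)
  p <- list(n_samples = as.integer(n_samples),
            n_lncrna = as.integer(n_lncrna), n_mrna = as.integer(n_mrna),
            subtype_props = subtype_props, prevalence = prevalence,
            noise_sd = noise_sd, baseline_range = baseline_range,
            gene_sets = gene_sets,
            planted_shift = planted_shift, planted_cor = planted_cor,
            planted_loghr = planted_loghr,
            survival_loading = survival_loading,
            within_set_cor = within_set_cor,
            base_hazard = base_hazard, censor_max = censor_max,
            stage_props = stage_props)
  if (p$n_samples < 2L || p$n_lncrna < 1L || p$n_mrna < 1L)
    .fail("cohort counts must be positive (and n_samples >= 2)")
  if (abs(sum(subtype_props) - 1) > 1e-8)
    .fail("subtype proportions must sum to 1")
  if (abs(sum(stage_props) - 1) > 1e-8)
    .fail("stage proportions must sum to 1")
  if (noise_sd <= 0) .fail("noise_sd must be positive")
  .check_frac(survival_loading, "survival_loading")
  .check_frac(within_set_cor, "within_set_cor")
  class(p) <- "cohort_params"
  p
}

.lnc_ids <- function(n) sprintf("lnc%05d", seq_len(n))
.mrna_ids <- function(n) sprintf("mrna%05d", seq_len(n))

.binary_levels <- list(location = c("distal", "proximal"),
                       mmr = c("dMMR", "pMMR"),
                       cimp = c("pos", "neg"),
                       cin = c("high", "low"),
                       braf = c("mut", "wt"),
                       kras = c("mut", "wt"),
                       tp53 = c("mut", "wt"))

#' Generate a synthetic cohort with planted ground truth
#'
#' Expression is `baseline + planted group shifts + noise` on the log2
#' scale; wired lncRNAs and gene-set members are signed linear mixtures of
#' a per-set latent factor so the target Pearson correlation holds in
#' expectation; survival times are exponential with hazard proportional to
#' `exp(loghr x latent prognostic factor)` under uniform administrative
#' censoring. All randomness is governed by `seed`.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed.
#' @return A list with elements `expr` ([expression_matrix()]), `clinical`
#'   (data frame, see [read_clinical_table()]), and `truth` (data frame of
#'   planted effects: `type`, `gene`, `target`, `value`, `weight`).
#' @export
generate_cohort <- function(params, seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(derive_seed(seed, "cohort"))
  n <- params$n_samples
  lnc <- .lnc_ids(params$n_lncrna)
  mrna <- .mrna_ids(params$n_mrna)
  genes <- c(lnc, mrna)
  samples <- sprintf("s%04d", seq_len(n))

  ## ---- clinical labels -------------------------------------------------
  clinical <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (f in names(.binary_levels)) {
    lv <- .binary_levels[[f]]
    pos <- params$prevalence[[f]]
    clinical[[f]] <- ifelse(stats::runif(n) < pos, lv[1L], lv[2L])
  }
  clinical$subtype <- sample(names(params$subtype_props), n, replace = TRUE,
                             prob = params$subtype_props)
  clinical$stage <- sample(seq_along(params$stage_props), n, replace = TRUE,
                           prob = params$stage_props)

  ## ---- planted-effect bookkeeping -------------------------------------
  truth <- data.frame(type = character(), gene = character(),
                      target = character(), value = numeric(),
                      weight = numeric(), stringsAsFactors = FALSE)
  .check_genes <- function(ids, what) {
    bad <- setdiff(ids, genes)
    if (length(bad))
      .fail(what, " names gene(s) absent from the cohort: ",
            paste(utils::head(bad, 5L), collapse = ", "))
  }
  ps <- params$planted_shift
  pc <- params$planted_cor
  ph <- params$planted_loghr
  if (!is.null(ps)) .check_genes(ps$gene, "planted_shift")
  if (!is.null(pc)) .check_genes(pc$gene, "planted_cor")
  if (!is.null(ph)) .check_genes(ph$gene, "planted_loghr")
  if (!is.null(pc) && !is.null(ph) && length(intersect(pc$gene, ph$gene)))
    .fail("a gene cannot carry both a correlation and a survival plant")
  if (!is.null(pc)) {
    if (is.null(params$gene_sets))
      .fail("planted_cor requires 'gene_sets' in the parameters")
    bad <- setdiff(pc$set, names(params$gene_sets))
    if (length(bad)) .fail("planted_cor names unknown set(s): ",
                           paste(bad, collapse = ", "))
    if (!all(pc$weight %in% c(-1, 1)))
      .fail("planted_cor weights must be -1 or +1")
    if (any(pc$rho <= 0 | pc$rho >= 1))
      .fail("planted_cor rho must lie in (0, 1)")
    if (anyDuplicated(pc$gene))
      .fail("each lncRNA may be wired to at most one gene set")
  }

  ## ---- latent structure ------------------------------------------------
  ## standardized (unit-variance) latent component per gene, then scaled by
  ## noise_sd and shifted by baseline + planted group effects
  z <- matrix(stats::rnorm(length(genes) * n), length(genes), n,
              dimnames = list(genes, samples))

  if (!is.null(params$gene_sets)) {
    wired_sets <- if (is.null(pc)) character() else unique(pc$set)
    for (s in names(params$gene_sets)) {
      members <- intersect(params$gene_sets[[s]], genes)
      rho_set <- if (s %in% wired_sets) max(pc$rho[pc$set == s]) else
        params$within_set_cor
      if (rho_set <= 0 || !length(members)) next
      f <- stats::rnorm(n)
      a <- sqrt(rho_set)
      z[members, ] <- a * matrix(f, length(members), n, byrow = TRUE) +
        sqrt(1 - a^2) * z[members, , drop = FALSE]
      if (s %in% wired_sets) {
        rows <- pc[pc$set == s, , drop = FALSE]
        b <- rows$weight * rows$rho / a   # cor(lnc, member) = b * a = w * rho
        if (any(abs(b) > 1)) .fail("planted rho too large for set '", s, "'")
        z[rows$gene, ] <- b %o% f +
          sqrt(1 - b^2) * z[rows$gene, , drop = FALSE]
        truth <- rbind(truth, data.frame(type = "cor", gene = rows$gene,
                                         target = s, value = rows$rho,
                                         weight = rows$weight))
      }
    }
  } else if (!is.null(pc)) {
    .fail("planted_cor requires 'gene_sets' in the parameters")
  }

  ## latent prognostic factor(s): one per distinct |log-HR| magnitude;
  ## planted genes load on their factor at survival_loading so each keeps
  ## (approximately) the stated marginal per-SD log hazard ratio
  eta <- rep(0, n)
  if (!is.null(ph)) {
    lam <- params$survival_loading
    for (m in unique(abs(ph$loghr))) {
      rows <- ph[abs(ph$loghr) == m, , drop = FALSE]
      f <- stats::rnorm(n)
      sgn <- sign(rows$loghr)
      z[rows$gene, ] <- sgn * (lam * matrix(f, nrow(rows), n, byrow = TRUE) +
                                 sqrt(1 - lam^2) * z[rows$gene, , drop = FALSE])
      eta <- eta + m * f
      truth <- rbind(truth, data.frame(type = "loghr", gene = rows$gene,
                                       target = "rfs", value = rows$loghr,
                                       weight = NA_real_))
    }
  }

  ## ---- assemble expression --------------------------------------------
  baseline <- stats::runif(length(genes), params$baseline_range[1L],
                           params$baseline_range[2L])
  values <- baseline + params$noise_sd * z
  if (!is.null(ps)) {
    for (i in seq_len(nrow(ps))) {
      f <- ps$feature[i]
      pos <- if (f %in% paste0("C", 1:6)) clinical$subtype == f
             else clinical[[f]] == .binary_levels[[f]][1L]
      values[ps$gene[i], pos] <- values[ps$gene[i], pos] + ps$shift[i]
      truth <- rbind(truth, data.frame(type = "shift", gene = ps$gene[i],
                                       target = f, value = ps$shift[i],
                                       weight = NA_real_))
    }
  }

  ## ---- survival --------------------------------------------------------
  t_event <- stats::rexp(n) / (params$base_hazard * exp(eta))
  t_cens <- stats::runif(n, 0, params$censor_max)
  clinical$rfs_time <- pmin(t_event, t_cens)
  clinical$rfs_event <- as.integer(t_event <= t_cens)
  clinical <- clinical[, .clinical_columns]

  expr <- expression_matrix(values, c(rep("lncRNA", length(lnc)),
                                      rep("mRNA", length(mrna))))
  list(expr = expr, clinical = validate_clinical(clinical), truth = truth)
}

#' Generate synthetic gene sets over the mRNA universe
#'
#' Sets are disjoint by default; a positive `overlap` makes each
#' even-numbered set share `round(overlap * min(sizes))` genes with the
#' preceding set (overlap coefficient `|A n B| / min(|A|, |B|)`), for
#' exercising redundancy clustering.
#'
#' @param n_sets Number of sets.
#' @param set_size Integer size (recycled to `n_sets`).
#' @param n_mrna Size of the mRNA universe the members are drawn from.
#' @param overlap Overlap coefficient in `[0, 1)` between paired sets.
#' @param seed Integer seed.
#' @return Named list of mRNA-id vectors (`set01`, `set02`, ...).
#' @export
generate_gene_sets <- function(n_sets = 20L, set_size = 30L, n_mrna = 2000L,
                               overlap = 0, seed = 1L) {
  if (any(set_size < 1L)) .fail("set sizes must be >= 1")
  .check_frac(overlap, "overlap", 0, 1)
  sizes <- rep_len(as.integer(set_size), n_sets)
  if (sum(sizes) > n_mrna)
    .fail("total requested genes (", sum(sizes),
          ") exceed the mRNA universe (", n_mrna, ")")
  set.seed(derive_seed(seed, "gene-sets"))
  pool <- sample(.mrna_ids(n_mrna))
  sets <- vector("list", n_sets)
  used <- 0L
  for (i in seq_len(n_sets)) {
    take <- pool[(used + 1L):(used + sizes[i])]
    used <- used + sizes[i]
    if (overlap > 0 && i %% 2L == 0L) {
      k <- round(overlap * min(sizes[i - 1L], sizes[i]))
      if (k > 0L) take[seq_len(k)] <- sets[[i - 1L]][seq_len(k)]
    }
    sets[[i]] <- sort(take)
  }
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  attr(sets, "descriptions") <- stats::setNames(
    rep("synthetic gene set", n_sets), names(sets))
  sets
}

#' Generate a synthetic methylation matrix with planted delta-beta shifts
#'
#' Beta-values are drawn from Beta distributions with a common precision;
#' planted sites shift the second group's mean by `delta_beta`, giving a
#' group median difference of approximately the target.
#'
#' @param n_sites Number of CpG sites.
#' @param n_per_group Two sample counts `c(group1, group2)`.
#' @param planted Optional data frame with columns `site` (index into the
#'   generated sites), `delta_beta`, and optionally `base` (group-1 mean).
#' @param base_range Range the unplanted baseline means are drawn from.
#' @param precision Beta-distribution precision (a + b).
#' @param seed Integer seed.
#' @return List with `beta` (sites x samples matrix), `groups` (factor
#'   `g1`/`g2` per sample) and `truth` (data frame `site`, `base`,
#'   `delta_beta`).
#' @export
generate_methylation <- function(n_sites = 200L, n_per_group = c(50L, 50L),
                                 planted = NULL, base_range = c(0.2, 0.6),
                                 precision = 30, seed = 1L) {
  if (n_sites < 1L || any(n_per_group < 1L))
    .fail("n_sites and both group sizes must be positive")
  set.seed(derive_seed(seed, "methylation"))
  sites <- sprintf("cg%05d", seq_len(n_sites))
  groups <- factor(rep(c("g1", "g2"), n_per_group))
  mu <- stats::runif(n_sites, base_range[1L], base_range[2L])
  delta <- rep(0, n_sites)
  if (!is.null(planted)) {
    if (any(planted$site < 1L | planted$site > n_sites))
      .fail("planted site index out of range")
    if (!is.null(planted$base)) mu[planted$site] <- planted$base
    delta[planted$site] <- planted$delta_beta
  }
  lo <- pmin(mu, mu + delta)
  hi <- pmax(mu, mu + delta)
  if (any(lo <= 0.005 | hi >= 0.995))
    .fail("planted delta-beta pushes beta-values outside (0, 1)")
  ntot <- sum(n_per_group)
  beta <- matrix(NA_real_, n_sites, ntot,
                 dimnames = list(sites, sprintf("m%03d", seq_len(ntot))))
  g2 <- groups == "g2"
  for (i in seq_len(n_sites)) {
    m <- ifelse(g2, mu[i] + delta[i], mu[i])
    beta[i, ] <- stats::rbeta(ntot, m * precision, (1 - m) * precision)
  }
  ## guard the open-interval support against floating underflow
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  truth <- data.frame(site = sites, base = mu, delta_beta = delta,
                      stringsAsFactors = FALSE)
  list(beta = beta, groups = groups, truth = truth)
}
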
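#' Split samples into two halves with matched subtype distribution
#'
#' Within each subtype stratum (missing labels form their own stratum),
#' samples are shuffled by the seed and dealt alternately to the two
#' halves, starting each stratum in the currently smaller half, so
#' per-stratum counts differ by at most one and so do the totals. A
#' 566-sample cohort yields halves of 283 and 283.
#'
#' @param samples Character vector of sample ids.
#' @param subtype Subtype label per sample (NA allowed).
#' @param seed Integer seed.
#' @return List with `half1` and `half2` (disjoint id vectors whose union
#'   is `samples`).
#' @export
stratified_split <- function(samples, subtype, seed = 1L) {
  if (length(samples) < 2L) .fail("need at least 2 samples to split")
  if (length(subtype) != length(samples))
    .fail("'subtype' must have one label per sample")
  set.seed(derive_seed(seed, "split"))
  strata <- ifelse(is.na(subtype), "<NA>", as.character(subtype))
  half1 <- character(); half2 <- character()
  for (s in sort(unique(strata))) {
    members <- sample(samples[strata == s])
    first_to_1 <- length(half1) <= length(half2)
    odd <- seq_along(members) %% 2L == 1L
    if (first_to_1) {
      half1 <- c(half1, members[odd]); half2 <- c(half2, members[!odd])
    } else {
      half2 <- c(half2, members[odd]); half1 <- c(half1, members[!odd])
    }
  }
  list(half1 = half1, half2 = half2)
}

#' Rank mRNAs by Pearson correlation with one lncRNA
#'
#' @param lnc_expr_row Numeric expression vector of the lncRNA across
#'   samples (length >= 3, non-constant).
#' @param mrna_expr Numeric matrix, mRNAs x samples (same sample order).
#' @return Named numeric vector of Pearson r, sorted descending with ties
#'   broken by gene id; attribute `"lncRNA"` carries the lncRNA id when
#'   `lnc_expr_row` is named in the input matrix sense.
#' @export
correlation_rank <- function(lnc_expr_row, mrna_expr) {
  if (length(lnc_expr_row) < 3L) .fail("need at least 3 samples")
  if (stats::sd(lnc_expr_row) == 0) .fail("constant lncRNA expression row")
  r <- suppressWarnings(
    as.vector(stats::cor(lnc_expr_row, t(mrna_expr))))
  names(r) <- rownames(mrna_expr)
  if (anyNA(r)) {
    warning(sum(is.na(r)), " constant mRNA row(s); correlation set to 0",
            call. = FALSE)
    r[is.na(r)] <- 0
  }
  r[order(-r, names(r))]
}

## fast signed-maximum-deviation ES given sorted hit positions.
## idx: increasing positions of the set members in the ranked list;
## w: |metric|^exponent at those positions; N: universe size.
.es_at_hits <- function(idx, w, N) {
  k <- length(idx)
  S <- sum(w)
  cw <- if (S > 0) cumsum(w) / S else cumsum(rep(1 / k, k))
  dec <- (idx - seq_len(k)) / (N - k)
  top <- cw - dec                  # running sum just after each hit
  bot <- top - cw + c(0, cw[-k])   # running sum just before each hit
  es_pos <- max(top)
  es_neg <- min(bot)
  ## tie between the two extrema (up to summation rounding) goes positive
  if (es_pos + es_neg >= -1e-12) es_pos else es_neg
}

#' Running-sum enrichment score of a gene set in a ranked list
#'
#' Walks the ranked list from top to bottom; at a set member the running
#' sum increases by `|metric|^exponent / sum over members`, at a
#' non-member it decreases by `1 / (N - N_hits)`. The enrichment score is
#' the signed maximum deviation of the running sum from zero (ties
#' resolved toward the positive extremum).
#'
#' @param ranked Named numeric vector of ranking metrics (any order;
#'   sorted internally, descending, ties broken by gene id).
#' @param gene_set Character vector of member gene ids.
#' @param exponent Weighting exponent on the metric (1 = weighted,
#'   0 = classic Kolmogorov-Smirnov-like).
#' @return List: `es`, `running` (the running sum at every position of
#'   the sorted list), `hits` (member positions in the sorted list).
#' @export
enrichment_score <- function(ranked, gene_set, exponent = 1) {
  ord <- order(-ranked, names(ranked))
  metric <- ranked[ord]
  idx <- which(names(metric) %in% gene_set)
  N <- length(metric)
  if (!length(idx)) .fail("set not represented in the ranked universe")
  if (length(idx) == N)
    .fail("gene set equals the ranked universe; enrichment undefined")
  w <- abs(metric[idx])^exponent
  S <- sum(w)
  steps <- rep(-1 / (N - length(idx)), N)
  steps[idx] <- if (S > 0) w / S else 1 / length(idx)
  running <- cumsum(steps)
  es <- .es_at_hits(idx, unname(w), N)
  list(es = es, running = unname(running), hits = idx)
}

#' Pre-ranked GSEA with gene-set-permutation FWER control
#'
#' For each gene set within the size window (after intersecting the
#' ranked universe): the observed enrichment score; a null distribution
#' of scores from `nperm` random same-size gene sets drawn from the
#' ranked universe (drawn independently per set); a normalized score
#' `NES = ES / mean(|null ES| of matching sign)`; and a family-wise error
#' rate p-value, the fraction of permutations whose maximum `|NES|`
#' across all tested sets reaches the observed `|NES|`.
#'
#' @param ranked Named numeric metric vector (see [enrichment_score()]).
#' @param gene_sets Named list of gene-id vectors.
#' @param nperm Number of gene-set permutations.
#' @param min_size,max_size Size window applied after intersection.
#' @param exponent Weighting exponent.
#' @param seed Integer seed.
#' @return Data frame `set`, `size`, `es`, `nes`, `fwer`, one row per
#'   tested set; excluded sets are reported in the
#'   `"excluded"` attribute.
#' @export
gsea_preranked <- function(ranked, gene_sets, nperm = 1000L, min_size = 15L,
                           max_size = 500L, exponent = 1, seed = 1L) {
  if (nperm < 1L) .fail("nperm must be >= 1")
  ord <- order(-ranked, names(ranked))
  metric <- ranked[ord]
  N <- length(metric)
  absw <- abs(unname(metric))^exponent
  pos <- stats::setNames(seq_len(N), names(metric))

  sizes <- vapply(gene_sets, function(s) sum(s %in% names(metric)), 0L)
  keep <- sizes >= min_size & sizes <= max_size
  excluded <- names(gene_sets)[!keep]
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]
  if (!length(gene_sets))
    .fail("no gene set within the size window [", min_size, ", ",
          max_size, "]")

  es_obs <- vapply(gene_sets, function(s) {
    idx <- sort.int(unname(pos[intersect(s, names(metric))]))
    .es_at_hits(idx, absw[idx], N)
  }, 0)

  set.seed(derive_seed(seed, "gsea-null"))
  nset <- length(gene_sets)
  null_es <- matrix(NA_real_, nperm, nset,
                    dimnames = list(NULL, names(gene_sets)))
  for (j in seq_len(nset)) {
    k <- sizes[j]
    col <- numeric(nperm)
    for (b in seq_len(nperm)) {
      idx <- sort.int(sample.int(N, k))
      col[b] <- .es_at_hits(idx, absw[idx], N)
    }
    null_es[, j] <- col
  }

  norm_denom <- function(es, nulls) {
    same <- if (es >= 0) nulls[nulls > 0] else nulls[nulls < 0]
    if (!length(same)) {
      warning("no same-sign null enrichment scores; NES inflated",
              call. = FALSE)
      return(1e-6)
    }
    mean(abs(same))
  }
  denom_pos <- vapply(seq_len(nset), function(j) {
    x <- null_es[null_es[, j] > 0, j]
    if (length(x)) mean(x) else 1e-6
  }, 0)
  denom_neg <- vapply(seq_len(nset), function(j) {
    x <- null_es[null_es[, j] < 0, j]
    if (length(x)) mean(abs(x)) else 1e-6
  }, 0)
  nes_obs <- vapply(seq_len(nset), function(j)
    es_obs[j] / norm_denom(es_obs[j], null_es[, j]), 0)
  null_nes <- sweep(pmax(null_es, 0), 2L, denom_pos, "/") +
    sweep(pmin(null_es, 0), 2L, denom_neg, "/")
  max_stat <- apply(abs(null_nes), 1L, max)
  fwer <- vapply(abs(nes_obs), function(s) mean(max_stat >= s), 0)

  out <- data.frame(set = names(gene_sets), size = as.integer(sizes),
                    es = unname(es_obs), nes = nes_obs, fwer = fwer,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Split-half guilt-by-association enrichment of lncRNAs
#'
#' Splits the cohort into two subtype-matched halves, computes in each
#' half the Pearson correlation of every selected lncRNA with every mRNA,
#' ranks the mRNAs, and runs pre-ranked GSEA per lncRNA. Seeds for the
#' split and for every (half, lncRNA) GSEA are derived from the
#' configuration seed.
#'
#' @param expr An [expression_matrix()] containing lncRNA and mRNA rows.
#' @param subtype Subtype label per sample (for the matched split).
#' @param gene_sets Named list of mRNA-id sets.
#' @param lnc_ids lncRNAs to analyze (default: all lncRNA rows).
#' @param config A [lnchet_config()].
#' @return List: `half1`, `half2` (data frames `lncRNA`, `set`, `size`,
#'   `es`, `nes`, `fwer`, `half`), and `split`.
#' @export
gba_enrichment <- function(expr, subtype, gene_sets, lnc_ids = NULL,
                           config = lnchet_config()) {
  stopifnot(inherits(expr, "expr_matrix"))
  lnc <- expr_rows(expr, "lncRNA")
  mrna <- expr_rows(expr, "mRNA")
  if (!is.null(lnc_ids)) {
    bad <- setdiff(lnc_ids, rownames(lnc))
    if (length(bad)) .fail("unknown lncRNA id(s): ",
                           paste(bad, collapse = ", "))
    lnc <- lnc[lnc_ids, , drop = FALSE]
  }
  split <- stratified_split(colnames(expr$values), subtype, config$seed)
  halves <- list(half1 = split$half1, half2 = split$half2)
  res <- lapply(names(halves), function(h) {
    ids <- halves[[h]]
    records <- lapply(rownames(lnc), function(l) {
      ranked <- correlation_rank(lnc[l, ids], mrna[, ids, drop = FALSE])
      rec <- gsea_preranked(ranked, gene_sets, nperm = config$gsea_nperm,
                            min_size = config$gsea_min,
                            max_size = config$gsea_max,
                            seed = derive_seed(config$seed,
                                               paste0("gsea:", h, ":", l)))
      cbind(lncRNA = l, rec, half = if (h == "half1") 1L else 2L,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, records)
  })
  list(half1 = res[[1L]], half2 = res[[2L]], split = split)
}

#' Consensus enrichment profile across the two data halves
#'
#' Keeps the (lncRNA, gene set) pairs whose FWER p-value passes the gate
#' in BOTH halves and scores them by the mean of the two enrichment
#' scores. Pairs significant in both halves but with opposite ES signs
#' are dropped (averaging opposite signs would fabricate a near-zero
#' score) and reported via a message.
#'
#' @param records_half1,records_half2 Per-half outputs of
#'   [gba_enrichment()] (must cover identical gene-set collections).
#' @param fwer FWER threshold applied in each half.
#' @return Data frame `lncRNA`, `set`, `es1`, `es2`, `es_mean` of class
#'   `"consensus_profile"`; attribute `"lncRNAs"` lists every analyzed
#'   lncRNA (the permutation-null pool), `"sets"` every tested set.
#' @export
consensus_enrichment <- function(records_half1, records_half2, fwer = 0.05) {
  if (!setequal(unique(records_half1$set), unique(records_half2$set)) ||
      !setequal(unique(records_half1$lncRNA), unique(records_half2$lncRNA)))
    .fail("the two halves cover different gene-set collections or lncRNAs")
  m <- merge(records_half1, records_half2, by = c("lncRNA", "set"),
             suffixes = c("1", "2"))
  sig <- m$fwer1 < fwer & m$fwer2 < fwer
  conflict <- sig & m$es1 * m$es2 < 0
  if (any(conflict))
    message(sum(conflict),
            " pair(s) significant in both halves with opposite ES signs",
            " dropped")
  keep <- m[sig & !conflict, , drop = FALSE]
  out <- data.frame(lncRNA = keep$lncRNA, set = keep$set,
                    es1 = keep$es1, es2 = keep$es2,
                    es_mean = (keep$es1 + keep$es2) / 2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncRNA, out$set), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("consensus_profile", "data.frame"),
            lncRNAs = sort(unique(records_half1$lncRNA)),
            sets = sort(unique(records_half1$set)))
}

#' Cluster and merge redundant gene sets by overlap distance
#'
#' Similarity between two sets is the overlap coefficient
#' `|A n B| / min(|A|, |B|)`; the distance `1 - similarity` is clustered
#' with complete linkage and the tree is cut at `cut`. Sets within one
#' cluster are merged into their union, named by concatenating the member
#' set names. Input order does not matter (sets are sorted by name
#' first).
#'
#' @param gene_sets Named list of at least two nonempty sets.
#' @param cut Tree-cut height on the overlap distance.
#' @return List: `sets` (merged collection), `membership` (named integer
#'   cluster index per original set).
#' @export
cluster_redundant_gene_sets <- function(gene_sets, cut = 0.5) {
  if (length(gene_sets) < 2L) .fail("need at least 2 gene sets")
  if (any(lengths(gene_sets) == 0L)) .fail("empty gene set")
  gene_sets <- gene_sets[order(names(gene_sets))]
  n <- length(gene_sets)
  d <- matrix(0, n, n, dimnames = list(names(gene_sets), names(gene_sets)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- length(intersect(gene_sets[[i]], gene_sets[[j]])) /
      min(length(gene_sets[[i]]), length(gene_sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - s
  }
  tree <- stats::hclust(stats::as.dist(d), method = "complete")
  membership <- stats::cutree(tree, h = cut)
  merged <- lapply(split(names(membership), membership), function(nms) {
    sort(unique(unlist(gene_sets[nms], use.names = FALSE)))
  })
  names(merged) <- vapply(split(names(membership), membership),
                          paste, "", collapse = "+")
  list(sets = merged, membership = membership)
}
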
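# Independent reference implementations used to verify the package's own
# statistics. They deliberately take the brute-force route: the full
# running-sum walk for the enrichment score, and direct evaluation of the
# step-up formula for BH.

# full-walk enrichment score: signed maximum deviation of the running sum,
# ties between the positive and negative extremum resolved positive
oracle_es <- function(metric, gene_set, exponent) {
  ord <- order(-metric, names(metric))
  m <- metric[ord]
  hit <- names(m) %in% gene_set
  stopifnot(any(hit), !all(hit))
  w <- abs(m)^exponent
  w[!hit] <- 0
  s <- sum(w)
  inc <- if (s > 0) w / s else ifelse(hit, 1 / sum(hit), 0)
  dec <- ifelse(hit, 0, 1 / (length(m) - sum(hit)))
  running <- cumsum(inc - dec)
  es_pos <- max(running)
  es_neg <- min(running)
  es <- if (es_pos + es_neg >= -1e-12) es_pos else es_neg
  list(es = es, running = unname(running))
}

# direct step-up evaluation: q_i = min over {j : p_j >= p_i} of
# m * p_j / rank_j, clipped at 1
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(m * p[js] / r[js]))
  }, 0)
}

# small ready-made cohort for screen tests
small_cohort <- function(n_samples = 100, n_lnc = 40, n_mrna = 60,
                         seed = 1, ...) {
  generate_cohort(cohort_params(n_samples = n_samples, n_lncrna = n_lnc,
                                n_mrna = n_mrna, ...), seed = seed)
}
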
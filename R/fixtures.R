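#' Generate probe-reannotation fixtures with a rule-implied expected table
#'
#' Builds alignment records, transcript models, a shared-bases table and a
#' probe-level expression matrix that exercise every reannotation rule:
#' coverage filtering, biotype discordance, multi-target exclusion with
#' the duplicate-group exception, chained (transitive) duplicate groups,
#' largest-locus isoform merging, and max-variance probe selection with a
#' lexicographic tie. The expected annotation table is assembled directly
#' from the construction plan (each rule applied by hand), independently
#' of the [reannotate_affy()] chain it is meant to verify.
#'
#' @param n_clean Number of plain single-transcript genes with two
#'   concordant full-coverage probes each.
#' @param scenarios Include the rule-specific scenario blocks (duplicate
#'   pair, duplicate chain, discordant/low-coverage/multi-target probes,
#'   isoform merge, variance tie, probe-less gene)?
#' @param n_samples Columns of the probe-level expression matrix.
#' @param seed Integer seed.
#' @return A list with `records`, `transcripts`, `shared`, `expr`
#'   (probe-level matrix) and `expected` (the annotation table
#'   [reannotate_affy()] must reproduce).
#' @export
generate_probe_fixtures <- function(n_clean = 5L, scenarios = TRUE,
                                    n_samples = 20L, seed = 1L) {
  set.seed(derive_seed(seed, "probe-fixtures"))
  rec <- list(); tr <- list(); sh <- list()
  probe_sd <- numeric()

  add_tr <- function(id, locus, start, end, strand = "+") {
    tr[[length(tr) + 1L]] <<- data.frame(
      transcript = id, locus = locus, chrom = "chr1", strand = strand,
      start = start, end = end, length = end - start,
      stringsAsFactors = FALSE)
  }
  add_rec <- function(probe, len, transcript, aligned,
                      db = "lncRNA", ref = "lncRNA") {
    rec[[length(rec) + 1L]] <<- data.frame(
      probe = probe, probe_length = len, transcript = transcript,
      aligned = aligned, biotype_db = db, biotype_ref = ref,
      stringsAsFactors = FALSE)
    if (!probe %in% names(probe_sd)) probe_sd[probe] <<- stats::runif(1, 0.2, 0.4)
  }
  add_sh <- function(a, b, bases) {
    sh[[length(sh) + 1L]] <<- data.frame(t1 = a, t2 = b, shared_bases = bases,
                                         stringsAsFactors = FALSE)
  }

  expected <- list()
  expect_gene <- function(gene, start, end, n_transcripts, probes,
                          strand = "+") {
    expected[[length(expected) + 1L]] <<- data.frame(
      gene = gene, chrom = "chr1", start = start, end = end, strand = strand,
      category = "lncRNA", n_transcripts = n_transcripts,
      probes = paste(sort(probes), collapse = ","),
      chosen_probe = NA_character_, stringsAsFactors = FALSE)
  }

  ## -- plain genes: two full-coverage probes, well-separated variances ----
  for (i in seq_len(n_clean)) {
    g <- sprintf("gClean%02d", i)
    t <- sprintf("tClean%02d", i)
    s <- 10000L * i
    add_tr(t, g, s, s + 1000L)
    p_lo <- sprintf("pClean%02d_a", i)
    p_hi <- sprintf("pClean%02d_b", i)
    add_rec(p_lo, 60L, t, 60L)
    add_rec(p_hi, 60L, t, 60L)
    probe_sd[p_lo] <- 0.3
    probe_sd[p_hi] <- 3.0
    expect_gene(g, s, s + 1000L, 1L, c(p_lo, p_hi))
  }

  if (scenarios) {
    ## low-coverage probe on clean gene 1 (45/60 = 75% < 80%): dropped,
    ## and a discordant-biotype probe (54/60 = 90%): dropped
    if (n_clean >= 1L) {
      add_rec("pLowCov", 60L, "tClean01", 45L)
      add_rec("pDiscord", 60L, "tClean01", 54L, ref = "protein_coding")
    }

    ## duplicate pair: 480/500 = 0.96 >= 0.95; multi-target probe kept
    add_tr("tDup1", "gDup1", 200000L, 200500L)
    add_tr("tDup2", "gDup2", 300000L, 300800L)
    add_sh("tDup1", "tDup2", 480L)
    add_rec("pDup", 60L, "tDup1", 60L)
    add_rec("pDup", 60L, "tDup2", 60L)
    ## largest locus is gDup2 (800 bp); smallest member name is gDup1
    expect_gene("multi-gDup1", 300000L, 300800L, 2L, "pDup")

    ## duplicate chain A~B, B~C, A!~C: one component of three loci
    add_tr("tChainA", "gChainA", 400000L, 400500L)
    add_tr("tChainB", "gChainB", 500000L, 500600L)
    add_tr("tChainC", "gChainC", 600000L, 600700L)
    add_sh("tChainA", "tChainB", 490L)  # 0.98
    add_sh("tChainB", "tChainC", 580L)  # 0.967
    add_sh("tChainA", "tChainC", 100L)  # 0.20, below threshold
    add_rec("pChain", 50L, "tChainA", 50L)
    add_rec("pChain", 50L, "tChainB", 50L)
    add_rec("pChain", 50L, "tChainC", 50L)
    expect_gene("multi-gChainA", 600000L, 600700L, 3L, "pChain")

    ## multi-target probe across unrelated groups: dropped entirely
    if (n_clean >= 1L) {
      add_rec("pCross", 60L, "tClean01", 60L)
      add_rec("pCross", 60L, "tDup1", 60L)
    }

    ## isoform pair of one locus: gene span is the union of the spans;
    ## the probe hitting a single isoform survives, the one hitting both
    ## isoforms is a multi-target probe outside any duplicate group
    add_tr("tIsoA", "gIso", 700000L, 700500L)
    add_tr("tIsoB", "gIso", 700300L, 700900L)
    add_rec("pIso", 60L, "tIsoA", 60L)
    add_rec("pIsoBoth", 60L, "tIsoA", 60L)
    add_rec("pIsoBoth", 60L, "tIsoB", 60L)
    expect_gene("gIso", 700000L, 700900L, 2L, "pIso")

    ## exact variance tie: two probes with identical expression rows;
    ## the lexicographically smaller id must be chosen
    add_tr("tTie", "gTie", 800000L, 800400L)
    add_rec("pTie_a", 60L, "tTie", 60L)
    add_rec("pTie_b", 60L, "tTie", 60L)
    expect_gene("gTie", 800000L, 800400L, 1L, c("pTie_a", "pTie_b"))

    ## gene whose only probe fails coverage: absent from the table
    add_tr("tNone", "gNone", 900000L, 900300L)
    add_rec("pNone", 60L, "tNone", 30L)
  }

  empty_records <- data.frame(probe = character(), probe_length = integer(),
                              transcript = character(), aligned = integer(),
                              biotype_db = character(),
                              biotype_ref = character(),
                              stringsAsFactors = FALSE)
  empty_tr <- data.frame(transcript = character(), locus = character(),
                         chrom = character(), strand = character(),
                         start = integer(), end = integer(),
                         length = integer(), stringsAsFactors = FALSE)
  empty_sh <- data.frame(t1 = character(), t2 = character(),
                         shared_bases = integer(), stringsAsFactors = FALSE)
  records <- if (length(rec)) do.call(rbind, rec) else empty_records
  transcripts <- if (length(tr)) do.call(rbind, tr) else empty_tr
  shared <- if (length(sh)) do.call(rbind, sh) else empty_sh

  ## probe-level expression with the planted per-probe SDs; the tie pair
  ## shares one row so its sample variances are exactly equal
  probes <- unique(records$probe)
  expr <- matrix(0, length(probes), n_samples,
                 dimnames = list(probes,
                                 sprintf("fs%02d", seq_len(n_samples))))
  for (p in probes)
    expr[p, ] <- 6 + stats::rnorm(n_samples, sd = probe_sd[[p]])
  if (all(c("pTie_a", "pTie_b") %in% probes))
    expr["pTie_b", ] <- expr["pTie_a", ]

  ## fill in expected chosen probes by direct application of the
  ## max-variance rule (ties to the smallest probe id)
  if (length(expected)) {
    expected <- do.call(rbind, expected)
    expected$chosen_probe <- vapply(expected$probes, function(ps) {
      ps <- sort(strsplit(ps, ",", fixed = TRUE)[[1L]])
      v <- apply(expr[ps, , drop = FALSE], 1L, stats::var)
      ps[which.max(v)]
    }, "")
    expected <- expected[order(expected$gene), , drop = FALSE]
    rownames(expected) <- NULL
  } else {
    expected <- data.frame(gene = character(), chrom = character(),
                           start = integer(), end = integer(),
                           strand = character(), category = character(),
                           n_transcripts = integer(), probes = character(),
                           chosen_probe = character(),
                           stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  rownames(transcripts) <- NULL
  rownames(shared) <- NULL
  list(records = records, transcripts = transcripts, shared = shared,
       expr = expr, expected = expected)
}
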
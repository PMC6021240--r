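test_that("the stratified split matches subtype distributions and halves sizes", {
  co <- small_cohort(n_samples = 566, n_lnc = 2, n_mrna = 2, seed = 20)
  sp <- stratified_split(co$clinical$sample, co$clinical$subtype, seed = 1)
  expect_identical(length(sp$half1), 283L)
  expect_identical(length(sp$half2), 283L)
  expect_identical(sort(c(sp$half1, sp$half2)), sort(co$clinical$sample))
  tab1 <- table(co$clinical$subtype[match(sp$half1, co$clinical$sample)])
  tab2 <- table(co$clinical$subtype[match(sp$half2, co$clinical$sample)])
  expect_true(all(abs(tab1 - tab2[names(tab1)]) <= 1))
  # odd stratum of 7 splits 4/3
  sp2 <- stratified_split(paste0("x", 1:7), rep("C1", 7), seed = 2)
  expect_setequal(c(length(sp2$half1), length(sp2$half2)), c(4L, 3L))
  expect_identical(stratified_split(co$clinical$sample,
                                    co$clinical$subtype, seed = 1), sp)
  sp3 <- stratified_split(co$clinical$sample, co$clinical$subtype, seed = 3)
  expect_false(identical(sp, sp3))
  expect_error(stratified_split("a", "C1"), "at least 2")
})

test_that("correlation ranking matches the covariance formula and edge rules", {
  set.seed(21)
  lnc <- rnorm(10)
  mrna <- matrix(rnorm(50), 5, 10,
                 dimnames = list(paste0("m", 1:5), paste0("s", 1:10)))
  r <- correlation_rank(lnc, mrna)
  manual <- vapply(rownames(mrna), function(g) {
    x <- mrna[g, ]
    sum((lnc - mean(lnc)) * (x - mean(x))) /
      sqrt(sum((lnc - mean(lnc))^2) * sum((x - mean(x))^2))
  }, 0)
  expect_equal(r[names(manual)][order(names(manual))],
               manual[order(names(manual))], tolerance = 1e-12)
  expect_true(all(diff(unname(r)) <= 1e-15))
  # perfect correlates sit at the ends
  mrna2 <- rbind(mrna, same = lnc, anti = -lnc)
  r2 <- correlation_rank(lnc, mrna2)
  expect_identical(names(r2)[1], "same")
  expect_equal(unname(r2[1]), 1)
  expect_identical(names(r2)[length(r2)], "anti")
  expect_equal(unname(r2[length(r2)]), -1)
  mrna3 <- rbind(mrna, flat = rep(1, 10))
  expect_warning(r3 <- correlation_rank(lnc, mrna3), "constant mRNA")
  expect_equal(unname(r3["flat"]), 0)
  expect_error(correlation_rank(rep(2, 10), mrna), "constant lncRNA")
})

test_that("enrichment scores match the worked running-sum examples", {
  r <- c(g1 = 0.9, g2 = 0.5, g3 = 0.1, g4 = -0.8)
  top <- enrichment_score(r, "g1", exponent = 0)
  expect_equal(top$es, 1)
  expect_equal(top$running, c(1, 2 / 3, 1 / 3, 0))
  bottom <- enrichment_score(r, "g4", exponent = 0)
  expect_equal(bottom$es, -1)
  # walk: +0.9/1.7, -1/2, -1/2, +0.8/1.7; max deviation right after g1
  both <- enrichment_score(r, c("g1", "g4"), exponent = 1)
  expect_equal(both$es, 0.9 / 1.7, tolerance = 1e-12)
  expect_error(enrichment_score(r, "zz"), "not represented")
  expect_error(enrichment_score(r, names(r)), "equals the ranked universe")
})

test_that("enrichment scores agree with the brute-force walk on random cases", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    metric <- setNames(round(rnorm(n), 3), sprintf("g%02d", 1:n))
    k <- sample(1:(n - 1), 1)
    set <- sample(names(metric), k)
    for (expo in c(0, 1)) {
      got <- enrichment_score(metric, set, expo)
      ref <- oracle_es(metric, set, expo)
      expect_equal(got$es, ref$es, tolerance = 1e-12)
      expect_equal(got$running, ref$running, tolerance = 1e-12)
      expect_true(got$es >= -1 && got$es <= 1)
    }
  }
})

test_that("enrichment scores agree with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(23)
  metric <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  set <- sample(names(metric), 10)
  got <- enrichment_score(metric, set, exponent = 1)$es
  stats_sorted <- sort(metric, decreasing = TRUE)
  ref <- fgsea::calcGseaStat(unname(stats_sorted),
                             which(names(stats_sorted) %in% set),
                             gseaParam = 1)
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("pre-ranked GSEA flags planted sets and honors the size window", {
  set.seed(24)
  n <- 300
  metric <- setNames(rnorm(n, sd = 0.1), sprintf("g%03d", 1:n))
  planted <- names(sort(metric, decreasing = TRUE))[1:20]
  metric[planted] <- metric[planted] + 0.8
  sets <- list(planted = planted,
               small = sprintf("g%03d", 1:10),
               null1 = sample(names(metric), 25),
               null2 = sample(names(metric), 40))
  res <- gsea_preranked(metric, sets, nperm = 200, min_size = 15,
                        max_size = 100, seed = 5)
  expect_false("small" %in% res$set)
  expect_true("small" %in% attr(res, "excluded"))
  expect_lt(res$fwer[res$set == "planted"], 0.05)
  expect_gt(res$es[res$set == "planted"], 0.5)
  expect_identical(sign(res$nes), sign(res$es))
  expect_error(gsea_preranked(metric, sets, nperm = 0), "nperm")
  # determinism
  res2 <- gsea_preranked(metric, sets, nperm = 200, min_size = 15,
                         max_size = 100, seed = 5)
  expect_identical(res, res2)
})

test_that("GSEA FWER is conservative on shuffled metrics", {
  set.seed(25)
  n <- 200
  sets <- lapply(1:20, function(i) sample(sprintf("g%03d", 1:n), 15))
  names(sets) <- paste0("ns", 1:20)
  hits <- 0
  for (rep in 1:10) {
    metric <- setNames(sample(rnorm(n)), sprintf("g%03d", 1:n))
    res <- gsea_preranked(metric, sets, nperm = 100, min_size = 10,
                          max_size = 50, seed = rep)
    if (min(res$fwer) >= 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("consensus keeps only pairs significant in both halves", {
  h1 <- data.frame(lncRNA = "l1", set = c("A", "B", "C"),
                   size = 20, es = c(0.6, 0.5, 0.6),
                   nes = 1, fwer = c(0.01, 0.01, 0.01), half = 1L)
  h2 <- data.frame(lncRNA = "l1", set = c("A", "B", "C"),
                   size = 20, es = c(0.8, 0.4, -0.5),
                   nes = 1, fwer = c(0.01, 0.2, 0.01), half = 2L)
  expect_message(prof <- consensus_enrichment(h1, h2), "opposite ES signs")
  expect_identical(prof$set, "A")
  expect_equal(prof$es_mean, 0.7)
  expect_false("B" %in% prof$set)   # FWER fails in half 2
  expect_false("C" %in% prof$set)   # sign conflict
  expect_identical(attr(prof, "lncRNAs"), "l1")
  h3 <- h2[h2$set != "C", ]
  expect_error(consensus_enrichment(h1, h3), "different gene-set")
})

test_that("redundant gene sets merge by overlap distance at the 0.5 cut", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"),
               C = c("x", "y", "z"), D = c("x", "y", "z"))
  cl <- cluster_redundant_gene_sets(sets)
  # A-B distance 1/3 -> merged; C identical to D -> merged; A/B vs C/D
  # disjoint -> separate
  expect_identical(length(cl$sets), 2L)
  expect_identical(cl$sets[["A+B"]], c("a", "b", "c", "d"))
  expect_identical(cl$sets[["C+D"]], c("x", "y", "z"))
  expect_identical(unname(cl$membership["A"]), unname(cl$membership["B"]))
  # permutation invariance
  cl2 <- cluster_redundant_gene_sets(sets[c(3, 1, 4, 2)])
  expect_identical(cl$sets, cl2$sets)
  expect_error(cluster_redundant_gene_sets(list(A = "a")), "at least 2")
  expect_error(cluster_redundant_gene_sets(list(A = "a", B = character())),
               "empty")
})

test_that("split-half guilt-by-association recovers a wired lncRNA-set pair", {
  sets <- generate_gene_sets(n_sets = 6, set_size = 20, n_mrna = 400,
                             seed = 3)
  pc <- data.frame(gene = "lnc00001", set = "set04", rho = 0.6, weight = 1)
  co <- small_cohort(n_samples = 200, n_lnc = 4, n_mrna = 400, seed = 30,
                     gene_sets = sets, planted_cor = pc)
  cfg <- lnchet_config(gsea_nperm = 100, gsea_min = 10, seed = 30)
  gba <- gba_enrichment(co$expr, co$clinical$subtype, sets, config = cfg)
  prof <- consensus_enrichment(gba$half1, gba$half2, cfg$fwer)
  expect_true(any(prof$lncRNA == "lnc00001" & prof$set == "set04"))
  expect_gt(prof$es_mean[prof$lncRNA == "lnc00001" & prof$set == "set04"],
            0.5)
})
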
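test_that("fold change follows the log2 identity and its reciprocal law", {
  expect_equal(compute_fold_change(5, 5), 1)
  expect_equal(compute_fold_change(6, 5), 2)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(compute_fold_change(a, b) * compute_fold_change(b, a),
               rep(1, 20))
  expect_error(compute_fold_change(NA, 1), "finite")
})

test_that("two-group tests behave on degenerate, separated, and skewed data", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(as.numeric(test_differential(x, x, "wilcoxon")), 1)
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50, mean = 3)
  expect_lt(as.numeric(test_differential(a, b, "wilcoxon")), 1e-6)
  expect_lt(as.numeric(test_differential(a, b, "ttest")), 1e-6)
  # heavily skewed data must take the rank-sum branch under 'auto'
  skewed <- exp(rnorm(40, sd = 2))
  p <- test_differential(skewed, skewed + 1, "auto")
  expect_identical(attr(p, "method"), "wilcoxon")
  # normal homoscedastic data takes the t branch
  p2 <- test_differential(rnorm(40), rnorm(40), "auto")
  expect_identical(attr(p2, "method"), "ttest")
  expect_error(test_differential(1:2, 1:5), "at least 3")
  expect_warning(p3 <- test_differential(rep(1, 5), rep(1, 5), "ttest"),
                 "zero variance")
  expect_equal(as.numeric(p3), 1)
})

test_that("BH adjustment matches the step-up formula and preserves order", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.04), 0.04)
  set.seed(3)
  for (i in 1:25) {
    p <- sample(seq(0.01, 1, by = 0.01), sample(2:8, 1), replace = TRUE)
    q <- adjust_bh(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(adjust_bh(c(0.1, 1.2)), "0, 1")
})

test_that("the binary screen calls planted shifts and respects the FC gate", {
  ps <- data.frame(gene = c("lnc00001", "lnc00002"), feature = "mmr",
                   shift = c(1, -1))
  co <- small_cohort(n_samples = 160, n_lnc = 60, n_mrna = 5, seed = 6,
                     prevalence = list(location = 0.5, mmr = 0.5, cimp = 0.2,
                                       cin = 0.5, braf = 0.1, kras = 0.4,
                                       tp53 = 0.5),
                     planted_shift = ps)
  lnc <- expr_rows(co$expr, "lncRNA")
  out <- screen_binary_feature(lnc, co$clinical$mmr, "dMMR",
                               lnchet_config(), "mmr")
  expect_identical(out$direction[out$gene == "lnc00001"], "up")
  expect_identical(out$direction[out$gene == "lnc00002"], "down")
  # a highly significant gene below the FC gate stays uncalled
  n <- 300
  x <- rbind(g1 = c(rnorm(n, 5.485), rnorm(n, 5)),   # FC ~ 1.40
             g2 = c(rnorm(n, 5), rnorm(n, 5)))
  colnames(x) <- paste0("s", 1:(2 * n))
  labels <- rep(c("pos", "neg"), each = n)
  out2 <- screen_binary_feature(x, labels, "pos")
  r <- out2[out2$gene == "g1", ]
  expect_lt(r$q, 0.001)
  expect_lt(r$fc, 1.5)
  expect_identical(r$direction, "none")
  expect_error(screen_binary_feature(x, rep("neg", 2 * n), "pos"),
               "empty")
})

test_that("direction labels flip consistently when the groups are swapped", {
  co <- small_cohort(n_samples = 120, n_lnc = 30, n_mrna = 5, seed = 8,
                     planted_shift = data.frame(gene = "lnc00003",
                                                feature = "cin", shift = 1.2))
  lnc <- expr_rows(co$expr, "lncRNA")
  up <- screen_binary_feature(lnc, co$clinical$cin, "high",
                              feature = "cin")
  dn <- screen_binary_feature(lnc, co$clinical$cin, "low",
                              feature = "cin")
  m <- merge(up, dn, by = "gene")
  expect_equal(m$fc.x * m$fc.y, rep(1, nrow(m)))
  expect_equal(m$p.x, m$p.y)
  swap <- c(up = "down", down = "up", none = "none")
  expect_identical(unname(swap[m$direction.x]), m$direction.y)
  # sample order must not matter
  perm <- sample(ncol(lnc))
  up2 <- screen_binary_feature(lnc[, perm], co$clinical$cin[perm], "high",
                               feature = "cin")
  expect_equal(up, up2)
})

test_that("subtype screen uses the mean of the per-subtype means", {
  # 6 subtypes; focal mean 8, every other subtype mean 5 => FC = 2^3
  set.seed(4)
  subtype <- rep(paste0("C", 1:6), each = 30)
  mu <- ifelse(subtype == "C4", 8, 5)
  x <- matrix(rnorm(length(mu), mu, 0.3), nrow = 1,
              dimnames = list("lncX", paste0("s", seq_along(mu))))
  out <- screen_subtype_distinctive(x, subtype)
  r4 <- out[out$feature == "C4", ]
  expect_equal(r4$fc, 8, tolerance = 0.15)
  expect_identical(r4$direction, "up")
  # with two subtypes the FC reduces to the binary-screen FC
  sub2 <- rep(c("C1", "C2"), each = 40)
  x2 <- matrix(rnorm(80, rep(c(6, 5), each = 40), 0.4), nrow = 1,
               dimnames = list("g", paste0("t", 1:80)))
  s2 <- screen_subtype_distinctive(x2, sub2)
  b2 <- screen_binary_feature(x2, sub2, "C1", feature = "C1")
  expect_equal(s2$fc[s2$feature == "C1"], b2$fc)
  expect_warning(
    screen_subtype_distinctive(x2, c(rep("C1", 40), rep("C2", 38),
                                     "C3", "C3")),
    "fewer than 3")
})
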
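rec <- function(probe, len, transcript, aligned, db = "lncRNA",
                ref = "lncRNA") {
  data.frame(probe = probe, probe_length = len, transcript = transcript,
             aligned = aligned, biotype_db = db, biotype_ref = ref,
             stringsAsFactors = FALSE)
}
trx <- function(id, locus, start, end, chrom = "chr1", strand = "+") {
  data.frame(transcript = id, locus = locus, chrom = chrom, strand = strand,
             start = start, end = end, length = end - start,
             stringsAsFactors = FALSE)
}

test_that("coverage and biotype rules keep and discard the right probes", {
  records <- rbind(rec("p1", 60, "t1", 50),                    # 83.3%
                   rec("p2", 60, "t1", 45),                    # 75%
                   rec("p3", 50, "t1", 42, ref = "protein_coding")) # 84%
  kept <- filter_probe_alignments(records)
  expect_identical(kept$probe, "p1")
  expect_error(filter_probe_alignments(rec("p", 60, "t", 70)),
               "aligned")
})

test_that("duplicate detection applies the 95% rule over the shorter transcript", {
  transcripts <- rbind(trx("A", "gA", 0, 500), trx("B", "gB", 1000, 1800))
  shared <- data.frame(t1 = "A", t2 = "B", shared_bases = 480) # 0.96
  d <- detect_duplicates(transcripts, shared)
  expect_identical(unname(d$membership[c("A", "B")]), c("A", "A"))
  shared$shared_bases <- 400                                   # 0.80
  d2 <- detect_duplicates(transcripts, shared)
  expect_identical(length(d2$groups), 0L)
  expect_error(detect_duplicates(transcripts,
                                 data.frame(t1 = "A", t2 = "B",
                                            shared_bases = 600)),
               "exceed")
})

test_that("duplicate grouping closes chains and ignores input order", {
  transcripts <- rbind(trx("A", "gA", 0, 500), trx("B", "gB", 1000, 1600),
                       trx("C", "gC", 2000, 2700))
  shared <- data.frame(t1 = c("A", "B", "A"), t2 = c("B", "C", "C"),
                       shared_bases = c(490, 580, 100))
  d <- detect_duplicates(transcripts, shared)
  expect_identical(d$groups[["A"]], c("A", "B", "C"))
  # shuffle transcript rows and the pair order
  d2 <- detect_duplicates(transcripts[c(3, 1, 2), ], shared[c(2, 3, 1), ])
  expect_identical(sort(d2$groups[[1]]), c("A", "B", "C"))
  expect_identical(sort(names(d$membership)), sort(names(d2$membership)))
  expect_identical(d$membership[sort(names(d$membership))],
                   d2$membership[sort(names(d2$membership))])
})

test_that("multi-target probes survive only inside one duplicate group", {
  transcripts <- rbind(trx("T1", "g1", 0, 500), trx("T2", "g2", 1000, 1500),
                       trx("T3", "g3", 2000, 2500))
  dup <- detect_duplicates(transcripts,
                           data.frame(t1 = "T1", t2 = "T2",
                                      shared_bases = 480))
  records <- rbind(rec("pa", 60, "T1", 60),
                   rec("pb", 60, "T1", 60), rec("pb", 60, "T2", 60),
                   rec("pc", 60, "T1", 60), rec("pc", 60, "T3", 60))
  kept <- resolve_multi_target_probes(records, dup)
  expect_identical(sort(unique(kept$probe)), c("pa", "pb"))
})

test_that("locus collapsing takes span unions and the largest duplicate locus", {
  transcripts <- rbind(trx("i1", "gI", 100, 500), trx("i2", "gI", 300, 900))
  d <- detect_duplicates(transcripts, NULL)
  g <- collapse_to_genes(transcripts, d)
  expect_identical(g$genes$start, 100)
  expect_identical(g$genes$end, 900)
  expect_identical(g$genes$gene, "gI")
  # duplicate group of 3 -> one 'multi' gene at the largest locus
  transcripts <- rbind(trx("A", "gA", 0, 500), trx("B", "gB", 1000, 1600),
                       trx("C", "gC", 2000, 2700))
  shared <- data.frame(t1 = c("A", "B"), t2 = c("B", "C"),
                       shared_bases = c(490, 580))
  d <- detect_duplicates(transcripts, shared)
  g <- collapse_to_genes(transcripts, d)
  expect_identical(nrow(g$genes), 1L)
  expect_identical(g$genes$gene, "multi-gA")
  expect_identical(g$genes$start, 2000)  # gC spans 700 bp, the largest
  expect_identical(unname(g$transcript2gene[c("A", "B", "C")]),
                   rep("multi-gA", 3))
  # transcripts of one locus on two chromosomes are rejected
  bad <- rbind(trx("x1", "gX", 0, 100), trx("x2", "gX", 0, 100,
                                            chrom = "chr2"))
  expect_error(collapse_to_genes(bad, detect_duplicates(bad, NULL)),
               "different chromosomes")
})

test_that("probe selection maximizes variance with a lexicographic tie rule", {
  expr <- rbind(p1 = c(1, 5, 9, 2), p2 = c(4, 4.2, 4.1, 4.3),
                p3 = c(0, 1, 0, 1))
  colnames(expr) <- paste0("s", 1:4)
  sel <- select_probe_per_gene(expr, c(p1 = "g1", p2 = "g1", p3 = "g2"))
  expect_identical(unname(sel$chosen["g1"]), "p1")
  expect_identical(unname(sel$values["g1", ]), unname(expr["p1", ]))
  # exact tie between pA and pB -> pA
  expr2 <- rbind(pB = c(1, 2, 3), pA = c(1, 2, 3))
  colnames(expr2) <- paste0("s", 1:3)
  sel2 <- select_probe_per_gene(expr2, c(pB = "g", pA = "g"))
  expect_identical(unname(sel2$chosen), "pA")
  expect_error(select_probe_per_gene(expr, c(p1 = "g1"), genes = c("g1", "gZ")),
               "zero mapped probes")
})

test_that("strand-specific padded-exon overlap maps probes correctly", {
  exons <- data.frame(transcript = "t", chrom = "chr1", strand = "+",
                      start = 1000, end = 1100)
  # 60 bp probe overlapping the raw exon by 58 bp
  probes <- data.frame(probe = c("pOk", "pStrand", "pPad", "pShort"),
                       chrom = "chr1",
                       strand = c("+", "-", "+", "+"),
                       start = c(1042, 1042, 1047, 1050),
                       end = c(1102, 1102, 1107, 1107))
  hits <- annotate_probes_by_overlap(probes, exons)
  # pOk: 58 bp raw; pStrand: same interval, wrong strand; pPad: 53 bp raw
  # reaching 58 only through the +5 bp padding; pShort: 55 bp padded
  expect_identical(hits$probe, c("pOk", "pPad"))
  expect_error(annotate_probes_by_overlap(
    data.frame(probe = "p", chrom = "chr1", strand = "+",
               start = 10, end = 10), exons), "malformed interval")
})

test_that("cytosines are assigned to promoters and gene bodies strand-awarely", {
  genes <- data.frame(gene = c("gp", "gm"), chrom = "chr1",
                      strand = c("+", "-"),
                      tss = c(10000, 20000), tts = c(20000, 12000))
  sites <- data.frame(site = c("c1", "c2", "c3", "c4"), chrom = "chr1",
                      pos = c(8500, 15000, 21500, 3000))
  ann <- annotate_cytosines(sites, genes)
  expect_identical(ann$region[ann$site == "c1" & ann$gene == "gp"],
                   "promoter")
  expect_identical(ann$region[ann$site == "c2" & ann$gene == "gp"],
                   "gene_body")
  # 21,500 is 1,500 bp upstream of the minus-strand TSS at 20,000
  expect_identical(ann$region[ann$site == "c3" & ann$gene == "gm"],
                   "promoter")
  expect_false("c4" %in% ann$site)
  genes$tts[1] <- 9000
  expect_error(annotate_cytosines(sites, genes), "inconsistent with strand")
})

test_that("the reannotation chain reproduces the fixture's expected table", {
  fx <- generate_probe_fixtures(n_clean = 4, seed = 21)
  res <- reannotate_affy(fx$records, fx$transcripts, fx$shared, fx$expr)
  expect_identical(res$annotation, fx$expected)
  # chosen probe's row is carried over verbatim
  g <- fx$expected$gene[1]
  expect_identical(unname(res$values[g, ]),
                   unname(fx$expr[fx$expected$chosen_probe[1], ]))
  # per-gene output variance equals the max over that gene's probes
  for (i in seq_len(nrow(fx$expected))) {
    probes <- strsplit(fx$expected$probes[i], ",")[[1]]
    expect_equal(var(res$values[fx$expected$gene[i], ]),
                 max(apply(fx$expr[probes, , drop = FALSE], 1, var)))
  }
})
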
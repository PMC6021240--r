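#' Filter probe-to-transcript alignments by coverage and biotype concordance
#'
#' Keeps alignment records where at least `coverage` of the probe's bases
#' align to the target transcript and the two annotation sources agree on
#' the target's biotype; records with discordant biotype information are
#' discarded regardless of coverage.
#'
#' @param records Data frame with columns `probe`, `probe_length`,
#'   `transcript`, `aligned`, `biotype_db` (lncRNA database) and
#'   `biotype_ref` (reference transcriptome).
#' @param coverage Minimum aligned fraction (default 0.80).
#' @return The kept rows of `records`.
#' @export
filter_probe_alignments <- function(records, coverage = 0.80) {
  .check_frac(coverage, "coverage")
  need <- c("probe", "probe_length", "transcript", "aligned",
            "biotype_db", "biotype_ref")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    .fail("alignment records lack column(s): ",
          paste(missing_cols, collapse = ", "))
  if (any(records$aligned < 0) || any(records$aligned > records$probe_length))
    .fail("aligned bases must lie in [0, probe_length]")
  keep <- records$aligned / records$probe_length >= coverage &
    records$biotype_db == records$biotype_ref
  records[keep, , drop = FALSE]
}

## minimal union-find; components keyed later by lexicographic min member
.uf_new <- function(ids) stats::setNames(ids, ids)
.uf_find <- function(uf, x) {
  while (uf[[x]] != x) x <- uf[[x]]
  x
}
.uf_union <- function(uf, a, b) {
  ra <- .uf_find(uf, a); rb <- .uf_find(uf, b)
  if (ra != rb) uf[[max(ra, rb)]] <- min(ra, rb)
  uf
}
.uf_components <- function(uf) {
  roots <- vapply(names(uf), function(x) .uf_find(uf, x), "")
  split(names(uf), roots)
}

#' Detect duplicate transcripts and group them
#'
#' Two transcripts are duplicates when the shorter one shares at least
#' `share` of its sequence with the longer one. The duplicate relation is
#' closed into connected components, so grouping is order-invariant.
#'
#' @param transcripts Data frame with columns `transcript`, `locus`,
#'   `chrom`, `strand`, `start`, `end`, `length`.
#' @param shared Data frame of pairwise shared bases: columns `t1`, `t2`,
#'   `shared_bases` (each unordered pair listed once).
#' @param share Minimum shared fraction of the shorter transcript.
#' @return A list with `membership` (named character vector mapping every
#'   transcript to its group key, the lexicographically smallest member)
#'   and `groups` (list of multi-member groups, keyed the same way).
#' @export
detect_duplicates <- function(transcripts, shared, share = 0.95) {
  .check_frac(share, "share")
  len <- stats::setNames(transcripts$length, transcripts$transcript)
  uf <- .uf_new(transcripts$transcript)
  if (!is.null(shared) && nrow(shared)) {
    bad <- setdiff(c(shared$t1, shared$t2), names(len))
    if (length(bad)) .fail("shared-bases table names unknown transcript(s): ",
                           paste(unique(bad), collapse = ", "))
    shorter <- pmin(len[shared$t1], len[shared$t2])
    if (any(shared$shared_bases > shorter))
      .fail("shared bases exceed the shorter transcript's length")
    dup <- shared$shared_bases / shorter >= share
    for (i in which(dup)) uf <- .uf_union(uf, shared$t1[i], shared$t2[i])
  }
  comps <- .uf_components(uf)
  membership <- stats::setNames(rep(names(comps), lengths(comps)),
                                unlist(comps, use.names = FALSE))
  membership <- membership[transcripts$transcript]
  groups <- comps[lengths(comps) > 1L]
  list(membership = membership, groups = lapply(groups, sort))
}

#' Drop probes with multiple targets outside one duplicate group
#'
#' A probe aligning to more than one transcript is excluded unless all of
#' its targets belong to a single duplicate group (transcripts arising
#' from a duplicated genomic region cannot be distinguished, so such a
#' probe still measures one signal).
#'
#' @param records Alignment records (typically the output of
#'   [filter_probe_alignments()]).
#' @param dup_groups Result of [detect_duplicates()].
#' @return The kept rows of `records`.
#' @export
resolve_multi_target_probes <- function(records, dup_groups) {
  membership <- dup_groups$membership
  bad <- setdiff(records$transcript, names(membership))
  if (length(bad))
    .fail("alignment records target unknown transcript(s): ",
          paste(unique(bad), collapse = ", "))
  keep_probe <- vapply(split(records$transcript, records$probe), function(tg) {
    tg <- unique(tg)
    length(tg) == 1L || length(unique(membership[tg])) == 1L
  }, TRUE)
  records[keep_probe[records$probe], , drop = FALSE]
}

#' Collapse transcripts into gene loci
#'
#' Alternative transcripts of a locus merge into one gene spanning the
#' union of their extents (the largest locus); each duplicate group yields
#' exactly one gene, located at its largest member locus and named by
#' prefixing `multi-` to the smallest member locus name.
#'
#' @param transcripts Transcript table (see [detect_duplicates()]).
#' @param dup_groups Result of [detect_duplicates()].
#' @return A list with `genes` (data frame `gene`, `chrom`, `strand`,
#'   `start`, `end`, `n_transcripts`) and `transcript2gene` (named
#'   character vector).
#' @export
collapse_to_genes <- function(transcripts, dup_groups) {
  ## 1. merge isoforms locus by locus
  loci <- split(transcripts, transcripts$locus)
  locus_tab <- do.call(rbind, lapply(names(loci), function(l) {
    tr <- loci[[l]]
    if (length(unique(tr$chrom)) > 1L)
      .fail("transcripts of locus '", l, "' lie on different chromosomes")
    data.frame(locus = l, chrom = tr$chrom[1L], strand = tr$strand[1L],
               start = min(tr$start), end = max(tr$end),
               n_transcripts = nrow(tr), stringsAsFactors = FALSE)
  }))
  ## 2. merge loci connected through a duplicate group
  t2l <- stats::setNames(transcripts$locus, transcripts$transcript)
  uf <- .uf_new(locus_tab$locus)
  for (g in dup_groups$groups) {
    gl <- unique(t2l[g])
    for (i in seq_along(gl)[-1L]) uf <- .uf_union(uf, gl[1L], gl[i])
  }
  comps <- .uf_components(uf)
  genes <- do.call(rbind, lapply(comps, function(members) {
    rows <- locus_tab[match(sort(members), locus_tab$locus), , drop = FALSE]
    if (nrow(rows) == 1L)
      return(data.frame(gene = rows$locus, rows[, -1L],
                        stringsAsFactors = FALSE))
    largest <- rows[which.max(rows$end - rows$start), , drop = FALSE]
    data.frame(gene = paste0("multi-", rows$locus[1L]),
               chrom = largest$chrom, strand = largest$strand,
               start = largest$start, end = largest$end,
               n_transcripts = sum(rows$n_transcripts),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  l2root <- vapply(locus_tab$locus, function(l) .uf_find(uf, l), "")
  root2gene <- stats::setNames(
    vapply(comps, function(members) {
      if (length(members) == 1L) members else paste0("multi-", sort(members)[1L])
    }, ""), names(comps))
  t2g <- stats::setNames(root2gene[l2root[t2l]], names(t2l))
  list(genes = genes, transcript2gene = t2g)
}

#' Select one probe per gene by maximal expression variance
#'
#' When several probes measure the same gene, the probe with the highest
#' variance across samples is retained; exact ties go to the
#' lexicographically smallest probe id.
#'
#' @param expr Numeric matrix of probe-level expression (probes x samples).
#' @param probe2gene Named character vector mapping probe id to gene.
#' @param genes Optional character vector of genes that must be covered;
#'   a listed gene with no mapped probe raises an error.
#' @return A list with `values` (gene-level matrix, rows ordered by gene)
#'   and `chosen` (named character vector gene -> probe).
#' @export
select_probe_per_gene <- function(expr, probe2gene, genes = NULL) {
  missing_probes <- setdiff(names(probe2gene), rownames(expr))
  if (length(missing_probes))
    .fail("mapped probe(s) absent from the expression matrix: ",
          paste(missing_probes, collapse = ", "))
  if (!is.null(genes)) {
    uncovered <- setdiff(genes, probe2gene)
    if (length(uncovered))
      .fail("gene(s) with zero mapped probes: ",
            paste(uncovered, collapse = ", "))
  }
  by_gene <- split(names(probe2gene), unname(probe2gene))
  by_gene <- by_gene[order(names(by_gene))]
  chosen <- vapply(by_gene, function(pr) {
    v <- apply(expr[pr, , drop = FALSE], 1L, stats::var)
    pr <- sort(pr)                     # lexicographic tie-break
    pr[which.max(v[pr])]
  }, "")
  values <- expr[chosen, , drop = FALSE]
  rownames(values) <- names(chosen)
  list(values = values, chosen = chosen)
}

#' Map array probes to transcripts by strand-specific exon overlap
#'
#' A probe is assigned to a transcript when, on the same strand, its
#' genomic interval overlaps an exon (padded by `pad` bp on both sides,
#' since exon boundaries are not always sharply defined) by at least
#' `min_overlap` bp. Coordinates are 0-based half-open.
#'
#' @param probes Data frame `probe`, `chrom`, `strand`, `start`, `end`.
#' @param exons Data frame `transcript`, `chrom`, `strand`, `start`, `end`.
#' @param min_overlap Minimum overlap in bp (default 58).
#' @param pad Exon padding in bp (default 5).
#' @return Data frame `probe`, `transcript` (unique pairs).
#' @export
annotate_probes_by_overlap <- function(probes, exons, min_overlap = 58L,
                                       pad = 5L) {
  for (df in list(probes, exons))
    if (any(df$end <= df$start))
      .fail("malformed interval: end must be greater than start")
  hits <- merge(probes, exons, by = c("chrom", "strand"),
                suffixes = c(".p", ".e"))
  if (!nrow(hits))
    return(data.frame(probe = character(), transcript = character(),
                      stringsAsFactors = FALSE))
  ov <- pmin(hits$end.p, hits$end.e + pad) -
    pmax(hits$start.p, hits$start.e - pad)
  out <- unique(hits[ov >= min_overlap, c("probe", "transcript")])
  out <- out[order(out$probe, out$transcript), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign CpG sites to promoters and gene bodies
#'
#' A site falls in a gene's promoter when it lies within
#' `[-promoter_up, +promoter_down]` of the TSS in transcription
#' orientation, and in the gene body when it lies anywhere else between
#' the TSS and the TTS. A site may be labeled by several genes.
#'
#' @param sites Data frame `site`, `chrom`, `pos`.
#' @param gene_models Data frame `gene`, `chrom`, `strand`, `tss`, `tts`.
#' @param promoter_up,promoter_down Promoter window in bp around the TSS.
#' @return Data frame `site`, `gene`, `region` (`promoter`/`gene_body`).
#' @export
annotate_cytosines <- function(sites, gene_models, promoter_up = 2000L,
                               promoter_down = 1000L) {
  plus <- gene_models$strand == "+"
  if (any(plus & gene_models$tss >= gene_models$tts) ||
      any(!plus & gene_models$tss <= gene_models$tts))
    .fail("TSS/TTS inconsistent with strand for gene(s): ",
          paste(gene_models$gene[(plus & gene_models$tss >= gene_models$tts) |
                                 (!plus & gene_models$tss <= gene_models$tts)],
                collapse = ", "))
  hits <- merge(sites, gene_models, by = "chrom")
  if (!nrow(hits))
    return(data.frame(site = character(), gene = character(),
                      region = character(), stringsAsFactors = FALSE))
  up <- ifelse(hits$strand == "+", hits$tss - promoter_up,
               hits$tss - promoter_down)
  dn <- ifelse(hits$strand == "+", hits$tss + promoter_down,
               hits$tss + promoter_up)
  in_prom <- hits$pos >= up & hits$pos <= dn
  lo <- pmin(hits$tss, hits$tts)
  hi <- pmax(hits$tss, hits$tts)
  in_body <- !in_prom & hits$pos >= lo & hits$pos <= hi
  out <- rbind(
    data.frame(site = hits$site[in_prom], gene = hits$gene[in_prom],
               region = "promoter", stringsAsFactors = FALSE),
    data.frame(site = hits$site[in_body], gene = hits$gene[in_body],
               region = "gene_body", stringsAsFactors = FALSE))
  out <- out[order(out$site, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full expression-array reannotation chain
#'
#' Applies, in order: coverage/biotype filtering, duplicate detection,
#' multi-target resolution, locus collapsing, and max-variance probe
#' selection, and assembles the per-gene annotation table (genes with at
#' least one surviving probe).
#'
#' @param records Alignment records (see [filter_probe_alignments()]).
#' @param transcripts Transcript table (see [detect_duplicates()]).
#' @param shared Pairwise shared-bases table.
#' @param expr Probe-level expression matrix (probes x samples).
#' @param coverage,share Rule thresholds.
#' @return A list with `annotation` (data frame `gene`, `chrom`, `start`,
#'   `end`, `strand`, `category`, `n_transcripts`, `probes`,
#'   `chosen_probe`, sorted by gene), `values` (gene-level expression) and
#'   `chosen` (gene -> probe).
#' @export
reannotate_affy <- function(records, transcripts, shared, expr,
                            coverage = 0.80, share = 0.95) {
  kept <- filter_probe_alignments(records, coverage)
  dup <- detect_duplicates(transcripts, shared, share)
  kept <- resolve_multi_target_probes(kept, dup)
  genes <- collapse_to_genes(transcripts, dup)
  if (!nrow(kept))
    return(list(annotation = data.frame(), values = NULL, chosen = character()))
  probe2gene <- stats::setNames(
    unname(genes$transcript2gene[kept$transcript]), kept$probe)
  probe2gene <- probe2gene[!duplicated(names(probe2gene))]
  sel <- select_probe_per_gene(expr, probe2gene)
  probed <- genes$genes[genes$genes$gene %in% probe2gene, , drop = FALSE]
  probes_by_gene <- split(names(probe2gene), unname(probe2gene))
  annotation <- data.frame(
    probed[, c("gene", "chrom", "start", "end", "strand")],
    category = "lncRNA",
    n_transcripts = probed$n_transcripts,
    probes = vapply(probed$gene, function(g)
      paste(sort(probes_by_gene[[g]]), collapse = ","), ""),
    chosen_probe = unname(sel$chosen[probed$gene]),
    stringsAsFactors = FALSE)
  rownames(annotation) <- NULL
  list(annotation = annotation, values = sel$values, chosen = sel$chosen)
}
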
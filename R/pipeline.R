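.binary_positive <- c(location = "distal", mmr = "dMMR", cimp = "pos",
                      cin = "high", braf = "mut", kras = "mut", tp53 = "mut")

#' Run the full lncRNA heterogeneity pipeline
#'
#' Orchestrates, over one expression cohort: per-feature differential
#' screens (location, MMR, CIMP, CIN, BRAF/KRAS/TP53 mutation),
#' subtype-distinctive screens, the uni/multivariate Cox survival screen,
#' redundancy clustering of the gene sets, split-half
#' guilt-by-association GSEA with both-halves consensus, and the
#' Enrichment Metascore over the feature-defined lncRNA groups. Results
#' are written as TSV tables with fixed column order plus a
#' machine-readable JSON run log recording the configuration and seed;
#' identical config and seed reproduce identical tables. A failing stage
#' is recorded in the log and the remaining stages still run.
#'
#' @param config A [lnchet_config()].
#' @param expression An [expression_matrix()] or a TSV path.
#' @param clinical A clinical data frame or a TSV path.
#' @param gene_sets A named list of gene sets or a GMT path (required for
#'   the `gba`/`metascore` stages).
#' @param outdir Output directory (created if missing).
#' @param stages Stages to run, a subset of `c("features", "subtypes",
#'   "survival", "gba", "metascore")`.
#' @param gba_lnc_ids Optional explicit lncRNA selection for the
#'   guilt-by-association stage; by default the union of lncRNAs called
#'   by the requested screens.
#' @return Invisibly, a list of the stage results and the run-log list.
#' @export
run_full_pipeline <- function(config, expression, clinical,
                              gene_sets = NULL, outdir,
                              stages = c("features", "subtypes", "survival",
                                         "gba", "metascore"),
                              gba_lnc_ids = NULL) {
  stopifnot(inherits(config, "lnchet_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(expression)) expression <- read_expression_matrix(expression)
  if (is.character(clinical)) clinical <- read_clinical_table(clinical)
  clinical <- validate_clinical(clinical)
  if (is.character(gene_sets)) gene_sets <- read_gene_sets_gmt(gene_sets)

  ## fail fast on structurally missing inputs, before any computation
  if (!setequal(clinical$sample, colnames(expression$values)) ||
      !all(clinical$sample == colnames(expression$values)))
    .fail("clinical samples must match the expression columns (same order)")
  if ("survival" %in% stages && all(is.na(clinical$rfs_time)))
    .fail("survival stage requested but rfs_time is entirely missing")
  if (any(c("gba", "metascore") %in% stages) && is.null(gene_sets))
    .fail("gba/metascore stages requested but no gene sets supplied")

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lnc <- expr_rows(expression, "lncRNA")
  log <- list(package = "lnchet",
              version = as.character(utils::packageVersion("lnchet")),
              seed = config$seed, test_method = config$test_method,
              config = unclass(config), stages = list())
  results <- list()

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      log$stages[[name]] <<- list(status = "failed",
                                  error = conditionMessage(res))
      warning("stage '", name, "' failed: ", conditionMessage(res),
              call. = FALSE)
      NULL
    } else {
      log$stages[[name]] <<- list(status = "ok")
      results[[name]] <<- res
      res
    }
  }

  run_stage("features", function() {
    tabs <- lapply(names(.binary_positive), function(f) {
      screen_binary_feature(lnc, clinical[[f]], .binary_positive[[f]],
                            config, feature = f)
    })
    out <- do.call(rbind, tabs)
    .write_tsv(out, file.path(outdir, "differential_features.tsv"))
    out
  })

  run_stage("subtypes", function() {
    out <- screen_subtype_distinctive(lnc, clinical$subtype, config)
    .write_tsv(out, file.path(outdir, "subtype_distinctive.tsv"))
    out
  })

  run_stage("survival", function() {
    out <- screen_survival(lnc, clinical, config)
    .write_tsv(out, file.path(outdir, "survival.tsv"))
    out
  })

  ## lncRNAs entering guilt-by-association: screen hits, unless overridden
  screen_hits <- function() {
    hits <- character()
    for (nm in c("features", "subtypes"))
      if (!is.null(results[[nm]]))
        hits <- c(hits, results[[nm]]$gene[results[[nm]]$direction != "none"])
    if (!is.null(results$survival))
      hits <- c(hits,
                results$survival$gene[results$survival$direction != "none"])
    sort(unique(hits))
  }

  run_stage("gba", function() {
    ids <- if (is.null(gba_lnc_ids)) screen_hits() else gba_lnc_ids
    if (!length(ids)) .fail("no lncRNAs selected for guilt-by-association")
    grouped <- cluster_redundant_gene_sets(gene_sets, config$overlap_cut)
    write_gene_sets_gmt(grouped$sets,
                        file.path(outdir, "grouped_gene_sets.gmt"),
                        descriptions = stats::setNames(
                          rep("merged redundant sets", length(grouped$sets)),
                          names(grouped$sets)))
    halves <- gba_enrichment(expression, clinical$subtype, grouped$sets,
                             lnc_ids = ids, config = config)
    profile <- consensus_enrichment(halves$half1, halves$half2, config$fwer)
    .write_tsv(profile, file.path(outdir, "consensus_enrichment.tsv"))
    list(halves = halves, profile = profile, grouped = grouped$sets,
         lnc_ids = ids)
  })

  run_stage("metascore", function() {
    gba <- results$gba
    if (is.null(gba)) .fail("metascore stage needs the gba stage results")
    tabs <- list()
    add_groups <- function(screen, features) {
      for (f in features) {
        sub <- screen[screen$feature == f & screen$direction != "none", ,
                      drop = FALSE]
        sub <- sub[sub$gene %in% attr(gba$profile, "lncRNAs"), , drop = FALSE]
        if (!nrow(sub)) next
        grp <- lnc_group(f, sub$gene,
                         ifelse(sub$direction == "up", 1, -1))
        wts <- stats::setNames(ifelse(sub$direction == "up", 1, -1),
                               sub$gene)
        tabs[[f]] <<- metascore_table(list(grp), gba$profile,
                                      config = config, lnc_weights = wts)
      }
    }
    if (!is.null(results$features))
      add_groups(results$features, unique(results$features$feature))
    if (!is.null(results$subtypes))
      add_groups(results$subtypes, unique(results$subtypes$feature))
    if (!is.null(results$survival)) {
      sv <- results$survival
      for (d in c("RFS-positive", "RFS-negative")) {
        members <- intersect(sv$gene[sv$direction == d],
                             attr(gba$profile, "lncRNAs"))
        if (!length(members)) next
        tabs[[d]] <- metascore_table(list(lnc_group(d, members)),
                                     gba$profile, config = config)
      }
    }
    if (!length(tabs)) .fail("no lncRNA group has consensus profiles")
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    .write_tsv(out, file.path(outdir, "metascore.tsv"))
    out
  })

  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(log = log, outdir = outdir)))
}
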
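#' Run the full characterization pipeline on a data bundle
#'
#' Orchestrates identify -> cis-targets -> correlation screen ->
#' transcriptional complexity -> pairwise differential expression -> DEL
#' union -> k-means pattern clustering -> per-cluster pathway enrichment ->
#' candidate ranking, and assembles a run report of per-stage counts.
#' Differential expression is computed on the full count matrix (so size
#' factors see all features) and DEL calling is restricted to the retained
#' lncRNAs.
#'
#' @param bundle A list with elements `reference` and `novel`
#'   ([transcript_set]s), `calls` (`coding_calls`), `counts` and `tpm`
#'   (`expr_matrix`es) and `gmt` (named list of pathways), e.g. a
#'   `synthetic_bundle` from [generate_dataset], or the same pieces loaded
#'   from files.
#' @param min_length,min_exons,min_tpm Identification thresholds.
#' @param window Flank window for lincRNA cis-targets (bp).
#' @param alpha Significance level of the correlation screen and enrichment.
#' @param lfc,fdr DEL thresholds.
#' @param k Number of expression-pattern clusters.
#' @param seed Seed for clustering restarts (recorded in the report).
#' @param top_n Number of ranked candidates to report.
#' @param out_dir Optional directory; when given, every stage's table is
#'   written there as TSV.
#' @return List of class `pipeline_result` with elements `lncrnas`,
#'   `targets`, `correlations`, `correlation_summary`, `complexity`, `de`,
#'   `dels`, `clusters`, `enrichment`, `candidates` and `report`.
#' @export
run_pipeline <- function(bundle, min_length = 200, min_exons = 2,
                         min_tpm = 0.1, window = 1e5, alpha = 0.05,
                         lfc = 1.5, fdr = 0.01, k = 8, seed = 1,
                         top_n = 10, out_dir = NULL) {
  for (el in c("reference", "novel", "calls", "counts", "tpm")) {
    if (is.null(bundle[[el]])) stop("bundle is missing element '", el, "'")
  }
  index <- build_annotation_index(bundle$reference)
  lncrnas <- identify_lncrnas(bundle$novel, bundle$reference, bundle$tpm,
                              bundle$calls, min_length = min_length,
                              min_exons = min_exons, min_tpm = min_tpm)
  targets <- assign_cis_targets(lncrnas, index, window = window)
  correlations <- correlation_screen(targets, bundle$tpm, alpha = alpha)
  cor_summary <- summarize_correlation(correlations,
                                       n_total = nrow(lncrnas))

  lnc_tpm <- bundle$tpm
  lnc_tpm$values <- lnc_tpm$values[
    rownames(lnc_tpm$values) %in% lncrnas$transcript_id, , drop = FALSE]
  cx <- complexity_profile(lnc_tpm, by = "stage", k = 10)

  de_all <- de_pairwise(bundle$counts, lfc = lfc, fdr = fdr)
  de_lnc <- lapply(de_all, function(d) {
    d[d$feature_id %in% lncrnas$transcript_id, , drop = FALSE]
  })
  cat_map <- stats::setNames(lncrnas$category, lncrnas$transcript_id)
  dels <- del_union(de_lnc, categories = cat_map)

  clusters <- NULL
  enrichment <- NULL
  if (length(dels$ids) >= k) {
    sm <- stage_means(lnc_tpm)
    z <- suppressWarnings(zscore_rows(sm[dels$ids, , drop = FALSE]))
    if (nrow(z) >= k) {
      clusters <- kmeans_cluster(z, k = k, seed = seed)
      if (!is.null(bundle$gmt)) {
        universe <- unique(unlist(bundle$gmt))
        enrichment <- lapply(split(names(clusters$labels),
                                   clusters$labels), function(members) {
          q <- intersect(
            unique(targets$gene_id[targets$lncrna_id %in% members]),
            universe)
          if (length(q) == 0L) return(NULL)
          hypergeom_enrich(q, bundle$gmt, universe, alpha = alpha)
        })
      }
    }
  }

  candidates <- rank_candidates(lncrnas, dels$ids, correlations,
                                stage_means(lnc_tpm), top_n = top_n)

  report <- list(
    seed = seed,
    thresholds = list(min_length = min_length, min_exons = min_exons,
                      min_tpm = min_tpm, window = window, alpha = alpha,
                      lfc = lfc, fdr = fdr, k = k),
    n_lncrnas = nrow(lncrnas),
    category_counts = attr(lncrnas, "category_counts"),
    n_novel = sum(lncrnas$origin == "novel"),
    n_annotated = sum(lncrnas$origin == "annotated"),
    del_per_comparison = dels$per_comparison,
    n_dels = length(dels$ids),
    del_breakdown = dels$breakdown,
    correlation = cor_summary,
    top10_share = cx$top_k,
    cluster_sizes = if (!is.null(clusters)) table(clusters$labels) else NULL,
    n_significant_pathways = if (!is.null(enrichment)) {
      sum(vapply(enrichment, function(e)
        if (is.null(e)) 0L else sum(e$significant), integer(1)))
    } else NULL
  )

  res <- structure(list(
    lncrnas = lncrnas, targets = targets, correlations = correlations,
    correlation_summary = cor_summary, complexity = cx, de = de_lnc,
    dels = dels, clusters = clusters, enrichment = enrichment,
    candidates = candidates, report = report), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' Rank candidate lncRNAs for follow-up
#'
#' Candidates are the lncRNAs that are differentially expressed in at least
#' one stage comparison and have at least one significant cis correlation;
#' they are ranked by maximum stage-mean TPM, descending (abundance as the
#' deciding criterion on top of the two filters).
#'
#' @param lncrnas An `lncrna_set`.
#' @param del_ids Character vector of DEL feature ids.
#' @param correlations Pair table from [correlation_screen].
#' @param stage_tpm Features x stages matrix of stage-mean TPM.
#' @param top_n Number of candidates to return.
#' @return `data.frame`: `transcript_id`, `category`, `origin`, `max_tpm`
#'   (maximum stage-mean), sorted by `max_tpm` descending.
#' @export
rank_candidates <- function(lncrnas, del_ids, correlations, stage_tpm,
                            top_n = 10) {
  sig_ids <- unique(correlations$lncrna_id[
    correlations$klass %in% c("pos", "neg")])
  cand <- lncrnas[lncrnas$transcript_id %in% del_ids &
                    lncrnas$transcript_id %in% sig_ids, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(transcript_id = character(), category = character(),
                      origin = character(), max_tpm = numeric(),
                      stringsAsFactors = FALSE))
  }
  mx <- apply(stage_tpm[cand$transcript_id, , drop = FALSE], 1L, max)
  ord <- order(-mx, cand$transcript_id)
  out <- data.frame(transcript_id = cand$transcript_id[ord],
                    category = cand$category[ord],
                    origin = cand$origin[ord],
                    max_tpm = unname(mx[ord]), stringsAsFactors = FALSE)
  utils::head(out, top_n)
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, nm) {
    utils::write.table(x, file.path(out_dir, nm), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(as.data.frame(res$lncrnas), "lncrnas.tsv")
  wt(res$targets, "cis_targets.tsv")
  wt(res$correlations, "correlations.tsv")
  wt(res$correlation_summary$per_category, "correlation_summary.tsv")
  wt(res$complexity$curves, "complexity_curves.tsv")
  wt(res$complexity$top_k, "complexity_topk.tsv")
  for (nm in names(res$de)) wt(res$de[[nm]], paste0("de_", nm, ".tsv"))
  wt(res$dels$per_comparison, "del_counts.tsv")
  wt(data.frame(feature_id = res$dels$ids), "del_union.tsv")
  if (!is.null(res$clusters)) {
    wt(data.frame(feature_id = names(res$clusters$labels),
                  cluster = unname(res$clusters$labels)), "clusters.tsv")
  }
  if (!is.null(res$enrichment)) {
    enr <- do.call(rbind, lapply(names(res$enrichment), function(cl) {
      e <- res$enrichment[[cl]]
      if (is.null(e)) return(NULL)
      cbind(cluster = cl, e)
    }))
    if (!is.null(enr)) wt(enr, "enrichment.tsv")
  }
  wt(res$candidates, "candidates.tsv")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("pipeline_result\n")
  cat(sprintf("  lncRNAs: %d (%d novel + %d annotated)\n", r$n_lncrnas,
              r$n_novel, r$n_annotated))
  cat("  categories:",
      paste(names(r$category_counts), as.integer(r$category_counts),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  DELs: %d (union over %d comparisons)\n", r$n_dels,
              nrow(r$del_per_comparison)))
  cat(sprintf("  significantly correlated fraction: %.3f\n",
              r$correlation$fraction_significant))
  invisible(x)
}
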
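#' Row z-scoring
#'
#' Centers and scales each row to mean 0 and population standard deviation
#' 1 (divisor n, not n - 1). Zero-variance rows carry no pattern and are
#' dropped with a warning.
#'
#' @param m Numeric matrix.
#' @return The z-scored matrix, possibly with fewer rows.
#' @export
zscore_rows <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  keep <- sdev > 0
  if (any(!keep)) {
    warning(sum(!keep), " zero-variance row(s) dropped before scaling")
  }
  (m[keep, , drop = FALSE] - mu[keep]) / sdev[keep]
}

#' K-means clustering of expression patterns
#'
#' Clusters features (typically row-z-scored stage-mean TPM of DELs) into k
#' expression-pattern groups with stats::kmeans, taking the best of `n_init`
#' random restarts by total within-cluster sum of squares. Deterministic
#' given `seed`. Cluster labels are renumbered canonically (by the first
#' feature id each cluster contains) so runs are comparable.
#'
#' @param m Numeric matrix (features x stages) with rownames.
#' @param k Number of clusters (default 8).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param n_init Number of random restarts.
#' @param max_iter Maximum iterations per restart.
#' @return List with `labels` (named integer vector in 1..k), `centroids`
#'   (k x stages matrix) and `tot_withinss`.
#' @export
kmeans_cluster <- function(m, k = 8, seed, n_init = 25, max_iter = 300) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (missing(seed)) stop("seed is mandatory")
  if (nrow(m) < k) stop("fewer rows (", nrow(m), ") than clusters (", k, ")")
  set.seed(seed)
  fit <- stats::kmeans(m, centers = k, nstart = n_init,
                       iter.max = max_iter)
  # canonical relabeling: cluster containing the alphabetically first
  # feature id becomes 1, and so on
  first_member <- vapply(seq_len(k), function(cl) {
    min(rownames(m)[fit$cluster == cl])
  }, character(1))
  remap <- match(seq_len(k), order(first_member))
  labels <- stats::setNames(remap[fit$cluster], rownames(m))
  centroids <- fit$centers[order(first_member), , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  list(labels = labels, centroids = centroids,
       tot_withinss = fit$tot.withinss)
}

#' Read a GMT pathway-membership file
#'
#' @param path GMT file: one pathway per line, tab-separated fields
#'   (id, description, gene ids...).
#' @return Named list of character vectors (gene ids per pathway), with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("parse error: GMT line ", bad[1L], " has fewer than 3 fields")
  }
  out <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(out) <- vapply(fields, `[[`, "", 1L)
  attr(out, "description") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), names(out))
  out
}

#' Write a pathway list as GMT
#'
#' @param pathways Named list of gene-id vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to the ids.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(pathways), names(pathways))
  }
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, descriptions[[nm]], pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' For each pathway, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap when |query| genes are drawn without
#' replacement from the universe: P(X >= overlap) with population size
#' |universe|, successes |pathway intersect universe|, draws |query|.
#' Pathways are intersected with the universe first and the query must be a
#' subset of the universe. No multiple-testing correction is applied (the
#' screen is reported at nominal p < alpha).
#'
#' @param query Character vector of gene ids (e.g. cis-targets of one DEL
#'   cluster).
#' @param pathways Named list of gene-id vectors (see [read_gmt]).
#' @param universe Character vector of background gene ids.
#' @param alpha Significance level.
#' @return `data.frame` sorted by p: `pathway_id`, `pathway_size`,
#'   `overlap`, `p`, `significant`.
#' @export
hypergeom_enrich <- function(query, pathways, universe, alpha = 0.05) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L || length(query) == 0L) {
    stop("empty universe or query")
  }
  if (!all(query %in% universe)) {
    stop("query must be a subset of the universe")
  }
  res <- do.call(rbind, lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], universe)
    ov <- length(intersect(query, pw))
    p <- stats::phyper(ov - 1L, length(pw),
                       length(universe) - length(pw),
                       length(query), lower.tail = FALSE)
    data.frame(pathway_id = nm, pathway_size = length(pw), overlap = ov,
               p = p, stringsAsFactors = FALSE)
  }))
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
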
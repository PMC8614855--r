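#' Assign cis-target protein-coding genes to lncRNAs
#'
#' Genic lncRNAs (antisense, intronic, sense-overlapping) are assigned the
#' protein-coding genes whose locus overlaps the lncRNA span (relationship
#' `host`, distance 0). Intergenic lncRNAs (lincRNA) are assigned every
#' protein-coding gene whose body lies within `window` bp of the lncRNA
#' span; the distance reported is the gap between closest boundaries and the
#' window boundary is inclusive (a gap of exactly `window` is in).
#'
#' @param lncrnas An `lncrna_set` (see [identify_lncrnas]).
#' @param index An `annotation_index` including protein-coding genes.
#' @param window Flank window in bp for lincRNAs (default 100 kb).
#' @return `data.frame` with columns `lncrna_id`, `gene_id`, `relationship`
#'   (`host`/`flank`), `distance` (bp gap, 0 for host), `category`.
#' @export
assign_cis_targets <- function(lncrnas, index, window = 1e5) {
  stopifnot(inherits(lncrnas, "lncrna_set"),
            inherits(index, "annotation_index"))
  if (anyNA(lncrnas$category)) stop("state error: unclassified lncRNA record")
  empty <- data.frame(lncrna_id = character(), gene_id = character(),
                      relationship = character(), distance = integer(),
                      category = character(), stringsAsFactors = FALSE)
  if (nrow(lncrnas) == 0L) return(empty)
  pc <- index$genes[S4Vectors::mcols(index$genes)$biotype ==
                      "protein_coding"]
  if (length(pc) == 0L) return(empty)
  spans <- GenomicRanges::GRanges(
    seqnames = lncrnas$chrom,
    ranges = IRanges::IRanges(lncrnas$start, lncrnas$end),
    strand = "*"
  )
  genic <- lncrnas$category %in% c("antisense", "intronic",
                                   "sense_overlapping")
  res <- list()
  if (any(genic)) {
    h <- find_overlaps_quiet(spans[genic], pc, ignore.strand = TRUE)
    if (length(h) > 0L) {
      qi <- which(genic)[S4Vectors::queryHits(h)]
      res$host <- data.frame(
        lncrna_id = lncrnas$transcript_id[qi],
        gene_id = S4Vectors::mcols(pc)$gene_id[S4Vectors::subjectHits(h)],
        relationship = "host", distance = 0L,
        category = lncrnas$category[qi], stringsAsFactors = FALSE)
    }
  }
  linc <- lncrnas$category == "lincRNA"
  if (any(linc)) {
    # gap distance between closest boundaries; overlap would give 0 but a
    # lincRNA never overlaps a gene body by definition
    h <- find_overlaps_quiet(spans[linc], pc,
                                     maxgap = window, ignore.strand = TRUE)
    if (length(h) > 0L) {
      qi <- which(linc)[S4Vectors::queryHits(h)]
      d <- GenomicRanges::distance(
        spans[linc][S4Vectors::queryHits(h)],
        pc[S4Vectors::subjectHits(h)], ignore.strand = TRUE)
      keep <- !is.na(d) & d <= window
      res$flank <- data.frame(
        lncrna_id = lncrnas$transcript_id[qi][keep],
        gene_id = S4Vectors::mcols(pc)$gene_id[
          S4Vectors::subjectHits(h)][keep],
        relationship = "flank", distance = as.integer(d[keep]),
        category = lncrnas$category[qi][keep], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else empty
  rownames(out) <- NULL
  out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation with the usual t-approximation:
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with elements `r` and `p`; both `NA` (flagged by attribute
#'   `zero_variance`) when either vector is constant.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(structure(list(r = NA_real_, p = NA_real_),
                     zero_variance = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Screen lncRNA-target expression correlations
#'
#' Computes a Pearson correlation (TPM across all samples) for every
#' (lncRNA, cis-target) pair and partitions the outcomes: `pos` (r > 0,
#' p < alpha), `neg` (r < 0, p < alpha), otherwise `ns`. Pairs whose
#' expression is untestable (zero variance) are reported `ns`; target genes
#' absent from the matrix are skipped with a warning.
#'
#' @param targets Cis-target table from [assign_cis_targets].
#' @param tpm An `expr_matrix` of TPM covering lncRNAs and genes.
#' @param alpha Significance level on the raw p-value (no multiple-testing
#'   correction: the screen is reported at nominal p < 0.05).
#' @param log2p1 If `TRUE`, correlate log2(TPM + 1) instead of raw TPM.
#' @return `data.frame` with columns `lncrna_id`, `gene_id`, `category`,
#'   `r`, `p`, `klass`.
#' @export
correlation_screen <- function(targets, tpm, alpha = 0.05, log2p1 = FALSE) {
  stopifnot(inherits(tpm, "expr_matrix"))
  vals <- tpm$values
  if (log2p1) vals <- log2(vals + 1)
  ok_l <- targets$lncrna_id %in% rownames(vals)
  ok_g <- targets$gene_id %in% rownames(vals)
  if (any(!ok_g) || any(!ok_l)) {
    warning(sum(!ok_g | !ok_l),
            " pair(s) skipped: feature absent from expression matrix")
  }
  t2 <- targets[ok_l & ok_g, , drop = FALSE]
  if (nrow(t2) == 0L) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      category = character(), r = numeric(), p = numeric(),
                      klass = character(), stringsAsFactors = FALSE))
  }
  rp <- vapply(seq_len(nrow(t2)), function(i) {
    x <- vals[t2$lncrna_id[i], ]
    y <- vals[t2$gene_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(c(NA_real_, NA_real_))
    res <- pearson_with_p(x, y)
    c(res$r, res$p)
  }, numeric(2))
  r <- rp[1L, ]
  p <- rp[2L, ]
  klass <- rep("ns", nrow(t2))
  klass[!is.na(p) & p < alpha & r > 0] <- "pos"
  klass[!is.na(p) & p < alpha & r < 0] <- "neg"
  data.frame(lncrna_id = t2$lncrna_id, gene_id = t2$gene_id,
             category = t2$category, r = r, p = p, klass = klass,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize the correlation screen per category
#'
#' Counts lncRNAs (not pairs): an lncRNA counts as positively (negatively)
#' correlated when at least one of its cis-target pairs is `pos` (`neg`).
#' The overall fraction is the number of lncRNAs with any significant
#' partner divided by the total number of expressed lncRNAs.
#'
#' @param records Pair-level table from [correlation_screen].
#' @param n_total Total number of expressed lncRNAs (denominator of the
#'   overall fraction); defaults to the number of distinct lncRNAs in
#'   `records`.
#' @return List with `per_category` (`data.frame`: category, pos, neg, ns)
#'   and `fraction_significant` (a single number in [0, 1]).
#' @export
summarize_correlation <- function(records, n_total = NULL) {
  cats <- c("lincRNA", "antisense", "intronic", "sense_overlapping")
  ids <- unique(records$lncrna_id)
  if (is.null(n_total)) n_total <- length(ids)
  per <- lapply(cats, function(cc) {
    rr <- records[records$category == cc, , drop = FALSE]
    lnc <- unique(rr$lncrna_id)
    has_pos <- vapply(lnc, function(l)
      any(rr$klass[rr$lncrna_id == l] == "pos"), logical(1))
    has_neg <- vapply(lnc, function(l)
      any(rr$klass[rr$lncrna_id == l] == "neg"), logical(1))
    data.frame(category = cc, pos = sum(has_pos), neg = sum(has_neg),
               ns = sum(!has_pos & !has_neg), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  n_sig <- sum(vapply(ids, function(l)
    any(records$klass[records$lncrna_id == l] %in% c("pos", "neg")),
    logical(1)))
  list(per_category = per,
       fraction_significant = if (n_total > 0) n_sig / n_total else 0)
}
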
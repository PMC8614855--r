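# findOverlaps across objects with disjoint seqlevels warns; disjoint
# chromosome sets are an expected, meaningful case here (no overlap)
find_overlaps_quiet <- function(...) {
  suppressWarnings(GenomicRanges::findOverlaps(...))
}

#' Build a strand-aware annotation index
#'
#' Pre-computes the reference-side structures positional classification and
#' cis-target assignment query: gene bodies (union span of all exons of a
#' gene), reference exons, derived introns, and per-transcript intron-chain
#' keys. All overlap queries on the index go through
#' [GenomicRanges::findOverlaps] and are strand-aware unless a query asks
#' otherwise.
#'
#' @param reference A [transcript_set] carrying biotypes (the reference
#'   annotation).
#' @return An object of class `annotation_index` with elements `genes`
#'   (GRanges with `gene_id`, `biotype`), `exons` and `introns` (GRanges with
#'   `gene_id`, `transcript_id`), `chains` (named intron-chain keys) and
#'   `biotype` (named character, gene id to biotype).
#' @export
build_annotation_index <- function(reference) {
  stopifnot(inherits(reference, "transcript_set"))
  tx <- reference$tx
  if (anyDuplicated(tx$transcript_id)) {
    stop("validation error: duplicate transcript_id in reference")
  }
  if (nrow(tx) == 0L) {
    idx <- list(
      genes = GenomicRanges::GRanges(), exons = GenomicRanges::GRanges(),
      introns = GenomicRanges::GRanges(),
      chains = character(), biotype = character()
    )
    return(structure(idx, class = "annotation_index"))
  }
  # gene body = union span of the gene's transcripts; gene biotype is
  # protein_coding if any transcript is, else lncRNA if any is
  spans <- transcript_spans(reference)
  gsplit <- split(seq_len(nrow(tx)), tx$gene_id)
  gene_df <- do.call(rbind, lapply(names(gsplit), function(g) {
    i <- gsplit[[g]]
    bt <- if ("protein_coding" %in% tx$biotype[i]) "protein_coding"
          else if ("lncRNA" %in% tx$biotype[i]) "lncRNA" else "other"
    data.frame(gene_id = g, chrom = tx$chrom[i[1L]],
               start = min(GenomicRanges::start(spans)[i]),
               end = max(GenomicRanges::end(spans)[i]),
               strand = tx$strand[i[1L]], biotype = bt,
               stringsAsFactors = FALSE)
  }))
  genes <- GenomicRanges::GRanges(
    seqnames = gene_df$chrom,
    ranges = IRanges::IRanges(gene_df$start, gene_df$end),
    strand = gene_df$strand,
    gene_id = gene_df$gene_id, biotype = gene_df$biotype
  )
  structure(list(
    genes = genes,
    exons = reference$exons,
    introns = derive_introns(reference),
    chains = intron_chain_keys(reference),
    biotype = stats::setNames(gene_df$biotype, gene_df$gene_id)
  ), class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat(sprintf(
    "annotation_index: %d genes (%d protein-coding), %d exons, %d introns\n",
    length(x$genes), sum(x$biotype == "protein_coding"),
    length(x$exons), length(x$introns)))
  invisible(x)
}

#' Query the index for overlapping reference entries
#'
#' @param index An `annotation_index`.
#' @param query A `GRanges` of query intervals; strand `*` matches both
#'   strands, `+`/`-` only their own (set `ignore_strand = TRUE` to override).
#' @param what Which reference layer to query.
#' @param type Overlap type, as in [IRanges::findOverlaps()].
#' @param ignore_strand Ignore strand when matching.
#' @return The subset of the queried layer overlapping any query interval.
#' @export
query_index <- function(index, query,
                        what = c("genes", "exons", "introns"),
                        type = "any", ignore_strand = FALSE) {
  stopifnot(inherits(index, "annotation_index"))
  what <- match.arg(what)
  subj <- index[[what]]
  if (length(subj) == 0L || length(query) == 0L) return(subj[integer()])
  hits <- find_overlaps_quiet(query, subj, type = type,
                              ignore.strand = ignore_strand)
  subj[sort(unique(S4Vectors::subjectHits(hits)))]
}
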
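#' Structural and expression filtering of assembled transcripts
#'
#' Applies the candidate filter for lncRNA discovery: transcripts shorter
#' than `min_length` are discarded (strictly shorter: a 200-nt transcript is
#' kept at the default), single-exon transcripts are discarded, and a
#' transcript must exceed `min_tpm` (strictly) in at least one sample.
#'
#' @param ts A [transcript_set] of candidate transcripts.
#' @param tpm An `expr_matrix` of kind TPM covering the candidates.
#' @param min_length Minimum transcript length in nt (sum of exon widths).
#' @param min_exons Minimum exon count.
#' @param min_tpm TPM that must be exceeded in at least one sample.
#' @param on_missing What to do with transcripts absent from the TPM matrix:
#'   `"drop"` (with a warning) or `"error"`.
#' @return The retained [transcript_set]; attribute `"filter_summary"` holds
#'   the per-rule discard counts.
#' @export
filter_structural <- function(ts, tpm, min_length = 200, min_exons = 2,
                              min_tpm = 0.1, on_missing = c("drop", "error")) {
  stopifnot(inherits(ts, "transcript_set"), inherits(tpm, "expr_matrix"))
  on_missing <- match.arg(on_missing)
  if (tpm$kind != "TPM") stop("expression matrix must be of kind TPM")
  tx <- ts$tx
  in_tpm <- tx$transcript_id %in% rownames(tpm$values)
  if (any(!in_tpm)) {
    msg <- paste0(sum(!in_tpm), " transcript(s) absent from TPM matrix")
    if (on_missing == "error") stop("validation error: ", msg)
    warning(msg, "; dropped")
  }
  max_tpm <- rep(0, nrow(tx))
  max_tpm[in_tpm] <- apply(
    tpm$values[tx$transcript_id[in_tpm], , drop = FALSE], 1L, max)
  keep_len <- tx$length >= min_length
  keep_ex <- tx$n_exons >= min_exons
  keep_tpm <- in_tpm & max_tpm > min_tpm
  keep <- keep_len & keep_ex & keep_tpm
  out <- subset_transcripts(ts, tx$transcript_id[keep])
  attr(out, "filter_summary") <- data.frame(
    rule = c("too_short", "single_exon", "low_tpm", "retained"),
    n = c(sum(!keep_len), sum(!keep_ex), sum(!keep_tpm), sum(keep))
  )
  out
}

#' Positional classification of candidate transcripts
#'
#' Classifies each transcript against the reference annotation by a fixed
#' decision cascade (precedence mirrors gffcompare's o/x/i/u class codes):
#'
#' 1. same-strand exonic overlap with an exact reference intron-chain match
#'    -> `rejected_known` (the transcript reproduces a known structure;
#'    single-exon transcripts have no intron chain and never match);
#' 2. same-strand exonic overlap without a full structural match
#'    -> `sense_overlapping`;
#' 3. opposite-strand exonic overlap -> `antisense`;
#' 4. transcript entirely contained in a single intron of one reference
#'    transcript (either strand) -> `intronic`;
#' 5. no overlap with any gene body -> `lincRNA`;
#' 6. anything left (e.g. overlapping a gene body but no exon, spanning an
#'    exon-intron boundary without exonic overlap) -> `rejected_known`.
#'
#' @param ts A [transcript_set] of candidates.
#' @param index An `annotation_index` built from the reference.
#' @param strict If `TRUE`, a transcript on a chromosome absent from the
#'   reference is an error; by default it is classified `lincRNA` with a
#'   warning.
#' @return Named character vector of categories (one of `lincRNA`,
#'   `antisense`, `intronic`, `sense_overlapping`, `rejected_known`).
#' @export
classify_position <- function(ts, index, strict = FALSE) {
  stopifnot(inherits(ts, "transcript_set"),
            inherits(index, "annotation_index"))
  tx <- ts$tx
  if (nrow(tx) == 0L) return(stats::setNames(character(), character()))
  spans <- transcript_spans(ts)

  ref_chroms <- unique(as.character(GenomicRanges::seqnames(index$genes)))
  off_ref <- !tx$chrom %in% ref_chroms
  if (any(off_ref)) {
    if (strict) {
      stop("chromosome absent from reference: ",
           paste(unique(tx$chrom[off_ref]), collapse = ", "))
    }
    warning(sum(off_ref), " transcript(s) on chromosomes absent from the ",
            "reference; classified lincRNA")
  }

  hit_ids <- function(hits) {
    unique(as.character(
      S4Vectors::mcols(ts$exons)$transcript_id)[S4Vectors::queryHits(hits)])
  }
  sense_ids <- if (length(index$exons)) hit_ids(
    find_overlaps_quiet(ts$exons, index$exons)) else character()
  flipped <- ts$exons
  GenomicRanges::strand(flipped) <- ifelse(
    as.character(GenomicRanges::strand(flipped)) == "+", "-", "+")
  anti_ids <- if (length(index$exons)) hit_ids(
    find_overlaps_quiet(flipped, index$exons)) else character()

  # single-exon transcripts have no intron chain and can never reproduce a
  # reference structure exactly
  keys <- intron_chain_keys(ts)
  kk <- keys[tx$transcript_id]
  known <- tx$transcript_id[kk %in% index$chains & !endsWith(kk, ":mono")]

  intronic_ids <- if (length(index$introns)) {
    h <- find_overlaps_quiet(spans, index$introns, type = "within",
                                     ignore.strand = TRUE)
    unique(names(spans)[S4Vectors::queryHits(h)])
  } else character()

  body_ids <- if (length(index$genes)) {
    h <- find_overlaps_quiet(spans, index$genes,
                                     ignore.strand = TRUE)
    unique(names(spans)[S4Vectors::queryHits(h)])
  } else character()

  id <- tx$transcript_id
  out <- ifelse(
    id %in% sense_ids & id %in% known, "rejected_known",
    ifelse(id %in% sense_ids, "sense_overlapping",
    ifelse(id %in% anti_ids, "antisense",
    ifelse(id %in% intronic_ids, "intronic",
    ifelse(!id %in% body_ids, "lincRNA", "rejected_known")))))
  stats::setNames(out, id)
}

#' End-to-end lncRNA identification
#'
#' Composes the discovery pipeline: structural/expression filtering, then
#' positional classification (keeping the four lncRNA categories), then the
#' four-predictor non-coding consensus. Annotated lncRNAs from the reference
#' (biotype `lncRNA`) that pass the same TPM expression filter are merged in
#' with origin `annotated` and category `lincRNA`, since reference lncRNA
#' catalogues are dominated by intergenic models and carry no positional
#' call of their own here.
#'
#' @param novel A [transcript_set] of assembled candidate transcripts.
#' @param reference A [transcript_set] of the reference annotation.
#' @param tpm An `expr_matrix` of TPM covering novel transcripts and
#'   reference lncRNAs.
#' @param calls A `coding_calls` object covering the novel transcripts.
#' @param min_length,min_exons,min_tpm Filter thresholds, see
#'   [filter_structural].
#' @param window Retained for interface symmetry; cis-target assignment is a
#'   separate step ([assign_cis_targets]).
#' @return Object of class `lncrna_set`: a `data.frame` with one row per
#'   retained lncRNA (`transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `length`, `n_exons`, `category`, `origin`, `max_tpm`),
#'   with the category tally in attribute `"category_counts"`.
#' @export
identify_lncrnas <- function(novel, reference, tpm, calls,
                             min_length = 200, min_exons = 2,
                             min_tpm = 0.1, window = 1e5) {
  stopifnot(inherits(novel, "transcript_set"),
            inherits(reference, "transcript_set"),
            inherits(tpm, "expr_matrix"))
  index <- build_annotation_index(reference)
  kept <- filter_structural(novel, tpm, min_length = min_length,
                            min_exons = min_exons, min_tpm = min_tpm)
  categories <- classify_position(kept, index)
  lnc_cat <- categories[categories %in%
    c("lincRNA", "antisense", "intronic", "sense_overlapping")]
  nc <- consensus_noncoding(calls, names(lnc_cat))
  keep_ids <- names(lnc_cat)[nc]

  novel_rows <- lncrna_rows(kept, keep_ids, lnc_cat[keep_ids], "novel", tpm)

  # annotated lncRNAs: reference models of biotype lncRNA, expressed above
  # the same TPM cutoff; assigned category lincRNA, bypassing classification
  ann_ids <- reference$tx$transcript_id[reference$tx$biotype == "lncRNA"]
  ann_ids <- ann_ids[ann_ids %in% rownames(tpm$values)]
  if (length(ann_ids) > 0L) {
    mt <- apply(tpm$values[ann_ids, , drop = FALSE], 1L, max)
    ann_ids <- ann_ids[mt > min_tpm]
  }
  ann_rows <- lncrna_rows(reference, ann_ids,
                          stats::setNames(rep("lincRNA", length(ann_ids)),
                                          ann_ids),
                          "annotated", tpm)
  out <- rbind(novel_rows, ann_rows)
  rownames(out) <- NULL
  counts <- table(factor(out$category, levels = c(
    "lincRNA", "antisense", "intronic", "sense_overlapping")))
  structure(out, class = c("lncrna_set", "data.frame"),
            category_counts = counts)
}

lncrna_rows <- function(ts, ids, category, origin, tpm) {
  if (length(ids) == 0L) {
    return(data.frame(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(), start = integer(),
      end = integer(), length = integer(), n_exons = integer(),
      category = character(), origin = character(), max_tpm = numeric(),
      stringsAsFactors = FALSE))
  }
  sub <- subset_transcripts(ts, ids)
  spans <- transcript_spans(sub)
  tx <- sub$tx
  data.frame(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    chrom = tx$chrom,
    strand = tx$strand,
    start = GenomicRanges::start(spans)[match(tx$transcript_id,
                                              names(spans))],
    end = GenomicRanges::end(spans)[match(tx$transcript_id, names(spans))],
    length = tx$length,
    n_exons = tx$n_exons,
    category = unname(category[tx$transcript_id]),
    origin = origin,
    max_tpm = apply(tpm$values[tx$transcript_id, , drop = FALSE], 1L, max),
    stringsAsFactors = FALSE
  )
}
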
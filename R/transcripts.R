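#' Transcript set container
#'
#' A `transcript_set` holds a collection of transcript models: per-transcript
#' exon intervals (1-based, closed, the Bioconductor convention) on a single
#' chromosome and strand, together with gene assignment, origin and biotype.
#' It is the common currency of the identification pipeline: assembled
#' ("novel") transcripts and the reference annotation are both represented
#' this way.
#'
#' @param exons A [GenomicRanges::GRanges] of exon intervals with metadata
#'   columns `transcript_id` and `gene_id`. Exons of one transcript must lie
#'   on a single chromosome and strand (`+` or `-`) and must not overlap one
#'   another.
#' @param source Origin of the models: `"reference"` or `"novel"`. A single
#'   value, or a character vector named by transcript id.
#' @param biotype Transcript biotype, one of `"protein_coding"`, `"lncRNA"`,
#'   `"other"`. A single value or a vector named by transcript id.
#'
#' @return An object of class `transcript_set`: a list with elements
#'   `exons` (exon `GRanges`, sorted within transcript) and `tx` (a
#'   `data.frame` with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `n_exons`, `length`, `source`, `biotype`).
#' @export
transcript_set <- function(exons, source = "novel", biotype = "other") {
  stopifnot(methods::is(exons, "GRanges"))
  mc <- S4Vectors::mcols(exons)
  if (is.null(mc$transcript_id) || is.null(mc$gene_id)) {
    stop("exons must carry 'transcript_id' and 'gene_id' metadata columns")
  }
  if (length(exons) == 0L) {
    tx <- data.frame(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(),
      n_exons = integer(), length = integer(),
      source = character(), biotype = character(),
      stringsAsFactors = FALSE
    )
    return(structure(list(exons = exons, tx = tx), class = "transcript_set"))
  }
  if (any(GenomicRanges::width(exons) < 1L)) {
    stop("validation error: exon with end < start")
  }
  tid <- as.character(mc$transcript_id)
  ord <- order(tid, GenomicRanges::start(exons))
  exons <- exons[ord]
  tid <- tid[ord]

  chrom <- as.character(GenomicRanges::seqnames(exons))
  str <- as.character(GenomicRanges::strand(exons))
  if (any(tapply(chrom, tid, function(x) length(unique(x))) > 1L)) {
    stop("validation error: transcript with exons on mixed chromosomes")
  }
  if (any(tapply(str, tid, function(x) length(unique(x))) > 1L)) {
    stop("validation error: transcript with exons on mixed strands")
  }
  if (any(!str %in% c("+", "-"))) {
    stop("validation error: transcript strand must be '+' or '-'")
  }
  # non-overlap within transcript: with exons sorted by start, each exon must
  # start after the previous one ends
  st <- GenomicRanges::start(exons)
  en <- GenomicRanges::end(exons)
  same_tx <- tid[-1L] == tid[-length(tid)]
  if (any(same_tx & st[-1L] <= en[-length(en)])) {
    stop("validation error: overlapping exons within a transcript ",
         "(duplicate transcript_id?)")
  }

  ids <- unique(tid)
  take <- function(x, what) {
    if (length(x) == 1L) return(stats::setNames(rep(x, length(ids)), ids))
    if (is.null(names(x)) || !all(ids %in% names(x))) {
      stop(what, " must be a single value or named by transcript id")
    }
    x[ids]
  }
  src <- take(source, "source")
  bty <- take(biotype, "biotype")
  stopifnot(all(src %in% c("reference", "novel")),
            all(bty %in% c("protein_coding", "lncRNA", "other")))

  first <- !duplicated(tid)
  tx <- data.frame(
    transcript_id = tid[first],
    gene_id = as.character(mc$gene_id[ord])[first],
    chrom = chrom[first],
    strand = str[first],
    n_exons = as.integer(table(tid)[ids]),
    length = as.integer(tapply(en - st + 1L, tid, sum)[ids]),
    source = unname(src),
    biotype = unname(bty),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(exons = exons, tx = tx), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d exons\n",
              nrow(x$tx), length(x$exons)))
  if (nrow(x$tx) > 0) {
    cat("  sources:", paste(names(table(x$tx$source)),
                            table(x$tx$source), collapse = ", "), "\n")
    cat("  biotypes:", paste(names(table(x$tx$biotype)),
                             table(x$tx$biotype), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.transcript_set <- function(x) nrow(x$tx)

#' Subset a transcript set by transcript id
#'
#' @param ts A `transcript_set`.
#' @param ids Character vector of transcript ids to keep.
#' @return A `transcript_set` restricted to `ids`.
#' @export
subset_transcripts <- function(ts, ids) {
  stopifnot(inherits(ts, "transcript_set"))
  keep <- as.character(S4Vectors::mcols(ts$exons)$transcript_id) %in% ids
  ex <- ts$exons[keep]
  src <- stats::setNames(ts$tx$source, ts$tx$transcript_id)
  bty <- stats::setNames(ts$tx$biotype, ts$tx$transcript_id)
  if (length(ex) == 0L) return(transcript_set(ex))
  transcript_set(ex, source = src, biotype = bty)
}

#' Per-transcript span ranges
#'
#' @param ts A `transcript_set`.
#' @return A `GRanges` with one range per transcript (first to last exon),
#'   named by transcript id, with `transcript_id` and `gene_id` columns.
#' @export
transcript_spans <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  if (nrow(ts$tx) == 0L) return(GenomicRanges::GRanges())
  tid <- as.character(S4Vectors::mcols(ts$exons)$transcript_id)
  st <- tapply(GenomicRanges::start(ts$exons), tid, min)[ts$tx$transcript_id]
  en <- tapply(GenomicRanges::end(ts$exons), tid, max)[ts$tx$transcript_id]
  gr <- GenomicRanges::GRanges(
    seqnames = ts$tx$chrom,
    ranges = IRanges::IRanges(start = unname(st), end = unname(en)),
    strand = ts$tx$strand,
    transcript_id = ts$tx$transcript_id,
    gene_id = ts$tx$gene_id
  )
  names(gr) <- ts$tx$transcript_id
  gr
}

#' Derive introns from exon structure
#'
#' Introns are the gaps between consecutive exons of a transcript; exons and
#' introns tile the transcript span exactly. Single-exon transcripts have no
#' introns.
#'
#' @param ts A `transcript_set`.
#' @return A `GRanges` of introns with `transcript_id` and `gene_id` columns,
#'   ordered by transcript then start; empty when no transcript has more than
#'   one exon.
#' @export
derive_introns <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  ex <- ts$exons
  if (length(ex) == 0L) return(GenomicRanges::GRanges())
  tid <- as.character(S4Vectors::mcols(ex)$transcript_id)
  gid <- as.character(S4Vectors::mcols(ex)$gene_id)
  # exons are sorted by (transcript, start): an intron spans from one exon's
  # end + 1 to the next exon's start - 1
  n <- length(ex)
  inner <- which(tid[-1L] == tid[-n])
  if (length(inner) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(ex)[inner],
    ranges = IRanges::IRanges(
      start = GenomicRanges::end(ex)[inner] + 1L,
      end = GenomicRanges::start(ex)[inner + 1L] - 1L
    ),
    strand = GenomicRanges::strand(ex)[inner],
    transcript_id = tid[inner],
    gene_id = gid[inner]
  )
}

#' Intron-chain keys
#'
#' A transcript's intron chain (the ordered intron boundaries on its
#' chromosome and strand) identifies its splice structure; two transcripts
#' with equal keys are structurally identical up to terminal exon ends.
#' Single-exon transcripts get a key marking them as mono-exonic.
#'
#' @param ts A `transcript_set`.
#' @return Named character vector, one key per transcript.
#' @export
intron_chain_keys <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  if (nrow(ts$tx) == 0L) return(stats::setNames(character(), character()))
  introns <- derive_introns(ts)
  key <- stats::setNames(
    paste0(ts$tx$chrom, ":", ts$tx$strand, ":mono"),
    ts$tx$transcript_id
  )
  if (length(introns) > 0L) {
    itid <- as.character(S4Vectors::mcols(introns)$transcript_id)
    chain <- tapply(
      paste0(GenomicRanges::start(introns), "-", GenomicRanges::end(introns)),
      itid, paste, collapse = ","
    )
    chr <- stats::setNames(ts$tx$chrom, ts$tx$transcript_id)
    str <- stats::setNames(ts$tx$strand, ts$tx$transcript_id)
    key[names(chain)] <- paste0(chr[names(chain)], ":", str[names(chain)],
                                ":", unname(chain))
  }
  key
}
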
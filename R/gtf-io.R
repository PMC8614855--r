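#' Read transcript models from a GTF file
#'
#' Imports the exon features of a GTF file (via rtracklayer) and assembles
#' them into a [transcript_set]. Coordinates stay in the GTF's 1-based closed
#' convention, which is also the package's internal convention. Biotype is
#' taken from a `transcript_biotype` or `gene_biotype` attribute when
#' present; values containing "lnc"/"linc"/"antisense" map to `lncRNA`,
#' `protein_coding` maps to itself and anything else to `other`.
#'
#' @param path Path to a GTF file.
#' @param source Origin tag for all transcripts: `"novel"` or `"reference"`.
#' @param default_biotype Biotype used when the file carries no biotype
#'   attribute.
#' @return A [transcript_set].
#' @export
read_gtf <- function(path, source = "novel", default_biotype = "other") {
  if (!file.exists(path)) stop("file not found: ", path)
  check_gtf_lines(path)
  lines <- readLines(path, warn = FALSE)
  if (!any(!startsWith(lines, "#") & nzchar(lines))) {
    return(transcript_set(GenomicRanges::GRanges(
      transcript_id = character(), gene_id = character()
    ), source = source))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) {
    return(transcript_set(GenomicRanges::GRanges(
      transcript_id = character(), gene_id = character()
    ), source = source))
  }
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$transcript_id) || is.null(mc$gene_id) ||
      anyNA(mc$transcript_id) || anyNA(mc$gene_id)) {
    stop("parse error: exon feature missing transcript_id or gene_id in ",
         path)
  }
  raw_bt <- if (!is.null(mc$transcript_biotype)) {
    as.character(mc$transcript_biotype)
  } else if (!is.null(mc$gene_biotype)) {
    as.character(mc$gene_biotype)
  } else {
    rep(NA_character_, length(gr))
  }
  bt <- normalize_biotype(raw_bt, default_biotype)
  names(bt) <- as.character(mc$transcript_id)
  bt <- bt[!duplicated(names(bt))]
  ex <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id)
  )
  transcript_set(ex, source = source, biotype = bt)
}

# Structural pre-scan so malformed tab lines are reported with their line
# number (rtracklayer's own errors do not carry one).
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(body)) return(invisible(TRUE))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    bad <- which(body)[which(nf < 8L)[1L]]
    stop("parse error: malformed GTF line ", bad, " in ", path,
         " (", nf[which(nf < 8L)[1L]], " fields)")
  }
  st <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  en <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(st) || anyNA(en)) {
    bad <- which(body)[which(is.na(st) | is.na(en))[1L]]
    stop("parse error: non-numeric coordinates on GTF line ", bad,
         " in ", path)
  }
  if (any(en < st)) {
    bad <- which(body)[which(en < st)[1L]]
    stop("validation error: end < start on GTF line ", bad, " in ", path)
  }
  invisible(TRUE)
}

normalize_biotype <- function(x, default = "other") {
  out <- rep(default, length(x))
  out[!is.na(x) & x == "protein_coding"] <- "protein_coding"
  out[!is.na(x) & grepl("linc|lnc|antisense", x, ignore.case = TRUE)] <-
    "lncRNA"
  out[is.na(x)] <- default
  out
}

#' Write a transcript set to a GTF file
#'
#' Emits one `transcript` feature per transcript plus its `exon` features,
#' with `transcript_id`, `gene_id` and `transcript_biotype` attributes, so
#' that [read_gtf] round-trips the set exactly.
#'
#' @param ts A [transcript_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ts, path) {
  stopifnot(inherits(ts, "transcript_set"))
  if (nrow(ts$tx) == 0L) {
    writeLines("#gtf empty transcript set", path)
    return(invisible(path))
  }
  spans <- transcript_spans(ts)
  bt <- stats::setNames(ts$tx$biotype, ts$tx$transcript_id)
  src <- stats::setNames(ts$tx$source, ts$tx$transcript_id)

  tx_gr <- spans
  S4Vectors::mcols(tx_gr) <- S4Vectors::DataFrame(
    source = unname(src[names(spans)]),
    type = "transcript",
    transcript_id = ts$tx$transcript_id,
    gene_id = ts$tx$gene_id,
    transcript_biotype = unname(bt[names(spans)])
  )
  ex <- ts$exons
  etid <- as.character(S4Vectors::mcols(ex)$transcript_id)
  ex_gr <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(ex),
    ranges = IRanges::ranges(ex),
    strand = GenomicRanges::strand(ex)
  )
  S4Vectors::mcols(ex_gr) <- S4Vectors::DataFrame(
    source = unname(src[etid]),
    type = "exon",
    transcript_id = etid,
    gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
    transcript_biotype = unname(bt[etid])
  )
  all_gr <- c(tx_gr, ex_gr)
  names(all_gr) <- NULL
  ord <- order(as.character(GenomicRanges::seqnames(all_gr)),
               GenomicRanges::start(all_gr),
               S4Vectors::mcols(all_gr)$type != "transcript")
  rtracklayer::export(all_gr[ord], path, format = "gtf")
  invisible(path)
}
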
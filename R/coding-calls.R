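#' Read and merge coding-potential predictor call tables
#'
#' Four predictors are consulted for coding potential: CPC2, CPAT, CNCI and
#' Pfam. Each supplies a table mapping transcript id to a coding/noncoding
#' label; dialects differ between tools, so the id/label column names and
#' the label vocabulary are configurable per predictor via `column_map`.
#' Transcripts absent from a predictor's file are recorded as `missing` for
#' that predictor.
#'
#' @param paths Named character vector or list of file paths; names must be
#'   drawn from `CPC2`, `CPAT`, `CNCI`, `Pfam` (case-insensitive).
#' @param column_map Optional named list (per predictor) of lists with
#'   entries `id`, `label`, `coding`, `noncoding` giving the column names and
#'   the label values; defaults to columns `transcript_id`/`call` with values
#'   `coding`/`noncoding`.
#' @param transcripts Optional character vector of transcript ids defining
#'   the universe of the merged table; defaults to the union of ids seen in
#'   the files.
#' @return Object of class `coding_calls`: a `data.frame` with columns
#'   `transcript_id`, `CPC2`, `CPAT`, `CNCI`, `Pfam`, each call one of
#'   `coding`, `noncoding`, `missing`.
#' @export
read_coding_calls <- function(paths, column_map = NULL, transcripts = NULL) {
  predictors <- c("CPC2", "CPAT", "CNCI", "Pfam")
  nm <- names(paths)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("config error: predictor paths must be named")
  }
  canon <- predictors[match(tolower(nm), tolower(predictors))]
  if (anyNA(canon)) {
    stop("config error: unknown predictor name(s): ",
         paste(nm[is.na(canon)], collapse = ", "))
  }
  names(paths) <- canon
  per <- lapply(canon, function(p) {
    map <- column_map[[p]]
    id_col <- if (!is.null(map$id)) map$id else "transcript_id"
    label_col <- if (!is.null(map$label)) map$label else "call"
    coding_val <- if (!is.null(map$coding)) map$coding else "coding"
    noncoding_val <- if (!is.null(map$noncoding)) map$noncoding else
      "noncoding"
    tab <- utils::read.delim(paths[[p]], stringsAsFactors = FALSE)
    if (!all(c(id_col, label_col) %in% names(tab))) {
      stop("config error: predictor ", p, " file lacks columns ",
           id_col, "/", label_col)
    }
    lab <- as.character(tab[[label_col]])
    call <- ifelse(lab %in% coding_val, "coding",
                   ifelse(lab %in% noncoding_val, "noncoding", NA))
    if (anyNA(call)) {
      stop("config error: predictor ", p, " has unmapped label(s): ",
           paste(unique(lab[is.na(call)]), collapse = ", "))
    }
    stats::setNames(call, as.character(tab[[id_col]]))
  })
  names(per) <- canon
  ids <- if (is.null(transcripts)) {
    sort(unique(unlist(lapply(per, names))))
  } else {
    unique(as.character(transcripts))
  }
  out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  for (p in predictors) {
    calls <- if (p %in% names(per)) per[[p]][ids] else
      rep(NA_character_, length(ids))
    calls[is.na(calls)] <- "missing"
    out[[p]] <- unname(calls)
  }
  structure(out, class = c("coding_calls", "data.frame"))
}

#' Construct coding calls from an in-memory table
#'
#' @param df `data.frame` with `transcript_id` plus the four predictor
#'   columns (`CPC2`, `CPAT`, `CNCI`, `Pfam`), values in
#'   `coding`/`noncoding`/`missing`.
#' @return A `coding_calls` object.
#' @export
coding_calls <- function(df) {
  predictors <- c("CPC2", "CPAT", "CNCI", "Pfam")
  stopifnot(all(c("transcript_id", predictors) %in% names(df)))
  for (p in predictors) {
    if (!all(df[[p]] %in% c("coding", "noncoding", "missing"))) {
      stop("validation error: calls must be coding/noncoding/missing")
    }
  }
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            class = c("coding_calls", "data.frame"))
}

#' Four-predictor non-coding consensus
#'
#' A transcript is a credible lncRNA only when all four predictors agree it
#' is non-coding (the intersection rule). A `missing` call is conservatively
#' treated as "not confirmed non-coding" and fails the consensus, with a
#' warning so silently absent predictions are visible.
#'
#' @param calls A `coding_calls` object.
#' @param ids Transcript ids to evaluate; all must be present in `calls`.
#' @return Named logical vector: `TRUE` where all four predictors call
#'   non-coding.
#' @export
consensus_noncoding <- function(calls, ids) {
  stopifnot(inherits(calls, "coding_calls"))
  i <- match(ids, calls$transcript_id)
  if (anyNA(i)) {
    stop("lookup error: transcript(s) absent from coding calls: ",
         paste(ids[is.na(i)], collapse = ", "))
  }
  m <- as.matrix(calls[i, c("CPC2", "CPAT", "CNCI", "Pfam")])
  n_missing <- sum(rowSums(m == "missing") > 0L)
  if (n_missing > 0L) {
    warning(n_missing, " transcript(s) with missing predictor calls ",
            "treated as not confirmed non-coding")
  }
  stats::setNames(rowSums(m == "noncoding") == 4L, ids)
}

#' Longest open reading frame (deterministic predictor stand-in)
#'
#' Scans the three forward frames for ATG..stop open reading frames and
#' returns the longest one's length in codons (stop codon excluded). An ORF
#' must be terminated by an in-frame stop codon. This is not a real coding
#' potential predictor; it provides a deterministic stand-in (non-coding iff
#' < 100 codons) so end-to-end tests can fabricate predictor call tables.
#'
#' @param seq A nucleotide string over A, C, G, T, N (case-insensitive).
#' @return Integer length in codons of the longest ORF (0 when none).
#' @export
longest_orf <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) {
    stop("validation error: sequence has characters outside ACGTN")
  }
  n <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L || starts[1L] > n - 2L) next
    codons <- substring(s, starts, starts + 2L)
    open_at <- NA_integer_
    for (k in seq_along(codons)) {
      if (is.na(open_at) && codons[k] == "ATG") open_at <- k
      if (!is.na(open_at) && codons[k] %in% stops) {
        best <- max(best, k - open_at)
        open_at <- NA_integer_
      }
    }
  }
  best
}
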
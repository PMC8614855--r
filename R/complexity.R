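#' Cumulative expression-share curve
#'
#' Transcriptional complexity is profiled by sorting features from most to
#' least expressed and accumulating their share of total expression: entry i
#' of the curve is the fraction of total expression contributed by the i
#' most-expressed features. A steep curve (few features carrying most of the
#' signal) means low complexity; classical brown adipose tissue is the
#' extreme case, with its top 10 lncRNAs carrying most lncRNA output.
#'
#' @param x Non-negative numeric vector of expression values (one stage or
#'   sample) with a positive sum. Names, if present, are carried through the
#'   sort (ties broken by name for determinism).
#' @return Numeric vector of cumulative fractions in (0, 1], non-decreasing
#'   with non-increasing increments, ending at 1.
#' @export
complexity_curve <- function(x) {
  stopifnot(is.numeric(x))
  if (any(x < 0)) stop("expression values must be non-negative")
  total <- sum(x)
  if (total <= 0) stop("all-zero expression vector: curve undefined")
  ord <- if (is.null(names(x))) order(-x) else order(-x, names(x))
  cumsum(x[ord]) / total
}

#' Share of expression carried by the top k features
#'
#' @param x As in [complexity_curve].
#' @param k Rank cutoff (capped at the number of features).
#' @return The curve value at rank `min(k, length(x))`.
#' @export
top_k_fraction <- function(x, k = 10) {
  stopifnot(k >= 1)
  curve <- complexity_curve(x)
  unname(curve[min(k, length(curve))])
}

#' Complexity profiling over stages or samples
#'
#' Computes one cumulative-share curve per group (stage-mean TPM by default,
#' matching how complexity curves are drawn per developmental stage) and a
#' top-k summary.
#'
#' @param tpm An `expr_matrix` of TPM restricted to the features of
#'   interest (e.g. retained lncRNAs).
#' @param by `"stage"` (curves on replicate-mean TPM per stage) or
#'   `"sample"`.
#' @param k Rank cutoff for the summary.
#' @return List with `curves` (long `data.frame`: group, rank, fraction) and
#'   `top_k` (`data.frame`: group, k, fraction).
#' @export
complexity_profile <- function(tpm, by = c("stage", "sample"), k = 10) {
  stopifnot(inherits(tpm, "expr_matrix"))
  by <- match.arg(by)
  groups <- if (by == "stage") {
    m <- stage_means(tpm)
    stats::setNames(lapply(colnames(m), function(s) m[, s]), colnames(m))
  } else {
    stats::setNames(lapply(colnames(tpm$values),
                           function(s) tpm$values[, s]),
                    colnames(tpm$values))
  }
  curves <- do.call(rbind, lapply(names(groups), function(g) {
    cv <- complexity_curve(groups[[g]])
    data.frame(group = g, rank = seq_along(cv), fraction = unname(cv),
               stringsAsFactors = FALSE)
  }))
  topk <- data.frame(
    group = names(groups), k = k,
    fraction = vapply(groups, top_k_fraction, numeric(1), k = k),
    row.names = NULL, stringsAsFactors = FALSE)
  list(curves = curves, top_k = topk)
}
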
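# Independent oracles and fixture builders. Everything here works on plain
# data frames / base R so it shares no code path with the package.

# build a transcript_set from a compact list:
#   list(t1 = list(chrom = "chr1", strand = "+", gene = "g1",
#                  exons = list(c(1, 100), c(201, 300))), ...)
make_ts <- function(spec, source = "novel", biotype = "other") {
  rows <- do.call(rbind, lapply(names(spec), function(id) {
    s <- spec[[id]]
    ex <- do.call(rbind, s$exons)
    data.frame(chrom = s$chrom, start = ex[, 1], end = ex[, 2],
               strand = s$strand, transcript_id = id,
               gene_id = if (is.null(s$gene)) paste0("g_", id) else s$gene,
               stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand,
    transcript_id = rows$transcript_id, gene_id = rows$gene_id)
  transcript_set(gr, source = source, biotype = biotype)
}

# small expression matrix with a 4-stage x nrep design
make_expr <- function(values, kind = "TPM",
                      stages = c("D0", "D15", "D85", "Y2")) {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  nrep <- ncol(values) / length(stages)
  meta <- data.frame(
    sample_id = colnames(values),
    stage = rep(stages, each = nrep),
    replicate = rep(seq_len(nrep), length(stages)),
    stringsAsFactors = FALSE)
  expression_matrix(values, kind = kind, metadata = meta,
                    stage_order = stages)
}

# exon data.frame view of a transcript_set, for feeding the oracles
exon_df <- function(ts) {
  ex <- ts$exons
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    transcript_id = as.character(S4Vectors::mcols(ex)$transcript_id),
    gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
    stringsAsFactors = FALSE)
}

# --- brute-force positional classification oracle ------------------------
# Linear scans over raw exon tables, following the documented cascade.
oracle_classify <- function(nov, ref) {
  ovl <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
  ref_by_tx <- split(ref, ref$transcript_id)
  chain_key <- function(df) {
    df <- df[order(df$start), ]
    if (nrow(df) == 1L) return(NA_character_)
    paste(df$chrom[1], df$strand[1],
          paste(df$end[-nrow(df)] + 1L, df$start[-1L] - 1L,
                sep = "-", collapse = ","))
  }
  ref_chains <- stats::na.omit(vapply(ref_by_tx, chain_key, character(1)))
  ref_introns <- do.call(rbind, lapply(ref_by_tx, function(df) {
    df <- df[order(df$start), ]
    if (nrow(df) < 2L) return(NULL)
    data.frame(chrom = df$chrom[1],
               start = df$end[-nrow(df)] + 1L,
               end = df$start[-1L] - 1L, stringsAsFactors = FALSE)
  }))
  bodies <- do.call(rbind, lapply(split(ref, ref$gene_id), function(df) {
    data.frame(chrom = df$chrom[1], start = min(df$start),
               end = max(df$end), stringsAsFactors = FALSE)
  }))
  out <- character(0)
  for (id in unique(nov$transcript_id)) {
    t_ex <- nov[nov$transcript_id == id, ]
    t_ex <- t_ex[order(t_ex$start), ]
    sense <- FALSE
    anti <- FALSE
    for (i in seq_len(nrow(t_ex))) {
      same_chr <- ref$chrom == t_ex$chrom[i]
      hit <- same_chr & ovl(t_ex$start[i], t_ex$end[i], ref$start, ref$end)
      sense <- sense || any(hit & ref$strand == t_ex$strand[i])
      anti <- anti || any(hit & ref$strand != t_ex$strand[i])
    }
    key <- chain_key(t_ex)
    known <- !is.na(key) && key %in% ref_chains
    span <- c(min(t_ex$start), max(t_ex$end))
    in_intron <- !is.null(ref_introns) &&
      any(ref_introns$chrom == t_ex$chrom[1] &
            ref_introns$start <= span[1] & span[2] <= ref_introns$end)
    in_body <- any(bodies$chrom == t_ex$chrom[1] &
                     ovl(span[1], span[2], bodies$start, bodies$end))
    out[id] <- if (sense && known) "rejected_known"
    else if (sense) "sense_overlapping"
    else if (anti) "antisense"
    else if (in_intron) "intronic"
    else if (!in_body) "lincRNA"
    else "rejected_known"
  }
  out
}

# random annotation + random query transcripts for classifier equivalence
random_annotation_df <- function(n_genes, chroms = c("cA", "cB")) {
  rows <- list()
  for (g in seq_len(n_genes)) {
    chrom <- sample(chroms, 1)
    n_ex <- sample(1:4, 1)
    start <- sample.int(900000L, 1)
    elen <- sample(100:800, n_ex, replace = TRUE)
    ilen <- if (n_ex > 1) sample(200:3000, n_ex - 1, replace = TRUE) else
      integer()
    st <- start + cumsum(c(0L, elen[-n_ex] + ilen))
    rows[[g]] <- data.frame(
      chrom = chrom, start = st, end = st + elen - 1L,
      strand = sample(c("+", "-"), 1),
      transcript_id = sprintf("rt%03d", g),
      gene_id = sprintf("rg%03d", g), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

random_transcripts_df <- function(n, chroms = c("cA", "cB")) {
  rows <- list()
  for (k in seq_len(n)) {
    chrom <- sample(chroms, 1)
    n_ex <- sample(1:3, 1)
    start <- sample.int(950000L, 1)
    elen <- sample(80:600, n_ex, replace = TRUE)
    ilen <- if (n_ex > 1) sample(100:2000, n_ex - 1, replace = TRUE) else
      integer()
    st <- start + cumsum(c(0L, elen[-n_ex] + ilen))
    rows[[k]] <- data.frame(
      chrom = chrom, start = st, end = st + elen - 1L,
      strand = sample(c("+", "-"), 1),
      transcript_id = sprintf("q%04d", k),
      gene_id = sprintf("qg%04d", k), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

df_to_ts <- function(df, source = "novel", biotype = "other") {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom, ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand, transcript_id = df$transcript_id,
    gene_id = df$gene_id)
  transcript_set(gr, source = source, biotype = biotype)
}

# --- other oracles -------------------------------------------------------

# step-up BH by direct looping (independent of stats::p.adjust)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# exhaustive-enumeration hypergeometric upper tail
oracle_hyper_enum <- function(N, K, n, ov) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= ov))
}

# adjusted Rand index from the contingency table
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# product-moment r and two-sided t p-value, written out longhand
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# longest forward-frame ORF by scanning every (start, stop) pair
oracle_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- 0L
  codon <- function(i) substr(s, i, i + 2L)
  for (i in seq_len(max(0L, n - 2L))) {
    if (codon(i) != "ATG") next
    j <- i + 3L
    while (j <= n - 2L) {
      if (codon(j) %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, (j - i) / 3L)
        break
      }
      j <- j + 3L
    }
  }
  as.integer(best)
}
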
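# Independent oracles: straight-line transcriptions of the definitions,
# written separately from the implementation paths they check.

# Type-7 quantile at p = 0.95 by explicit sort-and-interpolate.
oracle_q95 <- function(v) {
  s <- sort(v)
  m <- length(s)
  if (m == 1L) return(s)
  h <- (m - 1) * 0.95
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[min(lo + 2, m)] - s[lo + 1])
}

# Line-by-line transcription of the usage formulas: e_j = sum_i x_ij / n,
# r_ij = x_ij / e_j (0 when e_j = 0), y_ij = min(r_ij / Q95_i, 1) when
# Q95_i > 0.05 else min(r_ij / 0.05, 1).
oracle_usage <- function(x) {
  n <- nrow(x); m <- ncol(x)
  e <- numeric(m)
  for (j in seq_len(m)) {
    s <- 0
    for (i in seq_len(n)) s <- s + x[i, j]
    e[j] <- s / n
  }
  r <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    r[i, j] <- if (e[j] == 0) 0 else x[i, j] / e[j]
  }
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- oracle_q95(r[i, ])
  y <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    denom <- if (q[i] > 0.05) q[i] else 0.05
    y[i, j] <- min(r[i, j] / denom, 1)
  }
  list(e = e, q95 = q, y = y)
}

# Brute-force all-pairs overlap assignment: feature x transcript loop.
oracle_annotate <- function(features, gene) {
  lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    hits <- character()
    for (tx in gene$transcripts) {
      if (f$chrom != tx$chrom) next
      if (f$strand != "*" && tx$strand != "*" && f$strand != tx$strand) next
      ts <- tx$span[["start"]]; te <- tx$span[["end"]]
      ok <- if (f$kind == "junction") {
        ts <= f$donor && f$acceptor < te
      } else {
        f$start < te && ts < f$end
      }
      if (ok) hits <- c(hits, tx$transcript_id)
    }
    sort(hits)
  })
}

# Product-limit estimator as an explicit loop over distinct event times.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(0); risk <- numeric(0)
  for (t in ts) {
    r <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / r)
    surv <- c(surv, s); risk <- c(risk, r)
  }
  list(times = ts, surv = surv, at_risk = risk)
}

# Random non-negative quant matrix with names.
random_quant <- function(n, m, zero_frac = 0.1) {
  v <- matrix(stats::rexp(n * m, rate = 0.1), n, m)
  v[stats::runif(n * m) < zero_frac] <- 0
  rownames(v) <- sprintf("F%02d", seq_len(n))
  colnames(v) <- sprintf("S%02d", seq_len(m))
  v
}

# Minimal GTF writer for hand-built test genes.
write_test_gtf <- function(path, rows) {
  # rows: data.frame gene_id, tx_id, start1, end1, chrom, strand, symbol
  lines <- sprintf(
    '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s";',
    rows$chrom, rows$start1, rows$end1, rows$strand, rows$gene_id,
    rows$tx_id, rows$symbol)
  writeLines(lines, path)
  path
}

eval_km_at <- function(cv, t) cv$survival[max(which(cv$times <= t))]
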
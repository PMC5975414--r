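# Internal coordinate convention: 0-based half-open [start, end).
# GTF files and feature-ID strings are 1-based inclusive; conversion happens
# only at I/O boundaries.

#' Construct a genomic interval
#'
#' Intervals are 0-based half-open. Strand is `"+"`, `"-"` or `"*"`
#' (unknown).
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start 0-based inclusive start, `>= 0`.
#' @param end 0-based exclusive end, `> start`.
#' @param strand One of `"+"`, `"-"`, `"*"`.
#' @return A list of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || start < 0) stop("interval start must be >= 0")
  if (is.na(end) || end <= start) stop("interval end must be > start")
  if (!strand %in% c("+", "-", "*")) stop("strand must be '+', '-' or '*'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

new_transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  # exons: data.frame(start, end), 0-based half-open, sorted, non-overlapping
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1 &&
      any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("exons overlap within transcript ", transcript_id)
  }
  structure(list(
    transcript_id = transcript_id,
    gene_id = gene_id,
    chrom = chrom,
    strand = strand,
    exons = exons,
    span = c(start = exons$start[1], end = exons$end[nrow(exons)])
  ), class = "transcript_model")
}

new_gene_model <- function(gene_id, symbol, aliases, transcripts) {
  stopifnot(length(transcripts) >= 1)
  structure(list(gene_id = gene_id, symbol = symbol,
                 aliases = aliases, transcripts = transcripts),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene %s (%s), %d transcript(s)\n",
              x$symbol, x$gene_id, length(x$transcripts)))
  for (tx in x$transcripts) {
    cat(sprintf("  %s  %s:%d-%d(%s)  %d exons\n", tx$transcript_id, tx$chrom,
                tx$span["start"], tx$span["end"], tx$strand, nrow(tx$exons)))
  }
  invisible(x)
}

# Pull a quoted attribute value out of a GTF column-9 string; NA if absent.
gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, ' "([^"]*)"'), attrs))
  vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_, "")
}

#' Read gene models from a GTF file
#'
#' Parses exon features from an Ensembl/UCSC-dialect GTF (tab-separated,
#' nine columns, attributes `gene_id "..."; transcript_id "..."`; optional
#' `gene_name` and `gene_alias`). GTF coordinates (1-based inclusive) are
#' converted to the internal 0-based half-open convention. Book-ended or
#' overlapping exon records within a transcript are merged. Genes are
#' returned sorted by `gene_id`, transcripts by `transcript_id`.
#'
#' @param gtf_path Path to a GTF file (plain or gzip).
#' @return A named list of `gene_model` objects (names are gene IDs).
#' @export
read_gene_models <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF file not found: ", gtf_path)
  lines <- readLines(if (grepl("\\.gz$", gtf_path)) gzfile(gtf_path) else gtf_path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(list())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("malformed GTF line ", idx[which(nf != 9L)[1]],
         ": expected 9 tab-separated columns, got ", nf[nf != 9L][1])
  }
  tab <- do.call(rbind, fields)
  ex <- tab[, 3] == "exon"
  if (!any(ex)) return(list())
  tab <- tab[ex, , drop = FALSE]
  lineno <- idx[ex]
  start1 <- suppressWarnings(as.numeric(tab[, 4]))
  end1 <- suppressWarnings(as.numeric(tab[, 5]))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
  if (length(bad)) {
    stop("malformed GTF line ", lineno[bad[1]], ": invalid coordinates '",
         tab[bad[1], 4], "', '", tab[bad[1], 5], "'")
  }
  strand <- tab[, 7]
  strand[!strand %in% c("+", "-")] <- "*"
  gene_id <- gtf_attr(tab[, 9], "gene_id")
  tx_id <- gtf_attr(tab[, 9], "transcript_id")
  bad <- which(is.na(gene_id) | is.na(tx_id))
  if (length(bad)) {
    stop("malformed GTF line ", lineno[bad[1]],
         ": missing gene_id or transcript_id attribute")
  }
  symbol <- gtf_attr(tab[, 9], "gene_name")
  alias <- gtf_attr(tab[, 9], "gene_alias")

  exdf <- data.frame(
    gene_id = gene_id, transcript_id = tx_id, chrom = tab[, 1],
    start = start1 - 1, end = end1, strand = strand,
    symbol = symbol, alias = alias, stringsAsFactors = FALSE
  )

  tx_gene <- tapply(exdf$gene_id, exdf$transcript_id,
                    function(g) length(unique(g)))
  if (any(tx_gene > 1L)) {
    stop("duplicate transcript ID across genes: ",
         names(tx_gene)[tx_gene > 1L][1])
  }

  models <- list()
  for (g in sort(unique(exdf$gene_id))) {
    gdf <- exdf[exdf$gene_id == g, , drop = FALSE]
    txs <- list()
    for (t in sort(unique(gdf$transcript_id))) {
      tdf <- gdf[gdf$transcript_id == t, , drop = FALSE]
      if (length(unique(tdf$chrom)) > 1L || length(unique(tdf$strand)) > 1L) {
        stop("transcript ", t, " has exons on multiple chromosomes/strands")
      }
      exons <- merge_exons(tdf$start, tdf$end)
      txs[[t]] <- new_transcript_model(t, g, tdf$chrom[1], tdf$strand[1], exons)
    }
    sym <- stats::na.omit(unique(gdf$symbol))
    ali <- stats::na.omit(unique(gdf$alias))
    aliases <- if (length(ali)) unique(unlist(strsplit(ali, ","))) else character()
    models[[g]] <- new_gene_model(
      g, symbol = if (length(sym)) sym[1] else g,
      aliases = aliases, transcripts = txs
    )
  }
  syms <- vapply(models, `[[`, "", "symbol")
  if (anyDuplicated(syms)) {
    stop("gene symbol not unique across models: ", syms[duplicated(syms)][1])
  }
  models
}

# Merge overlapping or book-ended exon records (0-based half-open input).
merge_exons <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (k in seq_along(start)[-1]) {
    if (start[k] <= me) {               # overlap or book-ended: extend
      me <- max(me, end[k])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[k]; me <- end[k]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Write gene models back to GTF
#'
#' Emits one `exon` line per exon, 1-based inclusive coordinates, with
#' `gene_id`, `transcript_id`, `gene_name` and `gene_alias` attributes, in
#' deterministic (gene, transcript, start) order. Re-reading the file with
#' [read_gene_models()] reproduces identical models.
#'
#' @param models Named list of `gene_model` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  out <- character()
  for (gm in models[order(names(models))]) {
    for (tx in gm$transcripts[order(names(gm$transcripts))]) {
      attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";%s',
                       gm$gene_id, tx$transcript_id, gm$symbol,
                       if (length(gm$aliases))
                         sprintf(' gene_alias "%s";',
                                 paste(gm$aliases, collapse = ",")) else "")
      out <- c(out, sprintf("%s\tspliceusage\texon\t%d\t%d\t.\t%s\t.\t%s",
                            tx$chrom, tx$exons$start + 1, tx$exons$end,
                            if (tx$strand == "*") "." else tx$strand, attrs))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Export gene models as BED12
#'
#' One line per transcript: chrom, span, transcript ID, block layout from
#' the exon structure. Coordinates are 0-based half-open as BED requires.
#'
#' @param models Named list of `gene_model` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_bed12 <- function(models, path) {
  out <- character()
  for (gm in models[order(names(models))]) {
    for (tx in gm$transcripts[order(names(gm$transcripts))]) {
      s <- tx$span["start"]; e <- tx$span["end"]
      sizes <- tx$exons$end - tx$exons$start
      starts <- tx$exons$start - s
      out <- c(out, sprintf(
        "%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
        tx$chrom, s, e, tx$transcript_id,
        if (tx$strand == "*") "." else tx$strand, s, e, nrow(tx$exons),
        paste0(paste(sizes, collapse = ","), ","),
        paste0(paste(starts, collapse = ","), ",")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Parse a quantification feature ID into kind and interval
#'
#' Exon IDs follow `chrom:start-end:strand` and junction IDs
#' `chrom:pos:strand,chrom:pos:strand` (both 1-based inclusive in the ID
#' string, as in TCGA level-3 row names). The return value uses the
#' internal 0-based half-open convention; a junction is represented by its
#' two single-base anchors (donor, acceptor) plus the interval spanning
#' them.
#'
#' @param feature_id A single feature ID string.
#' @return A list with `kind` (`"exon"` or `"junction"`) and `interval`
#'   (a [genomic_interval()]; for junctions with extra fields `donor` and
#'   `acceptor`, the 0-based anchor positions).
#' @export
parse_feature_id <- function(feature_id) {
  stopifnot(is.character(feature_id), length(feature_id) == 1L)
  exon_re <- "^([^:,[:space:]]+):([0-9]+)-([0-9]+):([+*.-])$"
  anchor_re <- "^([^:,[:space:]]+):([0-9]+):([+*.-])$"
  if (grepl(exon_re, feature_id)) {
    m <- regmatches(feature_id, regexec(exon_re, feature_id))[[1]]
    strand <- if (m[5] %in% c("+", "-")) m[5] else "*"
    return(list(kind = "exon",
                interval = genomic_interval(m[2], as.numeric(m[3]) - 1,
                                            as.numeric(m[4]), strand)))
  }
  parts <- strsplit(feature_id, ",", fixed = TRUE)[[1]]
  if (length(parts) == 2L && all(grepl(anchor_re, parts))) {
    m1 <- regmatches(parts[1], regexec(anchor_re, parts[1]))[[1]]
    m2 <- regmatches(parts[2], regexec(anchor_re, parts[2]))[[1]]
    if (m1[2] != m2[2]) {
      stop("junction anchors on different chromosomes in '", feature_id, "'")
    }
    a1 <- as.numeric(m1[3]) - 1; a2 <- as.numeric(m2[3]) - 1
    donor <- min(a1, a2); acceptor <- max(a1, a2)
    strand <- if (m1[4] %in% c("+", "-")) m1[4] else "*"
    iv <- genomic_interval(m1[2], donor, acceptor + 1, strand)
    iv$donor <- donor; iv$acceptor <- acceptor
    return(list(kind = "junction", interval = iv))
  }
  stop("cannot parse feature ID '", feature_id, "'; expected ",
       "'chrom:start-end:strand' (exon) or ",
       "'chrom:pos:strand,chrom:pos:strand' (junction), ",
       "1-based inclusive coordinates")
}

#' Parse a vector of feature IDs into a feature table
#'
#' Convenience wrapper around [parse_feature_id()] producing the
#' data frame consumed by [annotate_features()].
#'
#' @param feature_ids Character vector of feature IDs.
#' @return Data frame with columns `feature_id`, `kind`, `chrom`, `start`,
#'   `end`, `strand`, `donor`, `acceptor` (anchors `NA` for exons).
#' @export
parse_feature_table <- function(feature_ids) {
  parsed <- lapply(feature_ids, parse_feature_id)
  data.frame(
    feature_id = feature_ids,
    kind = vapply(parsed, `[[`, "", "kind"),
    chrom = vapply(parsed, function(p) p$interval$chrom, ""),
    start = vapply(parsed, function(p) p$interval$start, 0),
    end = vapply(parsed, function(p) p$interval$end, 0),
    strand = vapply(parsed, function(p) p$interval$strand, ""),
    donor = vapply(parsed, function(p) p$interval$donor %||% NA_real_, 0),
    acceptor = vapply(parsed, function(p) p$interval$acceptor %||% NA_real_, 0),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Annotate quantified features to a gene's transcripts by overlap
#'
#' An exon feature is assigned to every transcript whose genomic span it
#' overlaps by at least one base; a junction is assigned to every
#' transcript whose span contains both anchors. Features with unknown
#' strand match either strand; a known-vs-known strand mismatch excludes
#' the match. A feature on a different chromosome simply gets no
#' assignment. `gene_id` is set iff at least one transcript matched.
#'
#' @param features Data frame as produced by [parse_feature_table()] (one
#'   row per feature; 0-based half-open coordinates).
#' @param gene A `gene_model`.
#' @return Data frame in input order with columns `feature_id`, `kind`,
#'   `gene_id` (`NA` if unassigned) and list-column `transcript_ids`.
#' @export
annotate_features <- function(features, gene) {
  stopifnot(inherits(gene, "gene_model"), length(gene$transcripts) >= 1)
  txs <- gene$transcripts
  tx_gr <- GenomicRanges::GRanges(
    seqnames = vapply(txs, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(txs, function(t) t$span[["start"]], 0) + 1,
      end = vapply(txs, function(t) t$span[["end"]], 0)),
    strand = vapply(txs, `[[`, "", "strand")
  )
  tx_ids <- vapply(txs, `[[`, "", "transcript_id")

  f_gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1, end = features$end),
    strand = features$strand
  )

  is_junc <- features$kind == "junction"
  hits_any <- GenomicRanges::findOverlaps(f_gr, tx_gr, type = "any",
                                          ignore.strand = FALSE)
  hits_within <- GenomicRanges::findOverlaps(f_gr, tx_gr, type = "within",
                                             ignore.strand = FALSE)
  pick <- function(i) {
    h <- if (is_junc[i]) hits_within else hits_any
    unname(sort(tx_ids[S4Vectors::subjectHits(h)[S4Vectors::queryHits(h) == i]]))
  }
  tx_lists <- lapply(seq_len(nrow(features)), pick)
  matched <- lengths(tx_lists) > 0
  data.frame(
    feature_id = features$feature_id,
    kind = features$kind,
    gene_id = ifelse(matched, gene$gene_id, NA_character_),
    transcript_ids = I(tx_lists),
    stringsAsFactors = FALSE
  )
}
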
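# Seeded synthetic cohort generator emulating TCGA level-3 style inputs:
# gene models with a cassette (skipped) exon, exon/junction/isoform/gene
# quantification TSVs, and a raw-style clinical table. A JSON manifest
# records the ground truth (group labels, inclusion levels, survival
# parameters, expected harmonized category counts) so downstream results
# can be verified without re-deriving them.

#' Build a fixture configuration
#'
#' Defaults describe the canonical study condition the package is tested
#' under: a two-group cohort (tumor-like vs normal-like) of 200 samples
#' where one cassette exon is included at level 0.9 in the tumor-like
#' group and 0.1 in the normal-like group, with moderate log-normal
#' multiplicative noise (sdlog 0.15, about 15% CV of residual
#' exon-to-gene ratio noise) on all quantifications, and
#' exponential survival whose rate increases with the expression of the
#' cassette-containing isoform.
#'
#' @param seed Integer seed (mandatory; all generators derive from it).
#' @param n_genes Number of genes.
#' @param transcripts_per_gene Transcripts per gene (>= 2; the first
#'   carries the cassette exon, later ones skip it).
#' @param exons_per_transcript Exons in the full transcript.
#' @param cassette_index Index (1-based, internal) of the cassette exon.
#' @param n_samples Cohort size.
#' @param group_fractions Named proportions summing to 1.
#' @param inclusion List: `high_group` label, `included` and `excluded`
#'   inclusion levels of the cassette isoform.
#' @param noise sdlog of the multiplicative log-normal quantification
#'   noise.
#' @param survival List: `baseline` hazard (events/day), `effect` (log
#'   hazard ratio across the 0-1 scaled isoform expression range),
#'   `censor_max` (days; follow-up uniform on (0, censor_max]).
#' @return List of class `fixture_config`.
#' @export
fixture_config <- function(seed,
                           n_genes = 1,
                           transcripts_per_gene = 2,
                           exons_per_transcript = 7,
                           cassette_index = 4,
                           n_samples = 200,
                           group_fractions = c("Solid Tissue Normal" = 0.5,
                                               "Primary Solid Tumor" = 0.5),
                           inclusion = list(high_group = "Primary Solid Tumor",
                                            included = 0.9, excluded = 0.1),
                           noise = 0.15,
                           survival = list(baseline = 0.0008, effect = 1.2,
                                           censor_max = 2500)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(sum(group_fractions) - 1) < 1e-9,
            transcripts_per_gene >= 2,
            cassette_index > 1, cassette_index < exons_per_transcript,
            n_samples >= 2, noise >= 0)
  if (!inclusion$high_group %in% names(group_fractions)) {
    stop("inclusion$high_group must be one of the group labels")
  }
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 transcripts_per_gene = transcripts_per_gene,
                 exons_per_transcript = exons_per_transcript,
                 cassette_index = cassette_index, n_samples = n_samples,
                 group_fractions = group_fractions, inclusion = inclusion,
                 noise = noise, survival = survival),
            class = "fixture_config")
}

# Deterministic block assignment of samples to groups (exact counts).
fixture_groups <- function(config) {
  m <- config$n_samples
  counts <- diff(c(0, round(cumsum(config$group_fractions) * m)))
  rep(names(config$group_fractions), counts)
}

fixture_sample_ids <- function(config) {
  sprintf("SAMP%04d", seq_len(config$n_samples))
}

#' Generate synthetic gene models (GTF + manifest entry)
#'
#' Genes are non-overlapping on chr1; within a gene, transcripts share the
#' flanking exons and differ by the cassette exon: the first transcript
#' includes every exon, transcript k (k >= 2) skips one internal exon
#' starting at the configured cassette index (the classic skipped-exon
#' pattern).
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @return List with `gtf` (path) and `genes` (manifest entries: per gene
#'   the gene_id, symbol, alias, and per transcript its exon count and
#'   skipped exon index).
#' @export
make_gene_models <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exon_len <- 200; intron_len <- 800; gene_gap <- 100000
  genes <- list()
  lines <- character()
  for (g in seq_len(config$n_genes)) {
    gene_id <- as.character(1000 + g)
    symbol <- sprintf("GENE%d", g)
    alias <- sprintf("G%dALT", g)
    offset <- (g - 1) * gene_gap + 10000
    ex_start0 <- offset + (seq_len(config$exons_per_transcript) - 1) *
      (exon_len + intron_len)
    ex_end0 <- ex_start0 + exon_len
    txs <- list()
    for (k in seq_len(config$transcripts_per_gene)) {
      tx_id <- sprintf("TX%d.%d", g, k)
      if (k == 1) {
        skip <- NA_integer_
        idx <- seq_len(config$exons_per_transcript)
      } else {
        internal <- 2:(config$exons_per_transcript - 1)
        skip <- internal[((config$cassette_index - 2) + (k - 2)) %%
                           length(internal) + 1]
        idx <- setdiff(seq_len(config$exons_per_transcript), skip)
      }
      for (i in idx) {
        lines <- c(lines, sprintf(
          'chr1\tfixtures\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_alias "%s";',
          ex_start0[i] + 1, ex_end0[i], gene_id, tx_id, symbol, alias))
      }
      txs[[tx_id]] <- list(transcript_id = tx_id, n_exons = length(idx),
                           skipped_exon = skip)
    }
    genes[[gene_id]] <- list(gene_id = gene_id, symbol = symbol,
                             alias = alias,
                             exon_starts0 = ex_start0, exon_ends0 = ex_end0,
                             transcripts = txs)
  }
  gtf <- file.path(dir, "models.gtf")
  writeLines(lines, gtf)
  list(gtf = gtf, genes = genes)
}

#' Generate synthetic quantification matrices (TSVs + manifest entry)
#'
#' Per sample a gene abundance is drawn log-normally and split across the
#' isoforms by the group-dependent inclusion level of the cassette
#' isoform; exon values are the sums of the abundances of the isoforms
#' containing the exon, junction values the sums over isoforms carrying
#' that exon adjacency, each under multiplicative log-normal noise.
#'
#' @param config A [fixture_config()].
#' @param models Output of [make_gene_models()].
#' @param dir Output directory.
#' @return List with TSV paths (`exon`, `junction`, `isoform`, `gene`),
#'   the sample `groups`, per-group `inclusion` levels, and
#'   `designated_isoform` (id + per-sample expression driving survival).
#' @export
make_quantifications <- function(config, models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)
  m <- config$n_samples
  samples <- fixture_sample_ids(config)
  groups <- fixture_groups(config)
  p_incl <- ifelse(groups == config$inclusion$high_group,
                   config$inclusion$included, config$inclusion$excluded)

  exon_rows <- list(); junc_rows <- list(); iso_rows <- list()
  gene_rows <- list()
  designated <- NULL
  for (gi in seq_along(models$genes)) {
    gene <- models$genes[[gi]]
    abundance <- stats::rlnorm(m, meanlog = log(1000), sdlog = 0.5)
    tx_ids <- names(gene$transcripts)
    n_tx <- length(tx_ids)
    # base (noise-free) isoform abundances: cassette isoform gets the
    # inclusion fraction, the rest split the remainder equally
    iso_base <- matrix(0, n_tx, m, dimnames = list(tx_ids, samples))
    iso_base[1, ] <- abundance * p_incl
    if (n_tx > 1) {
      for (k in 2:n_tx) iso_base[k, ] <- abundance * (1 - p_incl) / (n_tx - 1)
    }
    # which exons each isoform contains
    E <- config$exons_per_transcript
    contains <- matrix(TRUE, n_tx, E, dimnames = list(tx_ids, NULL))
    for (k in seq_len(n_tx)) {
      sk <- gene$transcripts[[k]]$skipped_exon
      if (!is.na(sk)) contains[k, sk] <- FALSE
    }
    noise <- function() matrix(stats::rlnorm(m, 0, config$noise), nrow = 1)
    for (i in seq_len(E)) {
      fid <- sprintf("chr1:%d-%d:+", gene$exon_starts0[i] + 1,
                     gene$exon_ends0[i])
      vals <- colSums(iso_base[contains[, i], , drop = FALSE]) * noise()
      exon_rows[[fid]] <- as.numeric(vals)
    }
    # junctions: all adjacencies realized by at least one isoform
    adjacency <- list()
    for (k in seq_len(n_tx)) {
      idx <- which(contains[k, ])
      for (a in seq_len(length(idx) - 1)) {
        key <- paste(idx[a], idx[a + 1], sep = "-")
        adjacency[[key]] <- union(adjacency[[key]], tx_ids[k])
      }
    }
    for (key in names(adjacency)) {
      ij <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
      fid <- sprintf("chr1:%d:+,chr1:%d:+",
                     gene$exon_ends0[ij[1]], gene$exon_starts0[ij[2]] + 1)
      vals <- colSums(iso_base[adjacency[[key]], , drop = FALSE]) * noise()
      junc_rows[[fid]] <- as.numeric(vals)
    }
    for (k in seq_len(n_tx)) {
      iso_rows[[tx_ids[k]]] <- as.numeric(iso_base[k, ] *
                                            stats::rlnorm(m, 0, config$noise))
    }
    gene_rows[[gene$gene_id]] <- as.numeric(abundance)
    if (gi == 1) {
      designated <- list(transcript_id = tx_ids[1],
                         expression = as.numeric(iso_rows[[tx_ids[1]]]))
    }
  }
  write_rows <- function(rows, path) {
    mat <- do.call(rbind, rows)
    df <- data.frame(feature_id = names(rows),
                     matrix(sprintf("%.4f", mat), nrow = length(rows),
                            dimnames = list(NULL, samples)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- list(
    exon = write_rows(exon_rows, file.path(dir, "exon.tsv")),
    junction = write_rows(junc_rows, file.path(dir, "junction.tsv")),
    isoform = write_rows(iso_rows, file.path(dir, "isoform.tsv")),
    gene = write_rows(gene_rows, file.path(dir, "gene.tsv"))
  )
  c(paths, list(
    samples = samples, groups = groups,
    inclusion = stats::setNames(
      ifelse(names(config$group_fractions) == config$inclusion$high_group,
             config$inclusion$included, config$inclusion$excluded),
      names(config$group_fractions)),
    designated_isoform = designated))
}

# Generator-side category lookup tables: the ground truth the clinical
# module's rules are verified against. Values are sampled per category, so
# expected counts are known by construction, independent of the rules code.
clin_cat_specs <- function() {
  list(
    pack_years = list(
      cats = c("less than 10", "less than 100", "greater than 100",
               "UNDEFINED"),
      prob = c(0.3, 0.35, 0.1, 0.25),
      draw = list(function(n) sample(0:9, n, TRUE),
                  function(n) sample(10:99, n, TRUE),
                  function(n) sample(100:200, n, TRUE),
                  function(n) rep("", n))),
    pathology_stage = list(
      cats = c("I", "II", "III", "IV", "X", "UNDEFINED"),
      prob = c(0.2, 0.25, 0.25, 0.1, 0.05, 0.15),
      draw = list(function(n) sample(c("Stage I", "Stage IA", "Stage IB"), n, TRUE),
                  function(n) sample(c("Stage II", "Stage IIA", "Stage IIB"), n, TRUE),
                  function(n) sample(c("Stage III", "Stage IIIA", "Stage IIIC"), n, TRUE),
                  function(n) sample(c("Stage IV", "Stage IVA"), n, TRUE),
                  function(n) rep("Stage X", n),
                  function(n) sample(c("", "Indeterminate"), n, TRUE))),
    risk_factor = list(
      cats = c("others", "Alcohol consumption", "hepatitis b", "hepatitis c",
               "UNDEFINED"),
      prob = c(0.2, 0.3, 0.2, 0.15, 0.15),
      draw = list(function(n) sample(c("Alpha-1 antitrypsin deficiency",
                                       "hemochromatosis", "other"), n, TRUE),
                  function(n) rep("Alcohol consumption", n),
                  function(n) rep("hepatitis b", n),
                  function(n) rep("hepatitis c", n),
                  function(n) rep("", n))),
    alcohol_per_day = list(
      cats = c("0", ">0", "UNDEFINED"),
      prob = c(0.4, 0.35, 0.25),
      draw = list(function(n) rep("0", n),
                  function(n) sample(c("0.5", "1", "2.5", "4"), n, TRUE),
                  function(n) rep("", n))),
    pregnancies = list(
      cats = c("1", "2", "3", "4", "5", ">5", "UNDEFINED"),
      prob = c(0.12, 0.15, 0.12, 0.08, 0.06, 0.07, 0.4),
      draw = list(function(n) rep("1", n), function(n) rep("2", n),
                  function(n) rep("3", n), function(n) rep("4", n),
                  function(n) rep("5", n),
                  function(n) as.character(sample(6:10, n, TRUE)),
                  function(n) sample(c("", "0"), n, TRUE)))
  )
}

#' Generate a synthetic raw clinical table (TSV + manifest entry)
#'
#' Survival times are exponential with a rate that increases with the
#' designated isoform's expression (0-1 scaled within the cohort);
#' censoring comes from an independent uniform follow-up. Categorical
#' fields are drawn category-first from fixed tables, so the manifest's
#' expected harmonized counts are ground truth by construction.
#'
#' @param config A [fixture_config()].
#' @param quants Output of [make_quantifications()].
#' @param dir Output directory.
#' @return List with `clinical` (TSV path), `expected_counts` (per
#'   variable: category -> count), `n_events`, and the true survival
#'   parameters.
#' @export
make_clinical <- function(config, quants, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 2L)
  m <- config$n_samples
  samples <- quants$samples
  expr <- quants$designated_isoform$expression
  z <- if (max(expr) > min(expr)) (expr - min(expr)) / (max(expr) - min(expr))
       else rep(0, m)
  rate <- config$survival$baseline * exp(config$survival$effect * z)
  t_death <- stats::rexp(m, rate)
  t_censor <- stats::runif(m, 1, config$survival$censor_max)
  dead <- t_death <= t_censor
  day_to_death <- ifelse(dead, as.character(pmax(round(t_death), 1)), "")
  follow_up <- ifelse(dead, "", as.character(pmax(round(t_censor), 1)))

  specs <- clin_cat_specs()
  expected <- list()
  raw_cols <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    cat_idx <- sample.int(length(sp$cats), m, replace = TRUE, prob = sp$prob)
    raw <- character(m)
    for (k in seq_along(sp$cats)) {
      sel <- cat_idx == k
      if (any(sel)) raw[sel] <- sp$draw[[k]](sum(sel))
    }
    tb <- table(factor(sp$cats[cat_idx], levels = sp$cats))
    expected[[nm]] <- as.list(stats::setNames(as.integer(tb), names(tb)))
    raw_cols[[nm]] <- raw
  }

  df <- data.frame(
    sample_id = samples,
    sample_type = quants$groups,
    day_to_death = day_to_death,
    `days_to_last_follow-up` = follow_up,
    number_pack_years_smoked = raw_cols$pack_years,
    pathology_stage = raw_cols$pathology_stage,
    risk_factor = raw_cols$risk_factor,
    alcohol_per_day = raw_cols$alcohol_per_day,
    number_of_pregnancies = raw_cols$pregnancies,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  path <- file.path(dir, "clinical.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(clinical = path, expected_counts = expected,
       n_events = sum(dead),
       survival_params = config$survival)
}

#' Generate a complete synthetic cohort
#'
#' Runs the three generators and writes a JSON manifest of the ground
#' truth (file paths, per-sample groups, inclusion levels, expected
#' harmonized category counts, survival parameters, event count).
#'
#' @param config A [fixture_config()].
#' @param outdir Output directory.
#' @return The manifest, invisibly (also written to
#'   `<outdir>/manifest.json`).
#' @export
simulate_cohort <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  models <- make_gene_models(config, outdir)
  quants <- make_quantifications(config, models, outdir)
  clin <- make_clinical(config, quants, outdir)
  # file entries are basenames relative to the manifest's own directory so
  # that reruns into different directories are byte-identical
  manifest <- list(
    seed = config$seed,
    files = list(gtf = basename(models$gtf), exon = basename(quants$exon),
                 junction = basename(quants$junction),
                 isoform = basename(quants$isoform),
                 gene = basename(quants$gene),
                 clinical = basename(clin$clinical)),
    genes = lapply(models$genes, function(g) list(
      gene_id = g$gene_id, symbol = g$symbol, alias = g$alias,
      transcripts = lapply(g$transcripts, function(t)
        list(transcript_id = t$transcript_id, n_exons = t$n_exons,
             skipped_exon = t$skipped_exon)))),
    samples = quants$samples,
    groups = quants$groups,
    inclusion = as.list(quants$inclusion),
    cassette_index = config$cassette_index,
    designated_isoform = quants$designated_isoform$transcript_id,
    expected_counts = clin$expected_counts,
    n_events = clin$n_events,
    survival_params = clin$survival_params
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$files <- lapply(manifest$files, function(f) file.path(outdir, f))
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' Loads `manifest.json` as written by [simulate_cohort()], resolving the
#' relative file entries against the manifest's directory.
#'
#' @param path Path to a `manifest.json`.
#' @return The manifest list with absolute file paths.
#' @export
read_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  man$files <- lapply(man$files, function(f) file.path(dirname(path), f))
  man
}
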
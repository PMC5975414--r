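# Static rendering of the three figure types: the multi-track main plot
# (clinical band, gene-expression bars, per-feature usage rows, transcript
# structure diagram), per-group isoform box plots, and Kaplan-Meier plots.

#' Construct a plot specification for the main multi-track figure
#'
#' @param gene A `gene_model` (drawn as the left-hand transcript diagram).
#' @param usage A `usage_matrix` of the gene's exon or junction features.
#' @param groups Ordered named list: group label -> character vector of
#'   sample IDs. Groups must be disjoint, non-empty and all samples must
#'   exist in the usage matrix.
#' @param gene_expr Optional gene expression vector; defaults to the one
#'   recorded in `usage`.
#' @param options Named list of layout overrides (`cell_w`, `row_h`,
#'   `left_width`, `expr_band_h`, `group_band_h`, `margin`).
#' @return Object of class `plot_spec`.
#' @export
plot_spec <- function(gene, usage, groups, gene_expr = NULL, options = list()) {
  stopifnot(inherits(gene, "gene_model"), inherits(usage, "usage_matrix"))
  if (length(groups) == 0 || is.null(names(groups))) {
    stop("groups must be a named list of sample ID vectors")
  }
  if (any(lengths(groups) == 0)) stop("empty group: ", names(groups)[lengths(groups) == 0][1])
  all_ids <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("groups must be disjoint")
  missing_ids <- setdiff(all_ids, colnames(usage$values))
  if (length(missing_ids)) {
    stop("samples absent from usage matrix: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  if (is.null(gene_expr)) gene_expr <- usage$gene_expr
  structure(list(gene = gene, usage = usage, groups = groups,
                 gene_expr = gene_expr, options = options),
            class = "plot_spec")
}

#' Order samples for display: within-group ascending gene expression
#'
#' Within each group samples are sorted from low to high gene expression;
#' ties break lexicographically by sample ID (stable); groups keep their
#' given order and are concatenated.
#'
#' @param groups Named list: label -> sample ID vector.
#' @param gene_expr Named numeric vector of per-sample gene expression.
#' @return Data frame with columns `sample_id`, `group` in render order.
#' @export
order_samples <- function(groups, gene_expr) {
  stopifnot(!is.null(names(gene_expr)))
  out <- lapply(names(groups), function(lab) {
    ids <- as.character(groups[[lab]])
    if (any(!ids %in% names(gene_expr))) {
      stop("sample without gene expression value in group '", lab, "'")
    }
    e <- gene_expr[ids]
    ids <- ids[order(e, ids, method = "radix")]
    data.frame(sample_id = ids, group = lab, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Transcript diagram geometry under a linear genomic-to-pixel scale
#'
#' Exons are boxes, introns thin lines; the scale maps the gene span
#' (earliest exon start to latest exon end over all transcripts) onto
#' `[0, pixel_width]`.
#'
#' @param gene A `gene_model`.
#' @param pixel_width Width in pixels of the diagram area.
#' @return List with `scale` (`offset`, `factor`) and `transcripts`, one
#'   entry per transcript: `transcript_id`, `line` (x1, x2) and `boxes`
#'   data frame (`x`, `width`).
#' @export
layout_transcripts <- function(gene, pixel_width) {
  stopifnot(inherits(gene, "gene_model"), pixel_width > 0)
  gmin <- min(vapply(gene$transcripts, function(t) t$span[["start"]], 0))
  gmax <- max(vapply(gene$transcripts, function(t) t$span[["end"]], 0))
  fac <- pixel_width / (gmax - gmin)
  px <- function(pos) (pos - gmin) * fac
  txs <- lapply(gene$transcripts, function(t) {
    list(transcript_id = t$transcript_id,
         line = c(x1 = px(t$span[["start"]]), x2 = px(t$span[["end"]])),
         boxes = data.frame(x = px(t$exons$start),
                            width = (t$exons$end - t$exons$start) * fac))
  })
  list(scale = c(offset = gmin, factor = fac), transcripts = txs)
}

main_layout_defaults <- list(
  margin = 10, left_width = 220, cell_w = 4, row_h = 22, row_gap = 2,
  group_band_h = 14, expr_band_h = 50, band_gap = 4
)

#' Render the multi-track main figure as SVG
#'
#' Top band: group (clinical) colors and labels. Second band: per-sample
#' gene-expression bars. Below: one row per exon/junction feature where
#' each sample's usage y is a vertical mark of height proportional to y.
#' Left panel: the gene's transcript structure diagram. Every usage cell
#' carries `data-sample-id`, `data-feature-id` and `data-y` attributes.
#'
#' @param spec A [plot_spec()].
#' @return An `svg_document`.
#' @export
render_main <- function(spec) {
  stopifnot(inherits(spec, "plot_spec"))
  opt <- utils::modifyList(main_layout_defaults, spec$options)
  ord <- order_samples(spec$groups, spec$gene_expr)
  y <- spec$usage$values
  feats <- rownames(y)
  m <- nrow(ord); nf <- length(feats)

  x0 <- opt$margin + opt$left_width + opt$band_gap   # right panel origin
  rows_top <- opt$margin + opt$group_band_h + opt$band_gap +
    opt$expr_band_h + opt$band_gap
  width <- x0 + m * opt$cell_w + opt$margin
  height <- rows_top + nf * (opt$row_h + opt$row_gap) + opt$margin

  pal <- palette_for(names(spec$groups))
  els <- character()

  # group band
  pos <- 0
  for (lab in names(spec$groups)) {
    k <- sum(ord$group == lab)
    els <- c(els, svg_rect(x0 + pos * opt$cell_w, opt$margin,
                           k * opt$cell_w, opt$group_band_h, pal[[lab]],
                           c(class = "group-band", `data-group` = lab,
                             `data-n` = k)))
    els <- c(els, svg_text(x0 + (pos + k / 2) * opt$cell_w,
                           opt$margin + opt$group_band_h - 3,
                           lab, size = 9, anchor = "middle"))
    pos <- pos + k
  }

  # gene expression bars
  e <- spec$gene_expr[ord$sample_id]
  emax <- max(e)
  etop <- opt$margin + opt$group_band_h + opt$band_gap
  for (j in seq_len(m)) {
    bh <- if (emax > 0) e[[j]] / emax * opt$expr_band_h else 0
    els <- c(els, svg_rect(x0 + (j - 1) * opt$cell_w,
                           etop + opt$expr_band_h - bh,
                           opt$cell_w * 0.9, bh, "#555555",
                           c(class = "expr-bar",
                             `data-sample-id` = ord$sample_id[j],
                             `data-e` = fmt_data(e[[j]]))))
  }

  # usage rows
  for (i in seq_len(nf)) {
    ry <- rows_top + (i - 1) * (opt$row_h + opt$row_gap)
    els <- c(els, svg_line(x0, ry + opt$row_h, x0 + m * opt$cell_w,
                           ry + opt$row_h, "#cccccc", 0.5))
    els <- c(els, svg_text(width - opt$margin, ry + opt$row_h / 2, feats[i],
                           size = 6, anchor = "end",
                           attrs = c(class = "feature-label")))
    for (j in seq_len(m)) {
      yv <- y[feats[i], ord$sample_id[j]]
      els <- c(els, svg_rect(x0 + (j - 1) * opt$cell_w,
                             ry + opt$row_h * (1 - yv),
                             opt$cell_w * 0.9, opt$row_h * yv, "#c0392b",
                             c(class = "usage-cell",
                               `data-sample-id` = ord$sample_id[j],
                               `data-feature-id` = feats[i],
                               `data-y` = fmt_data(yv))))
    }
  }

  # transcript diagram, left panel, one lane per transcript
  lay <- layout_transcripts(spec$gene, opt$left_width - 10)
  ntx <- length(lay$transcripts)
  lane_h <- (height - rows_top - opt$margin) / max(ntx, 1)
  for (k in seq_len(ntx)) {
    tx <- lay$transcripts[[k]]
    cy <- rows_top + (k - 0.5) * lane_h
    els <- c(els, svg_line(opt$margin + tx$line[["x1"]], cy,
                           opt$margin + tx$line[["x2"]], cy, "#333333", 1,
                           c(class = "tx-line",
                             `data-transcript-id` = tx$transcript_id)))
    for (b in seq_len(nrow(tx$boxes))) {
      els <- c(els, svg_rect(opt$margin + tx$boxes$x[b], cy - 4,
                             tx$boxes$width[b], 8, "#2c3e50",
                             c(class = "tx-exon",
                               `data-transcript-id` = tx$transcript_id)))
    }
    els <- c(els, svg_text(opt$margin, cy - 6, tx$transcript_id, size = 7))
  }
  els <- c(els, svg_text(opt$margin, opt$margin + 8,
                         sprintf("%s (%s)", spec$gene$symbol,
                                 spec$gene$gene_id), size = 11,
                         attrs = c(class = "gene-title")))

  svg_document(width, height, els)
}

#' Render per-group box plots as SVG
#'
#' Tukey convention: box from first to third quartile with the median
#' line, whiskers to the most extreme points within 1.5 IQR of the box,
#' points beyond drawn as dots. Quartiles use linear interpolation
#' (type 7). The box carries `data-median`, `data-q1`, `data-q3`.
#'
#' @param values_by_group Named list: group label -> numeric vector.
#' @param options Layout overrides (`width`, `height`, `margin`).
#' @return An `svg_document`.
#' @export
render_boxplot <- function(values_by_group, options = list()) {
  stopifnot(length(values_by_group) >= 1, !is.null(names(values_by_group)))
  opt <- utils::modifyList(list(width = 420, height = 300, margin = 40),
                           options)
  all_v <- unlist(values_by_group, use.names = FALSE)
  stopifnot(length(all_v) >= 1, !anyNA(all_v))
  lo <- min(all_v); hi <- max(all_v)
  if (hi == lo) { hi <- lo + 1 }                 # degenerate scale
  pad <- 0.05 * (hi - lo)
  ylo <- lo - pad; yhi <- hi + pad
  py <- function(v) opt$margin + (yhi - v) / (yhi - ylo) *
    (opt$height - 2 * opt$margin)
  ng <- length(values_by_group)
  slot_w <- (opt$width - 2 * opt$margin) / ng
  box_w <- slot_w * 0.5
  pal <- palette_for(names(values_by_group))
  els <- c(
    svg_line(opt$margin, opt$margin, opt$margin, opt$height - opt$margin,
             "#000000", 1, c(class = "axis")),
    svg_text(opt$margin - 4, py(lo) + 3, fmt3(lo), size = 8, anchor = "end"),
    svg_text(opt$margin - 4, py(hi) + 3, fmt3(hi), size = 8, anchor = "end")
  )
  for (k in seq_len(ng)) {
    lab <- names(values_by_group)[k]
    v <- values_by_group[[k]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    wlo <- min(v[v >= q[1] - 1.5 * iqr])
    whi <- max(v[v <= q[3] + 1.5 * iqr])
    out_pts <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
    cx <- opt$margin + (k - 0.5) * slot_w
    els <- c(els,
      svg_line(cx, py(wlo), cx, py(q[1]), "#000000", 1,
               c(class = "whisker")),
      svg_line(cx, py(q[3]), cx, py(whi), "#000000", 1,
               c(class = "whisker")),
      svg_line(cx - box_w / 4, py(wlo), cx + box_w / 4, py(wlo), "#000000", 1),
      svg_line(cx - box_w / 4, py(whi), cx + box_w / 4, py(whi), "#000000", 1),
      svg_rect(cx - box_w / 2, py(q[3]), box_w,
               max(py(q[1]) - py(q[3]), 0), pal[[lab]],
               c(class = "box", `data-group` = lab,
                 `data-q1` = fmt_data(q[1]), `data-median` = fmt_data(q[2]),
                 `data-q3` = fmt_data(q[3]), `data-n` = length(v),
                 stroke = "#000000")),
      svg_line(cx - box_w / 2, py(q[2]), cx + box_w / 2, py(q[2]),
               "#000000", 1.5, c(class = "median-line",
                                 `data-median` = fmt_data(q[2]))),
      svg_text(cx, opt$height - opt$margin + 14, lab, size = 9,
               anchor = "middle")
    )
    for (p in sort(out_pts)) {
      els <- c(els, svg_circle(cx, py(p), 2, "#000000",
                               c(class = "outlier", `data-value` = fmt_data(p))))
    }
  }
  svg_document(opt$width, opt$height, els)
}

#' Render Kaplan-Meier curves as SVG
#'
#' Step-function paths, one per curve, with censor tick marks and a legend
#' carrying each group's label (including n) and the cutoff when given.
#' Each path carries `data-times` and `data-survival` attributes holding
#' the curve values.
#'
#' @param curves A `km_curve` or list of them.
#' @param options Layout overrides (`width`, `height`, `margin`,
#'   `cutoff` shown in the legend).
#' @return An `svg_document`.
#' @export
render_km <- function(curves, options = list()) {
  if (inherits(curves, "km_curve")) curves <- list(curves)
  opt <- utils::modifyList(list(width = 520, height = 340, margin = 45,
                                cutoff = NULL), options)
  tmax <- max(c(1e-9, unlist(lapply(curves, function(cv)
    c(cv$times, cv$censor_times)))))
  px <- function(t) opt$margin + t / tmax * (opt$width - 2 * opt$margin)
  py <- function(s) opt$margin + (1 - s) * (opt$height - 2 * opt$margin)
  pal <- palette_for(vapply(curves, `[[`, "", "group_label"))
  els <- c(
    svg_line(opt$margin, py(1), opt$margin, py(0), "#000000", 1,
             c(class = "axis-y")),
    svg_line(px(0), py(0), px(tmax), py(0), "#000000", 1,
             c(class = "axis-x")),
    svg_text(opt$margin - 4, py(1) + 3, "1.0", size = 8, anchor = "end"),
    svg_text(opt$margin - 4, py(0.5) + 3, "0.5", size = 8, anchor = "end"),
    svg_text(opt$margin - 4, py(0) + 3, "0.0", size = 8, anchor = "end"),
    svg_text(px(0), py(0) + 14, "0", size = 8, anchor = "middle"),
    svg_text(px(tmax), py(0) + 14, fmt3(tmax), size = 8, anchor = "middle")
  )
  for (k in seq_along(curves)) {
    cv <- curves[[k]]
    col <- pal[[cv$group_label]]
    if (length(cv$times) > 0) {
      d <- sprintf("M %s %s", fmt3(px(cv$times[1])), fmt3(py(cv$survival[1])))
      if (length(cv$times) > 1) {
        for (i in 2:length(cv$times)) {
          d <- paste(d, sprintf("H %s V %s", fmt3(px(cv$times[i])),
                                fmt3(py(cv$survival[i]))))
        }
      }
      tend <- max(c(cv$times, cv$censor_times))
      if (tend > cv$times[length(cv$times)]) {
        d <- paste(d, sprintf("H %s", fmt3(px(tend))))
      }
      els <- c(els, svg_path(d, col, 1.5, c(
        class = "km-curve", `data-group` = cv$group_label,
        `data-n` = cv$n,
        `data-times` = paste(fmt_data(cv$times), collapse = ","),
        `data-survival` = paste(fmt_data(cv$survival), collapse = ","))))
    }
    for (ct in cv$censor_times) {
      s_at <- cv$survival[max(which(cv$times <= ct))]
      els <- c(els, svg_line(px(ct), py(s_at) - 3, px(ct), py(s_at) + 3,
                             col, 1, c(class = "censor-tick")))
    }
    els <- c(els, svg_text(opt$width - opt$margin - 160,
                           opt$margin + 12 * k,
                           cv$group_label, size = 9,
                           attrs = c(class = "legend", fill = col)))
  }
  if (!is.null(opt$cutoff)) {
    els <- c(els, svg_text(opt$width - opt$margin - 160,
                           opt$margin + 12 * (length(curves) + 1),
                           sprintf("cutoff = %s", fmt3(opt$cutoff)),
                           size = 9, attrs = c(class = "legend-cutoff")))
  }
  svg_document(opt$width, opt$height, els)
}
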
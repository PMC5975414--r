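# Minimal deterministic SVG authoring. Documents are built as ordered
# element strings with fixed 3-decimal coordinate formatting and no
# timestamps, so identical inputs yield byte-identical files. Provenance
# data attributes (data-y etc.) keep higher precision (%.12g) so values
# can be recovered from the document.

#' Format a coordinate for SVG output (fixed 3 decimals)
#' @param x Numeric vector.
#' @return Character vector.
#' @keywords internal
fmt3 <- function(x) {
  s <- sprintf("%.3f", x)
  s[s == "-0.000"] <- "0.000"
  s
}

fmt_data <- function(x) sprintf("%.12g", x)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_attrs <- function(attrs) {
  if (length(attrs) == 0) return("")
  paste0(" ", paste(sprintf('%s="%s"', names(attrs),
                            xml_escape(as.character(attrs))),
                    collapse = " "))
}

svg_rect <- function(x, y, w, h, fill, attrs = character()) {
  sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
          fmt3(x), fmt3(y), fmt3(w), fmt3(h), fill, svg_attrs(attrs))
}

svg_line <- function(x1, y1, x2, y2, stroke, width = 1, attrs = character()) {
  sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s/>',
          fmt3(x1), fmt3(y1), fmt3(x2), fmt3(y2), stroke, fmt3(width),
          svg_attrs(attrs))
}

svg_circle <- function(cx, cy, r, fill, attrs = character()) {
  sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"%s/>',
          fmt3(cx), fmt3(cy), fmt3(r), fill, svg_attrs(attrs))
}

svg_text <- function(x, y, label, size = 10, anchor = "start",
                     attrs = character()) {
  sprintf('<text x="%s" y="%s" font-size="%s" text-anchor="%s" font-family="sans-serif"%s>%s</text>',
          fmt3(x), fmt3(y), fmt3(size), anchor, svg_attrs(attrs),
          xml_escape(label))
}

svg_path <- function(d, stroke, width = 1.5, attrs = character()) {
  sprintf('<path d="%s" fill="none" stroke="%s" stroke-width="%s"%s/>',
          d, stroke, fmt3(width), svg_attrs(attrs))
}

#' Construct an SVG document
#'
#' @param width,height Pixel dimensions.
#' @param elements Character vector of SVG element strings, in draw order.
#' @return Object of class `svg_document`.
#' @export
svg_document <- function(width, height, elements = character()) {
  structure(list(width = width, height = height, elements = elements),
            class = "svg_document")
}

#' @export
as.character.svg_document <- function(x, ...) {
  paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt3(x$width), fmt3(x$height), fmt3(x$width), fmt3(x$height)),
    x$elements,
    "</svg>"
  ), collapse = "\n")
}

#' @export
print.svg_document <- function(x, ...) {
  cat(sprintf("svg_document %gx%g, %d elements\n",
              x$width, x$height, length(x$elements)))
  invisible(x)
}

#' Write an SVG document to a file
#'
#' Byte-deterministic: fixed float formatting, stable element order, no
#' timestamps.
#'
#' @param doc An `svg_document`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(doc, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(as.character(doc), "\n")), con)
  invisible(path)
}

# Fixed default palette; clinical category -> color is deterministic by
# sorted label order.
default_palette <- c(
  "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
  "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf"
)

palette_for <- function(labels) {
  u <- sort(unique(labels))
  stats::setNames(default_palette[(seq_along(u) - 1L) %% length(default_palette) + 1L], u)
}
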
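OVERLAY_DEFAULTS <- list(
  down_color = "#0571B0",   # blue, down-regulated endpoint
  up_color = "#CA0020",     # red, up-regulated endpoint
  mid_color = "#FFFFFF",
  neutral_color = "#BEBEBE",  # genes without statistics / non-gene nodes
  frame_color = "#33A02C",    # significance frame
  limit = 2,
  alpha = 0.05)

hex_to_rgb <- function(hex) as.integer(grDevices::col2rgb(hex))
rgb_to_hex <- function(v) sprintf("#%02X%02X%02X", v[1], v[2], v[3])

#' Map a log2 fold change to a diverging fill color
#'
#' Linear interpolation in RGB along a diverging blue-white-red scale:
#' `-limit` maps to the full down-color, 0 to white, `+limit` to the full
#' up-color; values beyond the limit clamp to the endpoints, and a missing
#' fold change (gene not on the array) maps to neutral gray.
#'
#' @param log2_fc Numeric vector of log2 fold changes (`NA` allowed).
#' @param limit Positive saturation bound in log2 units (default 2, i.e.
#'   a four-fold change saturates the scale).
#' @param down_color,up_color,neutral_color Hex anchor colors.
#' @return Character vector of 6-digit hex colors.
#' @export
fold_change_to_color <- function(log2_fc, limit = OVERLAY_DEFAULTS$limit,
                                 down_color = OVERLAY_DEFAULTS$down_color,
                                 up_color = OVERLAY_DEFAULTS$up_color,
                                 neutral_color = OVERLAY_DEFAULTS$neutral_color) {
  if (!is.numeric(limit) || length(limit) != 1 || is.na(limit) || limit <= 0)
    stop("fold_change_to_color: 'limit' must be a positive number")
  white <- hex_to_rgb(OVERLAY_DEFAULTS$mid_color)
  up <- hex_to_rgb(up_color)
  down <- hex_to_rgb(down_color)
  vapply(log2_fc, function(fc) {
    if (is.na(fc)) return(toupper(neutral_color))
    f <- min(abs(fc), limit) / limit
    anchor <- if (fc >= 0) up else down
    rgb_to_hex(as.integer(round(white + f * (anchor - white))))
  }, "")
}

#' Significance frame color from an adjusted p-value
#'
#' Genes significant at the chosen FDR level get a colored frame in the
#' pathway view; the boundary `q == alpha` counts as significant
#' (inclusive, matching the usual "significant on the 5% level" phrasing).
#'
#' @param q_value Numeric vector of BH-adjusted p-values (`NA` = gene not
#'   in the dataset).
#' @param alpha FDR level in (0, 1), default 0.05.
#' @param frame_color Hex color used for significant genes.
#' @return Character vector: the frame color where `q <= alpha`, `NA`
#'   (no frame) otherwise.
#' @export
significance_frame <- function(q_value, alpha = OVERLAY_DEFAULTS$alpha,
                               frame_color = OVERLAY_DEFAULTS$frame_color) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("significance_frame: 'alpha' must lie in (0, 1)")
  ifelse(!is.na(q_value) & q_value <= alpha, frame_color, NA_character_)
}

#' Build the visual overlay for a pathway graph
#'
#' Joins per-gene statistics onto pathway nodes: fill color from the log2
#' fold change, frame color from FDR significance. Every node of the graph
#' receives exactly one record. A gene node whose KEGG ids match several
#' genes with statistics is represented by the gene with the smallest
#' q-value (ties broken by lexicographically smallest gene id) — the signal
#' a researcher would want to notice first. Gene nodes without any matching
#' statistics, and non-gene nodes, get the neutral fill and no frame.
#'
#' @param graph A valid [pathway_graph].
#' @param stats data.frame with columns `gene_id`, `log2_fc`, `q_value`
#'   (e.g. from [differential_expression()]).
#' @param alpha FDR level for the significance frame.
#' @param limit Color saturation bound in log2 units.
#' @return An object of class `overlay_style`: data.frame with one row per
#'   node (`entry_id`, `fill_color`, `frame_color`, `source_gene`,
#'   `log2_fc`, `q_value`).
#' @export
build_overlay <- function(graph, stats, alpha = OVERLAY_DEFAULTS$alpha,
                          limit = OVERLAY_DEFAULTS$limit) {
  validate_pathway_graph(graph)
  stopifnot(is.data.frame(stats),
            all(c("gene_id", "log2_fc", "q_value") %in% names(stats)))
  if (anyDuplicated(stats$gene_id))
    stop("build_overlay: duplicate gene_id in stats")
  n <- graph$nodes
  rec <- lapply(seq_len(nrow(n)), function(i) {
    rep_gene <- NA_character_; fc <- NA_real_; q <- NA_real_
    if (n$node_type[i] == "gene") {
      hits <- stats[stats$gene_id %in% n$kegg_ids[[i]], , drop = FALSE]
      if (nrow(hits)) {
        hits <- hits[order(hits$q_value, hits$gene_id), , drop = FALSE]
        rep_gene <- hits$gene_id[1]
        fc <- hits$log2_fc[1]
        q <- hits$q_value[1]
      }
    }
    list(entry_id = n$entry_id[i], source_gene = rep_gene,
         log2_fc = fc, q_value = q)
  })
  out <- data.frame(
    entry_id = vapply(rec, `[[`, "", "entry_id"),
    fill_color = fold_change_to_color(vapply(rec, `[[`, 0, "log2_fc"),
                                      limit = limit),
    frame_color = significance_frame(vapply(rec, `[[`, 0, "q_value"),
                                     alpha = alpha),
    source_gene = vapply(rec, `[[`, "", "source_gene"),
    log2_fc = vapply(rec, `[[`, 0, "log2_fc"),
    q_value = vapply(rec, `[[`, 0, "q_value"),
    stringsAsFactors = FALSE)
  structure(out, class = c("overlay_style", "data.frame"))
}

#' @export
print.overlay_style <- function(x, ...) {
  cat(sprintf("overlay_style: %d nodes, %d colored, %d framed\n", nrow(x),
              sum(!is.na(x$source_gene)), sum(!is.na(x$frame_color))))
  invisible(x)
}

#' Overlay as a JSON-ready document keyed by entry id
#'
#' The document merges with the graph document from
#' [graph_to_view_document()]: each entry id maps to its fill, frame,
#' source gene and numeric annotations (`NA` becomes JSON null).
#'
#' @param overlay An `overlay_style` from [build_overlay()].
#' @return Named list keyed by entry id.
#' @export
overlay_document <- function(overlay) {
  stopifnot(inherits(overlay, "overlay_style"))
  na_null <- function(v) if (is.na(v)) NULL else v
  setNames(lapply(seq_len(nrow(overlay)), function(i) {
    list(fill = overlay$fill_color[i],
         frame = na_null(overlay$frame_color[i]),
         source_gene = na_null(overlay$source_gene[i]),
         log2_fc = na_null(overlay$log2_fc[i]),
         q_value = na_null(overlay$q_value[i]))
  }), overlay$entry_id)
}
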
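#' @importFrom stats p.adjust pnorm rnorm runif sd t.test setNames
#' @importFrom utils URLencode head tail
NULL

KGML_NODE_TYPES <- c("gene", "compound", "map", "group", "ortholog", "enzyme", "other")

#' Construct a pathway graph object
#'
#' A `pathway_graph` is the in-memory model of one KGML pathway: a node table
#' (one row per KGML `entry`, with pixel-space graphics) and an edge table
#' (one row per relation, plus one row per substrate-product pair of each
#' reaction).
#'
#' @param pathway_id KEGG pathway identifier, e.g. `"hsa04614"`.
#' @param title Display title of the pathway.
#' @param organism Organism code (e.g. `"hsa"`), may be `""`.
#' @param image_ref URL or path of the background pathway image, may be `""`.
#' @param nodes data.frame with columns `entry_id`, `node_type`, `label`,
#'   `x`, `y`, `width`, `height` and list columns `kegg_ids`, `member_ids`.
#'   Coordinates are node centers in the background image's pixel space
#'   (origin top-left, y increasing downward).
#' @param edges data.frame with columns `source`, `target`, `kind`
#'   (`"relation"` or `"reaction"`) and `subtype`.
#' @return An object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, title = "", organism = "", image_ref = "",
                          nodes = empty_node_table(), edges = empty_edge_table()) {
  g <- structure(
    list(pathway_id = pathway_id, title = title, organism = organism,
         image_ref = image_ref, nodes = nodes, edges = edges),
    class = "pathway_graph")
  validate_pathway_graph(g)
  g
}

empty_node_table <- function() {
  data.frame(entry_id = character(), node_type = character(), label = character(),
             x = numeric(), y = numeric(), width = numeric(), height = numeric(),
             kegg_ids = I(list()), member_ids = I(list()),
             stringsAsFactors = FALSE)
}

empty_edge_table <- function() {
  data.frame(source = character(), target = character(), kind = character(),
             subtype = character(), stringsAsFactors = FALSE)
}

#' Validate a pathway graph
#'
#' Checks the structural invariants: unique entry ids, positive node sizes,
#' node types from the known vocabulary, edge endpoints and group members
#' referring to existing nodes.
#'
#' @param g A `pathway_graph`.
#' @return `g`, invisibly. Throws a validation error otherwise.
#' @export
validate_pathway_graph <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  n <- g$nodes
  e <- g$edges
  if (anyDuplicated(n$entry_id))
    stop("pathway_graph: duplicate entry_id: ",
         paste(unique(n$entry_id[duplicated(n$entry_id)]), collapse = ", "))
  if (nrow(n) && any(n$width <= 0 | n$height <= 0))
    stop("pathway_graph: node width/height must be > 0")
  bad_type <- setdiff(unique(n$node_type), KGML_NODE_TYPES)
  if (length(bad_type))
    stop("pathway_graph: unknown node_type: ", paste(bad_type, collapse = ", "))
  ids <- n$entry_id
  if (nrow(e)) {
    missing_ep <- setdiff(unique(c(e$source, e$target)), ids)
    if (length(missing_ep))
      stop("pathway_graph: edge endpoint refers to no node: ",
           paste(missing_ep, collapse = ", "))
    bad_kind <- setdiff(unique(e$kind), c("relation", "reaction"))
    if (length(bad_kind))
      stop("pathway_graph: unknown edge kind: ", paste(bad_kind, collapse = ", "))
  }
  members <- unique(unlist(n$member_ids))
  if (length(members) && length(setdiff(members, ids)))
    stop("pathway_graph: group member refers to no node: ",
         paste(setdiff(members, ids), collapse = ", "))
  invisible(g)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph '%s' (%s)\n", x$pathway_id,
              if (nzchar(x$title)) x$title else "untitled"))
  cat(sprintf("  %d nodes (%s)\n", nrow(x$nodes),
              paste(sprintf("%s: %d", names(table(x$nodes$node_type)),
                            as.integer(table(x$nodes$node_type))), collapse = ", ")))
  cat(sprintf("  %d edges\n", nrow(x$edges)))
  invisible(x)
}

kgml_attr <- function(node, name, required = FALSE, element = "") {
  v <- xml2::xml_attr(node, name)
  if (required && (is.na(v) || !nzchar(v)))
    stop(sprintf("KGML structural error: <%s> missing required attribute '%s'",
                 element, name))
  v
}

#' Parse a KGML pathway document
#'
#' Reads a KEGG Markup Language (KGML) XML document and builds the typed
#' graph model. Each KGML `entry` becomes one node; each `relation` becomes
#' one edge; each `reaction` contributes one edge per substrate-product pair
#' (cross product), with the reaction type as the edge subtype.
#'
#' Entries may carry several KEGG identifiers in a space-separated `name`
#' attribute; all are kept in `kegg_ids`. The display label is the first
#' comma-separated alias of the KGML graphics name. Graphics x/y are node
#' centers in the background image's pixel space and are stored unchanged.
#' Entry types outside the known vocabulary map to `"other"`; `group`
#' entries keep their members in `member_ids` without flattening. Relations
#' or reactions whose endpoints do not correspond to a parsed entry are
#' dropped with a warning (some KEGG releases ship dangling references).
#'
#' @param x Path to a KGML file, or a single string containing KGML XML.
#' @return A [pathway_graph].
#' @export
parse_kgml <- function(x) {
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) stop("KGML parse error: ", conditionMessage(e)))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "pathway")
    stop("KGML structural error: root element is <", xml2::xml_name(root),
         ">, expected <pathway>")

  entries <- xml2::xml_find_all(root, "./entry")
  nodes <- lapply(entries, function(en) {
    id <- kgml_attr(en, "id", required = TRUE, element = "entry")
    type <- kgml_attr(en, "type", required = TRUE, element = "entry")
    if (!type %in% KGML_NODE_TYPES) type <- "other"
    gfx <- xml2::xml_find_first(en, "./graphics")
    if (inherits(gfx, "xml_missing"))
      stop("KGML structural error: <entry id=\"", id, "\"> has no <graphics>")
    x0 <- kgml_attr(gfx, "x", required = TRUE, element = "graphics")
    y0 <- kgml_attr(gfx, "y", required = TRUE, element = "graphics")
    w <- xml2::xml_attr(gfx, "width")
    h <- xml2::xml_attr(gfx, "height")
    gname <- xml2::xml_attr(gfx, "name")
    label <- if (is.na(gname) || !nzchar(gname)) ""
             else trimws(strsplit(gname, ",", fixed = TRUE)[[1]][1])
    name <- xml2::xml_attr(en, "name")
    kegg_ids <- if (is.na(name) || !nzchar(name)) character() else
      strsplit(trimws(name), "\\s+")[[1]]
    members <- if (type == "group")
      vapply(xml2::xml_find_all(en, "./component"), xml2::xml_attr, "", attr = "id")
    else character()
    list(entry_id = id, node_type = type, label = label,
         x = as.numeric(x0), y = as.numeric(y0),
         # KEGG draws 46x17 boxes when graphics omit explicit sizes
         width = if (is.na(w)) 46 else as.numeric(w),
         height = if (is.na(h)) 17 else as.numeric(h),
         kegg_ids = kegg_ids, member_ids = members)
  })
  node_tab <- if (length(nodes)) {
    data.frame(
      entry_id = vapply(nodes, `[[`, "", "entry_id"),
      node_type = vapply(nodes, `[[`, "", "node_type"),
      label = vapply(nodes, `[[`, "", "label"),
      x = vapply(nodes, `[[`, 0, "x"),
      y = vapply(nodes, `[[`, 0, "y"),
      width = vapply(nodes, `[[`, 0, "width"),
      height = vapply(nodes, `[[`, 0, "height"),
      kegg_ids = I(lapply(nodes, `[[`, "kegg_ids")),
      member_ids = I(lapply(nodes, `[[`, "member_ids")),
      stringsAsFactors = FALSE)
  } else empty_node_table()

  edge_rows <- list()
  for (rel in xml2::xml_find_all(root, "./relation")) {
    st <- xml2::xml_find_first(rel, "./subtype")
    edge_rows[[length(edge_rows) + 1L]] <- data.frame(
      source = kgml_attr(rel, "entry1", required = TRUE, element = "relation"),
      target = kgml_attr(rel, "entry2", required = TRUE, element = "relation"),
      kind = "relation",
      subtype = if (inherits(st, "xml_missing")) "" else xml2::xml_attr(st, "name"),
      stringsAsFactors = FALSE)
  }
  for (rx in xml2::xml_find_all(root, "./reaction")) {
    rtype <- xml2::xml_attr(rx, "type")
    subs <- vapply(xml2::xml_find_all(rx, "./substrate"), xml2::xml_attr, "", attr = "id")
    prods <- vapply(xml2::xml_find_all(rx, "./product"), xml2::xml_attr, "", attr = "id")
    for (s in subs) for (p in prods)
      edge_rows[[length(edge_rows) + 1L]] <- data.frame(
        source = s, target = p, kind = "reaction",
        subtype = if (is.na(rtype)) "" else rtype, stringsAsFactors = FALSE)
  }
  edge_tab <- if (length(edge_rows)) do.call(rbind, edge_rows) else empty_edge_table()
  if (nrow(edge_tab)) {
    ok <- edge_tab$source %in% node_tab$entry_id & edge_tab$target %in% node_tab$entry_id
    if (any(!ok)) {
      warning(sum(!ok), " edge(s) with unknown endpoints dropped")
      edge_tab <- edge_tab[ok, , drop = FALSE]
      rownames(edge_tab) <- NULL
    }
  }

  pathway_graph(
    pathway_id = sub("^path:", "", kgml_attr(root, "name", required = TRUE,
                                             element = "pathway")),
    title = {t <- xml2::xml_attr(root, "title"); if (is.na(t)) "" else t},
    organism = {o <- xml2::xml_attr(root, "org"); if (is.na(o)) "" else o},
    image_ref = {i <- xml2::xml_attr(root, "image"); if (is.na(i)) "" else i},
    nodes = node_tab, edges = edge_tab)
}

#' Export a pathway graph as a visualization-ready document
#'
#' Builds the graph document consumed by network viewers: a `nodes` array
#' (id, label, type, position, size, KEGG ids) and an `edges` array
#' (source, target, kind, subtype). Positions are the KGML graphics
#' coordinates, unchanged.
#'
#' @param graph A valid [pathway_graph].
#' @return A list with elements `pathway`, `nodes`, `edges`, serializable
#'   with [view_document_json()].
#' @seealso [read_view_document()] for the inverse.
#' @export
graph_to_view_document <- function(graph) {
  validate_pathway_graph(graph)
  n <- graph$nodes
  nodes <- lapply(seq_len(nrow(n)), function(i) {
    list(id = n$entry_id[i], label = n$label[i], type = n$node_type[i],
         x = n$x[i], y = n$y[i], width = n$width[i], height = n$height[i],
         kegg_ids = as.list(n$kegg_ids[[i]]),
         member_ids = as.list(n$member_ids[[i]]))
  })
  e <- graph$edges
  edges <- lapply(seq_len(nrow(e)), function(i) {
    list(source = e$source[i], target = e$target[i],
         kind = e$kind[i], subtype = e$subtype[i])
  })
  list(pathway = list(id = graph$pathway_id, title = graph$title,
                      organism = graph$organism, image = graph$image_ref),
       nodes = nodes, edges = edges)
}

#' Serialize a graph document (or any document list) to JSON
#' @param doc A document list, e.g. from [graph_to_view_document()].
#' @param pretty Pretty-print the JSON.
#' @return A JSON string.
#' @export
view_document_json <- function(doc, pretty = FALSE) {
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = pretty))
}

#' Re-import a graph document into a pathway graph
#'
#' Inverse of [graph_to_view_document()]: reconstructs the `pathway_graph`
#' from the exported document (given as a list or a JSON string), so that
#' parse, export and re-import round-trip losslessly.
#'
#' @param doc Document list or JSON string.
#' @return A [pathway_graph].
#' @export
read_view_document <- function(doc) {
  if (is.character(doc))
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  as_chr <- function(x) vapply(x, function(el) as.character(el), "")
  nodes <- if (length(doc$nodes)) data.frame(
    entry_id = vapply(doc$nodes, function(n) as.character(n$id), ""),
    node_type = vapply(doc$nodes, function(n) as.character(n$type), ""),
    label = vapply(doc$nodes, function(n) as.character(n$label), ""),
    x = vapply(doc$nodes, function(n) as.numeric(n$x), 0),
    y = vapply(doc$nodes, function(n) as.numeric(n$y), 0),
    width = vapply(doc$nodes, function(n) as.numeric(n$width), 0),
    height = vapply(doc$nodes, function(n) as.numeric(n$height), 0),
    kegg_ids = I(lapply(doc$nodes, function(n) as_chr(n$kegg_ids))),
    member_ids = I(lapply(doc$nodes, function(n) as_chr(n$member_ids))),
    stringsAsFactors = FALSE) else empty_node_table()
  edges <- if (length(doc$edges)) data.frame(
    source = vapply(doc$edges, function(e) as.character(e$source), ""),
    target = vapply(doc$edges, function(e) as.character(e$target), ""),
    kind = vapply(doc$edges, function(e) as.character(e$kind), ""),
    subtype = vapply(doc$edges, function(e) as.character(e$subtype), ""),
    stringsAsFactors = FALSE) else empty_edge_table()
  pathway_graph(pathway_id = doc$pathway$id, title = doc$pathway$title,
                organism = doc$pathway$organism, image_ref = doc$pathway$image,
                nodes = nodes, edges = edges)
}

#' KEGG gene identifiers referenced by a pathway graph
#'
#' Deduplicated union of `kegg_ids` over gene nodes, in first-occurrence
#' order. This is the join key between a pathway and an expression dataset.
#'
#' @param graph A valid [pathway_graph].
#' @return Character vector of KEGG gene identifiers (possibly empty).
#' @export
pathway_gene_ids <- function(graph) {
  validate_pathway_graph(graph)
  gene_rows <- graph$nodes$node_type == "gene"
  unique(unlist(graph$nodes$kegg_ids[gene_rows], use.names = FALSE)) %||% character()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
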
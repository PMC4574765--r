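#' Configure the data-service application
#'
#' Bundles everything the read-only HTTP data interface needs: the
#' expression dataset, the (optional) pathway resource client, and the
#' overlay parameters. Dataset-wide differential-expression statistics are
#' computed once at construction, so every request is answered from the
#' same table and repeated identical requests return identical bodies.
#'
#' @param dataset An [expression_dataset], or `NULL` for a service without
#'   data (endpoints then answer 503).
#' @param client A [kegg_client] for `/pathway/{id}` requests, or `NULL`
#'   (pathway requests then answer 404).
#' @param alpha FDR level for significance frames.
#' @param limit Color saturation bound in log2 units.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param port Default TCP port for [serve()], 8888.
#' @return An object of class `pathway_app`.
#' @export
pathway_app <- function(dataset = NULL, client = NULL, alpha = 0.05,
                        limit = 2, var_equal = FALSE, port = 8888) {
  stopifnot(is.null(dataset) || inherits(dataset, "expression_dataset"),
            is.null(client) || inherits(client, "kegg_client"))
  if (!is.numeric(port) || port < 1 || port > 65535)
    stop("pathway_app: port outside the valid TCP range")
  de <- if (!is.null(dataset)) differential_expression(dataset, var_equal = var_equal)
  structure(list(dataset = dataset, client = client, de = de,
                 alpha = alpha, limit = limit, port = as.integer(port)),
            class = "pathway_app")
}

#' @export
print.pathway_app <- function(x, ...) {
  cat("pathway_app:",
      if (is.null(x$dataset)) "no dataset" else
        sprintf("%d genes x %d samples", length(x$dataset$gene_ids),
                length(x$dataset$sample_ids)),
      sprintf("| alpha = %g, color limit = %g, port = %d\n",
              x$alpha, x$limit, x$port))
  invisible(x)
}

api_response <- function(status, body)
  list(status = status,
       json = as.character(jsonlite::toJSON(body, auto_unbox = TRUE,
                                            null = "null", digits = NA)))

api_error <- function(status, message)
  api_response(status, list(error = message))

na_to_null <- function(x) if (length(x) == 1 && is.na(x)) NULL else x

split_genes <- function(segment) {
  if (grepl(",", segment, fixed = TRUE))
    return(structure("use '+' to separate gene ids, not ','", class = "api_400"))
  genes <- strsplit(segment, "+", fixed = TRUE)[[1]]
  if (!length(genes) || any(!nzchar(genes)))
    return(structure("empty gene id in request", class = "api_400"))
  genes
}

#' Handle one request against the data interface
#'
#' Pure routing core of the service: takes a request path and returns the
#' status code and JSON body. [serve()] is a thin HTTP transport around
#' this function, and every endpoint is value-identical to the
#' corresponding library call:
#'
#' * `/genes` — all gene ids, in dataset order.
#' * `/fc/{g1+g2+...}` — gene to log2 fold change ([mean_log2_fold_change()]).
#' * `/pvalues/{g1+...}` — gene to `{p, q}` ([differential_expression()],
#'   q over the full dataset, never over the query).
#' * `/exprs/{g1+...}` — gene to `{samples, values}` ([raw_expression()]).
#' * `/pathway/{id}` — graph document plus overlay ([build_overlay()]).
#'
#' Genes absent from the dataset map to JSON `null` with status 200 (a
#' pathway query routinely includes genes off the array); 404 is reserved
#' for unknown routes and unresolvable pathways, 400 for malformed gene
#' lists, 503 for a service without a dataset. Trailing slashes are
#' accepted everywhere.
#'
#' @param app A [pathway_app].
#' @param path Request path, e.g. `"/fc/hsa:1356+hsa:183"`.
#' @return List with `status` (integer) and `json` (single string).
#' @export
handle_request <- function(app, path) {
  stopifnot(inherits(app, "pathway_app"))
  path <- utils::URLdecode(sub("\\?.*$", "", path))
  if (path != "/") path <- sub("/+$", "", path)
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  route <- if (length(parts)) parts[1] else ""
  segment <- if (length(parts) > 1) paste(parts[-1], collapse = "/") else ""

  if (!route %in% c("genes", "fc", "pvalues", "exprs", "pathway"))
    return(api_error(404L, paste0("unknown route: ", path)))
  if (route != "pathway" && is.null(app$dataset))
    return(api_error(503L, "no dataset loaded"))

  if (route == "genes") {
    if (nzchar(segment)) return(api_error(404L, paste0("unknown route: ", path)))
    return(api_response(200L, as.list(app$dataset$gene_ids)))
  }

  if (route %in% c("fc", "pvalues", "exprs")) {
    genes <- split_genes(segment)
    if (inherits(genes, "api_400")) return(api_error(400L, unclass(genes)))
    body <- switch(route,
      fc = {
        fc <- mean_log2_fold_change(app$dataset, genes)
        setNames(lapply(unname(fc), na_to_null), genes)
      },
      pvalues = {
        idx <- match(genes, app$de$gene_id)
        setNames(lapply(idx, function(i) {
          if (is.na(i)) NULL else list(p = app$de$p_value[i], q = app$de$q_value[i])
        }), genes)
      },
      exprs = {
        rows <- raw_expression(app$dataset, genes)
        lapply(rows, function(v) {
          if (is.null(v)) NULL else
            list(samples = as.list(names(v)), values = as.list(unname(v)))
        })
      })
    return(api_response(200L, body))
  }

  # /pathway/{id}
  if (!nzchar(segment)) return(api_error(404L, "missing pathway id"))
  if (is.null(app$client)) return(api_error(404L, "no pathway source configured"))
  payload <- tryCatch(fetch_pathway(app$client, segment), error = function(e) e)
  if (inherits(payload, "error"))
    return(api_error(404L, paste0("pathway not available: ", segment)))
  graph <- tryCatch(parse_kgml(payload$kgml), error = function(e) e)
  if (inherits(graph, "error"))
    return(api_error(404L, paste0("invalid pathway document: ", segment)))
  stats <- if (is.null(app$de))
    data.frame(gene_id = character(), log2_fc = numeric(), q_value = numeric())
  else app$de
  doc <- graph_to_view_document(graph)
  doc$overlay <- overlay_document(build_overlay(graph, stats,
                                                alpha = app$alpha,
                                                limit = app$limit))
  api_response(200L, doc)
}

http_status_text <- function(status)
  switch(as.character(status), "200" = "OK", "400" = "Bad Request",
         "404" = "Not Found", "503" = "Service Unavailable", "Internal Server Error")

#' Run the HTTP data service
#'
#' Minimal blocking HTTP/1.1 loop over a base R server socket: accept a
#' connection, read the request line, dispatch through [handle_request()],
#' write the JSON response, close. One request per connection, one at a
#' time — matching the service's read-only, idempotent contract. Each
#' request is logged as `method path status ms`.
#'
#' A request for `/__shutdown__` stops the loop (used by supervised
#' deployments and tests to terminate the server cleanly).
#'
#' @param app A [pathway_app].
#' @param port TCP port (default: the app's configured port).
#' @param host Bind address.
#' @param quiet Suppress request logging.
#' @return Invisibly, the number of requests served.
#' @export
serve <- function(app, port = app$port, host = "127.0.0.1", quiet = FALSE) {
  stopifnot(inherits(app, "pathway_app"))
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  if (!quiet) message("listening on ", host, ":", port)
  served <- 0L
  repeat {
    sock <- socketAccept(srv, blocking = TRUE, open = "r+b", timeout = 10)
    t0 <- proc.time()[["elapsed"]]
    shutdown <- FALSE
    # a misbehaving client must never take the service down
    tryCatch({
      req <- readLines(sock, n = 1L, warn = FALSE)
      if (length(req)) {
        parts <- strsplit(trimws(req), " ", fixed = TRUE)[[1]]
        method <- parts[1]
        path <- if (length(parts) >= 2) parts[2] else "/"
        shutdown <- identical(path, "/__shutdown__")
        res <- if (shutdown) api_response(200L, list(stopping = TRUE))
          else if (!identical(method, "GET")) api_error(404L, "only GET is supported")
          else tryCatch(handle_request(app, path),
                        error = function(e) api_error(500L, conditionMessage(e)))
        body <- charToRaw(res$json)
        head <- sprintf(paste0("HTTP/1.1 %d %s\r\nContent-Type: application/json\r\n",
                               "Content-Length: %d\r\nConnection: close\r\n\r\n"),
                        res$status, http_status_text(res$status), length(body))
        writeBin(c(charToRaw(head), body), sock)
        flush(sock)
        served <- served + 1L
        if (!quiet)
          message(sprintf("%s %s %d %.1fms", method, path, res$status,
                          1000 * (proc.time()[["elapsed"]] - t0)))
      }
    }, error = function(e) NULL)
    try(close(sock), silent = TRUE)
    if (shutdown) break
  }
  invisible(served)
}
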
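#' Create a KEGG-style resource client with a disk cache
#'
#' Every fetched resource is stored on disk and served from the cache on
#' subsequent requests, across process restarts. The byte source is an
#' injected function (give a resource path, receive a raw vector), so tests
#' and offline deployments run entirely on fixture files; the real REST
#' base URL is configuration, never hard-coded in any logic.
#'
#' Cache entries never expire automatically; [purge_cache()] removes them
#' explicitly. KEGG pathway payloads change rarely and pinning favors
#' reproducibility.
#'
#' @param cache_dir Directory for cached payloads (created if needed).
#' @param fetcher Function `(resource_path) -> raw vector`, called only on
#'   cache misses. Defaults to an HTTP fetcher against `base_url` unless
#'   `offline = TRUE`.
#' @param base_url Remote base, e.g. `"https://rest.kegg.jp"`.
#' @param offline If `TRUE`, any cache miss is an error: no byte source is
#'   ever invoked.
#' @return An object of class `kegg_client`.
#' @export
kegg_client <- function(cache_dir, fetcher = NULL,
                        base_url = "https://rest.kegg.jp", offline = FALSE) {
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(fetcher)) {
    fetcher <- if (offline) {
      function(path) stop("kegg_client is offline and '", path, "' is not cached")
    } else {
      function(path) {
        con <- url(paste(sub("/+$", "", base_url), path, sep = "/"), open = "rb")
        on.exit(close(con))
        out <- raw()
        repeat {
          chunk <- readBin(con, "raw", n = 65536L)
          if (!length(chunk)) break
          out <- c(out, chunk)
        }
        out
      }
    }
  }
  stopifnot(is.function(fetcher))
  structure(list(cache_dir = normalizePath(cache_dir), fetcher = fetcher,
                 base_url = base_url, offline = offline),
            class = "kegg_client")
}

#' @export
print.kegg_client <- function(x, ...) {
  cat(sprintf("kegg_client: cache '%s' (%d entries)%s\n", x$cache_dir,
              length(list.files(x$cache_dir)),
              if (x$offline) ", offline" else ""))
  invisible(x)
}

#' Deterministic, filesystem-safe cache key for a resource path
#'
#' Percent-encodes every reserved character (including `/`), so distinct
#' paths always map to distinct flat file names and the mapping is stable
#' across runs and platforms.
#'
#' @param resource_path Resource path string, e.g. `"get/hsa04614/kgml"`.
#' @return A single file-name-safe string.
#' @export
cache_key <- function(resource_path) {
  stopifnot(is.character(resource_path), length(resource_path) == 1,
            nzchar(resource_path))
  # repeated = TRUE also encodes literal '%', keeping the mapping injective
  URLencode(resource_path, reserved = TRUE, repeated = TRUE)
}

cache_file <- function(client, resource_path)
  file.path(client$cache_dir, cache_key(resource_path))

#' Fetch a resource through the cache
#'
#' The first request for a path invokes the client's fetcher and stores the
#' payload; later requests for the same path are answered from disk without
#' touching the fetcher, also in a fresh process pointed at the same cache
#' directory. A failed fetch stores nothing, so the cache is never poisoned.
#'
#' @param client A [kegg_client].
#' @param resource_path Resource path relative to the remote base.
#' @return Raw vector payload.
#' @export
cached_get <- function(client, resource_path) {
  stopifnot(inherits(client, "kegg_client"))
  f <- cache_file(client, resource_path)
  if (file.exists(f))
    return(readBin(f, "raw", n = file.size(f)))
  payload <- client$fetcher(resource_path)
  if (!is.raw(payload)) payload <- charToRaw(paste(payload, collapse = "\n"))
  # write via temp file + rename so an interrupted write never leaves a
  # truncated cache entry behind
  tmp <- tempfile(tmpdir = client$cache_dir)
  writeBin(payload, tmp)
  file.rename(tmp, f)
  payload
}

#' Remove all cached entries
#' @param client A [kegg_client].
#' @return Invisibly, the number of entries removed.
#' @export
purge_cache <- function(client) {
  stopifnot(inherits(client, "kegg_client"))
  files <- list.files(client$cache_dir, full.names = TRUE)
  unlink(files)
  invisible(length(files))
}

#' Fetch a pathway's KGML document and background image
#'
#' Retrieves the KGML representation and the pathway image through the
#' cache, using the standard KEGG REST resource layout
#' (`get/<id>/kgml`, `get/<id>/image`).
#'
#' @param client A [kegg_client].
#' @param pathway_id Pathway identifier matching `[a-z]{2,4}[0-9]{5}`,
#'   e.g. `"hsa04614"`.
#' @return List with `kgml` (single character string) and `image` (raw
#'   bytes, not decoded).
#' @export
fetch_pathway <- function(client, pathway_id) {
  if (!grepl("^[a-z]{2,4}[0-9]{5}$", pathway_id))
    stop("fetch_pathway: malformed pathway id: '", pathway_id, "'")
  list(kgml = rawToChar(cached_get(client, paste0("get/", pathway_id, "/kgml"))),
       image = cached_get(client, paste0("get/", pathway_id, "/image")))
}

#' Parse a KEGG flat-file gene record
#'
#' KEGG gene entries use a keyword layout: a 12-column keyword field
#' (ENTRY, NAME, DEFINITION, PATHWAY, ...) followed by the value, with
#' continuation lines indented into the value column. Extracts the symbol
#' aliases, the description and the ordered pathway memberships.
#'
#' @param flat_text Record text (single string or character vector of lines).
#' @return An object of class `gene_record`: list with `gene_id`, `name`
#'   (character vector of aliases), `definition`, and `pathways`
#'   (data.frame `id`, `name` in file order).
#' @export
parse_gene_record <- function(flat_text) {
  lines <- if (length(flat_text) == 1) strsplit(flat_text, "\n", fixed = TRUE)[[1]]
           else flat_text
  lines <- lines[lines != "///"]
  if (!length(lines) || !grepl("^ENTRY", lines[1]))
    stop("parse_gene_record: record does not start with an ENTRY line")
  keyword <- ifelse(grepl("^\\S", lines), trimws(substr(lines, 1, 12)), NA)
  for (i in seq_along(keyword))
    if (is.na(keyword[i])) keyword[i] <- keyword[i - 1]
  value <- trimws(substring(lines, 13))
  section <- function(kw) value[keyword == kw]

  entry <- strsplit(section("ENTRY")[1], "\\s+")[[1]][1]
  name_txt <- paste(section("NAME"), collapse = " ")
  aliases <- if (nzchar(name_txt)) trimws(strsplit(name_txt, ",")[[1]]) else character()
  definition <- paste(section("DEFINITION"), collapse = " ")
  pw_lines <- section("PATHWAY")
  pathways <- if (length(pw_lines)) {
    ids <- sub("^(\\S+)\\s+.*$", "\\1", pw_lines)
    nms <- sub("^\\S+\\s+", "", pw_lines)
    data.frame(id = ids, name = nms, stringsAsFactors = FALSE)
  } else data.frame(id = character(), name = character(), stringsAsFactors = FALSE)

  structure(list(gene_id = entry, name = aliases, definition = definition,
                 pathways = pathways),
            class = "gene_record")
}

#' Fetch and parse one gene record through the cache
#' @param client A [kegg_client].
#' @param gene_id KEGG gene identifier, e.g. `"hsa:1356"`.
#' @return A `gene_record` (see [parse_gene_record()]).
#' @export
fetch_gene_record <- function(client, gene_id) {
  stopifnot(nzchar(gene_id))
  parse_gene_record(rawToChar(cached_get(client, paste0("get/", gene_id))))
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("gene_record %s: %s\n", x$gene_id,
              paste(head(x$name, 3), collapse = ", ")))
  if (nzchar(x$definition)) cat("  ", x$definition, "\n", sep = "")
  cat(sprintf("  member of %d pathway(s)\n", nrow(x$pathways)))
  invisible(x)
}
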
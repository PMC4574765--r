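#' Generate a two-group expression dataset with planted effects
#'
#' Simulates a log2-scale expression matrix: each gene gets a baseline
#' drawn from Normal(7, 2) (a typical log2 microarray intensity range),
#' reference samples are Normal(baseline, noise_sd), and case samples are
#' shifted by `effect_size` for the planted differentially expressed genes
#' only. Fully deterministic for a fixed seed.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (>= 2).
#' @param n_de Number of differentially expressed genes (<= n_genes).
#' @param effect_size Planted log2 mean shift (delta), default 2.
#' @param noise_sd Within-group standard deviation (sigma > 0), default 1.
#' @param seed Integer seed governing all draws.
#' @param reference,case Group labels.
#' @return List with `dataset` (an [expression_dataset]) and `truth`
#'   (class `synthetic_truth`: `de_gene_ids`, `effect_size`, `noise_sd`,
#'   `n_per_group`, `seed`).
#' @export
generate_dataset <- function(n_genes = 1000, n_per_group = 10, n_de = 50,
                             effect_size = 2, noise_sd = 1, seed = 1,
                             reference = "low", case = "high") {
  if (n_de > n_genes) stop("generate_dataset: n_de must not exceed n_genes")
  if (n_per_group < 2) stop("generate_dataset: n_per_group must be >= 2")
  if (noise_sd <= 0) stop("generate_dataset: noise_sd must be > 0")
  set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  de_genes <- if (n_de > 0) sort(sample(gene_ids, n_de)) else character()
  sample_ids <- c(sprintf("ref_%02d", seq_len(n_per_group)),
                  sprintf("case_%02d", seq_len(n_per_group)))
  groups <- setNames(rep(c(reference, case), each = n_per_group), sample_ids)
  baseline <- rnorm(n_genes, mean = 7, sd = 2)
  values <- baseline + matrix(rnorm(n_genes * 2 * n_per_group, sd = noise_sd),
                              nrow = n_genes)
  shift_cols <- n_per_group + seq_len(n_per_group)
  values[gene_ids %in% de_genes, shift_cols] <-
    values[gene_ids %in% de_genes, shift_cols] + effect_size
  dimnames(values) <- list(gene_ids, sample_ids)
  list(dataset = expression_dataset(values, groups, reference),
       truth = structure(list(de_gene_ids = de_genes, effect_size = effect_size,
                              noise_sd = noise_sd, n_per_group = n_per_group,
                              seed = seed),
                         class = "synthetic_truth"))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d DE genes, delta = %g log2 units, sigma = %g, n = %d/group, seed = %d\n",
              length(x$de_gene_ids), x$effect_size, x$noise_sd,
              x$n_per_group, x$seed))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes the tab-delimited matrix and design files consumed by
#' [load_dataset()], plus a JSON truth manifest recording the planted
#' differentially expressed genes and all generator parameters, so every
#' simulated fixture carries its own provenance.
#'
#' @param sim List from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, named character vector of the three file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.json"))
  write_dataset(sim$dataset, paths[["matrix"]], paths[["design"]])
  jsonlite::write_json(unclass(sim$truth), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Generate a valid KGML pathway fixture
#'
#' Emits well-formed KGML accepted by [parse_kgml()]: `n_gene_nodes` gene
#' entries, `n_compound_nodes` compound entries and `n_edges` relations
#' between distinct nodes, so parsed node and relation counts equal the
#' generator parameters exactly. Optional extras exercise the rarer KGML
#' constructs: `include_map` adds one map entry, `include_group` adds one
#' group entry spanning the first two gene nodes, and `include_reaction`
#' adds one two-substrate/two-product reaction over the first four
#' compound nodes (parsed into four cross-product edges). Gene entries
#' draw their KEGG identifiers from `gene_pool` when given, which ties a
#' pathway fixture to a simulated expression dataset. Deterministic for a
#' fixed seed.
#'
#' @param n_gene_nodes,n_compound_nodes Node counts.
#' @param n_edges Number of relation edges; must not exceed the number of
#'   distinct ordered pairs over all entries.
#' @param seed Integer seed.
#' @param gene_pool Optional character vector of gene ids to draw from.
#' @param pathway_id Identifier written into the document.
#' @param include_map,include_group,include_reaction Add the optional
#'   constructs described above (group needs >= 2 gene nodes, reaction
#'   needs >= 4 compound nodes; otherwise silently omitted).
#' @return Single string of KGML XML.
#' @export
generate_kgml_fixture <- function(n_gene_nodes, n_compound_nodes = 0,
                                  n_edges = 0, seed = 1, gene_pool = NULL,
                                  pathway_id = "syn00001",
                                  include_map = FALSE, include_group = FALSE,
                                  include_reaction = FALSE) {
  set.seed(seed)
  add_map <- include_map
  add_group <- include_group && n_gene_nodes >= 2
  add_reaction <- include_reaction && n_compound_nodes >= 4
  n_total <- n_gene_nodes + n_compound_nodes + add_map + add_group
  if (n_edges > n_total * (n_total - 1))
    stop("generate_kgml_fixture: n_edges exceeds the number of distinct ordered pairs")

  ids <- as.character(seq_len(n_total))
  types <- c(rep("gene", n_gene_nodes), rep("compound", n_compound_nodes),
             if (add_map) "map", if (add_group) "group")
  gene_names <- if (is.null(gene_pool)) {
    sprintf("hsa:%d", sample(1000:99999, n_gene_nodes))
  } else {
    # reuse of pool entries is deliberate: several nodes may share a gene
    as.character(sample(gene_pool, n_gene_nodes, replace = TRUE))
  }

  entry_xml <- vapply(seq_len(n_total), function(i) {
    type <- types[i]
    name <- switch(type,
      gene = gene_names[i],
      compound = sprintf("cpd:C%05d", sample.int(99999, 1)),
      map = sprintf("path:%s", pathway_id),
      group = "undefined")
    label <- switch(type,
      gene = sprintf("GENE%s, alias%s", ids[i], ids[i]),
      compound = sprintf("C%s", ids[i]),
      map = sprintf("MAP %s", pathway_id),
      group = "")
    gfx <- sprintf('<graphics name="%s" type="rectangle" x="%d" y="%d" width="46" height="17"/>',
                   xml_escape(label), sample.int(900, 1), sample.int(600, 1))
    comp <- if (type == "group")
      '<component id="1"/><component id="2"/>' else ""
    sprintf('<entry id="%s" name="%s" type="%s">%s%s</entry>',
            ids[i], xml_escape(name), type, gfx, comp)
  }, "")

  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  sel <- pairs[sample.int(nrow(pairs), n_edges), , drop = FALSE]
  subtypes <- c("activation", "inhibition", "compound", "expression")
  relation_xml <- if (n_edges > 0) vapply(seq_len(n_edges), function(i) {
    sprintf('<relation entry1="%s" entry2="%s" type="PPrel"><subtype name="%s" value="--&gt;"/></relation>',
            sel$source[i], sel$target[i], sample(subtypes, 1))
  }, "") else character()

  reaction_xml <- if (add_reaction) {
    cpd <- ids[n_gene_nodes + 1:4]
    sprintf(paste0('<reaction id="%s" name="rn:R%05d" type="irreversible">',
                   '<substrate id="%s" name="s"/><substrate id="%s" name="s"/>',
                   '<product id="%s" name="p"/><product id="%s" name="p"/></reaction>'),
            cpd[1], sample.int(99999, 1), cpd[1], cpd[2], cpd[3], cpd[4])
  } else character()

  paste0(
    '<?xml version="1.0"?>\n',
    sprintf('<pathway name="path:%s" org="%s" number="%s" title="Synthetic pathway %s" image="https://example.org/%s.png">\n',
            pathway_id, substr(pathway_id, 1, 3), gsub("\\D", "", pathway_id),
            pathway_id, pathway_id),
    paste(c(entry_xml, relation_xml, reaction_xml), collapse = "\n"),
    "\n</pathway>\n")
}
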
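# On-disk formats. Everything is plain text: TSV tables, MSigDB-style GMT,
# and Cytoscape-loadable GraphML / SIF network exports.

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a sample-group table
#'
#' TSV with columns `sample_id` and `group` (exactly two labels).
#'
#' @param path File path.
#' @param group1 Label to treat as group1; defaults to the first label in
#'   file order, with a message.
#' @return A [sample_groups()] object.
#' @export
read_sample_groups <- function(path, group1 = NULL) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  sample_groups(tbl, group1 = group1)
}

#' @rdname read_sample_groups
#' @param groups A `sample_groups` object to write.
#' @export
write_sample_groups <- function(groups, path) {
  readr::write_tsv(tibble(sample_id = groups$sample_id, group = groups$group),
                   path)
  invisible(path)
}

#' Read a probe-level PMA call table
#'
#' TSV with a header of sample ids, first column `probe_id`, and cells in
#' `P`/`M`/`A` (case-insensitive on read; upper-cased). Any other cell value
#' is a hard error naming the probe and sample. If `groups_path` is given the
#' matching group table is read and every sample must be labelled.
#'
#' @param path PMA TSV path.
#' @param groups_path Optional sample-group TSV path.
#' @param group1 Passed to [read_sample_groups()].
#' @return The PMA tibble, or `list(pma, groups)` when `groups_path` is given.
#' @export
read_pma_table <- function(path, groups_path = NULL, group1 = NULL) {
  pma <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  names(pma)[1L] <- "probe_id"
  if (anyDuplicated(pma$probe_id)) abort("duplicated probe ids in PMA table")
  for (s in names(pma)[-1L]) {
    v <- toupper(pma[[s]])
    bad <- which(!v %in% c("P", "M", "A"))
    if (length(bad) > 0L) {
      abort(sprintf("invalid call '%s' at (%s, %s)",
                    pma[[s]][bad[1]], pma$probe_id[bad[1]], s))
    }
    pma[[s]] <- v
  }
  if (is.null(groups_path)) return(pma)
  groups <- read_sample_groups(groups_path, group1 = group1)
  check_samples_labelled(names(pma)[-1L], groups)
  list(pma = pma, groups = groups)
}

#' @rdname read_pma_table
#' @param pma A PMA tibble to write (calls upper-cased).
#' @export
write_pma_table <- function(pma, path) {
  out <- pma
  for (s in names(out)[-1L]) out[[s]] <- toupper(out[[s]])
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' TSV with columns `probe_id` and `gene`; probe ids must be unique (a probe
#' measures one gene; a gene may own many probes).
#' @param path File path.
#' @return Tibble `probe_id`, `gene`.
#' @export
read_probe_map <- function(path) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  names(tbl)[1:2] <- c("probe_id", "gene")
  if (anyDuplicated(tbl$probe_id)) abort("duplicated probe ids in probe map")
  tbl[c("probe_id", "gene")]
}

#' Read / write gene-set collections in GMT format
#'
#' MSigDB dialect: one set per line -- name, description, then tab-separated
#' member symbols. Members are intersected with `universe`; sets empty after
#' intersection are dropped with a warning; duplicate set names are an error.
#' The description column is preserved but otherwise unused.
#'
#' @param path File path.
#' @param universe Character vector of measured gene symbols (the enrichment
#'   background).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short)) abort(sprintf("GMT line %d has fewer than 3 fields",
                                which(short)[1]))
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate set name in GMT: %s", nm[duplicated(nm)][1]))
  }
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- setNames(lapply(parts, function(x) x[-(1:2)]), nm)
  gene_set_collection(sets, universe, descriptions = setNames(desc, nm))
}

#' @rdname read_gmt
#' @param gene_sets A `gene_set_collection` to write.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- purrr::pmap_chr(
    list(gene_sets$set_name, gene_sets$description, gene_sets$genes),
    function(nm, d, g) paste(c(nm, d, g), collapse = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read / write gene-level activity tables
#'
#' Genes-by-samples TSV of 0/1 values, first column `gene`.
#' @param path File path.
#' @return Activity tibble.
#' @export
read_activity <- function(path) {
  tbl <- read_tsv_quiet(path)
  names(tbl)[1L] <- "gene"
  invisible(act_matrix(tbl))  # validates
  tbl
}

#' @rdname read_activity
#' @param activity Activity tibble to write.
#' @export
write_activity <- function(activity, path) {
  readr::write_tsv(activity, path)
  invisible(path)
}

# ---- gene-network edge lists ----------------------------------------------

#' Load a directed/undirected gene network from an edge-list TSV
#'
#' Rows `(source, target, type)` with `type` in `directed` / `undirected`.
#' Contradictory duplicates (2-cycles, an edge both directed and undirected)
#' are an error. Extra isolated nodes may be supplied via `nodes`.
#'
#' @param path File path.
#' @param nodes Optional node names to include even if unconnected.
#' @return A [cpdag()].
#' @export
load_network <- function(path, nodes = NULL) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  names(tbl)[1:3] <- c("source", "target", "type")
  bad <- !tbl$type %in% c("directed", "undirected")
  if (any(bad)) abort(sprintf("unknown edge type '%s'", tbl$type[bad][1]))
  all_nodes <- sort(unique(c(tbl$source, tbl$target, nodes)))
  cpdag(all_nodes,
        directed = tibble(from = tbl$source[tbl$type == "directed"],
                          to = tbl$target[tbl$type == "directed"]),
        undirected = tibble(from = tbl$source[tbl$type == "undirected"],
                            to = tbl$target[tbl$type == "undirected"]))
}

#' @rdname load_network
#' @param net A `cpdag` to write as `(source, target, type)` TSV.
#' @export
write_network_edges <- function(net, path) {
  stopifnot(inherits(net, "cpdag"))
  tbl <- dplyr::bind_rows(
    tibble(source = net$directed$from, target = net$directed$to,
           type = "directed"),
    tibble(source = net$undirected$from, target = net$undirected$to,
           type = "undirected"))
  readr::write_tsv(tbl, path)
  invisible(path)
}

# ---- pathway-network export ------------------------------------------------

#' Export a pathway network for Cytoscape
#'
#' GraphML carries node attribute `class` (group1/group2/both) and edge
#' attributes `p` and `q`; SIF writes `A interacts B` triples; TSV writes the
#' full edge table. An empty edge set yields a node-only file.
#'
#' @param network A `pathway_network` from [build_pathway_network()].
#' @param path Output file path.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "sif", "tsv")) {
  stopifnot(inherits(network, "pathway_network"))
  if (!is.character(format) || !format[1] %in% c("graphml", "sif", "tsv")) {
    abort(sprintf("unknown network format '%s'", format[1]))
  }
  format <- match.arg(format)
  nodes <- network$nodes
  edges <- network$edges
  if (format == "tsv") {
    readr::write_tsv(edges, path)
  } else if (format == "sif") {
    lines <- if (nrow(edges) > 0L) {
      paste(edges$pathway_a, "interacts", edges$pathway_b, sep = "\t")
    } else character(0)
    solo <- setdiff(nodes$pathway, c(edges$pathway_a, edges$pathway_b))
    readr::write_lines(c(lines, solo), path)
  } else {
    write_graphml(nodes, edges, path)
  }
  invisible(path)
}

write_graphml <- function(nodes, edges, path) {
  doc <- xml2::xml_new_root("graphml",
                            xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (k in list(c("class", "node", "string"),
                 c("p", "edge", "double"),
                 c("q", "edge", "double"))) {
    xml2::xml_add_child(doc, "key", id = k[1], `for` = k[2],
                        attr.name = k[1], attr.type = k[3])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "pathway_network",
                           edgedefault = "undirected")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = nodes$pathway[i])
    d <- xml2::xml_add_child(nd, "data", key = "class")
    xml2::xml_text(d) <- nodes$class[i]
  }
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = edges$pathway_a[i],
                              target = edges$pathway_b[i])
    dp <- xml2::xml_add_child(ed, "data", key = "p")
    xml2::xml_text(dp) <- format(edges$p[i], digits = 17)
    dq <- xml2::xml_add_child(ed, "data", key = "q")
    xml2::xml_text(dq) <- format(edges$q[i], digits = 17)
  }
  xml2::write_xml(doc, path)
}

#' Read back a GraphML pathway-network export
#'
#' Round-trip counterpart of [write_network()]'s GraphML writer.
#' @param path GraphML file.
#' @return List with `nodes` (tibble `pathway`, `class`) and `edges`
#'   (tibble `pathway_a`, `pathway_b`, `p`, `q`).
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node_els <- xml2::xml_find_all(doc, ".//g:node", ns)
  nodes <- tibble(
    pathway = xml2::xml_attr(node_els, "id"),
    class = xml2::xml_text(xml2::xml_find_first(node_els,
                                                ".//g:data[@key='class']", ns)))
  edge_els <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- tibble(
    pathway_a = xml2::xml_attr(edge_els, "source"),
    pathway_b = xml2::xml_attr(edge_els, "target"),
    p = as.numeric(xml2::xml_text(
      xml2::xml_find_first(edge_els, ".//g:data[@key='p']", ns))),
    q = as.numeric(xml2::xml_text(
      xml2::xml_find_first(edge_els, ".//g:data[@key='q']", ns))))
  list(nodes = nodes, edges = edges)
}

#' Read a pathway gene-pair edge list
#'
#' TSV with columns `pathway`, `gene_a`, `gene_b` (for example the
#' cytokine-receptor edges of a signalling pathway diagram).
#' @param path File path.
#' @return Tibble.
#' @export
read_pair_list <- function(path) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  names(tbl)[1:3] <- c("pathway", "gene_a", "gene_b")
  tbl[1:3]
}

#' Read a pathway node-to-member-gene map
#'
#' TSV with columns `pathway`, `node`, `gene` mapping diagram nodes (such as
#' a calmodulin box) to their interchangeable member genes.
#' @param path File path.
#' @return Tibble.
#' @export
read_node_map <- function(path) {
  tbl <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  names(tbl)[1:3] <- c("pathway", "node", "gene")
  tbl[1:3]
}
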
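RELATION_LEVELS <- c("BINARY_INTERACTOR", "KNOWN_SUBSTRATE",
                     "PREDICTED_SUBSTRATE", "PREDICTED_UPSTREAM_KINASE")

#' Read an annotation table of interactors and kinase-substrate relations
#'
#' The expected schema is four tab-separated columns: `gene` (symbol,
#' harmonized to the catalog's accession namespace by the caller), `site`
#' (like `"S392"`, or empty for protein-level records), `relation` (one of
#' BINARY_INTERACTOR, KNOWN_SUBSTRATE, PREDICTED_SUBSTRATE,
#' PREDICTED_UPSTREAM_KINASE) and `source` (free-text provenance, e.g. the
#' name of the interaction or kinase-substrate resource the table was
#' exported from).
#'
#' @param path TSV path
#' @return data.table (gene, site, relation, source)
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- fread(path, sep = "\t", na.strings = c("", "NA"),
               colClasses = list(character = c("gene", "site", "relation",
                                               "source")))
  need <- c("gene", "site", "relation", "source")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !(ann$relation %in% RELATION_LEVELS)
  if (any(bad)) stop("unknown relation(s): ",
                     paste(unique(ann$relation[bad]), collapse = ", "))
  if (any(is.na(ann$source))) stop("annotation source must be non-empty")
  ann
}

#' Overlay annotation records onto co-regulated PsOP results
#'
#' BINARY_INTERACTOR records match at the protein level; substrate/kinase
#' records match at the site level when the record carries a site, otherwise
#' at the protein level with `protein_level_match = TRUE`. PsOP rows are
#' never modified: annotations are returned as additional rows in a long
#' (psop x relation) table.
#'
#' @param psops data.table from [run_coregulation()] (typically filtered to
#'   `high_confidence` rows)
#' @param annotations data.table from [read_annotations()]
#' @return data.table (psop, gene, site, sign, coreg_frequency, relation,
#'   source, protein_level_match), one row per matched (PsOP, annotation)
#'   pair; summary counts attached as attribute `"summary"`: per relation,
#'   the number of distinct annotated proteins and the numbers of distinct
#'   positively / negatively co-regulated annotated sites
#' @export
annotate_psops <- function(psops, annotations) {
  ps <- as.data.table(psops)
  keys <- parse_site_key(ps$psop)
  ps <- cbind(ps[, .(psop, sign, coreg_frequency)],
              gene = keys$accession,
              site = paste0(keys$residue, keys$position))
  ann <- as.data.table(annotations)
  prot_level <- ann[relation == "BINARY_INTERACTOR" | is.na(site)]
  site_level <- ann[relation != "BINARY_INTERACTOR" & !is.na(site)]
  hits_p <- merge(ps, prot_level[, .(gene, relation, source)], by = "gene",
                  allow.cartesian = TRUE)
  if (nrow(hits_p)) hits_p[, protein_level_match := TRUE]
  hits_s <- merge(ps, site_level[, .(gene, site, relation, source)],
                  by = c("gene", "site"), allow.cartesian = TRUE)
  if (nrow(hits_s)) hits_s[, protein_level_match := FALSE]
  out <- rbindlist(list(hits_p, hits_s), use.names = TRUE, fill = TRUE)
  if (nrow(out)) {
    setcolorder(out, c("psop", "gene", "site", "sign", "coreg_frequency",
                       "relation", "source", "protein_level_match"))
    setorder(out, relation, psop)
  } else {
    out <- data.table(psop = character(), gene = character(),
                      site = character(), sign = character(),
                      coreg_frequency = integer(), relation = character(),
                      source = character(), protein_level_match = logical())
  }
  summ <- out[, .(
    n_proteins = uniqueN(gene),
    n_sites_positive = uniqueN(psop[sign == "POSITIVE"]),
    n_sites_negative = uniqueN(psop[sign == "NEGATIVE"])
  ), by = relation]
  unmatched <- ann[!(gene %in% ps$gene)]
  if (nrow(unmatched)) {
    msg(sprintf("annotate_psops: %d annotation record(s) matched no PsOP",
                nrow(unmatched)))
  }
  setattr(out, "summary", summ)
  out[]
}

#' Build the anchor-centric co-regulation network
#'
#' Star-plus topology: one edge from the anchor site to every annotated PsOP
#' site, weighted by co-regulation frequency, signed, and typed by relation.
#' A PsOP carrying several relations yields either multiple parallel typed
#' edges (`multi_edge = TRUE`, default) or a single edge whose `edge_type`
#' joins the relations with `;`.
#'
#' @param annotated data.table from [annotate_psops()]
#' @param anchor anchor site key string (e.g. `"CIT_S440"`)
#' @param multi_edge one edge per relation, or one merged edge per PsOP
#' @return an `igraph` graph with vertex attribute `node_type`
#'   (anchor/psop) and edge attributes `edge_type`, `sign`, `weight`
#' @export
build_network <- function(annotated, anchor, multi_edge = TRUE) {
  ann <- as.data.table(annotated)
  if (!nrow(ann)) {
    warning("empty annotated table: returning empty graph")
    g <- igraph::make_empty_graph(directed = FALSE)
    return(igraph::add_vertices(g, 1, name = anchor, node_type = "anchor"))
  }
  if (!multi_edge) {
    ann <- ann[, .(relation = paste(sort(unique(relation)), collapse = ";"),
                   sign = sign[1L], coreg_frequency = coreg_frequency[1L]),
               by = psop]
  }
  setorder(ann, psop, relation)
  edges <- ann[, .(from = anchor, to = psop, edge_type = relation,
                   sign = sign, weight = as.numeric(coreg_frequency))]
  verts <- data.table(name = c(anchor, sort(unique(edges$to))),
                      node_type = c("anchor",
                                    rep("psop", uniqueN(edges$to))))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Export a network in GraphML format
#'
#' @param graph igraph object from [build_network()]
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Export a network in SIF (simple interaction format)
#'
#' One line per edge: `source <TAB> edge_type <TAB> target`.
#'
#' @inheritParams write_graphml
#' @return invisibly, `path`
#' @export
write_sif <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  type <- igraph::edge_attr(graph, "edge_type")
  if (is.null(type)) type <- rep("edge", nrow(el))
  lines <- if (nrow(el)) paste(el[, 1], type, el[, 2], sep = "\t") else character()
  writeLines(lines, path)
  invisible(path)
}

#' Long-format regulation table for heat-map rendering
#'
#' One row per (site, experimental condition, dataset) regulation call for
#' the given sites — the machine-readable equivalent of a site-by-condition
#' regulation heat map.
#'
#' @param catalog a `phospho_catalog`
#' @param site_keys character vector of site keys to include
#' @return data.table (site, experimental_code, dataset_id, pmid, call)
#' @export
heatmap_long <- function(catalog, site_keys) {
  keys <- parse_site_key(site_keys)
  calls <- regulation_calls(catalog)
  calls[, site := site_key(accession, residue, position)]
  out <- calls[site %in% site_keys]
  out <- merge(out,
               catalog$datasets[, .(dataset_id, experimental_code, pmid)],
               by = "dataset_id")
  setorder(out, site, experimental_code, dataset_id)
  out[, .(site, experimental_code, dataset_id, pmid, call)]
}
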
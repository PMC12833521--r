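#' Default pipeline configuration
#'
#' @return named list of configuration defaults; any subset can be supplied
#'   in a YAML file or as overrides to [run_pipeline()]
#' @export
default_pipeline_config <- function() {
  list(
    observations = NULL, datasets = NULL, fasta = NULL, annotations = NULL,
    anchor = NULL,            # site key; NULL = top-ranked predominant site
    anchor_protein = NULL,    # protein whose sites are ranked; inferred from
                              # anchor when given
    log_fc = FALSE,
    min_loc_prob = 0.75, min_a_score = 13,
    up_fc = 1.3, down_fc = 0.76, max_p = 0.05,
    fet_max_p = 0.05, ratio_fraction = 0.10, ratio_absolute = NULL,
    min_pmids = 2L, min_expcodes = 2L, unregulated = "absent",
    predominant_fraction = 0.5, predominant_mode = "top_k",
    predominant_k = 6L,
    motif_mode = "adjacent",
    multi_edge = TRUE
  )
}

#' @noRd
load_pipeline_config <- function(config, overrides = list()) {
  cfg <- default_pipeline_config()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  for (src in list(config, overrides)) {
    for (nm in names(src)) {
      if (!nm %in% names(cfg)) stop("unknown config key: ", nm)
      cfg[[nm]] <- src[[nm]]
    }
  }
  cfg
}

#' Run the full co-regulation pipeline
#'
#' Stages: load and validate the catalog, Class-1 filter, optional window
#' validation against FASTA, site frequency ranking and predominant-site
#' selection for the anchor protein, within-protein co-occurrence, PsOP
#' co-regulation with confidence filtering, motif scan of high-confidence
#' PsOP windows plus the anchor window, annotation overlay, network
#' construction, and export. All stage outputs are written to `out_dir` as
#' TSV/GraphML/SIF plus a JSON run manifest (config snapshot, input file
#' MD5 digests, per-stage row counts, package version, timestamp).
#'
#' @param config path to a YAML config file, or a named list (see
#'   [default_pipeline_config()])
#' @param out_dir output directory (created if needed)
#' @param ... individual config overrides, e.g. `anchor = "ANCH_S15"`
#' @param verbose log stage progress to stderr
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest
#' @export
run_pipeline <- function(config, out_dir, ..., verbose = TRUE) {
  cfg <- load_pipeline_config(config, list(...))
  for (key in c("observations", "datasets")) {
    if (is.null(cfg[[key]])) stop("config must provide '", key, "'")
    if (!file.exists(cfg[[key]])) {
      stop("input file for '", key, "' not found: ", cfg[[key]])
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- threshold_config(cfg$min_loc_prob, cfg$min_a_score, cfg$up_fc,
                          cfg$down_fc, cfg$max_p)
  conf <- confidence_config(cfg$fet_max_p, cfg$ratio_fraction,
                            cfg$ratio_absolute, cfg$min_pmids,
                            cfg$min_expcodes, cfg$unregulated)

  msg("stage: load catalog", verbose = verbose)
  catalog <- read_catalog(cfg$observations, cfg$datasets, cfg = thr,
                          log_fc = cfg$log_fc, verbose = verbose)
  n_raw <- nrow(catalog$observations)
  catalog <- filter_class1(catalog)
  msg(sprintf("stage: class1 filter kept %d/%d observations",
              nrow(catalog$observations), n_raw), verbose = verbose)
  reference <- NULL
  if (!is.null(cfg$fasta)) {
    reference <- Biostrings::readAAStringSet(cfg$fasta)
    names(reference) <- sub("\\s.*$", "", names(reference))
    catalog <- filter_validated(catalog, reference)
    msg(sprintf("stage: window validation kept %d observations",
                nrow(catalog$observations)), verbose = verbose)
  }

  # anchor resolution: explicit key, else top-ranked predominant site of the
  # anchor protein, which defaults to the most-observed protein
  anchor_protein <- cfg$anchor_protein
  if (is.null(anchor_protein)) {
    anchor_protein <- if (!is.null(cfg$anchor)) {
      parse_site_key(cfg$anchor)$accession
    } else {
      # protein owning the single most frequently observed phosphosite
      catalog$observations[, .N, by = .(accession, residue, position)][
        order(-N)]$accession[1L]
    }
  }
  freqs <- site_frequencies(catalog, anchor_protein)
  n_prof_total <- catalog$datasets[kind == "PROFILE", .N]
  n_diff_total <- catalog$datasets[kind == "DIFFERENTIAL", .N]
  pre <- predominant_sites(freqs, max(n_prof_total, 1L),
                           max(n_diff_total, 1L),
                           fraction = cfg$predominant_fraction,
                           mode = cfg$predominant_mode,
                           k = cfg$predominant_k)
  anchor <- cfg$anchor
  if (is.null(anchor)) {
    if (!nrow(pre)) stop("no predominant site found for ", anchor_protein)
    anchor <- site_key(pre$accession[1L], pre$residue[1L], pre$position[1L])
  } else {
    ak <- parse_site_key(anchor)
    known <- freqs[residue == ak$residue & position == ak$position]
    if (!nrow(known)) {
      stop("anchor ", anchor, " not detected; available sites: ",
           paste(site_key(freqs$accession, freqs$residue, freqs$position),
                 collapse = ", "))
    }
  }
  msg("stage: anchor = ", anchor, verbose = verbose)

  cooc <- cooccurrence(catalog, anchor_protein)
  psops <- run_coregulation(catalog, anchor, conf)
  hc <- psops[high_confidence == TRUE]

  # motif scan: anchor-protein sites plus high-confidence PsOP windows
  win_tbl <- unique(catalog$observations[
    site_key(accession, residue, position) %in%
      c(anchor, hc$psop) & !is.na(window),
    .(accession, residue, position, window)])
  motifs <- scan_sites(win_tbl, mode = cfg$motif_mode)

  annotated <- NULL
  graph <- NULL
  if (!is.null(cfg$annotations) && nrow(hc)) {
    annotations <- read_annotations(cfg$annotations)
    annotated <- annotate_psops(hc, annotations)
    graph <- build_network(annotated, anchor, multi_edge = cfg$multi_edge)
  }

  msg("stage: export", verbose = verbose)
  wr <- function(x, f) fwrite(x, file.path(out_dir, f), sep = "\t", na = "",
                              quote = FALSE)
  wr(freqs, "site_frequencies.tsv")
  wr(pre, "predominant_sites.tsv")
  wr(cooc, "cooccurrence.tsv")
  wr(psops, "coregulation.tsv")
  wr(motifs, "motif_scan.tsv")
  wr(attr(motifs, "per_protein"), "motif_per_protein.tsv")
  hm <- heatmap_long(catalog, unique(c(anchor, hc$psop)))
  wr(hm, "heatmap_long.tsv")
  if (!is.null(annotated)) {
    wr(annotated, "annotated_psops.tsv")
    wr(attr(annotated, "summary"), "annotation_summary.tsv")
    write_graphml(graph, file.path(out_dir, "network.graphml"))
    write_sif(graph, file.path(out_dir, "network.sif"))
  }

  inputs <- Filter(Negate(is.null),
                   cfg[c("observations", "datasets", "fasta", "annotations")])
  manifest <- list(
    tool = "phoscoreg", version = as.character(packageVersion("phoscoreg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[!vapply(cfg, is.null, TRUE)],
    input_digests = as.list(tools::md5sum(unlist(inputs))),
    anchor = anchor,
    rows = list(
      observations_raw = n_raw,
      observations_class1 = nrow(catalog$observations),
      rejected = nrow(catalog$rejected),
      site_frequencies = nrow(freqs),
      predominant_sites = nrow(pre),
      cooccurrence_pairs = nrow(cooc),
      psop_candidates = nrow(psops),
      high_confidence_positive = psops[, sum(high_confidence & sign == "POSITIVE")],
      high_confidence_negative = psops[, sum(high_confidence & sign == "NEGATIVE")],
      motif_matches = motifs[, sum(matched_motif != "NONE")],
      motif_proteins_matched = attr(motifs, "n_proteins_matched"),
      annotated_rows = if (is.null(annotated)) 0L else nrow(annotated)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(catalog = catalog, frequencies = freqs, predominant = pre,
                 cooccurrence = cooc, psops = psops, motifs = motifs,
                 annotated = annotated, graph = graph, manifest = manifest))
}
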
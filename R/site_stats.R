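#' Phosphosite detection/regulation frequencies for one protein
#'
#' Counts, for every distinct phosphosite on `accession`, the number of
#' profile datasets in which the site was detected (`n_profile`) and the
#' number of differential datasets in which it was called up- or
#' downregulated (`n_diff = n_up + n_down`). This is the ranking used to
#' identify a protein's predominant phosphosite.
#'
#' @param catalog a `phospho_catalog`, Class-1 filter already applied
#' @param accession protein accession
#' @return data.table (accession, residue, position, n_profile, n_diff, n_up,
#'   n_down) sorted by n_diff desc, n_profile desc, position asc
#' @export
site_frequencies <- function(catalog, accession) {
  acc <- accession
  obs <- catalog$observations[accession == acc]
  if (!nrow(obs)) {
    warning("accession not present in catalog: ", acc)
    return(data.table(accession = character(), residue = character(),
                      position = integer(), n_profile = integer(),
                      n_diff = integer(), n_up = integer(),
                      n_down = integer()))
  }
  prof_ids <- catalog$datasets[kind == "PROFILE", dataset_id]
  prof <- obs[dataset_id %in% prof_ids,
              .(n_profile = uniqueN(dataset_id)),
              by = .(accession, residue, position)]
  calls <- regulation_calls(catalog)[accession == acc]
  dif <- calls[call %in% c("UP", "DOWN"),
               .(n_diff = .N, n_up = sum(call == "UP"),
                 n_down = sum(call == "DOWN")),
               by = .(accession, residue, position)]
  all_sites <- unique(obs[, .(accession, residue, position)])
  out <- merge(all_sites, prof, by = c("accession", "residue", "position"),
               all.x = TRUE)
  out <- merge(out, dif, by = c("accession", "residue", "position"),
               all.x = TRUE)
  for (col in c("n_profile", "n_diff", "n_up", "n_down")) {
    out[is.na(get(col)), (col) := 0L]
  }
  setorder(out, -n_diff, -n_profile, position)
  out[]
}

#' Select predominant phosphosites
#'
#' The strict rule keeps sites detected in more than `fraction` of the
#' profile datasets *and* regulated in more than `fraction` of the
#' differential datasets. Because frequently studied proteins often have only
#' one site clearing that bar, a rank-based alternative (`mode = "top_k"`,
#' top `k` by differential frequency) is also provided; the full ranked
#' frequency table is attached as attribute `"ranked"` either way.
#'
#' @param freqs output of [site_frequencies()]
#' @param n_profile_total,n_diff_total total numbers of profile and
#'   differential datasets in the catalog
#' @param fraction detection fraction threshold, strict `>` (default 0.5)
#' @param mode `"fraction"` (strict rule) or `"top_k"`
#' @param k number of sites kept in `top_k` mode (default 6)
#' @return data.table of selected sites (subset of `freqs` rows, same order),
#'   with the full ranked table in `attr(, "ranked")`
#' @export
predominant_sites <- function(freqs, n_profile_total, n_diff_total,
                              fraction = 0.5, mode = c("fraction", "top_k"),
                              k = 6L) {
  mode <- match.arg(mode)
  stopifnot(n_profile_total > 0, n_diff_total > 0)
  if (mode == "fraction") {
    sel <- freqs[n_profile / n_profile_total > fraction &
                 n_diff / n_diff_total > fraction]
  } else {
    sel <- freqs[seq_len(min(k, nrow(freqs)))][n_diff > 0]
  }
  setattr(sel, "ranked", copy(freqs))
  sel[]
}

#' Within-protein phosphosite co-occurrence across differential datasets
#'
#' For every unordered pair of phosphosites on `accession` that are both
#' called UP or DOWN in at least one differential dataset, tallies positive
#' co-occurrence (both UP or both DOWN) and negative co-occurrence (opposite
#' calls). Co-detections where either site is UNREGULATED are ignored: the
#' analysis concerns co-*differential* regulation.
#'
#' @param catalog a `phospho_catalog`, Class-1 filter applied
#' @param accession protein accession
#' @return data.table with one row per co-called pair: site_a/site_b keys
#'   (a before b by position), n_positive, n_both_up, n_both_down,
#'   n_negative, n_codetected (= n_positive + n_negative), n_conditions
#'   (distinct experimental codes among co-called datasets); sorted by
#'   n_positive descending
#' @export
cooccurrence <- function(catalog, accession) {
  acc <- accession
  calls <- regulation_calls(catalog)[accession == acc & call %in% c("UP", "DOWN")]
  empty <- data.table(site_a = character(), site_b = character(),
                      n_positive = integer(), n_both_up = integer(),
                      n_both_down = integer(), n_negative = integer(),
                      n_codetected = integer(), n_conditions = integer())
  if (nrow(calls) < 2L) return(empty)
  calls[, site := site_key(accession, residue, position)]
  a <- calls[, .(dataset_id, site_a = site, position_a = position,
                 call_a = call)]
  b <- calls[, .(dataset_id, site_b = site, position_b = position,
                 call_b = call)]
  pairs <- merge(a, b, by = "dataset_id", allow.cartesian = TRUE)
  pairs <- pairs[position_a < position_b]
  if (!nrow(pairs)) return(empty)
  pairs <- merge(pairs,
                 catalog$datasets[, .(dataset_id, experimental_code)],
                 by = "dataset_id")
  out <- pairs[, .(
    n_positive   = sum(call_a == call_b),
    n_both_up    = sum(call_a == "UP" & call_b == "UP"),
    n_both_down  = sum(call_a == "DOWN" & call_b == "DOWN"),
    n_negative   = sum(call_a != call_b),
    n_codetected = .N,
    n_conditions = uniqueN(experimental_code)
  ), by = .(site_a, site_b)]
  setorder(out, -n_positive, site_a, site_b)
  out[]
}

#' @importFrom data.table uniqueN setattr
NULL
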
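#' @importFrom data.table data.table as.data.table setDT setorder setorderv := .N .SD fread fwrite rbindlist setnames setcolorder copy
#' @importFrom stats runif rnorm rbinom setNames p.adjust
#' @importFrom utils packageVersion
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "accession", "residue", "position", "dataset_id", "window",
  "loc_prob", "a_score", "fold_change", "p_value", "kind", "pmid",
  "experimental_code", "enrichment", "call", "n_profile", "n_diff",
  "n_up", "n_down", "site_a", "site_b", "call_a", "call_b", "anchor",
  "psop", "p", "bh_q", "sign", "high_confidence", "relation", "gene",
  "site", "matched_motif", "n_positive", "n_negative", "class1",
  "coreg_frequency", "ratio", "pmid_count", "expcode_count", "source",
  "position_a", "position_b", "n_both_up", "n_both_down", "n_codetected",
  "n_conditions", "is_class1_obs", "tie", "n_matches", "protein_level_match"
))

#' Construct a phosphosite key string
#'
#' Sites are identified by protein accession, phosphoacceptor residue and
#' 1-based position on the canonical sequence, rendered as
#' `"<accession>_<residue><position>"` (e.g. `"CIT_S440"`).
#'
#' @param accession protein accession / gene symbol
#' @param residue one of `"S"`, `"T"`, `"Y"`
#' @param position 1-based integer position
#' @return character vector of site keys
#' @export
site_key <- function(accession, residue, position) {
  stopifnot(all(residue %in% c("S", "T", "Y")), all(position >= 1))
  if (!length(accession)) return(character())
  paste0(accession, "_", residue, position)
}

#' Parse a site key string into its components
#'
#' @param key character vector like `"CIT_S440"`; the accession may itself
#'   contain underscores — the residue/position suffix after the last
#'   underscore is parsed.
#' @return data.table with columns accession, residue, position
#' @export
parse_site_key <- function(key) {
  if (!length(key)) {
    return(data.table(accession = character(), residue = character(),
                      position = integer()))
  }
  m <- regmatches(key, regexec("^(.*)_([STY])([0-9]+)$", key))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed site key(s): ", paste(key[bad], collapse = ", "))
  }
  data.table(
    accession = vapply(m, `[`, "", 2L),
    residue   = vapply(m, `[`, "", 3L),
    position  = as.integer(vapply(m, `[`, "", 4L))
  )
}

#' @noRd
msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

# deterministic sub-seed derivation; keeps results < 2^31
#' @noRd
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}
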
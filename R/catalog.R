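#' Threshold configuration for confidence filtering and regulation calls
#'
#' Defaults follow the curation conventions used throughout the package:
#' Class-1 sites require a localization probability of at least 75% or an
#' ambiguity score (A-score) strictly above 13; differential regulation calls
#' require a study-level p-value strictly below 0.05 together with a linear
#' fold change of at least 1.3 (up) or at most 0.76 (down).
#'
#' @param min_loc_prob minimum localization probability, inclusive (default 0.75)
#' @param min_a_score A-score threshold, strict `>` (default 13)
#' @param up_fc upregulation fold-change threshold, inclusive `>=` (default 1.3)
#' @param down_fc downregulation fold-change threshold, inclusive `<=` (default 0.76)
#' @param max_p p-value threshold, strict `<` (default 0.05)
#' @return object of class `threshold_config`
#' @export
threshold_config <- function(min_loc_prob = 0.75, min_a_score = 13,
                             up_fc = 1.3, down_fc = 0.76, max_p = 0.05) {
  stopifnot(down_fc < 1, up_fc > 1, max_p > 0, max_p < 1,
            min_loc_prob >= 0, min_loc_prob <= 1, min_a_score >= 0)
  structure(list(min_loc_prob = min_loc_prob, min_a_score = min_a_score,
                 up_fc = up_fc, down_fc = down_fc, max_p = max_p),
            class = "threshold_config")
}

OBS_COLS <- c("accession", "residue", "position", "dataset_id", "window",
              "loc_prob", "a_score", "fold_change", "p_value")
DS_COLS <- c("dataset_id", "kind", "pmid", "experimental_code", "enrichment")

#' Read a curated phosphoproteomic catalog from TSV files
#'
#' The catalog consists of an observation table (one row per phosphosite
#' observation in one dataset) and a dataset metadata table. Observations in
#' differential datasets carry fold changes and p-values; profile (qualitative)
#' observations are detection-only. Rows with malformed residues or positions
#' are rejected with row-level diagnostics rather than aborting the load.
#'
#' @param observations_path TSV with columns accession, residue, position,
#'   dataset_id, window, loc_prob, a_score, fold_change, p_value (empty cells
#'   for absent values)
#' @param datasets_path TSV with columns dataset_id, kind (PROFILE or
#'   DIFFERENTIAL), pmid, experimental_code, enrichment (STY/ST/Y)
#' @param cfg a [threshold_config()]
#' @param log_fc if `TRUE`, fold changes in the file are log2 and are
#'   converted to the linear scale on load
#' @param verbose emit row-rejection diagnostics
#' @return object of class `phospho_catalog`: a list with data.tables
#'   `observations` and `datasets`, the `cfg`, and a `rejected` table of
#'   dropped rows with a `reason` column
#' @export
read_catalog <- function(observations_path, datasets_path,
                         cfg = threshold_config(), log_fc = FALSE,
                         verbose = TRUE) {
  for (pth in c(observations_path, datasets_path)) {
    if (!file.exists(pth)) stop("input file not found: ", pth)
  }
  obs <- fread(observations_path, sep = "\t", colClasses = list(
    character = c("accession", "residue", "dataset_id", "window")),
    na.strings = c("", "NA"))
  ds <- fread(datasets_path, sep = "\t", na.strings = c("", "NA"),
              colClasses = list(character = c("dataset_id", "pmid",
                                              "experimental_code")))
  miss_o <- setdiff(OBS_COLS, names(obs))
  if (length(miss_o)) stop("observation table missing column(s): ",
                           paste(miss_o, collapse = ", "))
  miss_d <- setdiff(DS_COLS, names(ds))
  if (length(miss_d)) stop("dataset table missing column(s): ",
                           paste(miss_d, collapse = ", "))
  if (anyDuplicated(ds$dataset_id)) stop("duplicate dataset_id in dataset table")
  if (!all(ds$kind %in% c("PROFILE", "DIFFERENTIAL")))
    stop("dataset kind must be PROFILE or DIFFERENTIAL")

  unknown <- setdiff(unique(obs$dataset_id), ds$dataset_id)
  if (length(unknown)) {
    stop("observations reference undeclared dataset_id(s): ",
         paste(unknown, collapse = ", "))
  }
  obs[, position := suppressWarnings(as.integer(position))]
  if (log_fc) obs[, fold_change := 2^fold_change]
  build_catalog(obs, ds, cfg, verbose = verbose)
}

# validates row-level invariants, splitting off a rejected table
#' @noRd
build_catalog <- function(obs, ds, cfg = threshold_config(), verbose = TRUE) {
  obs <- as.data.table(obs)
  ds <- as.data.table(ds)
  reason <- rep(NA_character_, nrow(obs))
  bad_res <- !(obs$residue %in% c("S", "T", "Y"))
  bad_pos <- is.na(obs$position) | obs$position < 1
  has_win <- !is.na(obs$window)
  bad_win <- has_win & nchar(obs$window) != 15L
  bad_ctr <- has_win & !bad_win & substr(obs$window, 8, 8) != obs$residue
  bad_fc <- !is.na(obs$fold_change) & obs$fold_change <= 0
  reason[bad_fc]  <- "non-positive fold change"
  reason[bad_ctr] <- "window center != residue"
  reason[bad_win] <- "window length != 15"
  reason[bad_pos] <- "invalid position"
  reason[bad_res] <- "invalid residue"
  rej <- obs[!is.na(reason)][, reason := reason[!is.na(reason)]]
  if (nrow(rej) && verbose) {
    msg(sprintf("read_catalog: rejected %d malformed observation row(s)",
                nrow(rej)))
  }
  obs <- obs[is.na(reason)]
  structure(list(observations = obs, datasets = ds, cfg = cfg,
                 rejected = rej),
            class = "phospho_catalog")
}

#' @export
print.phospho_catalog <- function(x, ...) {
  nk <- table(factor(x$datasets$kind, c("PROFILE", "DIFFERENTIAL")))
  cat(sprintf(paste0("phospho_catalog: %d observations | %d datasets ",
                     "(%d profile, %d differential) | %d rejected rows\n"),
              nrow(x$observations), nrow(x$datasets),
              nk[["PROFILE"]], nk[["DIFFERENTIAL"]], nrow(x$rejected)))
  invisible(x)
}

#' Write a catalog back to TSV files
#'
#' Inverse of [read_catalog()]; valid catalogs round-trip byte-identically.
#'
#' @param catalog a `phospho_catalog`
#' @param observations_path,datasets_path output TSV paths
#' @return invisibly, the two paths
#' @export
write_catalog <- function(catalog, observations_path, datasets_path) {
  fwrite(catalog$observations[, OBS_COLS, with = FALSE], observations_path,
         sep = "\t", na = "", quote = FALSE)
  fwrite(catalog$datasets[, DS_COLS, with = FALSE], datasets_path,
         sep = "\t", na = "", quote = FALSE)
  invisible(c(observations_path, datasets_path))
}

#' Class-1 confidence test for phosphosite observations
#'
#' A site observation is Class-1 (confidently localized) when its
#' localization probability is at least `cfg$min_loc_prob` *or* its A-score
#' exceeds `cfg$min_a_score` (the two criteria are alternatives because source
#' studies typically report only one of them). Observations carrying neither
#' score are unclassifiable and return `FALSE`.
#'
#' @param loc_prob numeric vector of localization probabilities (NA = absent)
#' @param a_score numeric vector of A-scores (NA = absent)
#' @param cfg a [threshold_config()]
#' @return logical vector
#' @export
is_class1 <- function(loc_prob, a_score, cfg = threshold_config()) {
  lp <- !is.na(loc_prob) & loc_prob >= cfg$min_loc_prob
  as_ <- !is.na(a_score) & a_score > cfg$min_a_score
  lp | as_
}

#' Apply the Class-1 filter to a catalog
#'
#' @param catalog a `phospho_catalog`
#' @return the catalog with non-Class-1 observations removed
#' @export
filter_class1 <- function(catalog) {
  keep <- is_class1(catalog$observations$loc_prob,
                    catalog$observations$a_score, catalog$cfg)
  catalog$observations <- catalog$observations[keep]
  catalog
}

#' Classify differential regulation from fold change and p-value
#'
#' `UP` when `fold_change >= cfg$up_fc` and `p_value < cfg$max_p`; `DOWN` when
#' `fold_change <= cfg$down_fc` and `p_value < cfg$max_p`; otherwise
#' `UNREGULATED`. Fold changes are on the linear scale. Every valid
#' (fold change, p-value) pair maps to exactly one of the three calls.
#'
#' @param fold_change positive numeric vector (linear scale)
#' @param p_value numeric vector in (0, 1]; `NA` p-values never pass
#' @param cfg a [threshold_config()]
#' @return character vector of calls in `{"UP","DOWN","UNREGULATED"}`
#' @export
classify_regulation <- function(fold_change, p_value, cfg = threshold_config()) {
  if (any(!is.na(fold_change) & fold_change <= 0)) {
    stop("fold_change must be positive (linear scale)")
  }
  sig <- !is.na(p_value) & p_value < cfg$max_p
  out <- rep("UNREGULATED", length(fold_change))
  out[sig & !is.na(fold_change) & fold_change >= cfg$up_fc] <- "UP"
  out[sig & !is.na(fold_change) & fold_change <= cfg$down_fc] <- "DOWN"
  out[is.na(fold_change)] <- NA_character_
  out
}

#' Per-dataset regulation calls for all sites in the differential datasets
#'
#' @param catalog a `phospho_catalog` (Class-1 filter applied by the caller if
#'   desired)
#' @return data.table (dataset_id, accession, residue, position, call) with
#'   call in UP/DOWN/UNREGULATED; sites absent from a dataset simply have no
#'   row (NOT_DETECTED is implicit)
#' @export
regulation_calls <- function(catalog) {
  diff_ids <- catalog$datasets[kind == "DIFFERENTIAL", dataset_id]
  d <- catalog$observations[dataset_id %in% diff_ids]
  if (!nrow(d)) {
    return(data.table(dataset_id = character(), accession = character(),
                      residue = character(), position = integer(),
                      call = character()))
  }
  d[, .(call = classify_regulation(fold_change, p_value, catalog$cfg)),
    by = .(dataset_id, accession, residue, position)][!is.na(call)]
}

#' Validate observation sequence windows against reference sequences
#'
#' Checks that each 15-mer window (ignoring `_` terminus padding) matches the
#' reference protein sequence centred at the reported position. Sites on
#' accessions absent from the reference are skipped with a warning (returned
#' as `NA`).
#'
#' @param sites data.frame/data.table with columns accession, residue,
#'   position, window
#' @param reference named character vector of protein sequences, or a
#'   `Biostrings::AAStringSet`
#' @return logical vector: `TRUE` valid, `FALSE` mismatch, `NA` no reference
#' @export
validate_window <- function(sites, reference) {
  if (inherits(reference, "AAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  sites <- as.data.table(sites)
  out <- rep(NA, nrow(sites))
  have <- sites$accession %in% names(reference)
  if (!all(have)) {
    warning("no reference sequence for accession(s): ",
            paste(unique(sites$accession[!have]), collapse = ", "),
            "; window validation skipped for those sites")
  }
  for (i in which(have)) {
    seqc <- reference[[sites$accession[i]]]
    pos <- sites$position[i]
    if (pos < 1 || pos > nchar(seqc)) { out[i] <- FALSE; next }
    out[i] <- identical(extract_window(seqc, pos), sites$window[i])
  }
  out
}

#' Drop observations whose windows fail reference validation
#'
#' Observations failing validation are excluded (no isoform remapping is
#' attempted); sites without reference coverage are kept.
#'
#' @inheritParams validate_window
#' @param catalog a `phospho_catalog`
#' @return the filtered catalog; dropped rows are appended to `$rejected`
#' @export
filter_validated <- function(catalog, reference) {
  ok <- validate_window(catalog$observations, reference)
  drop <- !is.na(ok) & !ok
  if (any(drop)) {
    bad <- copy(catalog$observations[drop])[, reason := "window mismatch vs reference"]
    catalog$rejected <- rbindlist(list(catalog$rejected, bad), fill = TRUE)
    catalog$observations <- catalog$observations[!drop]
  }
  catalog
}
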
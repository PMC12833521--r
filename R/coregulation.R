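#' Confidence-filter configuration for co-regulated PsOPs
#'
#' A PsOP (phosphosite in another protein) is high-confidence when all four
#' filters pass: FET p-value below `max_p`; concordant/discordant ratio at
#' least `ratio_fraction` times the anchor's total differential frequency
#' (or at least `ratio_absolute` when given, overriding the fraction);
#' co-regulation supported by at least `min_pmids` distinct studies (PubMed
#' IDs) and at least `min_expcodes` distinct experimental conditions.
#'
#' @param max_p FET p-value threshold, strict `<` (default 0.05)
#' @param ratio_fraction fraction of the anchor's differential frequency that
#'   the d/c (or c/d) ratio must reach, inclusive `>=` (default 0.10)
#' @param ratio_absolute optional absolute ratio threshold overriding
#'   `ratio_fraction`
#' @param min_pmids minimum distinct PubMed IDs among co-regulated datasets
#'   (default 2)
#' @param min_expcodes minimum distinct experimental codes among co-regulated
#'   datasets (default 2)
#' @param unregulated one of `"absent"` (default: detected-but-unregulated
#'   observations count as not detected when building the contingency cells)
#'   or `"detected"` (they count into the singles cell b)
#' @return object of class `confidence_config`
#' @export
confidence_config <- function(max_p = 0.05, ratio_fraction = 0.10,
                              ratio_absolute = NULL, min_pmids = 2L,
                              min_expcodes = 2L,
                              unregulated = c("absent", "detected")) {
  stopifnot(max_p > 0, max_p < 1, ratio_fraction > 0,
            min_pmids >= 1, min_expcodes >= 1)
  structure(list(max_p = max_p, ratio_fraction = ratio_fraction,
                 ratio_absolute = ratio_absolute,
                 min_pmids = as.integer(min_pmids),
                 min_expcodes = as.integer(min_expcodes),
                 unregulated = match.arg(unregulated)),
            class = "confidence_config")
}

CELL_NAMES <- c("n_UcUo", "n_UcDo", "n_DcUo", "n_DcDo",
                "n_Uc0", "n_Dc0", "n_0Uo", "n_0Do", "n_0c0o")

#' Nine-cell co-detection/co-regulation tally for an (anchor, PsOP) pair
#'
#' Each differential dataset is assigned to exactly one of nine mutually
#' exclusive cells by the anchor call (`Uc`/`Dc`/absent) and the other site's
#' call (`Uo`/`Do`/absent). The derived 2x2 contingency cells are
#' `a = n_0c0o` (neither detected), `b` = one-sided detections,
#' `c = n_UcDo + n_DcUo` (discordant) and `d = n_UcUo + n_DcDo` (concordant).
#'
#' @param anchor_calls,other_calls named character vectors of regulation calls
#'   (`"UP"`/`"DOWN"`; anything else or missing = not detected), names are
#'   dataset ids
#' @param dataset_ids character vector of all differential dataset ids under
#'   consideration
#' @return object of class `coreg_counts`: named integer vector of the nine
#'   cells plus `n_total`
#' @export
categorize_pair <- function(anchor_calls, other_calls, dataset_ids) {
  stray <- setdiff(c(names(anchor_calls), names(other_calls)), dataset_ids)
  if (length(stray)) {
    stop("call map references dataset(s) outside dataset_ids: ",
         paste(stray, collapse = ", "))
  }
  ac <- anchor_calls[dataset_ids]
  oc <- other_calls[dataset_ids]
  a_up <- !is.na(ac) & ac == "UP";   a_dn <- !is.na(ac) & ac == "DOWN"
  o_up <- !is.na(oc) & oc == "UP";   o_dn <- !is.na(oc) & oc == "DOWN"
  a_abs <- !(a_up | a_dn); o_abs <- !(o_up | o_dn)
  cells <- c(
    n_UcUo = sum(a_up & o_up), n_UcDo = sum(a_up & o_dn),
    n_DcUo = sum(a_dn & o_up), n_DcDo = sum(a_dn & o_dn),
    n_Uc0 = sum(a_up & o_abs), n_Dc0 = sum(a_dn & o_abs),
    n_0Uo = sum(a_abs & o_up), n_0Do = sum(a_abs & o_dn),
    n_0c0o = sum(a_abs & o_abs)
  )
  coreg_counts(cells, n_total = length(dataset_ids))
}

#' Construct a validated coreg_counts object
#'
#' @param cells named integer vector with the nine cell names (see
#'   [categorize_pair()])
#' @param n_total total number of differential datasets; must equal the cell
#'   sum
#' @return `coreg_counts` object
#' @export
coreg_counts <- function(cells, n_total = sum(cells)) {
  cells <- cells[CELL_NAMES]
  if (anyNA(cells) || any(cells < 0)) stop("invalid coreg cells")
  if (sum(cells) != n_total) stop("cells do not sum to n_total")
  structure(c(as.integer(cells), n_total = as.integer(n_total)),
            names = c(CELL_NAMES, "n_total"), class = "coreg_counts")
}

#' Derive the 2x2 contingency cells (a, b, c, d) from a nine-cell tally
#'
#' @param counts a `coreg_counts`
#' @return named integer vector `c(a=, b=, c=, d=)`
#' @export
contingency_cells <- function(counts) {
  cnt <- unclass(counts)
  c(a = unname(cnt["n_0c0o"]),
    b = unname(cnt["n_Uc0"] + cnt["n_Dc0"] + cnt["n_0Uo"] + cnt["n_0Do"]),
    c = unname(cnt["n_UcDo"] + cnt["n_DcUo"]),
    d = unname(cnt["n_UcUo"] + cnt["n_DcDo"]))
}

#' One-sided Fisher's exact p-value on the co-regulation contingency table
#'
#' The table is `[[a, b], [c, d]]` with margins fixed. For `sign =
#' "POSITIVE"` the p-value is the exact hypergeometric probability of a table
#' at least as extreme in the direction of larger `d` (concordant
#' co-regulation); for `"NEGATIVE"`, larger `c` (discordant). Computed as an
#' explicit tail sum of hypergeometric point masses over the support (no call
#' into `fisher.test`), so tests can verify it against independent oracles.
#'
#' @param counts a `coreg_counts`, or a named vector/list with elements
#'   `a, b, c, d`
#' @param sign `"POSITIVE"` or `"NEGATIVE"`
#' @return p-value in (0, 1]
#' @export
fet_pvalue <- function(counts, sign = c("POSITIVE", "NEGATIVE")) {
  sign <- match.arg(sign)
  cl <- if (inherits(counts, "coreg_counts")) contingency_cells(counts)
        else unlist(counts)[c("a", "b", "c", "d")]
  a <- cl[["a"]]; b <- cl[["b"]]; cc <- cl[["c"]]; d <- cl[["d"]]
  n <- a + b + cc + d
  if (n == 0) stop("empty contingency")
  row2 <- cc + d           # pair-detected margin
  col2 <- b + d
  # support of d with all four margins fixed
  xs <- max(0L, row2 + col2 - n):min(row2, col2)
  logp <- lchoose(col2, xs) + lchoose(n - col2, row2 - xs) - lchoose(n, row2)
  pmass <- exp(logp)
  p <- if (sign == "POSITIVE") sum(pmass[xs >= d]) else sum(pmass[xs <= d])
  min(max(p, .Machine$double.xmin), 1)
}

#' Concordant/discordant co-regulation ratio
#'
#' `d / c` for positive sign, `c / d` for negative sign; a zero denominator
#' yields `Inf` (a sentinel that passes any finite ratio threshold).
#'
#' @inheritParams fet_pvalue
#' @return non-negative real (possibly `Inf`)
#' @export
coregulation_ratio <- function(counts, sign = c("POSITIVE", "NEGATIVE")) {
  sign <- match.arg(sign)
  cl <- if (inherits(counts, "coreg_counts")) contingency_cells(counts)
        else unlist(counts)[c("a", "b", "c", "d")]
  num <- if (sign == "POSITIVE") cl[["d"]] else cl[["c"]]
  den <- if (sign == "POSITIVE") cl[["c"]] else cl[["d"]]
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

#' Apply the four high-confidence filters to a PsOP result row
#'
#' @param result one-row data.frame/list with fields p, ratio, pmid_count,
#'   expcode_count (as produced by [run_coregulation()])
#' @param anchor_diff_frequency the anchor site's total differential
#'   frequency (number of datasets where it is UP or DOWN)
#' @param cfg a [confidence_config()]
#' @return logical: high confidence or not
#' @export
apply_confidence_filters <- function(result, anchor_diff_frequency,
                                     cfg = confidence_config()) {
  thr <- if (!is.null(cfg$ratio_absolute)) cfg$ratio_absolute
         else cfg$ratio_fraction * anchor_diff_frequency
  isTRUE(result$p < cfg$max_p) &&
    isTRUE(result$ratio >= thr) &&
    isTRUE(result$pmid_count >= cfg$min_pmids) &&
    isTRUE(result$expcode_count >= cfg$min_expcodes)
}

#' Identify phosphosites in other proteins co-regulated with an anchor site
#'
#' For every phosphosite on a different protein that is co-called with the
#' anchor in at least one differential dataset, builds the nine-cell tally
#' over all differential datasets, computes the one-sided FET p-value in the
#' direction of the dominant pattern (concordant vs discordant; ties are
#' called POSITIVE and flagged), the co-regulation ratio and frequency, the
#' study (PMID) and experimental-condition diversity of the co-regulated
#' datasets, and the high-confidence flag.
#'
#' @param catalog a `phospho_catalog`, Class-1 filter applied
#' @param anchor anchor site: a key string like `"CIT_S440"` or a list/row
#'   with accession, residue, position
#' @param cfg a [confidence_config()]
#' @return data.table sorted by p ascending, one row per candidate PsOP, with
#'   columns anchor, psop, the nine cells, a/b/c/d, p, bh_q
#'   (Benjamini-Hochberg, reported for transparency; not used for filtering),
#'   sign, tie, coreg_frequency (d for POSITIVE, c for NEGATIVE), ratio,
#'   pmid_count, expcode_count, high_confidence. Summary counts are attached
#'   as attribute `"summary"`.
#' @export
run_coregulation <- function(catalog, anchor, cfg = confidence_config()) {
  if (is.character(anchor)) anchor <- parse_site_key(anchor)
  anchor <- as.list(as.data.frame(anchor))
  anchor_key <- site_key(anchor$accession, anchor$residue, anchor$position)

  diff_ids <- catalog$datasets[kind == "DIFFERENTIAL", dataset_id]
  calls <- regulation_calls(catalog)
  anchor_all <- calls[accession == anchor$accession &
                      residue == anchor$residue & position == anchor$position]
  acalls <- anchor_all[call %in% c("UP", "DOWN")]
  if (!nrow(acalls)) {
    stop("anchor site ", anchor_key,
         " is never differentially regulated in this catalog")
  }
  anchor_diff_frequency <- nrow(acalls)
  avec <- setNames(acalls$call, acalls$dataset_id)
  # in "detected" mode, detected-but-unregulated observations count as
  # detections for the singles cell b; in "absent" mode they are invisible
  a_unreg <- if (cfg$unregulated == "detected")
    anchor_all[call == "UNREGULATED", dataset_id] else character()

  cand <- calls[accession != anchor$accession]
  if (cfg$unregulated == "absent") cand <- cand[call %in% c("UP", "DOWN")]
  if (!nrow(cand)) return(empty_psop_table())
  cand[, psop := site_key(accession, residue, position)]
  ds_meta <- catalog$datasets[, .(dataset_id, pmid, experimental_code)]
  cand <- merge(cand, ds_meta, by = "dataset_id")

  n_total <- length(diff_ids)
  res <- cand[, psop_row(.SD, avec, a_unreg, n_total,
                         anchor_diff_frequency, cfg),
              by = psop]
  res <- res[!is.na(p)]
  if (!nrow(res)) return(empty_psop_table())
  res[, anchor := anchor_key]
  res[, bh_q := p.adjust(p, method = "BH")]
  setorder(res, p, psop)
  setcolorder(res, c("anchor", "psop"))
  summ <- list(
    anchor = anchor_key,
    anchor_diff_frequency = anchor_diff_frequency,
    n_candidates = nrow(res),
    n_high_confidence_positive = res[, sum(high_confidence & sign == "POSITIVE")],
    n_high_confidence_negative = res[, sum(high_confidence & sign == "NEGATIVE")]
  )
  setattr(res, "summary", summ)
  res[]
}

# one PsOP against the anchor; .sd has dataset_id, call, pmid, experimental_code
#' @noRd
psop_row <- function(.sd, avec, a_unreg, n_total, anchor_diff_frequency, cfg) {
  ovec <- setNames(.sd$call, .sd$dataset_id)
  a_reg <- names(avec)
  o_reg <- names(ovec)[ovec %in% c("UP", "DOWN")]
  o_unreg <- names(ovec)[ovec == "UNREGULATED"]
  co <- intersect(a_reg, o_reg)
  if (!length(co)) return(list(p = NA_real_))  # never co-called; dropped
  ac <- avec[co]; oc <- ovec[co]
  n_UcUo <- sum(ac == "UP" & oc == "UP")
  n_UcDo <- sum(ac == "UP" & oc == "DOWN")
  n_DcUo <- sum(ac == "DOWN" & oc == "UP")
  n_DcDo <- sum(ac == "DOWN" & oc == "DOWN")
  n_Uc0 <- sum(avec == "UP" & !(a_reg %in% co))
  n_Dc0 <- sum(avec == "DOWN" & !(a_reg %in% co))
  only_o <- setdiff(o_reg, a_reg)
  n_0Uo <- sum(ovec[only_o] == "UP")
  n_0Do <- sum(ovec[only_o] == "DOWN")
  d <- n_UcUo + n_DcDo
  cc <- n_UcDo + n_DcUo
  b <- n_Uc0 + n_Dc0 + n_0Uo + n_0Do
  # detected-but-unregulated observations optionally count as detections in b
  # (only datasets not already in a directional cell)
  b_extra <- length(setdiff(union(a_unreg, o_unreg),
                            c(co, a_reg, o_reg)))
  b <- b + b_extra
  a <- n_total - b - cc - d
  tie <- d == cc
  sgn <- if (d >= cc) "POSITIVE" else "NEGATIVE"
  p <- fet_pvalue(list(a = a, b = b, c = cc, d = d), sgn)
  ratio <- coregulation_ratio(list(a = a, b = b, c = cc, d = d), sgn)
  coreg_ds <- if (sgn == "POSITIVE") co[ac == oc] else co[ac != oc]
  meta <- .sd[dataset_id %in% coreg_ds]
  pmid_count <- uniqueN(meta$pmid)
  expcode_count <- uniqueN(meta$experimental_code)
  row <- list(
    n_UcUo = n_UcUo, n_UcDo = n_UcDo, n_DcUo = n_DcUo, n_DcDo = n_DcDo,
    n_Uc0 = n_Uc0, n_Dc0 = n_Dc0, n_0Uo = n_0Uo, n_0Do = n_0Do,
    n_0c0o = a, a = a, b = b, c = cc, d = d,
    p = p, sign = sgn, tie = tie,
    coreg_frequency = if (sgn == "POSITIVE") d else cc,
    ratio = ratio, pmid_count = pmid_count, expcode_count = expcode_count
  )
  row$high_confidence <- apply_confidence_filters(
    row, anchor_diff_frequency, cfg)
  row
}

#' @noRd
empty_psop_table <- function() {
  data.table(anchor = character(), psop = character(),
             n_UcUo = integer(), n_UcDo = integer(), n_DcUo = integer(),
             n_DcDo = integer(), n_Uc0 = integer(), n_Dc0 = integer(),
             n_0Uo = integer(), n_0Do = integer(), n_0c0o = integer(),
             a = integer(), b = integer(), c = integer(), d = integer(),
             p = numeric(), bh_q = numeric(), sign = character(),
             tie = logical(), coreg_frequency = integer(), ratio = numeric(),
             pmid_count = integer(), expcode_count = integer(),
             high_confidence = logical())
}
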
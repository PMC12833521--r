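#' Extract a +/-halfwidth sequence window around a phosphoacceptor
#'
#' Returns the `2*halfwidth + 1`-mer centred on `position`, padded with `_`
#' where the window runs past either terminus (MaxQuant-style convention).
#'
#' @param sequence amino-acid string (single protein sequence)
#' @param position 1-based acceptor position; vectorised
#' @param halfwidth window half-width in residues (default 7, i.e. a 15-mer)
#' @return character vector of windows
#' @export
extract_window <- function(sequence, position, halfwidth = 7L) {
  len <- nchar(sequence)
  if (any(position < 1L | position > len)) {
    stop("position out of range 1..", len)
  }
  padded <- paste0(strrep("_", halfwidth), sequence, strrep("_", halfwidth))
  # acceptor sits at index position + halfwidth in the padded string
  substring(padded, position, position + 2L * halfwidth)
}

#' Match the D(S/T)P / P(S/T)D kinase substrate motif in a 15-mer window
#'
#' The motif is aspartate and proline flanking the phosphoacceptor at
#' positions -1/+1 in either order: `D` at -1 with `P` at +1 (`DSP_TYPE`) or
#' `P` at -1 with `D` at +1 (`PSD_TYPE`). Matching is case-insensitive.
#' Windows centred on tyrosine return `NONE` (the motif describes a
#' serine/threonine kinase). With `mode = "anywhere"` the motif may occur at
#' any S/T acceptor within the window, not only the centre.
#'
#' @param window character vector of 15-character windows
#' @param mode `"adjacent"` (default: flanks of the central acceptor) or
#'   `"anywhere"` (substring scan across the window)
#' @return character vector in `{"DSP_TYPE","PSD_TYPE","NONE"}`
#' @export
match_motif <- function(window, mode = c("adjacent", "anywhere")) {
  mode <- match.arg(mode)
  if (any(nchar(window) != 15L)) stop("windows must be exactly 15 characters")
  w <- toupper(window)
  if (mode == "adjacent") {
    centre <- substr(w, 8, 8)
    left <- substr(w, 7, 7)
    right <- substr(w, 9, 9)
    out <- rep("NONE", length(w))
    st <- centre %in% c("S", "T")
    out[st & left == "D" & right == "P"] <- "DSP_TYPE"
    out[st & left == "P" & right == "D"] <- "PSD_TYPE"
  } else {
    out <- rep("NONE", length(w))
    out[grepl("P[ST]D", w)] <- "PSD_TYPE"
    out[grepl("D[ST]P", w)] <- "DSP_TYPE"  # DSP wins when both occur
  }
  out
}

#' Scan a table of phosphosite windows for the substrate motif
#'
#' @param sites data.frame/data.table with columns accession, residue,
#'   position, window (15-mers)
#' @param mode passed to [match_motif()]
#' @return data.table of all input sites with a `matched_motif` column;
#'   attributes `"per_protein"` (data.table accession, n_sites, n_matches)
#'   and `"n_proteins_matched"` (count of distinct proteins with >= 1 match)
#' @export
scan_sites <- function(sites, mode = c("adjacent", "anywhere")) {
  mode <- match.arg(mode)
  sites <- as.data.table(sites)
  if (!nrow(sites)) {
    out <- data.table(accession = character(), residue = character(),
                      position = integer(), window = character(),
                      matched_motif = character())
    setattr(out, "per_protein",
            data.table(accession = character(), n_sites = integer(),
                       n_matches = integer()))
    setattr(out, "n_proteins_matched", 0L)
    return(out)
  }
  out <- copy(sites)
  out[, matched_motif := match_motif(window, mode)]
  per <- out[, .(n_sites = .N, n_matches = sum(matched_motif != "NONE")),
             by = accession]
  setorder(per, accession)
  setattr(out, "per_protein", per)
  setattr(out, "n_proteins_matched", per[n_matches > 0, .N])
  out[]
}
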
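AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration for the synthetic catalog generator
#'
#' The defaults describe the stated benchmark world: 150 differential and 100
#' profile datasets drawn from 20 studies (PMIDs) across 30 experimental
#' conditions; an anchor protein whose first site is the planted predominant
#' site (differential detection 0.55, profile detection 0.74 — the detection
#' rates observed for a real predominant phosphosite); 30 planted positively
#' and 5 negatively co-regulated partner sites at concordance 0.95 on other
#' proteins; 47 background proteins x 5 sites = 235 non-anchor sites, of
#' which 200 are null. Fold changes for regulated events are drawn beyond the
#' 1.3/0.76 thresholds (truncated log-normal) with p < 0.05; unregulated
#' detections are centred at fold change 1 with p >= 0.05, so the overall
#' fold-change distribution straddles the thresholds and every classifier
#' branch is exercised.
#'
#' @param n_profile_datasets,n_diff_datasets dataset counts
#' @param n_pmids,n_expcodes numbers of distinct studies and experimental
#'   condition codes, assigned round-robin with 20% random reassignment
#' @param n_proteins,sites_per_protein background/partner protein structure
#' @param anchor_accession accession of the anchor protein (also gets
#'   `sites_per_protein` sites; site 1 is the anchor)
#' @param anchor_detect_prob anchor detection probability per differential
#'   dataset (default 0.55)
#' @param anchor_profile_detect_prob anchor detection probability per profile
#'   dataset (default 0.74)
#' @param planted_positive_pairs,planted_negative_pairs numbers of planted
#'   co-regulated partner sites (one per background protein, site 1)
#' @param concordance probability a planted partner's call matches (positive
#'   partners) or opposes (negative partners) the anchor's call when both are
#'   regulated in a dataset (default 0.95)
#' @param cooccur_concordance same, for the planted within-protein
#'   co-occurring sibling site on the anchor protein (default 0.9)
#' @param partner_detect_prob planted partner detection probability per
#'   differential dataset (default 0.6)
#' @param background_detect_prob detection probability for null sites and
#'   anchor-protein siblings in differential datasets (default 0.25)
#' @param background_profile_detect_prob detection probability for non-anchor
#'   sites in profile datasets (default 0.3)
#' @param background_up_prob P(direction = UP) for background regulated calls
#' @param reg_given_detect P(an independently detected site passes the
#'   fold-change/p thresholds) (default 0.9)
#' @param class1_prob P(an observation carries a Class-1-passing score)
#' @param fc_sdlog log-scale spread of regulated fold changes beyond the
#'   thresholds
#' @param motif_plant_rate fraction of sites given D/P (or P/D) flanks at
#'   -1/+1 (default 0.5)
#' @param annotate_interactor_frac,annotate_substrate_frac fractions of
#'   planted positive partners annotated as interactors (protein level) and
#'   predicted substrates (site level)
#' @param n_decoy_annotations decoy annotation records on null proteins
#' @param seed integer master seed; all sub-streams derive from it
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_profile_datasets = 100L,
                              n_diff_datasets = 150L,
                              n_pmids = 20L, n_expcodes = 30L,
                              n_proteins = 47L, sites_per_protein = 5L,
                              anchor_accession = "ANCH",
                              anchor_detect_prob = 0.55,
                              anchor_profile_detect_prob = 0.74,
                              planted_positive_pairs = 30L,
                              planted_negative_pairs = 5L,
                              concordance = 0.95,
                              cooccur_concordance = 0.9,
                              partner_detect_prob = 0.6,
                              background_detect_prob = 0.25,
                              background_profile_detect_prob = 0.3,
                              background_up_prob = 0.5,
                              reg_given_detect = 0.9,
                              class1_prob = 0.9,
                              fc_sdlog = 0.35,
                              motif_plant_rate = 0.5,
                              annotate_interactor_frac = 0.5,
                              annotate_substrate_frac = 0.5,
                              n_decoy_annotations = 10L,
                              seed = 42L) {
  cfg <- as.list(environment())
  fr <- c("anchor_detect_prob", "anchor_profile_detect_prob", "concordance",
          "cooccur_concordance", "partner_detect_prob",
          "background_detect_prob", "background_profile_detect_prob",
          "background_up_prob", "reg_given_detect", "class1_prob",
          "motif_plant_rate", "annotate_interactor_frac",
          "annotate_substrate_frac")
  for (f in fr) stopifnot(cfg[[f]] >= 0, cfg[[f]] <= 1)
  n_partners <- cfg$planted_positive_pairs + cfg$planted_negative_pairs
  if (n_partners > cfg$n_proteins) {
    stop("infeasible config: more planted partners (", n_partners,
         ") than background proteins (", cfg$n_proteins, ")")
  }
  structure(cfg, class = "simulation_config")
}

# site table with roles and planted motif flanks; positions every 20 residues
#' @noRd
site_table <- function(cfg) {
  prot <- c(cfg$anchor_accession,
            sprintf("P%03d", seq_len(cfg$n_proteins)))
  sites <- rbindlist(lapply(prot, function(acc) {
    data.table(accession = acc, site_idx = seq_len(cfg$sites_per_protein),
               position = 15L + 20L * (seq_len(cfg$sites_per_protein) - 1L))
  }))
  sites[, role := "null"]
  sites[accession == cfg$anchor_accession,
        role := c("anchor", "cooccur_sibling",
                  rep("sibling", cfg$sites_per_protein - 2L))[site_idx]]
  pos_prot <- prot[1L + seq_len(cfg$planted_positive_pairs)]
  neg_prot <- prot[1L + cfg$planted_positive_pairs +
                   seq_len(cfg$planted_negative_pairs)]
  sites[accession %in% pos_prot & site_idx == 1L, role := "pos_partner"]
  sites[accession %in% neg_prot & site_idx == 1L, role := "neg_partner"]
  sites
}

#' Generate random protein sequences with planted motif flanks
#'
#' Sequences are uniform-random over the 20 standard amino acids; each
#' phosphoacceptor is S (80%) or T (20%), and with probability
#' `motif_plant_rate` its -1/+1 flanks are set to D/P or P/D (50/50).
#' Without planting, flanks remain uniform-random, so the chance match rate
#' is 2 x (1/20)^2.
#'
#' @param cfg a [simulation_config()]
#' @return list: `sequences` (named character vector), `sites` (data.table
#'   accession, residue, position, window, motif_planted)
#' @export
generate_sequences <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 1L))
  sites <- site_table(cfg)
  seq_len_aa <- max(sites$position) + 14L
  seqs <- vapply(unique(sites$accession), function(acc) {
    paste(sample(AA20, seq_len_aa, replace = TRUE), collapse = "")
  }, "")
  sites[, residue := sample(c("S", "T"), .N, replace = TRUE,
                            prob = c(0.8, 0.2))]
  sites[, motif_planted := runif(.N) < cfg$motif_plant_rate]
  for (i in seq_len(nrow(sites))) {
    acc <- sites$accession[i]; pos <- sites$position[i]
    s <- seqs[[acc]]
    substr(s, pos, pos) <- sites$residue[i]
    if (sites$motif_planted[i]) {
      fl <- if (runif(1) < 0.5) c("D", "P") else c("P", "D")
      substr(s, pos - 1L, pos - 1L) <- fl[1L]
      substr(s, pos + 1L, pos + 1L) <- fl[2L]
    }
    seqs[[acc]] <- s
  }
  # planting one site's flank could overwrite a neighbour only if sites were
  # < 2 residues apart; spacing is 20, so windows stay consistent
  sites[, window := extract_window(seqs[[accession]], position),
        by = seq_len(nrow(sites))]
  list(sequences = seqs,
       sites = sites[, .(accession, residue, position, window,
                         motif_planted, role, site_idx)])
}

# regulated fold-change draw strictly beyond the threshold, with p < 0.05
#' @noRd
draw_regulated <- function(n, direction, cfg, thr = threshold_config()) {
  fc <- ifelse(direction == "UP",
               thr$up_fc * exp(abs(rnorm(n, 0, cfg$fc_sdlog))),
               thr$down_fc * exp(-abs(rnorm(n, 0, cfg$fc_sdlog))))
  list(fc = fc, p = runif(n, 1e-4, thr$max_p - 1e-3))
}

#' @noRd
draw_unregulated <- function(n, cfg) {
  list(fc = exp(rnorm(n, 0, 0.25)), p = runif(n, 0.05, 0.999))
}

# localization evidence: one of loc_prob / a_score per observation
#' @noRd
draw_scores <- function(n, cfg) {
  class1 <- runif(n) < cfg$class1_prob
  use_lp <- runif(n) < 0.7
  lp <- ifelse(class1, runif(n, 0.75, 1), runif(n, 0.2, 0.7499))
  as_ <- ifelse(class1, runif(n, 13.01, 40), runif(n, 0, 13))
  data.table(loc_prob = ifelse(use_lp, lp, NA_real_),
             a_score = ifelse(use_lp, NA_real_, as_))
}

#' Generate a synthetic phosphoproteomic catalog with known ground truth
#'
#' See [simulation_config()] for the generative model. Detection, direction,
#' fold-change magnitude and p-value are drawn hierarchically so that the
#' Class-1 filter and the fold-change/p thresholds are each independently
#' exercisable.
#'
#' @param cfg a [simulation_config()]
#' @param sequences optional pre-generated output of [generate_sequences()]
#'   (regenerated from `cfg` when omitted)
#' @return list: `observations` and `datasets` data.tables (the two catalog
#'   files), and `truth` — a list with the anchor key, planted
#'   positive/negative partner keys, the planted co-occurring sibling pair,
#'   planted motif site keys, and the planted dominant site
#' @export
generate_catalog <- function(cfg, sequences = NULL) {
  if (is.null(sequences)) sequences <- generate_sequences(cfg)
  sites <- sequences$sites
  set.seed(derive_seed(cfg$seed, 2L))

  rr <- function(n, labels) {  # round-robin with 20% jitter
    idx <- (seq_len(n) - 1L) %% length(labels) + 1L
    redo <- runif(n) < 0.2
    idx[redo] <- sample.int(length(labels), sum(redo), replace = TRUE)
    labels[idx]
  }
  pmids <- sprintf("PMID%05d", seq_len(cfg$n_pmids))
  codes <- sprintf("EC%03d", seq_len(cfg$n_expcodes))
  n_ds <- cfg$n_profile_datasets + cfg$n_diff_datasets
  datasets <- data.table(
    dataset_id = sprintf("DS%04d", seq_len(n_ds)),
    kind = rep(c("PROFILE", "DIFFERENTIAL"),
               c(cfg$n_profile_datasets, cfg$n_diff_datasets)),
    pmid = rr(n_ds, pmids),
    experimental_code = rr(n_ds, codes),
    enrichment = rr(n_ds, c("STY", "ST", "Y"))
  )
  diff_ids <- datasets[kind == "DIFFERENTIAL", dataset_id]
  prof_ids <- datasets[kind == "PROFILE", dataset_id]
  nd <- length(diff_ids)

  # anchor differential trajectory drives everything planted
  a_det <- runif(nd) < cfg$anchor_detect_prob
  a_reg <- a_det & runif(nd) < cfg$reg_given_detect
  a_dir <- ifelse(runif(nd) < 0.5, "UP", "DOWN")

  obs_list <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    role <- sites$role[i]
    det_p <- switch(role,
                    anchor = cfg$anchor_detect_prob,
                    pos_partner = , neg_partner = cfg$partner_detect_prob,
                    cfg$background_detect_prob)
    if (role == "anchor") {
      det <- a_det
      reg <- a_reg
      dir <- a_dir
    } else {
      det <- runif(nd) < det_p
      conc <- switch(role,
                     pos_partner = , neg_partner = cfg$concordance,
                     cooccur_sibling = cfg$cooccur_concordance,
                     NA_real_)
      if (!is.na(conc)) {
        # planted: when co-detected with a regulated anchor, always called,
        # matching (or opposing) its direction with prob = concordance
        match_dir <- runif(nd) < conc
        planted_dir <- ifelse(match_dir, a_dir,
                              ifelse(a_dir == "UP", "DOWN", "UP"))
        if (role == "neg_partner") {
          planted_dir <- ifelse(planted_dir == "UP", "DOWN", "UP")
        }
        linked <- det & a_reg
        reg <- det & (linked | runif(nd) < cfg$reg_given_detect)
        dir <- ifelse(linked, planted_dir,
                      ifelse(runif(nd) < cfg$background_up_prob, "UP", "DOWN"))
      } else {
        reg <- det & runif(nd) < cfg$reg_given_detect
        dir <- ifelse(runif(nd) < cfg$background_up_prob, "UP", "DOWN")
      }
    }
    idx <- which(det)
    if (!length(idx)) next
    n <- length(idx)
    fcp_r <- draw_regulated(n, dir[idx], cfg)
    fcp_u <- draw_unregulated(n, cfg)
    is_reg <- reg[idx]
    obs_list[[i]] <- data.table(
      accession = sites$accession[i], residue = sites$residue[i],
      position = sites$position[i], dataset_id = diff_ids[idx],
      window = sites$window[i],
      fold_change = ifelse(is_reg, fcp_r$fc, fcp_u$fc),
      p_value = ifelse(is_reg, fcp_r$p, fcp_u$p)
    )
  }
  diff_obs <- rbindlist(obs_list)

  prof_list <- lapply(seq_len(nrow(sites)), function(i) {
    p_det <- if (sites$role[i] == "anchor") cfg$anchor_profile_detect_prob
             else cfg$background_profile_detect_prob
    idx <- which(runif(length(prof_ids)) < p_det)
    if (!length(idx)) return(NULL)
    data.table(accession = sites$accession[i], residue = sites$residue[i],
               position = sites$position[i], dataset_id = prof_ids[idx],
               window = sites$window[i],
               fold_change = NA_real_, p_value = NA_real_)
  })
  prof_obs <- rbindlist(prof_list)

  obs <- rbindlist(list(prof_obs, diff_obs))
  obs <- cbind(obs, draw_scores(nrow(obs), cfg))
  setcolorder(obs, OBS_COLS)
  setorder(obs, dataset_id, accession, position)

  key <- function(dt) site_key(dt$accession, dt$residue, dt$position)
  truth <- list(
    anchor = key(sites[role == "anchor"]),
    dominant_site = key(sites[role == "anchor"]),
    positive_partners = key(sites[role == "pos_partner"]),
    negative_partners = key(sites[role == "neg_partner"]),
    cooccur_pair = c(key(sites[role == "anchor"]),
                     key(sites[role == "cooccur_sibling"])),
    motif_sites = key(sites[motif_planted == TRUE]),
    null_sites = key(sites[role %in% c("null", "sibling")])
  )
  list(observations = obs, datasets = datasets, truth = truth)
}

#' Generate annotation records for planted partners plus decoys
#'
#' A fraction of planted positive partners' proteins get BINARY_INTERACTOR
#' records (protein level) and a fraction of their sites get
#' PREDICTED_SUBSTRATE records (site level); negative partners get a
#' PREDICTED_UPSTREAM_KINASE record each; decoys go onto null proteins.
#' Bookkeeping of which records cover planted partners is appended to
#' `truth`.
#'
#' @param cfg a [simulation_config()]
#' @param truth ground-truth list from [generate_catalog()]
#' @return list: `annotations` data.table (gene, site, relation, source) and
#'   the augmented `truth`
#' @export
generate_annotations <- function(cfg, truth) {
  set.seed(derive_seed(cfg$seed, 3L))
  pos <- parse_site_key(truth$positive_partners)
  neg <- parse_site_key(truth$negative_partners)
  n_int <- round(cfg$annotate_interactor_frac * nrow(pos))
  n_sub <- round(cfg$annotate_substrate_frac * nrow(pos))
  int_idx <- sort(sample.int(nrow(pos), n_int))
  sub_idx <- sort(sample.int(nrow(pos), n_sub))
  ann <- list()
  if (n_int) ann$int <- data.table(
    gene = pos$accession[int_idx], site = NA_character_,
    relation = "BINARY_INTERACTOR", source = "synthetic_ppi")
  if (n_sub) ann$sub <- data.table(
    gene = pos$accession[sub_idx],
    site = paste0(pos$residue[sub_idx], pos$position[sub_idx]),
    relation = "PREDICTED_SUBSTRATE", source = "synthetic_kinase_pred")
  if (nrow(neg)) ann$kin <- data.table(
    gene = neg$accession, site = paste0(neg$residue, neg$position),
    relation = "PREDICTED_UPSTREAM_KINASE", source = "synthetic_kinase_pred")
  null_prot <- unique(parse_site_key(truth$null_sites)$accession)
  n_dec <- min(cfg$n_decoy_annotations, length(null_prot))
  if (n_dec) ann$dec <- data.table(
    gene = sort(sample(null_prot, n_dec)), site = NA_character_,
    relation = "BINARY_INTERACTOR", source = "synthetic_decoy")
  annotations <- rbindlist(ann)
  truth$annotated_interactors <- if (n_int) pos$accession[int_idx] else character()
  truth$annotated_substrates <- if (n_sub) truth$positive_partners[sub_idx] else character()
  truth$decoy_proteins <- if (n_dec) ann$dec$gene else character()
  list(annotations = annotations, truth = truth)
}

#' Generate the full synthetic input bundle
#'
#' @param cfg a [simulation_config()]
#' @return list with sequences, sites, observations, datasets, annotations
#'   and truth, all mutually consistent
#' @export
simulate_bundle <- function(cfg = simulation_config()) {
  seqs <- generate_sequences(cfg)
  cat <- generate_catalog(cfg, sequences = seqs)
  ann <- generate_annotations(cfg, cat$truth)
  list(sequences = seqs$sequences, sites = seqs$sites,
       observations = cat$observations, datasets = cat$datasets,
       annotations = ann$annotations, truth = ann$truth)
}

#' Write a synthetic bundle to an input directory
#'
#' Writes observations.tsv, datasets.tsv, sequences.fasta, sites.tsv,
#' annotations.tsv and ground_truth.json. Identical seeds produce
#' byte-identical files.
#'
#' @param cfg a [simulation_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, the bundle (as from [simulate_bundle()])
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- simulate_bundle(cfg)
  fwrite(b$observations, file.path(dir, "observations.tsv"), sep = "\t",
         na = "", quote = FALSE)
  fwrite(b$datasets, file.path(dir, "datasets.tsv"), sep = "\t",
         na = "", quote = FALSE)
  fwrite(b$sites, file.path(dir, "sites.tsv"), sep = "\t", na = "",
         quote = FALSE)
  fwrite(b$annotations, file.path(dir, "annotations.tsv"), sep = "\t",
         na = "", quote = FALSE)
  aa <- Biostrings::AAStringSet(b$sequences)
  Biostrings::writeXStringSet(aa, file.path(dir, "sequences.fasta"))
  jsonlite::write_json(b$truth, file.path(dir, "ground_truth.json"),
                       pretty = TRUE)
  invisible(b)
}
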
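library(data.table)

# ---- independent FET oracle -------------------------------------------------
# Brute-force enumeration: walk every non-negative integer 2x2 table with the
# margins of (a,b,c,d), compute its exact point probability from factorials,
# and sum the tables at least as extreme in the requested direction. Written
# before (and independently of) fet_pvalue's lchoose tail sum.
oracle_fet <- function(a, b, c, d, sign = "POSITIVE") {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  lmarg <- lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
    lfactorial(n)
  acc <- 0
  for (aa in 0:r1) {
    bb <- r1 - aa; cc <- c1 - aa; dd <- r2 - cc
    if (any(c(bb, cc, dd) < 0)) next
    pr <- exp(lmarg - lfactorial(aa) - lfactorial(bb) - lfactorial(cc) -
                lfactorial(dd))
    extreme <- if (sign == "POSITIVE") dd >= d else cc >= c
    if (extreme) acc <- acc + pr
  }
  acc
}

# ---- in-memory toy catalogs -------------------------------------------------
obs_row <- function(accession, residue, position, dataset_id,
                    fold_change = NA_real_, p_value = NA_real_,
                    loc_prob = 0.99, a_score = NA_real_, window = NA_character_) {
  data.table(accession = accession, residue = residue,
             position = as.integer(position), dataset_id = dataset_id,
             window = window, loc_prob = loc_prob, a_score = a_score,
             fold_change = fold_change, p_value = p_value)
}

ds_row <- function(dataset_id, kind, pmid = "PMID1", experimental_code = "EC1",
                   enrichment = "STY") {
  data.table(dataset_id = dataset_id, kind = kind, pmid = pmid,
             experimental_code = experimental_code, enrichment = enrichment)
}

make_catalog <- function(obs, ds, ...) {
  phoscoreg:::build_catalog(rbindlist(obs), rbindlist(ds), ...)
}

# toy catalog backing the hand-counted frequency example: PROT1_S10 detected
# in 3 of 4 profile datasets, UP in 2 and DOWN in 1 of 3 differential ones
toy_freq_catalog <- function() {
  ds <- c(lapply(sprintf("PR%d", 1:4), ds_row, kind = "PROFILE"),
          lapply(sprintf("DF%d", 1:3), ds_row, kind = "DIFFERENTIAL"))
  obs <- c(
    lapply(sprintf("PR%d", 1:3), function(d) obs_row("PROT1", "S", 10, d)),
    list(obs_row("PROT1", "S", 10, "DF1", 2.0, 0.01),
         obs_row("PROT1", "S", 10, "DF2", 1.5, 0.02),
         obs_row("PROT1", "S", 10, "DF3", 0.5, 0.01),
         obs_row("PROT1", "T", 20, "PR4"))  # profile-only second site
  )
  make_catalog(obs, ds)
}

# toy pair catalog: two sites on PROT1 co-called in 15 differential datasets:
# both UP in 5, both DOWN in 8, opposite in 2
toy_pair_catalog <- function() {
  ids <- sprintf("DF%02d", 1:15)
  ds <- lapply(seq_along(ids), function(i)
    ds_row(ids[i], "DIFFERENTIAL", pmid = sprintf("PMID%d", (i %% 4) + 1),
           experimental_code = sprintf("EC%d", (i %% 8) + 1)))
  dir_a <- c(rep("UP", 5), rep("DOWN", 8), "UP", "DOWN")
  dir_b <- c(rep("UP", 5), rep("DOWN", 8), "DOWN", "UP")
  fc <- function(dir) if (dir == "UP") 2.0 else 0.5
  obs <- unlist(lapply(seq_along(ids), function(i) {
    list(obs_row("PROT1", "S", 10, ids[i], fc(dir_a[i]), 0.01),
         obs_row("PROT1", "S", 20, ids[i], fc(dir_b[i]), 0.01))
  }), recursive = FALSE)
  make_catalog(obs, ds)
}

# small synthetic bundle shared by several test files (kept modest for speed)
small_bundle <- function(seed = 42L, ...) {
  simulate_bundle(simulation_config(seed = seed, ...))
}

bundle_catalog <- function(b) {
  filter_class1(phoscoreg:::build_catalog(b$observations, b$datasets))
}
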
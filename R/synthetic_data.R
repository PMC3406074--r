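#' Simulation configuration for the synthetic proteomics study
#'
#' Captures the study design being emulated: a two-tissue comparison
#' (default 10 skin donors vs 5 liver donors, both fractionated into
#' cytosol and microsomes and separated into 20 gel regions), plus the
#' identification-level noise model. Per-peptide ion intensity is protein
#' abundance x a fixed per-peptide response factor x multiplicative
#' log-normal noise, and observations below the detection limit are
#' censored at the observation (peptide) level. The same config plus seed
#' always reproduces byte-identical tables.
#'
#' @param seed integer random seed (fully determines all outputs).
#' @param n_skin,n_liver donors per tissue (defaults 10 and 5).
#' @param n_families number of protein families whose members share
#'   tryptic peptides (default 2).
#' @param family_size members per family (default 2).
#' @param family_unique_peptides peptides unique to each family member
#'   (default 1, so that family members are consolidated downstream).
#' @param n_singleton_xmes accepted XME proteins outside families.
#' @param n_reject,n_filtered,n_decoys counts of reject-list-hit,
#'   'hypothetical'/'like', and neutral decoy proteins.
#' @param peptides_per_protein tryptic peptides per protein (default 8).
#' @param sigma log-normal noise sd on the log scale (default 0.3).
#' @param detection_limit intensity censoring threshold (arbitrary units).
#' @param n_regions gel regions (default 20).
#' @param p_observe per-observation detection probability (default 0.9),
#'   emulating peptides lost to ionisation/undersampling.
#' @param base_abundance liver-abundance scale (arbitrary intensity units).
#' @param true_folds skin/liver fold differences assigned to XME proteins
#'   (recycled); non-XME proteins get fold 1.
#' @param xme_names optional character vector overriding the built-in
#'   singleton XME name pool.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_skin = 10L, n_liver = 5L,
                       n_families = 2L, family_size = 2L,
                       family_unique_peptides = 1L,
                       n_singleton_xmes = 6L, n_reject = 2L,
                       n_filtered = 2L, n_decoys = 6L,
                       peptides_per_protein = 8L, sigma = 0.3,
                       detection_limit = 5e4, n_regions = 20L,
                       p_observe = 0.9, base_abundance = 1e6,
                       true_folds = c(0.05, 0.1, 0.25, 0.5, 1, 2, 4),
                       xme_names = NULL) {
  cfg <- list(seed = as.integer(seed), n_skin = as.integer(n_skin),
              n_liver = as.integer(n_liver),
              n_families = as.integer(n_families),
              family_size = as.integer(family_size),
              family_unique_peptides = as.integer(family_unique_peptides),
              n_singleton_xmes = as.integer(n_singleton_xmes),
              n_reject = as.integer(n_reject),
              n_filtered = as.integer(n_filtered),
              n_decoys = as.integer(n_decoys),
              peptides_per_protein = as.integer(peptides_per_protein),
              sigma = sigma, detection_limit = detection_limit,
              n_regions = as.integer(n_regions), p_observe = p_observe,
              base_abundance = base_abundance, true_folds = true_folds,
              xme_names = xme_names)
  n_prot <- with(cfg, n_families * family_size + n_singleton_xmes +
                   n_reject + n_filtered + n_decoys)
  if (n_prot < 1L)
    stop("configuration error: database would contain 0 proteins")
  if (cfg$n_families > 0L && cfg$family_size < 2L)
    stop("configuration error: families need >= 2 members to share peptides")
  if (cfg$n_skin < 1L || cfg$n_liver < 1L)
    stop("configuration error: each tissue needs >= 1 donor")
  stopifnot(cfg$sigma >= 0, cfg$p_observe >= 0, cfg$p_observe <= 1,
            cfg$peptides_per_protein >= 1L, cfg$n_regions >= 1L)
  if (cfg$n_families > 0L &&
      cfg$family_unique_peptides >= cfg$peptides_per_protein)
    stop("configuration error: family members must share >= 1 peptide")
  structure(cfg, class = "sim_config")
}

# interior residues exclude K/R (no internal cleavage) and the first residue
# is never P (never suppresses the preceding cleavage site)
AA_INTERIOR <- setdiff(AA20, c("K", "R"))

random_tryptic_peptide <- function(len = NULL) {
  if (is.null(len)) len <- sample(7:14, 1L)
  first <- sample(setdiff(AA_INTERIOR, "P"), 1L)
  mid <- sample(AA_INTERIOR, len - 2L, replace = TRUE)
  paste0(paste(c(first, mid), collapse = ""), sample(c("K", "R"), 1L))
}

SINGLETON_XME_POOL <- c(
  "epoxide hydrolase 1", "catalase", "carbonyl reductase [NADPH] 1",
  "aldehyde dehydrogenase 2", "membrane primary amine oxidase",
  "aldehyde oxidase", "glutathione peroxidase 3", "xanthine dehydrogenase",
  "histamine N-methyltransferase", "carboxylesterase 2",
  "nicotinamide N-methyltransferase", "prostacyclin synthase",
  "catechol O-methyltransferase", "epoxide hydrolase 2",
  "quinone oxidoreductase", "thiosulfate sulfurtransferase")

FAMILY_STEM_POOL <- c(
  "glutathione transferase A", "aldo-keto reductase 1C",
  "cytochrome P450 2C", "alcohol dehydrogenase 1",
  "peroxiredoxin-", "sulfotransferase 1A")

REJECT_NAME_POOL <- c(
  "glucose-6-phosphate dehydrogenase",
  "protein-glutamine gamma-glutamyltransferase",
  "heparan sulfate proteoglycan core protein",
  "dolichyl-diphosphooligosaccharide-protein glycosyltransferase 48 kDa subunit",
  "carbohydrate sulfotransferase 1")

FILTERED_NAME_POOL <- c(
  "hypothetical protein LOC100134",
  "aldo-keto reductase family 1 member C3-like protein",
  "cytochrome P450 2B6-like protein",
  "hypothetical oxidoreductase YMR226C")

DECOY_NAME_POOL <- c(
  "keratin, type I cytoskeletal 14", "actin, cytoplasmic 1",
  "serum albumin", "vimentin", "annexin A2", "histone H4",
  "collagen alpha-1(I) chain", "elongation factor 1-alpha 1",
  "heat shock protein beta-1", "pyruvate kinase PKM")

take_names <- function(pool, n, label) {
  if (n <= length(pool)) return(pool[seq_len(n)])
  extra <- paste(pool[((seq_len(n - length(pool)) - 1L) %% length(pool)) + 1L],
                 "isoform", seq_len(n - length(pool)))
  c(pool, extra)
}

#' Generate a synthetic protein database with ground truth
#'
#' Builds protein records whose descriptive names cover the four selection
#' outcomes (accepted XMEs, reject-list hits, 'hypothetical'/'like' names,
#' neutral decoys) and whose sequences are concatenations of synthetic
#' fully-tryptic peptides, so that zero-missed-cleavage digestion recovers
#' the construction peptides exactly. Family members literally share
#' tryptic peptides (all but `family_unique_peptides` of them), which is
#' what drives downstream consolidation. No real proteome is bundled; all
#' sequences are random and accessions are prefixed `SYN`.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_database` with elements `proteins`
#'   (accession, name, category, family, fraction, region, sequence),
#'   `peptides` (accession, peptide, response), and `truth` (accession,
#'   family, fraction, skin_mean, liver_mean, fold).
#' @export
generate_database <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  stems <- take_names(FAMILY_STEM_POOL, config$n_families, "family")
  fam_names <- list()
  for (i in seq_len(config$n_families)) {
    fam_names[[i]] <- paste0(stems[i], seq_len(config$family_size))
  }
  singles <- if (is.null(config$xme_names))
    take_names(SINGLETON_XME_POOL, config$n_singleton_xmes, "xme")
  else take_names(config$xme_names, config$n_singleton_xmes, "xme")

  name <- c(unlist(fam_names), singles,
            take_names(REJECT_NAME_POOL, config$n_reject, "reject"),
            take_names(FILTERED_NAME_POOL, config$n_filtered, "filtered"),
            take_names(DECOY_NAME_POOL, config$n_decoys, "decoy"))
  category <- c(rep("xme", config$n_families * config$family_size),
                rep("xme", config$n_singleton_xmes),
                rep("reject", config$n_reject),
                rep("filtered", config$n_filtered),
                rep("decoy", config$n_decoys))
  family <- c(rep(sprintf("fam%02d", seq_len(config$n_families)),
                  each = config$family_size),
              sprintf("solo%03d", seq_len(length(name) -
                config$n_families * config$family_size)))
  n_prot <- length(name)
  accession <- sprintf("SYN_%03d", seq_len(n_prot))

  # peptides: families share all but family_unique_peptides of them
  pep_rows <- list()
  seqs <- character(n_prot)
  idx <- 1L
  for (f in seq_len(config$n_families)) {
    n_shared <- config$peptides_per_protein - config$family_unique_peptides
    shared <- replicate(n_shared, random_tryptic_peptide())
    for (m in seq_len(config$family_size)) {
      own <- replicate(config$family_unique_peptides,
                       random_tryptic_peptide())
      peps <- c(shared, own)
      seqs[idx] <- paste(peps, collapse = "")
      pep_rows[[idx]] <- data.frame(accession = accession[idx],
                                    peptide = peps,
                                    stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  while (idx <= n_prot) {
    peps <- replicate(config$peptides_per_protein, random_tryptic_peptide())
    seqs[idx] <- paste(peps, collapse = "")
    pep_rows[[idx]] <- data.frame(accession = accession[idx], peptide = peps,
                                  stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  peptides <- do.call(rbind, pep_rows)
  # fixed per-peptide response factor, drawn once
  peptides$response <- exp(stats::rnorm(nrow(peptides), 0, 0.5))

  fraction <- sample(c("cytosol", "microsome", "both"), n_prot,
                     replace = TRUE, prob = c(0.45, 0.45, 0.10))
  region <- sample.int(config$n_regions, n_prot, replace = TRUE)
  is_xme <- category == "xme"
  fold <- rep(1, n_prot)
  fold[is_xme] <- rep_len(config$true_folds, sum(is_xme))
  liver_mean <- config$base_abundance * 10^stats::runif(n_prot, -0.5, 1)
  skin_mean <- liver_mean * fold

  proteins <- data.frame(accession = accession, name = name,
                         category = category, family = family,
                         fraction = fraction, region = region,
                         sequence = seqs, stringsAsFactors = FALSE)
  truth <- data.frame(accession = accession, family = family,
                      fraction = fraction, skin_mean = skin_mean,
                      liver_mean = liver_mean, fold = fold,
                      stringsAsFactors = FALSE)
  structure(list(proteins = proteins, peptides = peptides, truth = truth,
                 config = config), class = "sim_database")
}

#' Simulate per-sample peptide-identification tables
#'
#' For every donor sample, every construction peptide of every protein
#' yields an ion intensity `tissue mean x response x exp(N(0, sigma))`; an
#' observation is kept with probability `p_observe` and censored (removed)
#' when its intensity falls below the detection limit. Proteins annotated
#' to both fractions contribute half their intensity to each fraction.
#' Charge (2-3) and an ion-trap-style identification score are attached to
#' each row.
#'
#' @param db a `sim_database` from [generate_database()].
#' @param config the same [sim_config()] (defaults to the one in `db`).
#' @return data.frame of observations with columns `sample_id`, `tissue`,
#'   `fraction`, `gel_region`, `peptide`, `charge`, `score`, `intensity`.
#' @export
simulate_samples <- function(db, config = db$config) {
  stopifnot(inherits(db, "sim_database"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  samples <- sample_roster(config)
  pep <- merge(db$peptides, db$truth, by = "accession", sort = FALSE)
  pro <- db$proteins[match(pep$accession, db$proteins$accession), ]
  out <- vector("list", nrow(samples))
  for (s in seq_len(nrow(samples))) {
    mu <- if (samples$tissue[s] == "skin") pep$skin_mean else pep$liver_mean
    intensity <- mu * pep$response *
      exp(stats::rnorm(nrow(pep), 0, config$sigma))
    keep <- stats::runif(nrow(pep)) < config$p_observe
    obs <- data.frame(sample_id = samples$sample_id[s],
                      tissue = samples$tissue[s],
                      fraction = pro$fraction,
                      gel_region = pro$region,
                      peptide = pep$peptide,
                      charge = sample(2:3, nrow(pep), replace = TRUE),
                      score = round(stats::runif(nrow(pep), 1.5, 5.0), 2),
                      intensity = intensity,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    both <- obs$fraction == "both"
    if (any(both)) {
      half1 <- obs[both, ]; half1$fraction <- "cytosol"
      half2 <- obs[both, ]; half2$fraction <- "microsome"
      half1$intensity <- half1$intensity / 2
      half2$intensity <- half2$intensity / 2
      obs <- rbind(obs[!both, ], half1, half2)
    }
    obs <- obs[obs$intensity > 0 & obs$intensity >= config$detection_limit, ]
    out[[s]] <- obs
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Donor-sample roster implied by a configuration
#'
#' @param config a [sim_config()].
#' @return data.frame with `sample_id`, `tissue`.
#' @export
sample_roster <- function(config) {
  data.frame(
    sample_id = c(sprintf("skin_%02d", seq_len(config$n_skin)),
                  sprintf("liver_%02d", seq_len(config$n_liver))),
    tissue = c(rep("skin", config$n_skin), rep("liver", config$n_liver)),
    stringsAsFactors = FALSE)
}

#' Generate a spike-in dilution series for one analyte
#'
#' Emulates spiking a matrix sample with increasing amounts of a purified
#' protein and counting the distinct tryptic peptides identified at each
#' amount. Each of `n_peptides` peptides has a fixed per-fmol response;
#' peptide `i` is detected at amount `a` when
#' `a x response_i x exp(N(0, sigma)) >=` the detection limit. With the
#' default responses `detection_limit / i`, peptide `i` first appears at
#' `i` fmol when `sigma = 0`, giving a controlled, known crossing point.
#'
#' @param analyte analyte name.
#' @param amounts_fmol non-negative spike amounts, sorted ascending.
#' @param config a [sim_config()] (supplies `detection_limit`, `sigma`,
#'   `seed`).
#' @param responses optional per-peptide intensities per fmol.
#' @param n_peptides number of observable peptides when `responses` is NULL.
#' @return data.frame with `analyte`, `amount_fmol`, `peptides_detected`.
#' @export
generate_spike_series <- function(analyte, amounts_fmol, config,
                                  responses = NULL, n_peptides = 5L) {
  stopifnot(inherits(config, "sim_config"))
  if (any(amounts_fmol < 0))
    stop("input error: spike amounts must be non-negative")
  if (is.unsorted(amounts_fmol))
    stop("input error: spike amounts must be sorted ascending")
  if (is.null(responses))
    responses <- config$detection_limit / seq_len(n_peptides)
  set.seed(config$seed + 2L)
  counts <- integer(length(amounts_fmol))
  for (i in seq_along(amounts_fmol)) {
    noise <- exp(stats::rnorm(length(responses), 0, config$sigma))
    counts[i] <- sum(amounts_fmol[i] * responses * noise >=
                       config$detection_limit & amounts_fmol[i] > 0)
  }
  data.frame(analyte = analyte, amount_fmol = amounts_fmol,
             peptides_detected = counts, stringsAsFactors = FALSE)
}

#' Write one TSV identification table per sample
#'
#' @param obs observation data.frame from [simulate_samples()].
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_sample_tables <- function(obs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("sample_id", "tissue", "fraction", "gel_region", "peptide",
            "charge", "score", "intensity")
  paths <- character(0)
  for (sid in unique(obs$sample_id)) {
    p <- file.path(dir, paste0(sid, ".tsv"))
    utils::write.table(obs[obs$sample_id == sid, cols], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read per-sample identification tables back into one observation table
#'
#' @param paths TSV file paths (as written by [write_sample_tables()]).
#' @return combined observation data.frame.
#' @export
read_sample_tables <- function(paths) {
  res <- do.call(rbind, lapply(paths, function(p) {
    utils::read.delim(p, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}
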
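#' Parameters controlling the profiling pipeline
#'
#' @param min_peptides distinct peptides per sample for a positive sample
#'   (default 2).
#' @param min_donors positive samples for a detection call (default 2).
#' @param min_unique unique peptides that keep a protein pair separate
#'   during consolidation (default 2).
#' @param lod intensity substituted for non-detections; `NULL` uses the
#'   smallest observed peptide intensity in the whole dataset.
#' @param similarity_threshold fold ratio treated as "similar levels"
#'   when resolving the reported fraction (default 2).
#' @return a list of class `pipeline_params`.
#' @export
pipeline_params <- function(min_peptides = 2L, min_donors = 2L,
                            min_unique = 2L, lod = NULL,
                            similarity_threshold = 2) {
  structure(list(min_peptides = as.integer(min_peptides),
                 min_donors = as.integer(min_donors),
                 min_unique = as.integer(min_unique), lod = lod,
                 similarity_threshold = similarity_threshold),
            class = "pipeline_params")
}

#' Run the comparative XME profiling pipeline on in-memory tables
#'
#' End-to-end ordering: keyword selection on database names; mapping of
#' observed peptides to all database sequences (unmatched peptides are
#' dropped with a warning); consolidation of indistinguishable accepted
#' proteins into groups; per-group gel-region resolution (the region with
#' the most detected peptides); detection calling and rates per tissue;
#' fraction resolution; summed-intensity fold differences with
#' limit-of-detection substitution; exact Mann-Whitney tests on the
#' per-sample sums.
#'
#' @param database data.frame `accession`, `name`, `sequence`.
#' @param obs observation table (`sample_id`, `tissue`, `fraction`,
#'   `gel_region`, `peptide`, `charge`, `score`, `intensity`).
#' @param samples roster data.frame `sample_id`, `tissue`; defaults to the
#'   samples present in `obs`.
#' @param keywords a [keyword_config()] (default: packaged lists).
#' @param params a [pipeline_params()].
#' @return list with `selection` (audit), `assignments` (with uniqueness
#'   classes), `grouping`, `quant` (one row per group: root name,
#'   accessions, region, fraction, per-tissue rates and detection flags,
#'   fold difference with bound, p-value), and `lod` (the substitution
#'   intensity used).
#' @export
profile_xmes <- function(database, obs, samples = NULL,
                         keywords = default_keyword_config(),
                         params = pipeline_params()) {
  check_database(database)
  if (is.null(samples))
    samples <- unique(obs[, c("sample_id", "tissue")])
  if (nrow(samples) == 0L) stop("no samples")
  if (nrow(obs) == 0L) stop("no samples: observation table is empty")
  tissues <- unique(samples$tissue)

  selection <- select_xmes(database$name, keywords)
  accepted_acc <- database$accession[database$name %in% selection$accepted]

  assignments <- map_peptides(unique(obs$peptide), database)
  n_unmatched <- sum(!assignments$matched)
  if (n_unmatched > 0L)
    warning(sprintf("%d observed peptide(s) matched no database record %s",
                    n_unmatched, "and were dropped"))
  matched <- assignments[assignments$matched, , drop = FALSE]

  grouping <- consolidate_groups(matched, accepted_acc,
                                 setNames(database$name,
                                          database$accession),
                                 min_unique = params$min_unique)
  # family partition: accepted accessions take their group, all other
  # accessions stand alone
  part <- data.frame(accession = database$accession,
                     family = database$accession,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grouping$groups))) {
    members <- strsplit(grouping$groups$accessions[i], ",", fixed = TRUE)[[1]]
    part$family[part$accession %in% members] <- grouping$groups$group_id[i]
  }
  assignments <- classify_uniqueness(assignments, part)

  lod <- params$lod
  if (is.null(lod)) {
    pos <- obs$intensity[obs$intensity > 0]
    if (length(pos) == 0L) stop("no positive intensities to derive lod")
    lod <- min(pos)
  }

  qrows <- list()
  for (i in seq_len(nrow(grouping$groups))) {
    g <- grouping$groups$group_id[i]
    support_p <- grouping$support$peptide[grouping$support$group_id == g]
    if (length(support_p) == 0L) next
    obs_s <- obs[obs$peptide %in% support_p, , drop = FALSE]
    if (nrow(obs_s) == 0L) next
    region <- resolve_region(support_p, obs_s)
    obs_g <- obs_s[obs_s$gel_region == region, , drop = FALSE]
    mini <- list(groups = grouping$groups[i, , drop = FALSE],
                 support = grouping$support[
                   grouping$support$group_id == g, , drop = FALSE])
    det <- apply_detection(mini, obs_g, samples,
                           min_peptides = params$min_peptides,
                           min_donors = params$min_donors)
    fraction <- resolve_fraction(support_p, obs_g,
                                 threshold = params$similarity_threshold)
    sums <- vapply(samples$sample_id, function(sid)
      summed_intensity(obs_g, support_p, sid), numeric(1))
    row <- data.frame(group_id = g,
                      root_name = grouping$groups$root_name[i],
                      accessions = grouping$groups$accessions[i],
                      region = region, fraction = fraction,
                      stringsAsFactors = FALSE)
    for (t in tissues) {
      dt <- det[det$tissue == t, ]
      row[[paste0(t, "_detection_rate")]] <- dt$detection_rate
      row[[paste0(t, "_detected")]] <- dt$detected
    }
    if (all(c("skin", "liver") %in% tissues)) {
      skin_sums <- sums[samples$tissue == "skin"]
      liver_sums <- sums[samples$tissue == "liver"]
      fd <- fold_difference(skin_sums, liver_sums, lod)
      sub <- function(v) ifelse(v == 0, lod, v)
      mw <- mann_whitney(sub(skin_sums), sub(liver_sums))
      row$fold <- fd$ratio
      row$bound <- fd$bound
      row$relative_level <- render_fold(fd$ratio, fd$bound)
      row$p_value <- mw$p.value
      row$p_display <- p_display(mw$p.value)
    }
    qrows[[length(qrows) + 1L]] <- row
  }
  quant <- do.call(rbind, qrows)
  list(selection = selection, assignments = assignments,
       grouping = grouping, quant = quant, lod = lod, samples = samples)
}

#' Load the packaged functional-class lookup
#'
#' Functional classes (OXIDOREDUCTASE, HYDROLASE, TRANSFERASE, ANTIOXIDANT,
#' OTHER) are an editorial table layout, assigned here by a first-hit
#' keyword lookup on the root name.
#'
#' @return data.frame `fragment`, `class` (ordered; first hit wins).
#' @export
default_class_map <- function() {
  utils::read.delim(system.file("extdata", "functional_classes.tsv",
                                package = "xmeprofiler", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Assign a functional class to a protein (root) name
#'
#' @param name protein name.
#' @param class_map lookup from [default_class_map()].
#' @return class label; `"OTHER"` when no fragment matches.
#' @export
functional_class <- function(name, class_map = default_class_map()) {
  norm <- normalize_name(name)
  for (i in seq_len(nrow(class_map))) {
    if (grepl(normalize_name(class_map$fragment[i]), norm, fixed = TRUE))
      return(class_map$class[i])
  }
  "OTHER"
}

#' Render a publication-style comparative table
#'
#' Rows are the groups detected in the focal tissue, grouped by functional
#' class and alphabetical within class; fold bounds keep their `<`/`>`
#' prefixes and p-values follow the display convention (`"<0.001"` below
#' 0.001, two significant figures otherwise).
#'
#' @param quant the `quant` table from [profile_xmes()].
#' @param tissue focal tissue whose detected groups are listed (default
#'   `"skin"`).
#' @param class_map functional-class lookup.
#' @return data.frame with columns `class`, `protein`, `accessions`,
#'   `fraction`, per-tissue detection rates, `relative_level`, `p_value`.
#' @export
render_table1 <- function(quant, tissue = "skin",
                          class_map = default_class_map()) {
  cols <- c("class", "protein", "accessions", "fraction",
            "skin_detection_rate", "liver_detection_rate",
            "relative_level", "p_value")
  if (is.null(quant) || nrow(quant) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols), stringsAsFactors = FALSE)
    return(out)
  }
  flag <- paste0(tissue, "_detected")
  q <- quant[quant[[flag]], , drop = FALSE]
  cls <- vapply(q$root_name, functional_class, "", class_map = class_map)
  out <- data.frame(class = cls, protein = q$root_name,
                    accessions = q$accessions, fraction = q$fraction,
                    skin_detection_rate = q$skin_detection_rate,
                    liver_detection_rate = q$liver_detection_rate,
                    relative_level = q$relative_level,
                    p_value = q$p_display, stringsAsFactors = FALSE)
  class_order <- c("OXIDOREDUCTASE", "HYDROLASE", "TRANSFERASE",
                   "ANTIOXIDANT", "OTHER")
  out <- out[order(match(out$class, class_order), out$protein), ]
  rownames(out) <- NULL
  out
}

#' Run the pipeline from files and write the result bundle
#'
#' Thin file-level wrapper: reads the FASTA database and per-sample TSV
#' identification tables, runs [profile_xmes()], and (when `out_dir` is
#' given) writes the group table, quant table, rendered comparative table,
#' selection audit and a run log with parameter values and per-stage
#' record counts. Identical inputs and parameters give byte-identical
#' outputs.
#'
#' @param database_fasta FASTA path.
#' @param sample_files character vector of per-sample TSV paths.
#' @param out_dir output directory (optional).
#' @param keywords a [keyword_config()].
#' @param params a [pipeline_params()].
#' @return the [profile_xmes()] result bundle, invisibly when writing.
#' @export
run_pipeline <- function(database_fasta, sample_files, out_dir = NULL,
                         keywords = default_keyword_config(),
                         params = pipeline_params()) {
  for (p in c(database_fasta, sample_files))
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
  if (length(sample_files) == 0L) stop("no samples")
  database <- read_database_fasta(database_fasta)
  obs <- read_sample_tables(sample_files)
  res <- profile_xmes(database, obs, keywords = keywords, params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(res$grouping$groups, "group_table.tsv")
    wt(res$quant, "quant_table.tsv")
    wt(render_table1(res$quant), "comparative_table.tsv")
    wt(res$selection$audit, "selection_audit.tsv")
    log <- c(sprintf("database records: %d", nrow(database)),
             sprintf("observations: %d", nrow(obs)),
             sprintf("samples: %d", nrow(res$samples)),
             sprintf("accepted names: %d", length(res$selection$accepted)),
             sprintf("groups: %d", nrow(res$grouping$groups)),
             sprintf("quantified groups: %d",
                     if (is.null(res$quant)) 0L else nrow(res$quant)),
             sprintf("lod substitution intensity: %g", res$lod),
             sprintf("min_peptides=%d min_donors=%d min_unique=%d",
                     params$min_peptides, params$min_donors,
                     params$min_unique))
    writeLines(log, file.path(out_dir, "run_log.txt"))
    return(invisible(res))
  }
  res
}
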
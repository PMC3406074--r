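#' Consolidate indistinguishable proteins into groups
#'
#' Builds an evidence graph over the accepted proteins with an edge
#' wherever a supporting peptide's match set contains both proteins of a
#' pair. A pair is merged when neither member has at least `min_unique`
#' supporting peptides unique to itself within the pair's union, i.e. when
#' the peptide evidence cannot distinguish them to the usual two-peptide
#' identification standard. Groups are the connected components of the
#' merged pairs. The root description of a group is the longest common
#' prefix of the member names with trailing digits/punctuation trimmed
#' (falling back to the alphabetically first member name), so that e.g.
#' indistinguishable glutathione transferase A isoforms report under the
#' family stem.
#'
#' Supporting peptides whose matches span more than one final group are
#' excluded from every group's support set, so the support sets partition
#' the retained evidence.
#'
#' @param assignments data.frame from [map_peptides()] (list column
#'   `accessions`), restricted to observed peptides.
#' @param accepted_accessions accessions that survived keyword selection.
#' @param protein_names named character vector, accession -> name.
#' @param min_unique peptides unique to a member needed to keep a pair
#'   separate (default 2).
#' @return list with `groups` (data.frame: `group_id`, `root_name`,
#'   `accessions` comma-joined, `n_members`, `n_peptides`) and `support`
#'   (data.frame: `group_id`, `peptide`).
#' @export
consolidate_groups <- function(assignments, accepted_accessions,
                               protein_names, min_unique = 2L) {
  stopifnot(is.data.frame(assignments), !is.null(assignments$accessions))
  acc <- intersect(unique(unlist(assignments$accessions)),
                   accepted_accessions)
  # restrict match sets to accepted proteins; drop peptides with no
  # accepted match
  sets <- lapply(assignments$accessions, intersect, y = acc)
  keep <- lengths(sets) > 0L
  peps <- assignments$peptide[keep]
  sets <- sets[keep]
  # deduplicate peptides (distinct sequences are the evidence unit)
  dup <- !duplicated(peps)
  peps <- peps[dup]; sets <- sets[dup]

  nodes <- sort(unique(unlist(sets)))
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # candidate pairs: co-occurrence in at least one match set
  pair_key <- character(0)
  for (s in sets) {
    if (length(s) < 2L) next
    cmb <- utils::combn(sort(s), 2L)
    pair_key <- c(pair_key, paste(cmb[1, ], cmb[2, ], sep = "\r"))
  }
  for (pk in unique(pair_key)) {
    ab <- strsplit(pk, "\r", fixed = TRUE)[[1]]
    a <- ab[1]; b <- ab[2]
    in_a <- vapply(sets, function(s) a %in% s, logical(1))
    in_b <- vapply(sets, function(s) b %in% s, logical(1))
    unique_a <- sum(in_a & !in_b)
    unique_b <- sum(in_b & !in_a)
    if (unique_a < min_unique && unique_b < min_unique) {
      ra <- find(match(a, nodes)); rb <- find(match(b, nodes))
      if (ra != rb) parent[ra] <- rb
    }
  }
  comp <- vapply(seq_along(nodes), find, integer(1))
  comp_ids <- unique(comp)
  groups <- data.frame(group_id = character(), root_name = character(),
                       accessions = character(), n_members = integer(),
                       n_peptides = integer(), stringsAsFactors = FALSE)
  support <- data.frame(group_id = character(), peptide = character(),
                        stringsAsFactors = FALSE)
  # group membership lookup for support assignment
  member_of <- setNames(match(comp, comp_ids), nodes)
  ord <- order(vapply(comp_ids, function(ci) {
    min(nodes[comp == ci])
  }, character(1)))
  rows <- list(); srows <- list()
  for (gi in seq_along(comp_ids[ord])) {
    ci <- comp_ids[ord][gi]
    members <- sort(nodes[comp == ci])
    gid <- sprintf("G%03d", gi)
    # support: peptides whose accepted matches all lie in this group
    in_group <- vapply(sets, function(s) all(s %in% members) &&
                         any(s %in% members), logical(1))
    rows[[gi]] <- data.frame(
      group_id = gid,
      root_name = root_description(unname(protein_names[members])),
      accessions = paste(members, collapse = ","),
      n_members = length(members),
      n_peptides = sum(in_group), stringsAsFactors = FALSE)
    if (any(in_group))
      srows[[gi]] <- data.frame(group_id = gid, peptide = peps[in_group],
                                stringsAsFactors = FALSE)
  }
  groups <- do.call(rbind, rows)
  support <- do.call(rbind, srows)
  if (is.null(groups)) groups <- data.frame(group_id = character(),
    root_name = character(), accessions = character(),
    n_members = integer(), n_peptides = integer(), stringsAsFactors = FALSE)
  if (is.null(support)) support <- data.frame(group_id = character(),
    peptide = character(), stringsAsFactors = FALSE)
  rownames(groups) <- rownames(support) <- NULL
  list(groups = groups, support = support)
}

#' Derive a root description from member protein names
#'
#' @param names character vector of member names.
#' @return longest common prefix, trimmed of trailing digits, punctuation
#'   and whitespace; if that is empty, the alphabetically first name.
#' @export
root_description <- function(names) {
  stopifnot(length(names) >= 1L)
  if (length(names) == 1L) return(names)
  prefix <- names[1]
  for (nm in names[-1]) {
    while (nchar(prefix) > 0L &&
           substr(nm, 1L, nchar(prefix)) != prefix) {
      prefix <- substr(prefix, 1L, nchar(prefix) - 1L)
    }
  }
  prefix <- sub("[[:digit:][:punct:][:space:]]+$", "", prefix)
  if (nzchar(prefix)) prefix else sort(names)[1]
}

#' Distinct-peptide counts per group and sample
#'
#' @param support data.frame `group_id`, `peptide` from
#'   [consolidate_groups()].
#' @param obs observation table (needs `sample_id`, `peptide`).
#' @return data.frame `group_id`, `sample_id`, `n_peptides` (distinct
#'   peptide sequences of the group seen in that sample).
#' @export
group_sample_counts <- function(support, obs) {
  m <- merge(support, obs[, c("sample_id", "peptide")], by = "peptide")
  if (nrow(m) == 0L)
    return(data.frame(group_id = character(), sample_id = character(),
                      n_peptides = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(peptide ~ group_id + sample_id, data = m,
                          FUN = function(p) length(unique(p)))
  names(agg)[3] <- "n_peptides"
  agg
}

#' Apply the detection criterion per tissue
#'
#' A group is called detected in a tissue when at least `min_donors`
#' samples of that tissue each contain at least `min_peptides` distinct
#' supporting peptides. The detection rate is the percentage of the
#' tissue's samples meeting the `min_peptides` threshold, regardless of the
#' donor minimum.
#'
#' @param grouping result of [consolidate_groups()].
#' @param obs observation table.
#' @param samples roster data.frame `sample_id`, `tissue` (defines the
#'   denominator; samples with no observations count).
#' @param min_peptides distinct peptides per sample (default 2).
#' @param min_donors samples required for a detection call (default 2).
#' @return data.frame: `group_id`, `tissue`, `n_samples`, `n_positive`,
#'   `detection_rate` (percent), `detected`.
#' @export
apply_detection <- function(grouping, obs, samples, min_peptides = 2L,
                            min_donors = 2L) {
  stopifnot(all(c("sample_id", "tissue") %in% names(samples)))
  tis <- unique(samples$tissue)
  if (any(tabulate(factor(samples$tissue, levels = tis)) == 0L) ||
      nrow(samples) == 0L)
    stop("configuration error: every tissue needs >= 1 sample")
  counts <- group_sample_counts(grouping$support, obs)
  out <- list()
  for (g in grouping$groups$group_id) {
    for (t in tis) {
      sids <- samples$sample_id[samples$tissue == t]
      cnt <- counts$n_peptides[counts$group_id == g &
                                 counts$sample_id %in% sids]
      n_pos <- sum(cnt >= min_peptides)
      out[[length(out) + 1L]] <- data.frame(
        group_id = g, tissue = t, n_samples = length(sids),
        n_positive = n_pos,
        detection_rate = 100 * n_pos / length(sids),
        detected = n_pos >= min_donors, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(group_id = character(), tissue = character(),
                      n_samples = integer(), n_positive = integer(),
                      detection_rate = numeric(), detected = logical(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Resolve the reporting gel region for a group
#'
#' When a protein is seen in several gel regions only the region with the
#' greatest total number of detected peptides is used downstream. Ties go
#' to the lowest region index (with a note).
#'
#' @param support_peptides character vector of the group's supporting
#'   peptide sequences.
#' @param obs observation table (needs `peptide`, `gel_region`,
#'   `sample_id`).
#' @return integer gel region.
#' @export
resolve_region <- function(support_peptides, obs) {
  o <- obs[obs$peptide %in% support_peptides, ]
  if (nrow(o) == 0L) stop("no observations for group")
  # total distinct-peptide count per region, summed across samples
  per <- stats::aggregate(peptide ~ gel_region + sample_id, data = o,
                          FUN = function(p) length(unique(p)))
  tot <- stats::aggregate(peptide ~ gel_region, data = per, FUN = sum)
  best <- tot$gel_region[tot$peptide == max(tot$peptide)]
  if (length(best) > 1L)
    message(sprintf("region tie (%s); using lowest region %d",
                    paste(best, collapse = ", "), min(best)))
  as.integer(min(best))
}

#' Resolve the reported subcellular fraction for a group
#'
#' Compares total intensity between cytosol and microsomes; when the two
#' are within `threshold`-fold of each other the protein is reported in
#' both fractions, otherwise in the dominant one.
#'
#' @param support_peptides the group's supporting peptide sequences.
#' @param obs observation table (needs `peptide`, `fraction`, `intensity`).
#' @param threshold fold ratio treated as "similar levels" (default 2).
#' @return one of `"cytosol"`, `"microsome"`, `"both"`.
#' @export
resolve_fraction <- function(support_peptides, obs, threshold = 2) {
  o <- obs[obs$peptide %in% support_peptides, ]
  if (nrow(o) == 0L) stop("no observations for group")
  sums <- c(cytosol = sum(o$intensity[o$fraction == "cytosol"]),
            microsome = sum(o$intensity[o$fraction == "microsome"]))
  if (all(sums == 0)) stop("no fraction intensity for group")
  if (min(sums) > 0 && max(sums) / min(sums) <= threshold) return("both")
  names(sums)[which.max(sums)]
}
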
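# Independent brute-force oracles and tiny fixture builders used across the
# suite. Each oracle takes a deliberately different route from the
# implementation it checks.

# Digestion oracle: test every substring of the sequence for being a valid
# tryptic fragment with at most k internal missed-cleavage sites.
oracle_digest <- function(sequence, k = 0L) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  site <- logical(n)  # cleavage allowed after position i
  for (i in seq_len(n - 1)) {
    site[i] <- chars[i] %in% c("K", "R") && chars[i + 1] != "P"
  }
  out <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      left_ok <- i == 1L || site[i - 1L]
      right_ok <- j == n || site[j]
      internal <- if (j > i) sum(site[i:(j - 1L)]) else 0L
      if (left_ok && right_ok && internal <= k)
        out <- c(out, substr(sequence, i, j))
    }
  }
  out
}

# Peptide mapping oracle: plain grepl scan over every record.
oracle_map <- function(peptide, database) {
  database$accession[vapply(database$sequence, grepl, logical(1),
                            pattern = peptide, fixed = TRUE,
                            USE.NAMES = FALSE)]
}

# Exact Mann-Whitney oracle: full enumeration of all C(N, n1) labellings.
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(r), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  p_lo <- mean(ws <= w_obs + 1e-9)
  p_hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# Consolidation oracle: apply the pairwise merge rule exhaustively to a
# fixpoint via boolean reachability, independent of union-find.
oracle_consolidate <- function(peptide_sets, accessions, min_unique = 2L) {
  accessions <- accessions[accessions %in% unlist(peptide_sets)]
  n <- length(accessions)
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      a <- accessions[i]; b <- accessions[j]
      shares <- any(vapply(peptide_sets,
                           function(s) a %in% s && b %in% s, logical(1)))
      if (!shares) next
      ua <- sum(vapply(peptide_sets,
                       function(s) a %in% s && !(b %in% s), logical(1)))
      ub <- sum(vapply(peptide_sets,
                       function(s) b %in% s && !(a %in% s), logical(1)))
      if (ua < min_unique && ub < min_unique) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  reach <- adj
  for (step in seq_len(n)) reach <- (reach %*% reach) > 0
  groups <- unique(apply(reach, 1, function(row)
    paste(sort(accessions[row]), collapse = ",")))
  sort(groups)
}

# Tiny hand-built database: two GST-like isoforms sharing peptides, one
# distinct hydrolase, one decoy.
tiny_database <- function() {
  shared1 <- "AAADDDEEEK"
  shared2 <- "CCCFFFGGGR"
  gst1_own <- "HHHIIIMMMK"
  gst2_own <- "NNNQQQSSSR"
  eh_p1 <- "TTTVVVWWWK"
  eh_p2 <- "YYYAAACCCR"
  dec_p1 <- "DDDFFFHHHK"
  dec_p2 <- "EEEGGGIIIR"
  data.frame(
    accession = c("SYN_A1", "SYN_A2", "SYN_B1", "SYN_C1"),
    name = c("glutathione transferase A1", "glutathione transferase A2",
             "epoxide hydrolase 1", "serum albumin"),
    sequence = c(paste0(shared1, shared2, gst1_own),
                 paste0(shared1, shared2, gst2_own),
                 paste0(eh_p1, eh_p2),
                 paste0(dec_p1, dec_p2)),
    stringsAsFactors = FALSE)
}

# Observation-table builder for hand fixtures.
make_obs <- function(sample_id, tissue, peptide, intensity,
                     fraction = "cytosol", gel_region = 1L) {
  data.frame(sample_id = sample_id, tissue = tissue, fraction = fraction,
             gel_region = gel_region, peptide = peptide, charge = 2L,
             score = 3.0, intensity = intensity, stringsAsFactors = FALSE)
}

# Random small database of fully tryptic synthetic peptides (uses the
# package generator building blocks indirectly: plain random strings).
random_peptide <- function(len = 8L) {
  inner <- sample(setdiff(LETTERS[LETTERS %in% c("A","C","D","E","F","G",
    "H","I","L","M","N","Q","S","T","V","W","Y")], "P"), 1)
  mid <- sample(c("A","C","D","E","F","G","H","I","L","M","N","P","Q",
                  "S","T","V","W","Y"), len - 2L, replace = TRUE)
  paste0(inner, paste(mid, collapse = ""), sample(c("K", "R"), 1))
}
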
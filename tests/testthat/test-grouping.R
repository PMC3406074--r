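# assignments builder: peptide -> set of matched accessions
make_assignments <- function(sets) {
  out <- data.frame(peptide = names(sets), matched = TRUE,
                    n_matches = lengths(sets), stringsAsFactors = FALSE)
  out$accessions <- unname(sets)
  out
}

test_that("fully shared isoforms consolidate under a common root name", {
  sets <- list(P1 = c("SYN_A1", "SYN_A2"), P2 = c("SYN_A1", "SYN_A2"),
               P3 = c("SYN_A1", "SYN_A2"))
  nm <- c(SYN_A1 = "glutathione transferase A1",
          SYN_A2 = "glutathione transferase A2")
  g <- consolidate_groups(make_assignments(sets), names(nm), nm)
  expect_identical(nrow(g$groups), 1L)
  expect_identical(g$groups$root_name, "glutathione transferase A")
  expect_identical(g$groups$accessions, "SYN_A1,SYN_A2")
  expect_identical(sort(g$support$peptide), c("P1", "P2", "P3"))
})

test_that("proteins with disjoint peptide evidence stay separate", {
  sets <- list(P1 = "SYN_A1", P2 = "SYN_A1", P3 = "SYN_B1", P4 = "SYN_B1")
  nm <- c(SYN_A1 = "catalase", SYN_B1 = "epoxide hydrolase 1")
  g <- consolidate_groups(make_assignments(sets), names(nm), nm)
  expect_identical(nrow(g$groups), 2L)
  expect_identical(g$groups$n_members, c(1L, 1L))
})

test_that("a pair with two unique peptides on one side stays separate", {
  # A and B share P1, but A carries two peptides of its own
  sets <- list(P1 = c("A", "B"), P2 = "A", P3 = "A", P4 = "B")
  nm <- c(A = "aldehyde dehydrogenase 1", B = "aldehyde dehydrogenase 2")
  g <- consolidate_groups(make_assignments(sets), names(nm), nm)
  expect_identical(nrow(g$groups), 2L)
  # the shared peptide spans two groups and is excluded from both supports
  expect_false("P1" %in% g$support$peptide)
  # relaxing min_unique merges them
  g2 <- consolidate_groups(make_assignments(sets), names(nm), nm,
                           min_unique = 3L)
  expect_identical(nrow(g2$groups), 1L)
  expect_true("P1" %in% g2$support$peptide)
})

test_that("random instances match the brute-force merge oracle", {
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    accs <- sprintf("SYN_%02d", seq_len(n))
    n_pep <- sample(3:10, 1)
    sets <- lapply(seq_len(n_pep), function(i) {
      k <- sample(1:min(3, n), 1)
      sample(accs, k)
    })
    names(sets) <- sprintf("P%02d", seq_len(n_pep))
    nm <- setNames(sprintf("protein %02d", seq_len(n)), accs)
    g <- consolidate_groups(make_assignments(sets), accs, nm)
    expect_identical(sort(g$groups$accessions),
                     oracle_consolidate(sets, accs))
  }
})

test_that("consolidation is order-independent", {
  set.seed(78)
  accs <- sprintf("SYN_%02d", 1:5)
  sets <- lapply(1:8, function(i) sample(accs, sample(1:3, 1)))
  names(sets) <- sprintf("P%02d", 1:8)
  nm <- setNames(sprintf("protein %02d", 1:5), accs)
  g1 <- consolidate_groups(make_assignments(sets), accs, nm)
  perm <- sample(length(sets))
  g2 <- consolidate_groups(make_assignments(sets[perm]), rev(accs), nm)
  expect_identical(g1$groups$accessions, g2$groups$accessions)
  expect_identical(g1$groups$root_name, g2$groups$root_name)
})

test_that("root descriptions trim trailing digits and punctuation", {
  expect_identical(root_description(c("glutathione transferase A1",
                                      "glutathione transferase A2")),
                   "glutathione transferase A")
  expect_identical(root_description(c("peroxiredoxin-1", "peroxiredoxin-2")),
                   "peroxiredoxin")
  # no common prefix: alphabetically first name
  expect_identical(root_description(c("zeta protein", "alpha protein")),
                   "alpha protein")
  expect_identical(root_description("catalase"), "catalase")
})

test_that("detection calls and rates follow the donor criterion", {
  support <- data.frame(group_id = "G001",
                        peptide = c("P1", "P2", "P3"),
                        stringsAsFactors = FALSE)
  groups <- data.frame(group_id = "G001", root_name = "x",
                       accessions = "A", n_members = 1L, n_peptides = 3L,
                       stringsAsFactors = FALSE)
  samples <- sample_roster(sim_config())
  # 8 of 10 skin donors with 2 peptides; liver none
  obs <- do.call(rbind, lapply(sprintf("skin_%02d", 1:8), function(s)
    make_obs(s, "skin", c("P1", "P2"), c(1e5, 2e5))))
  det <- apply_detection(list(groups = groups, support = support), obs,
                         samples)
  skin <- det[det$tissue == "skin", ]
  liver <- det[det$tissue == "liver", ]
  expect_true(skin$detected)
  expect_equal(skin$detection_rate, 80)
  expect_false(liver$detected)
  expect_equal(liver$detection_rate, 0)
  # 2 peptides in exactly 1 donor: rate 10, not detected
  obs1 <- make_obs("skin_01", "skin", c("P1", "P2"), c(1e5, 2e5))
  det1 <- apply_detection(list(groups = groups, support = support), obs1,
                          samples)
  expect_false(det1$detected[det1$tissue == "skin"])
  expect_equal(det1$detection_rate[det1$tissue == "skin"], 10)
  expect_error(apply_detection(list(groups = groups, support = support),
                               obs1, samples[0, ]), "configuration error")
})

test_that("randomized detection rates equal a direct recount oracle", {
  set.seed(79)
  support <- data.frame(group_id = "G001",
                        peptide = sprintf("P%d", 1:5),
                        stringsAsFactors = FALSE)
  groups <- data.frame(group_id = "G001", root_name = "x",
                       accessions = "A", n_members = 1L, n_peptides = 5L,
                       stringsAsFactors = FALSE)
  samples <- sample_roster(sim_config())
  for (rep in 1:10) {
    rows <- list()
    for (s in samples$sample_id) {
      k <- sample(0:5, 1)
      if (k > 0)
        rows[[length(rows) + 1]] <- make_obs(
          s, samples$tissue[samples$sample_id == s],
          sample(sprintf("P%d", 1:5), k), runif(k, 1e4, 1e6))
    }
    obs <- do.call(rbind, rows)
    det <- apply_detection(list(groups = groups, support = support), obs,
                           samples, min_peptides = 2, min_donors = 2)
    for (t in c("skin", "liver")) {
      sids <- samples$sample_id[samples$tissue == t]
      manual <- sum(vapply(sids, function(s)
        length(unique(obs$peptide[obs$sample_id == s])) >= 2, logical(1)))
      expect_equal(det$detection_rate[det$tissue == t],
                   100 * manual / length(sids))
      expect_identical(det$detected[det$tissue == t], manual >= 2)
    }
  }
})

test_that("detection is monotone in added peptide evidence", {
  support <- data.frame(group_id = "G001", peptide = c("P1", "P2", "P3"),
                        stringsAsFactors = FALSE)
  groups <- data.frame(group_id = "G001", root_name = "x", accessions = "A",
                       n_members = 1L, n_peptides = 3L,
                       stringsAsFactors = FALSE)
  samples <- sample_roster(sim_config())
  obs <- rbind(make_obs("skin_01", "skin", c("P1", "P2"), c(1, 2)),
               make_obs("skin_02", "skin", "P1", 1),
               make_obs("liver_01", "liver", c("P1", "P2"), c(1, 2)))
  before <- apply_detection(list(groups = groups, support = support), obs,
                            samples)
  obs2 <- rbind(obs, make_obs("skin_02", "skin", "P3", 5))
  after <- apply_detection(list(groups = groups, support = support), obs2,
                           samples)
  expect_true(all(after$detection_rate >= before$detection_rate))
  expect_true(all(after$detected >= before$detected))
})

test_that("region resolution picks the region with most peptides", {
  obs <- rbind(make_obs("s1", "skin", c("P1", "P2", "P3"), c(1, 1, 1),
                        gel_region = 3),
               make_obs("s2", "skin", c("P1", "P2"), c(1, 1),
                        gel_region = 3),
               make_obs("s1", "skin", c("P1", "P4"), c(1, 1),
                        gel_region = 9))
  expect_identical(resolve_region(sprintf("P%d", 1:4), obs), 3L)
  # all in one region
  obs7 <- make_obs("s1", "skin", "P1", 1, gel_region = 7)
  expect_identical(resolve_region("P1", obs7), 7L)
  # tie goes to the lowest region, with a note
  tie <- rbind(make_obs("s1", "skin", "P1", 1, gel_region = 5),
               make_obs("s1", "skin", "P2", 1, gel_region = 2))
  expect_message(r <- resolve_region(c("P1", "P2"), tie), "tie")
  expect_identical(r, 2L)
})

test_that("fraction resolution applies the similarity threshold", {
  all_cyt <- make_obs("s1", "skin", c("P1", "P2"), c(10, 5),
                      fraction = "cytosol")
  expect_identical(resolve_fraction(c("P1", "P2"), all_cyt), "cytosol")
  split_55_45 <- rbind(
    make_obs("s1", "skin", "P1", 55, fraction = "cytosol"),
    make_obs("s1", "skin", "P1", 45, fraction = "microsome"))
  expect_identical(resolve_fraction("P1", split_55_45), "both")
  split_10_1 <- rbind(
    make_obs("s1", "skin", "P1", 10, fraction = "microsome"),
    make_obs("s1", "skin", "P1", 1, fraction = "cytosol"))
  expect_identical(resolve_fraction("P1", split_10_1), "microsome")
})
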
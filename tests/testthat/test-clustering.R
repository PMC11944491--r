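test_that("greedy clustering handles degenerate cases", {
  same <- make_records(rep("ACGTACGTACGTACGTACGT", 3))
  cl <- greedy_cluster(same, 97)
  expect_equal(nrow(cl), 1L)
  expect_equal(lengths(cl$member_ids), 3L)
  expect_true(cl$centroid_id %in% cl$member_ids[[1]])

  # two sequences at 90% identity split at threshold 97
  a <- "ACGTACGTAC"
  b <- "ACGTACGTAT"
  expect_equal(pairwise_identity(a, b)$identity_pct, 90)
  cl <- greedy_cluster(make_records(c(a, b)), 97)
  expect_equal(nrow(cl), 2L)
  expect_equal(nrow(greedy_cluster(make_records(c(a, b)), 90)), 1L)

  empty <- make_records("ACGT")[0, ]
  class(empty) <- c("seq_records", "data.frame")
  expect_equal(nrow(greedy_cluster(empty, 97)), 0L)
})

test_that("greedy clustering matches a brute-force oracle", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(8:15, 1)
    # mixture of related and unrelated sequences for non-trivial clusters
    seed_seqs <- random_dna(3, 60)
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(seed_seqs, 1)
      ch <- strsplit(s, "")[[1]]
      k <- sample(0:8, 1)
      if (k > 0) {
        pos <- sample(60, k)
        for (p in pos) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
      }
      paste(ch, collapse = "")
    }, "")
    recs <- make_records(seqs, ids = sprintf("s%02d", seq_len(n)),
                         abundance = sample(1:5, n, replace = TRUE))
    got <- membership_of(greedy_cluster(recs, 90))
    want <- oracle_greedy(recs, 90)
    expect_equal(got[names(want)], want)
  }
})

test_that("clustering is invariant to input row order", {
  set.seed(33)
  recs <- make_records(random_dna(10, 40),
                       abundance = sample(1:6, 10, replace = TRUE))
  shuffled <- recs[sample(nrow(recs)), ]
  class(shuffled) <- c("seq_records", "data.frame")
  a <- greedy_cluster(recs, 80)
  b <- greedy_cluster(shuffled, 80)
  expect_equal(a$centroid_id, b$centroid_id)
  expect_equal(a$member_ids, b$member_ids)
})

test_that("every member meets the threshold to its centroid", {
  set.seed(34)
  cfg <- simulation_config(seed = 34, n_families = 3,
                           genera_per_family = 2, species_per_genus = 3)
  ref <- simulate_reference_taxonomy(cfg)
  ds <- simulate_dataset(ref, cfg)
  tiered <- tiered_cluster(dereplicate(ds$records))
  recs <- dereplicate(ds$records)
  seq_of <- setNames(recs$sequence, recs$id)
  for (lvl in c("species", "genus", "family")) {
    cl <- tiered[[lvl]]
    th <- tiered$thresholds[[lvl]]
    member_seq <- function(m) switch(lvl,
      species = seq_of[[m]],
      genus = tiered$species$sequence[match(m, tiered$species$centroid_id)],
      family = tiered$genus$sequence[match(m, tiered$genus$centroid_id)])
    for (i in seq_len(nrow(cl))) {
      cent <- cl$sequence[i]
      for (m in cl$member_ids[[i]])
        expect_gte(pairwise_identity(member_seq(m), cent)$identity_pct, th)
    }
  }
})

test_that("tiered clustering nests strictly and counts are monotone", {
  one <- make_records("ACGTACGTACGTACGTACGT")
  t1 <- tiered_cluster(one)
  expect_equal(c(nrow(t1$species), nrow(t1$genus), nrow(t1$family)),
               c(1L, 1L, 1L))

  set.seed(36)
  recs <- make_records(random_dna(25, 60),
                       abundance = sample(1:9, 25, replace = TRUE))
  tc <- tiered_cluster(recs, c(species = 90, genus = 80, family = 70))
  expect_lte(nrow(tc$family), nrow(tc$genus))
  expect_lte(nrow(tc$genus), nrow(tc$species))
  # partitions: every record in exactly one cluster per level
  expect_setequal(unlist(tc$species$member_ids), recs$id)
  expect_equal(anyDuplicated(unlist(tc$species$member_ids)), 0L)
  # nesting maps are total
  expect_setequal(names(tc$sotu_to_gotu), tc$species$centroid_id)
  expect_setequal(names(tc$gotu_to_fotu), tc$genus$centroid_id)
  # genus/family sample sets are unions of their members
  expect_setequal(unlist(tc$family$samples), unlist(tc$species$samples))
})

test_that("occupancy classes follow the distinct-sample count", {
  recs <- seq_records(
    id = c("a", "b", "c", "d"),
    sequence = random_dna(4, 30),
    samples = list("s1", c("s1", "s2"), c("s1", "s2", "s3"),
                   c("s1", "s2", "s3", "s4", "s5")))
  tc <- tiered_cluster(recs, c(species = 100, genus = 100, family = 100))
  occ <- occupancy_classes(tc)
  expect_equal(unname(occ[c("a", "b", "c", "d")]),
               c("singleton", "doubleton", "tripleton", "moreton"))
})

test_that("singleton removal drops single-OTU single-sample clusters", {
  set.seed(38)
  seqs <- random_dna(3, 60)
  recs <- seq_records(
    id = c("multi1", "multi2", "lone"),
    sequence = seqs,
    samples = list(c("s1", "s2"), c("s2", "s3"), "s4"),
    abundance = c(5L, 4L, 1L))
  tc <- tiered_cluster(recs, c(species = 95, genus = 85, family = 75))
  out <- remove_singletons(tc)
  expect_equal(unname(out$with["sotus"] - out$without["sotus"]), 1L)
  expect_equal(out$removed_sotus, "lone")

  # all clusters multi-sample: nothing changes
  tc2 <- tiered_cluster(recs[1:2, ], c(species = 95, genus = 85, family = 75))
  out2 <- remove_singletons(tc2)
  expect_equal(out2$with, out2$without)
})

test_that("planted singleton fraction is recovered from the generator", {
  cfg <- simulation_config(seed = 44, singleton_fraction = 0.5,
                           noise_rate = 0)
  ref <- simulate_reference_taxonomy(cfg)
  ds <- simulate_dataset(ref, cfg)
  n_sp <- nrow(ref$truth$species)
  expect_equal(length(ds$truth$planted_singletons), floor(0.5 * n_sp))
  tc <- tiered_cluster(dereplicate(ds$records))
  occ <- occupancy_classes(tc)
  # every planted singleton species yields a singleton SOTU (noise-free)
  expect_gte(sum(occ == "singleton"), length(ds$truth$planted_singletons))
})
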
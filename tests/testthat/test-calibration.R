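test_that("intra-taxon distributions isolate one rank boundary", {
  db <- tiny_refdb()
  # species rank: no two references share a species -> empty, with warning
  expect_warning(sp <- intra_taxon_identities(db, "species"), "no qualifying")
  expect_equal(sp$n_pairs, 0L)

  # genus rank: the three GenA species give 3 pairs, values checkable
  gn <- intra_taxon_identities(db, "genus")
  expect_equal(gn$n_pairs, 3L)
  seqs <- db$records$sequence[1:3]
  want <- c(pairwise_identity(seqs[1], seqs[2])$identity_pct,
            pairwise_identity(seqs[1], seqs[3])$identity_pct,
            pairwise_identity(seqs[2], seqs[3])$identity_pct)
  expect_setequal(round(gn$identities, 6), round(want, 6))

  # family rank excludes pairs that already share a genus:
  # FamA pairs all share GenA and FamB has one member -> nothing qualifies
  expect_warning(fm <- intra_taxon_identities(db, "family"))
  expect_equal(fm$n_pairs, 0L)

  # two identical sequences in one genus -> distribution {100}
  recs <- make_records(rep("ACGTACGTACGTACGT", 2), ids = c("p", "q"))
  tax <- data.frame(id = c("p", "q"), domain = "Archaea", phylum = "P",
                    class = "C", order = "O", family = "F", genus = "G",
                    species = c("S1", "S2"), stringsAsFactors = FALSE)
  d <- intra_taxon_identities(reference_db(recs, tax), "genus")
  expect_equal(d$identities, 100)
})

test_that("the sub-region mirrors full-length identity structure", {
  cfg <- simulation_config(seed = 51, n_families = 3, genera_per_family = 2,
                           species_per_genus = 3)
  ref <- simulate_reference_taxonomy(cfg)
  full <- intra_taxon_identities(ref$db, "genus")

  # aligned view of the references with a fixed gap pattern, then a region
  # covering most of it
  gapify <- function(s) paste0("..", substr(s, 1, 100), "-",
                               substr(s, 101, nchar(s)), "..")
  aln <- aligned_seqs(ref$db$records$id,
                      vapply(ref$db$records$sequence, gapify, "",
                             USE.NAMES = FALSE))
  spec <- region_spec(3, 3 + 200, 50)   # first ~200 bases of 250
  reg <- intra_taxon_identities(ref$db, "genus", region = spec, aligned = aln)
  chk <- mirror_check(full, reg, tolerance = 2)
  expect_true(chk$pass)
  expect_lte(chk$difference, 2)

  # identical distributions: difference exactly 0
  self <- mirror_check(full, full)
  expect_equal(self$difference, 0)
  expect_true(self$pass)

  # medians 3 points apart with tolerance 2 fail
  shifted <- full
  shifted$median <- full$median + 3
  expect_false(mirror_check(full, shifted, tolerance = 2)$pass)
  empty_dist <- suppressWarnings(intra_taxon_identities(tiny_refdb(),
                                                        "family"))
  expect_error(mirror_check(full, empty_dist), "empty|different")
})

test_that("threshold recommendation rounds medians and enforces monotonicity", {
  fake <- function(rank, median) {
    structure(list(rank = rank, identities = median, n_pairs = 10L,
                   median = median, q25 = median, q75 = median),
              class = "rank_identity_distribution")
  }
  th <- recommend_thresholds(fake("species", 97.2), fake("genus", 92.8),
                             fake("family", 89.4))
  expect_equal(unname(th), c(97, 93, 89))
  expect_error(recommend_thresholds(fake("species", 95), fake("genus", 96),
                                    fake("family", 89)),
               "non-monotone")
  expect_error(recommend_thresholds(fake("genus", 95), fake("genus", 93),
                                    fake("family", 89)),
               "rank")
})

test_that("calibration on a simulated reference set recovers the bands", {
  cfg <- simulation_config(seed = 53, n_families = 4, genera_per_family = 3,
                           species_per_genus = 3)
  ref <- simulate_reference_taxonomy(cfg)
  dists <- lapply(c(species = "species", genus = "genus", family = "family"),
                  function(r) intra_taxon_identities(ref$db, r))
  # band separation property: medians ordered
  expect_gte(dists$species$median, dists$genus$median)
  expect_gte(dists$genus$median, dists$family$median)
  th <- recommend_thresholds(dists$species, dists$genus, dists$family)
  expect_lte(max(abs(th - c(species = 97, genus = 93, family = 89))), 1)
})

test_that("taxon fragmentation counts greedy clusters per labelled taxon", {
  # a family whose two members sit at 85%: threshold 89 fragments it
  set.seed(54)
  a <- random_dna(1, 100)
  ch <- strsplit(a, "")[[1]]
  pos <- seq(3, by = 6, length.out = 15)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  b <- paste(ch, collapse = "")
  recs <- make_records(c(a, b), ids = c("x1", "x2"))
  tax <- data.frame(id = c("x1", "x2"), domain = "Archaea", phylum = "P",
                    class = "C", order = "O", family = "FamZ",
                    genus = c("G1", "G2"), species = c("S1", "S2"),
                    stringsAsFactors = FALSE)
  db <- reference_db(recs, tax)
  frag <- taxon_fragmentation(db, "family", 89)
  expect_equal(unname(frag["FamZ"]), 2L)
  expect_equal(unname(taxon_fragmentation(db, "family", 80)["FamZ"]), 1L)

  # derived: fragmentation equals an independent greedy run per taxon
  cfg <- simulation_config(seed = 55, n_families = 2, genera_per_family = 2,
                           species_per_genus = 3)
  ref <- simulate_reference_taxonomy(cfg)
  frag <- taxon_fragmentation(ref$db, "family", 89)
  tx <- ref$db$taxonomy
  for (fam in names(frag)) {
    ids <- tx$id[tx$family == fam]
    sub <- ref$db$records[ref$db$records$id %in% ids, ]
    class(sub) <- c("seq_records", "data.frame")
    want <- length(unique(oracle_greedy(sub, 89)))
    expect_equal(unname(frag[fam]), want)
  }
})
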
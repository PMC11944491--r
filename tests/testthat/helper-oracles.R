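# Independent oracles and small fixture builders used across the suite.

# Exhaustive-alignment identity oracle.
#
# Enumerates every global alignment of a and b as a monotone lattice path
# by depth-first search from the (m, n) corner. Terminal gap runs (the
# maximal same-direction gap run at either end of the path) are free and
# contribute no scored columns; interior steps score match +1, mismatch
# -1, gap -1. Among all alignments the one with the lexicographically
# maximal (score, matches, -columns) tuple is reported — the same total
# order the package's dynamic program optimises, stated here over the
# full enumeration rather than cell-wise.
oracle_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  best <- NULL
  better <- function(x, y) {           # is tuple x better than y?
    if (is.null(y)) return(TRUE)
    if (x$score != y$score) return(x$score > y$score)
    if (x$matches != y$matches) return(x$matches > y$matches)
    x$cols < y$cols
  }
  rec <- function(i, j, score, matches, cols, trail) {
    if (i == 0L || j == 0L) {          # leading overhang: free
      cand <- list(score = score, matches = matches, cols = cols)
      if (better(cand, best)) best <<- cand
      return(invisible(NULL))
    }
    s <- if (A[i] == B[j]) 1L else -1L
    rec(i - 1L, j - 1L, score + s, matches + (s == 1L), cols + 1L, "x")
    if (trail == "o" || trail == "U")  # still inside a free trailing run
      rec(i - 1L, j, score, matches, cols, "U")
    else
      rec(i - 1L, j, score - 1L, matches, cols + 1L, "x")
    if (trail == "o" || trail == "L")
      rec(i, j - 1L, score, matches, cols, "L")
    else
      rec(i, j - 1L, score - 1L, matches, cols + 1L, "x")
  }
  rec(m, n, 0L, 0L, 0L, "o")
  list(identity_pct = if (best$cols > 0) 100 * best$matches / best$cols else 0,
       matches = best$matches, scored_columns = best$cols,
       score = best$score)
}

# Brute-force greedy clustering oracle: same ordering contract
# (abundance desc, length desc, id asc) and first-matching-centroid rule,
# coded as a plain double loop over pairwise_identity calls.
oracle_greedy <- function(records, threshold) {
  ord <- order(-records$abundance, -nchar(records$sequence), records$id)
  ids <- records$id[ord]
  seqs <- records$sequence[ord]
  centroids <- integer(0)
  membership <- character(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (c in centroids) {
      if (pairwise_identity(seqs[i], seqs[c])$identity_pct >= threshold - 1e-9) {
        membership[i] <- ids[c]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      membership[i] <- ids[i]
    }
  }
  setNames(membership, ids)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

make_records <- function(seqs, ids = sprintf("r%02d", seq_along(seqs)),
                         abundance = 1L, samples = NULL) {
  if (is.null(samples)) samples <- as.list(ids)
  seq_records(id = ids, sequence = seqs, samples = samples,
              abundance = abundance)
}

# membership map (record id -> centroid id) from an otu_clusters table
membership_of <- function(clusters) {
  setNames(rep(clusters$centroid_id, lengths(clusters$member_ids)),
           unlist(clusters$member_ids))
}

# small reference database: 3 species in 1 genus plus an outgroup genus.
# The base is deliberately aperiodic so overlap alignments cannot rescue
# substitutions by sliding one sequence along the other.
tiny_refdb <- function() {
  base <- "ACGGTCAATCGGATCCTTGA"
  recs <- make_records(
    c(base,
      sub("^AC", "AA", base),            # 1 diff -> 95% to base
      sub("TTGA$", "TTCA", base),        # 1 diff -> 95% to base
      "TTCACGTGACTATTGCAGCC"),           # unrelated outgroup
    ids = c("ref1", "ref2", "ref3", "out1"))
  tax <- data.frame(
    id = c("ref1", "ref2", "ref3", "out1"),
    domain = "Archaea", phylum = "P1", class = "C1", order = "O1",
    family = c("FamA", "FamA", "FamA", "FamB"),
    genus = c("GenA", "GenA", "GenA", "GenB"),
    species = c("SpA", "SpB", "SpC", "SpX"),
    stringsAsFactors = FALSE)
  reference_db(recs, tax)
}
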
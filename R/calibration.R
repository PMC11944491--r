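# Threshold calibration from a labelled reference set: intra-rank identity
# distributions, the full-length vs sub-region mirror check, and the
# taxon-fragmentation diagnostic.

#' Intra-taxon pairwise identity distribution at a rank
#'
#' For every unordered pair of reference sequences that share the named
#' rank label (both labelled, i.e. not UNK) and do NOT share any lower
#' rank, computes pairwise identity — so each distribution characterises
#' exactly one rank boundary. With a \code{region} and the corresponding
#' aligned records, identities are computed on the extracted sub-region
#' instead of the full sequences.
#'
#' @param db a \code{\link{reference_db}}.
#' @param rank \code{"family"}, \code{"genus"} or \code{"species"}.
#' @param region optional \code{\link{region_spec}}.
#' @param aligned optional \code{aligned_seqs} covering every db id
#'   (required when \code{region} is given).
#' @return an object of class \code{rank_identity_distribution}: list with
#'   \code{rank}, \code{identities}, \code{n_pairs}, \code{median} and
#'   quartiles. Empty (with a warning) when no rank has two labelled
#'   members.
#' @export
intra_taxon_identities <- function(db, rank, region = NULL, aligned = NULL) {
  rank <- match.arg(rank, c("family", "genus", "species"))
  stopifnot(inherits(db, "reference_db"))
  seqs <- db$records$sequence
  names(seqs) <- db$records$id
  if (!is.null(region)) {
    if (is.null(aligned)) stop("region given but no aligned records")
    missing <- setdiff(db$records$id, aligned$id)
    if (length(missing) > 0)
      stop("no aligned record for reference id: ", missing[1])
    sub <- extract_region(aligned[match(db$records$id, aligned$id), ,
                                  drop = FALSE], region)
    seqs <- setNames(sub$sequence, sub$id)[db$records$id]
  }
  tx <- db$taxonomy[match(db$records$id, db$taxonomy$id), ]
  ri <- match(rank, TAXONOMY_RANKS)
  lower <- if (ri < length(TAXONOMY_RANKS))
    TAXONOMY_RANKS[seq(ri + 1, length(TAXONOMY_RANKS))] else character(0)
  lower <- intersect(lower, names(tx))
  labelled <- !is_unk(tx[[rank]])
  ids <- db$records$id[labelled]
  groups <- split(ids, tx[[rank]][labelled])
  identities <- numeric(0)
  for (g in groups) {
    if (length(g) < 2) next
    for (i in seq_len(length(g) - 1)) {
      for (j in seq(i + 1, length(g))) {
        ti <- tx[match(g[i], tx$id), lower, drop = FALSE]
        tj <- tx[match(g[j], tx$id), lower, drop = FALSE]
        shares_lower <- any(mapply(function(a, b)
          !is_unk(a) && !is_unk(b) && a == b, ti, tj))
        if (shares_lower) next
        identities <- c(identities,
                        identity_cpp(seqs[[g[i]]], seqs[[g[j]]])$identity_pct)
      }
    }
  }
  if (length(identities) == 0)
    warning("no qualifying sequence pairs at rank ", rank,
            "; empty distribution")
  structure(list(rank = rank, identities = identities,
                 n_pairs = length(identities),
                 median = if (length(identities)) median(identities) else NA_real_,
                 q25 = if (length(identities)) unname(quantile(identities, .25)) else NA_real_,
                 q75 = if (length(identities)) unname(quantile(identities, .75)) else NA_real_),
            class = "rank_identity_distribution")
}

#' @export
print.rank_identity_distribution <- function(x, ...) {
  cat(sprintf("<rank_identity_distribution> rank %s: %d pairs, median %.2f [%.2f, %.2f]\n",
              x$rank, x$n_pairs, x$median, x$q25, x$q75))
  invisible(x)
}

#' Check that a sub-region mirrors full-length identity structure
#'
#' Compares the medians of two intra-rank identity distributions — one on
#' full sequences, one on the extracted sub-region — and passes when their
#' absolute difference does not exceed the tolerance.
#'
#' @param full,region \code{rank_identity_distribution} objects for the
#'   same rank.
#' @param tolerance maximal allowed absolute median difference in
#'   percentage points (default 2).
#' @return list with \code{rank}, both medians, \code{difference} and
#'   logical \code{pass}.
#' @export
mirror_check <- function(full, region, tolerance = 2) {
  if (full$rank != region$rank)
    stop("distributions are for different ranks")
  if (full$n_pairs == 0 || region$n_pairs == 0)
    stop("cannot mirror-check an empty distribution")
  d <- abs(full$median - region$median)
  list(rank = full$rank, median_full = full$median,
       median_region = region$median, difference = d,
       tolerance = tolerance, pass = d <= tolerance)
}

#' Recommend clustering thresholds from rank identity distributions
#'
#' The threshold for each rank is the median of its intra-rank identity
#' distribution rounded to the nearest integer percent. Monotonicity
#' (species >= genus >= family) is enforced; a violation signals
#' mislabelled reference data and raises an error.
#'
#' @param species,genus,family \code{rank_identity_distribution} objects.
#' @return named numeric vector \code{c(species=, genus=, family=)}.
#' @export
recommend_thresholds <- function(species, genus, family) {
  dists <- list(species = species, genus = genus, family = family)
  for (r in names(dists)) {
    if (dists[[r]]$rank != r)
      stop("distribution passed as ", r, " is for rank ", dists[[r]]$rank)
    if (dists[[r]]$n_pairs == 0)
      stop("empty distribution for rank ", r)
  }
  th <- vapply(dists, function(d) round(d$median), 0)
  if (th[["species"]] < th[["genus"]] || th[["genus"]] < th[["family"]])
    stop("non-monotone rank medians (species ", th[["species"]],
         ", genus ", th[["genus"]], ", family ", th[["family"]],
         "): check reference labels")
  th
}

#' Quantify fragmentation of named taxa under greedy clustering
#'
#' Clusters the members of each named taxon at a rank with
#' \code{\link{greedy_cluster}} and reports the number of clusters
#' obtained. Counts above 1 quantify how much a purely similarity-based
#' clustering fragments curated taxa — and hence how much family-level
#' cluster counts overestimate the number of true families.
#'
#' @param db a \code{\link{reference_db}}.
#' @param rank \code{"family"}, \code{"genus"} or \code{"species"}.
#' @param threshold_pct identity threshold used for the clustering.
#' @return named integer vector: taxon name -> number of greedy clusters.
#' @export
taxon_fragmentation <- function(db, rank, threshold_pct) {
  rank <- match.arg(rank, c("family", "genus", "species"))
  tx <- db$taxonomy[match(db$records$id, db$taxonomy$id), ]
  labelled <- !is_unk(tx[[rank]])
  groups <- split(db$records$id[labelled], tx[[rank]][labelled])
  level <- if (rank == "species") "species" else rank
  vapply(groups, function(ids) {
    sub <- db$records[db$records$id %in% ids, , drop = FALSE]
    class(sub) <- c("seq_records", "data.frame")
    nrow(greedy_cluster(sub, threshold_pct, level = level))
  }, 0L)
}
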
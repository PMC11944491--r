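# Greedy centroid clustering and the tiered species/genus/family OTU
# construction with per-cluster occupancy classes.

CLUSTER_LEVELS <- c("species", "genus", "family")

#' Greedy centroid clustering at an identity threshold
#'
#' Records are processed in order of decreasing abundance (ties: decreasing
#' length, then increasing id) — the size-ordering convention of
#' UPARSE/VSEARCH-style tools. Each record joins the first existing
#' centroid whose identity to it is at least \code{threshold_pct};
#' otherwise it founds a new cluster with itself as centroid. The result
#' is deterministic and invariant to the input row order.
#'
#' @param records a \code{\link{seq_records}} object.
#' @param threshold_pct identity threshold in percent (membership is
#'   \code{>=}).
#' @param level cluster level label: \code{"species"}, \code{"genus"} or
#'   \code{"family"}.
#' @param match \code{"first"} (default, greedy convention) joins the
#'   first centroid meeting the threshold; \code{"best"} joins the
#'   highest-identity centroid meeting it.
#' @return a \code{data.frame} of class \code{otu_clusters}: one row per
#'   cluster with \code{centroid_id}, \code{sequence} (centroid sequence),
#'   list-columns \code{member_ids} and \code{samples}, \code{level} and
#'   \code{total_abundance}.
#' @export
greedy_cluster <- function(records, threshold_pct, level = "species",
                           match = c("first", "best")) {
  match <- match.arg(match)
  level <- match.arg(level, CLUSTER_LEVELS)
  if (nrow(records) == 0) {
    out <- data.frame(centroid_id = character(), sequence = character(),
                      level = character(), total_abundance = integer())
    out$member_ids <- list(); out$samples <- list()
    class(out) <- c("otu_clusters", "data.frame")
    return(out)
  }
  validate_seq_records(records)
  ord <- order(-records$abundance, -nchar(records$sequence), records$id)
  recs <- records[ord, , drop = FALSE]
  centroid_seq <- character(0)
  assign <- integer(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    k <- if (length(centroid_seq) == 0) 0L
         else if (match == "first")
           first_match_cpp(recs$sequence[i], centroid_seq, threshold_pct)
         else best_match_cpp(recs$sequence[i], centroid_seq, threshold_pct)
    if (k == 0L) {
      centroid_seq <- c(centroid_seq, recs$sequence[i])
      k <- length(centroid_seq)
    }
    assign[i] <- k
  }
  founders <- vapply(seq_along(centroid_seq), function(k)
    which(assign == k)[1], 0L)  # first member in processing order founded it
  members <- split(seq_len(nrow(recs)), assign)
  out <- data.frame(
    centroid_id = recs$id[founders],
    sequence = recs$sequence[founders],
    level = level,
    total_abundance = unname(vapply(members, function(ix)
      sum(recs$abundance[ix]), 0)),
    stringsAsFactors = FALSE)
  out$member_ids <- unname(lapply(members, function(ix) recs$id[ix]))
  out$samples <- unname(lapply(members, function(ix)
    sort(unique(unlist(recs$samples[ix])))))
  rownames(out) <- NULL
  class(out) <- c("otu_clusters", "data.frame")
  out
}

#' Nested species/genus/family clustering
#'
#' Species clusters (SOTUs) are built from the records at the species
#' threshold; genus clusters (GOTUs) by clustering the species centroids
#' (each weighted by its cluster's total abundance and carrying its
#' cluster's sample union) at the genus threshold; family clusters (FOTUs)
#' likewise from the genus centroids. Centroid propagation guarantees
#' strict nesting: every SOTU maps to exactly one GOTU and every GOTU to
#' exactly one FOTU.
#'
#' @param records a \code{\link{seq_records}} object.
#' @param thresholds named numeric vector \code{c(species=, genus=,
#'   family=)}; defaults 97/93/89.
#' @param match centroid matching rule, see \code{\link{greedy_cluster}}.
#' @return an object of class \code{tiered_clusters}: list with elements
#'   \code{species}, \code{genus}, \code{family} (each
#'   \code{otu_clusters}), the nesting maps \code{sotu_to_gotu} and
#'   \code{gotu_to_fotu} (named character vectors), and \code{thresholds}.
#' @export
tiered_cluster <- function(records,
                           thresholds = c(species = 97, genus = 93,
                                          family = 89),
                           match = "first") {
  stopifnot(all(c("species", "genus", "family") %in% names(thresholds)))
  sp <- greedy_cluster(records, thresholds[["species"]], "species", match)
  as_records <- function(cl) {
    r <- data.frame(id = cl$centroid_id, sequence = cl$sequence,
                    abundance = as.integer(cl$total_abundance),
                    source = "amplicon", stringsAsFactors = FALSE)
    r$samples <- cl$samples
    class(r) <- c("seq_records", "data.frame")
    r
  }
  gn <- greedy_cluster(as_records(sp), thresholds[["genus"]], "genus", match)
  fm <- greedy_cluster(as_records(gn), thresholds[["family"]], "family", match)
  member_map <- function(cl)
    setNames(rep(cl$centroid_id, lengths(cl$member_ids)),
             unlist(cl$member_ids))
  structure(list(species = sp, genus = gn, family = fm,
                 sotu_to_gotu = member_map(gn),
                 gotu_to_fotu = member_map(fm),
                 thresholds = thresholds),
            class = "tiered_clusters")
}

#' @export
print.tiered_clusters <- function(x, ...) {
  cat("<tiered_clusters>\n")
  cat(sprintf("  %d SOTUs (%.0f%%), %d GOTUs (%.0f%%), %d FOTUs (%.0f%%)\n",
              nrow(x$species), x$thresholds[["species"]],
              nrow(x$genus), x$thresholds[["genus"]],
              nrow(x$family), x$thresholds[["family"]]))
  invisible(x)
}

#' Map each record id to its cluster centroid at a level
#'
#' @param tiered a \code{tiered_clusters} object.
#' @param level \code{"species"}, \code{"genus"} or \code{"family"}.
#' @return named character vector record id -> centroid id at that level.
#' @export
cluster_membership <- function(tiered, level = "species") {
  level <- match.arg(level, CLUSTER_LEVELS)
  rec_to_sotu <- setNames(
    rep(tiered$species$centroid_id, lengths(tiered$species$member_ids)),
    unlist(tiered$species$member_ids))
  if (level == "species") return(rec_to_sotu)
  up <- tiered$sotu_to_gotu[rec_to_sotu]
  names(up) <- names(rec_to_sotu)
  if (level == "genus") return(up)
  up2 <- tiered$gotu_to_fotu[up]
  names(up2) <- names(rec_to_sotu)
  up2
}

#' Occupancy class of each species cluster
#'
#' An SOTU observed in exactly one distinct sample is a singleton; two,
#' a doubleton; three, a tripleton; four or more, a moreton.
#'
#' @param tiered a \code{tiered_clusters} object.
#' @return named character vector (by SOTU centroid id) with values
#'   \code{singleton}, \code{doubleton}, \code{tripleton}, \code{moreton}.
#' @export
occupancy_classes <- function(tiered) {
  n <- lengths(tiered$species$samples)
  cls <- ifelse(n >= 4, "moreton",
                c("singleton", "doubleton", "tripleton")[pmax(n, 1)])
  setNames(cls, tiered$species$centroid_id)
}

#' Tiered cluster counts with and without singletons
#'
#' A species cluster is removed when it is a singleton (one distinct
#' sample) and contains a single OTU record. Genus and family clusters
#' left empty by the removal are dropped as well.
#'
#' @param tiered a \code{tiered_clusters} object.
#' @return list with \code{with} and \code{without}: named vectors of
#'   FOTU/GOTU/SOTU counts, plus \code{removed_sotus}, the centroid ids of
#'   the removed species clusters.
#' @export
remove_singletons <- function(tiered) {
  occ <- occupancy_classes(tiered)
  single <- occ == "singleton" & lengths(tiered$species$member_ids) == 1
  removed <- tiered$species$centroid_id[single]
  kept_sotus <- setdiff(tiered$species$centroid_id, removed)
  kept_gotus <- unique(tiered$sotu_to_gotu[kept_sotus])
  kept_fotus <- unique(tiered$gotu_to_fotu[kept_gotus])
  counts <- function(f, g, s) c(fotus = f, gotus = g, sotus = s)
  list(with = counts(nrow(tiered$family), nrow(tiered$genus),
                     nrow(tiered$species)),
       without = counts(length(kept_fotus), length(kept_gotus),
                        length(kept_sotus)),
       removed_sotus = removed)
}
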
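# Diversity estimators: conservative lower bound, rarefaction with the
# per-sample discovery rate d_sotu, environment novelty scores, cluster
# environment assignment and per-taxon summaries.

#' Conservative lower bound on species-cluster diversity
#'
#' For each (sample, GOTU) pair, only the SOTU with the highest abundance
#' in that sample is counted (ties broken by the lexicographically
#' smallest SOTU id); the bound is the number of distinct SOTUs selected
#' over all pairs. Co-occurring SOTUs of one genus cluster in one sample
#' are treated as potential noise or sequencing artefacts, which makes the
#' resulting count a conservative estimate.
#'
#' @param tiered a \code{\link{tiered_cluster}} result.
#' @param provenance record-level provenance data.frame (\code{otu_id},
#'   \code{sample_id}, \code{count}); ids must match the clustered
#'   records.
#' @return list with \code{count} and \code{sotu_ids} (the kept SOTUs).
#' @export
conservative_lower_bound <- function(tiered, provenance) {
  rec_to_sotu <- cluster_membership(tiered, "species")
  prov <- provenance[provenance$otu_id %in% names(rec_to_sotu), , drop = FALSE]
  if (nrow(prov) == 0) return(list(count = 0L, sotu_ids = character(0)))
  sotu <- unname(rec_to_sotu[prov$otu_id])
  ab <- stats::aggregate(count ~ sotu + sample_id,
                         data = data.frame(sotu = sotu,
                                           sample_id = prov$sample_id,
                                           count = prov$count),
                         FUN = sum)
  ab$gotu <- unname(tiered$sotu_to_gotu[ab$sotu])
  keep <- unlist(lapply(split(ab, list(ab$sample_id, ab$gotu), drop = TRUE),
                        function(g) g$sotu[order(-g$count, g$sotu)[1]]))
  kept <- sort(unique(unname(keep)))
  list(count = length(kept), sotu_ids = kept)
}

#' Sample-to-SOTU incidence from a tiered clustering
#'
#' @param tiered a \code{\link{tiered_cluster}} result.
#' @return named list: sample id -> character vector of SOTU centroid ids
#'   observed in that sample.
#' @export
sotu_sample_incidence <- function(tiered) {
  long <- data.frame(
    sotu = rep(tiered$species$centroid_id, lengths(tiered$species$samples)),
    sample = unlist(tiered$species$samples), stringsAsFactors = FALSE)
  lapply(split(long$sotu, long$sample), unique)
}

#' Rarefaction of species-cluster discovery over samples
#'
#' Accumulates samples in \code{R} seeded random orders and records the
#' cumulative number of distinct SOTUs; the mean over permutations is the
#' rarefaction curve. \code{d_sotu} — the expected number of novel SOTUs
#' contributed by one additional sample — is estimated as the mean, over
#' permutations, of the increment contributed by the final sample.
#'
#' @param sotu_by_sample named list sample id -> SOTU ids (see
#'   \code{\link{sotu_sample_incidence}}); subset it to one environment's
#'   samples for per-environment curves.
#' @param R number of permutations (default 10).
#' @param seed integer seed driving the permutations (default 42).
#' @return object of class \code{rarefaction_result}: list with
#'   \code{n_samples}, \code{mean_curve} (length n, non-decreasing, its
#'   endpoint is permutation-invariant), \code{permutations}, \code{seed}
#'   and \code{d_sotu}.
#' @export
rarefaction <- function(sotu_by_sample, R = 10, seed = 42) {
  n <- length(sotu_by_sample)
  if (n == 0) stop("rarefaction needs at least one sample")
  set.seed(seed)
  curves <- matrix(0, nrow = R, ncol = n)
  for (r in seq_len(R)) {
    ord <- sample.int(n)
    seen <- character(0)
    for (k in seq_len(n)) {
      seen <- union(seen, sotu_by_sample[[ord[k]]])
      curves[r, k] <- length(seen)
    }
  }
  mean_curve <- colMeans(curves)
  d_sotu <- if (n == 1) mean(curves[, 1])
            else mean(curves[, n] - curves[, n - 1])
  structure(list(n_samples = n, mean_curve = mean_curve,
                 permutations = R, seed = seed, d_sotu = d_sotu),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat(sprintf("<rarefaction_result> %d samples, %d permutations: %g SOTUs total, d_sotu = %.3f\n",
              x$n_samples, x$permutations,
              x$mean_curve[x$n_samples], x$d_sotu))
  invisible(x)
}

#' Per-environment novelty scores
#'
#' For each environment, counts the distinct clusters at each level
#' (SOTU/GOTU/FOTU) observed in at least one of that environment's
#' samples, normalised by the environment's sample count. A cluster
#' observed in several environments counts toward each of them.
#' Environments with no samples are omitted.
#'
#' @param tiered a \code{\link{tiered_cluster}} result.
#' @param metadata sample metadata (see \code{\link{sample_metadata}});
#'   every clustered sample must be labelled.
#' @param ignore_samples sample ids to exclude from the scoring (e.g. the
#'   \code{"refdb"} pseudo-sample that appended reference records carry);
#'   any other unlabelled sample is an error.
#' @return data.frame with one row per environment: \code{environment},
#'   \code{n_samples}, raw cluster counts \code{n_sotus}/\code{n_gotus}/
#'   \code{n_fotus} and the normalised \code{sotu_score}/\code{gotu_score}/
#'   \code{fotu_score}. Nesting guarantees sotu_score >= gotu_score >=
#'   fotu_score within each row.
#' @export
novelty_scores <- function(tiered, metadata, ignore_samples = character(0)) {
  seen <- unique(unlist(tiered$species$samples))
  unlabelled <- setdiff(setdiff(seen, ignore_samples), metadata$sample_id)
  if (length(unlabelled) > 0)
    stop("samples without environment label: ",
         paste(utils::head(unlabelled, 3), collapse = ", "))
  rows <- lapply(intersect(ENVIRONMENTS, unique(metadata$environment)),
                 function(e) {
    env_samples <- metadata$sample_id[metadata$environment == e]
    if (length(env_samples) == 0) return(NULL)
    touches <- function(cl)
      sum(vapply(cl$samples, function(s) any(s %in% env_samples), TRUE))
    n_sotus <- touches(tiered$species)
    n_gotus <- touches(tiered$genus)
    n_fotus <- touches(tiered$family)
    data.frame(environment = e, n_samples = length(env_samples),
               n_sotus = n_sotus, n_gotus = n_gotus, n_fotus = n_fotus,
               sotu_score = n_sotus / length(env_samples),
               gotu_score = n_gotus / length(env_samples),
               fotu_score = n_fotus / length(env_samples),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Environment assignment of clusters
#'
#' Two assignments per cluster: \code{by_abundance} is the environment of
#' the sample contributing the single highest-abundance member occurrence
#' (ties: smallest sample id, then smallest member id); \code{by_majority}
#' is the most frequent environment over all member occurrences (ties
#' broken by alphabetical environment name).
#'
#' @param tiered a \code{\link{tiered_cluster}} result.
#' @param provenance record-level provenance data.frame.
#' @param metadata sample metadata.
#' @param level which cluster level to assign (default \code{"species"}).
#' @return data.frame with \code{cluster_id}, \code{by_abundance},
#'   \code{by_majority}.
#' @export
environment_assignment <- function(tiered, provenance, metadata,
                                   level = "species") {
  level <- match.arg(level, CLUSTER_LEVELS)
  membership <- cluster_membership(tiered, level)
  env_of <- setNames(metadata$environment, metadata$sample_id)
  prov <- provenance[provenance$otu_id %in% names(membership), , drop = FALSE]
  prov$cluster <- unname(membership[prov$otu_id])
  prov$environment <- unname(env_of[prov$sample_id])
  if (any(is.na(prov$environment)))
    stop("occurrence in unlabelled sample: ",
         prov$sample_id[is.na(prov$environment)][1])
  rows <- lapply(split(prov, prov$cluster), function(g) {
    top <- g[order(-g$count, g$sample_id, g$otu_id), ][1, ]
    freq <- table(g$environment)
    maj <- sort(names(freq)[freq == max(freq)])[1]
    data.frame(cluster_id = g$cluster[1], by_abundance = top$environment,
               by_majority = maj, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-taxon diversity summary
#'
#' For every named (non-UNK) taxon at each labelled rank, counts member
#' sequences and the distinct SOTU/GOTU/FOTU clusters they fall in, plus
#' the sequence-to-species rate \code{sotu_rate} = #SOTUs / #sequences —
#' a rate near 1 means almost every sequence founds its own molecular
#' species (high novelty), a small rate a tight, well-sampled taxon.
#'
#' @param tiered a \code{\link{tiered_cluster}} result.
#' @param taxonomy data.frame with \code{id} (record ids) and rank
#'   columns.
#' @param ranks which ranks to tabulate (default phylum..species).
#' @return data.frame with \code{rank}, \code{taxon}, \code{n_sequences},
#'   \code{n_sotus}, \code{n_gotus}, \code{n_fotus}, \code{sotu_rate}.
#' @export
taxon_summary <- function(tiered, taxonomy,
                          ranks = c("phylum", "class", "order", "family",
                                    "genus", "species")) {
  ranks <- intersect(ranks, names(taxonomy))
  maps <- lapply(setNames(CLUSTER_LEVELS, CLUSTER_LEVELS),
                 function(l) cluster_membership(tiered, l))
  ids <- intersect(taxonomy$id, names(maps$species))
  tx <- taxonomy[match(ids, taxonomy$id), , drop = FALSE]
  rows <- list()
  for (r in ranks) {
    labelled <- !is_unk(tx[[r]])
    for (taxon in sort(unique(tx[[r]][labelled]))) {
      members <- ids[labelled & tx[[r]] == taxon]
      rows[[length(rows) + 1]] <- data.frame(
        rank = r, taxon = taxon, n_sequences = length(members),
        n_sotus = length(unique(maps$species[members])),
        n_gotus = length(unique(maps$genus[members])),
        n_fotus = length(unique(maps$family[members])),
        sotu_rate = length(unique(maps$species[members])) / length(members),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
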
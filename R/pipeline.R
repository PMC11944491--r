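# End-to-end pipeline: trim -> filter -> replace -> append -> dereplicate
# -> tiered clustering -> estimators, with a per-stage count funnel.

#' Run the full analysis pipeline
#'
#' Executes the stages the funnel requires, each optional based on which
#' inputs are supplied: region trimming and the information filter (when
#' an aligned set and region are given), reference replacement and the
#' appending of unmatched references (when a reference database is
#' given), dereplication, tiered clustering, and the estimators
#' (conservative lower bound and rarefaction when provenance is given,
#' novelty scores when sample metadata is given, occupancy-stratified
#' match rates when a target collection is given). Reference replacement
#' operates after trimming, i.e. in region coordinate space: producing
#' new alignments for replaced sequences is outside this package's scope,
#' so the reference set supplied here must cover the same region as the
#' reads.
#'
#' Inputs may be in-memory objects or file paths (FASTA / aligned FASTA /
#' TSV), which are read with the package's readers.
#'
#' @param records \code{seq_records} or FASTA path (ignored when
#'   \code{aligned} is given).
#' @param aligned optional \code{aligned_seqs} or aligned-FASTA path.
#' @param region optional \code{\link{region_spec}} (required with
#'   \code{aligned}).
#' @param refdb optional \code{\link{reference_db}}.
#' @param provenance optional provenance data.frame or TSV path.
#' @param metadata optional sample metadata data.frame or TSV path.
#' @param target_db optional verification target \code{seq_records} or
#'   FASTA path.
#' @param thresholds clustering thresholds (default species 97, genus 93,
#'   family 89).
#' @param replace_threshold reference replacement threshold (default 98,
#'   strict).
#' @param rarefaction_permutations,seed rarefaction settings.
#' @param out_json optional path: write the report as JSON.
#' @return a \code{pipeline_report}: list with \code{stages} (per-stage
#'   record counts), \code{params}, \code{tiered}, \code{occupancy},
#'   and whichever estimator results were computed
#'   (\code{lower_bound}, \code{rarefaction}, \code{novelty},
#'   \code{match_table}, \code{replacement_log}).
#' @export
run_pipeline <- function(records = NULL, aligned = NULL, region = NULL,
                         refdb = NULL, provenance = NULL, metadata = NULL,
                         target_db = NULL,
                         thresholds = c(species = 97, genus = 93,
                                        family = 89),
                         replace_threshold = 98,
                         rarefaction_permutations = 10, seed = 42,
                         out_json = NULL) {
  if (is.character(aligned)) aligned <- read_aligned_fasta(aligned)
  if (is.character(records)) records <- read_fasta(records,
                                                   size_annotations = TRUE)
  if (is.character(provenance)) provenance <- read_provenance_table(provenance)
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  if (is.character(target_db)) target_db <- read_fasta(target_db)
  if (is.null(records) && is.null(aligned))
    stop("need either records or aligned input")

  stages <- list()
  note <- function(stage, n) stages[[length(stages) + 1]] <<-
    data.frame(stage = stage, n_records = n, stringsAsFactors = FALSE)

  if (!is.null(aligned)) {
    if (is.null(region)) stop("aligned input requires a region_spec")
    note("input", nrow(aligned))
    flt <- filter_by_information(aligned, region)
    note("information_filter", nrow(flt$kept))
    records <- extract_region(flt$kept, region)
    if (!is.null(provenance)) records <- attach_provenance(records, provenance)
    note("region_extraction", nrow(records))
  } else {
    note("input", nrow(records))
    if (!is.null(provenance)) records <- attach_provenance(records, provenance)
  }

  # cumulative map from original record ids to current representative ids,
  # composed across every merging stage so provenance can follow merges
  id_map <- setNames(records$id, records$id)
  compose <- function(id_map, stage_map) {
    extra <- setdiff(unname(id_map), names(stage_map))
    stage_map <- c(stage_map, setNames(extra, extra))
    setNames(unname(stage_map[unname(id_map)]), names(id_map))
  }

  replacement_log <- NULL
  if (!is.null(refdb)) {
    rep <- replace_by_reference(records, refdb, replace_threshold)
    id_map <- compose(id_map, attr(rep$records, "id_map"))
    records <- rep$records
    replacement_log <- rep$log
    note("reference_replacement", nrow(records))
    records <- append_unmatched_refs(records, refdb, replace_threshold)
    note("append_unmatched_refs", nrow(records))
  }

  records <- dereplicate(records)
  id_map <- compose(id_map, attr(records, "id_map"))
  note("dereplication", nrow(records))

  tiered <- tiered_cluster(records, thresholds)
  note("species_clusters", nrow(tiered$species))
  occupancy <- occupancy_classes(tiered)

  report <- list(
    params = list(thresholds = as.list(thresholds),
                  replace_threshold = replace_threshold,
                  rarefaction_permutations = rarefaction_permutations,
                  seed = seed),
    stages = do.call(rbind, stages),
    tiered = tiered,
    occupancy = occupancy,
    singleton_counts = remove_singletons(tiered),
    replacement_log = replacement_log)

  if (!is.null(provenance)) {
    keep <- provenance$otu_id %in% names(id_map)
    prov <- provenance[keep, , drop = FALSE]
    prov$otu_id <- unname(id_map[prov$otu_id])
    prov <- stats::aggregate(count ~ otu_id + sample_id, data = prov,
                             FUN = sum)
    report$lower_bound <- conservative_lower_bound(tiered, prov)
    # rarefy over real observed samples only (appended references carry a
    # "refdb" pseudo-sample that is not a survey sample)
    inc <- sotu_sample_incidence(tiered)
    inc <- inc[names(inc) %in% prov$sample_id]
    report$rarefaction <- rarefaction(inc, R = rarefaction_permutations,
                                      seed = seed)
    if (!is.null(metadata))
      report$environment_assignment <-
        environment_assignment(tiered, prov, metadata)
  }
  if (!is.null(metadata))
    report$novelty <- novelty_scores(tiered, metadata,
                                     ignore_samples = "refdb")
  if (!is.null(target_db)) {
    reps <- records[match(tiered$species$centroid_id, records$id), ,
                    drop = FALSE]
    class(reps) <- c("seq_records", "data.frame")
    report$match_table <- match_rates(reps, occupancy, target_db)
  }
  class(report) <- "pipeline_report"
  if (!is.null(out_json)) write_report_json(report_as_json(report), out_json)
  report
}

# flatten a pipeline report into JSON-friendly plain lists
report_as_json <- function(report) {
  out <- list(params = report$params,
              stages = report$stages,
              counts = list(
                sotus = nrow(report$tiered$species),
                gotus = nrow(report$tiered$genus),
                fotus = nrow(report$tiered$family)),
              singleton_counts = lapply(report$singleton_counts[c("with", "without")],
                                        as.list))
  if (!is.null(report$lower_bound))
    out$lower_bound <- report$lower_bound$count
  if (!is.null(report$rarefaction))
    out$rarefaction <- list(mean_curve = report$rarefaction$mean_curve,
                            d_sotu = report$rarefaction$d_sotu)
  if (!is.null(report$novelty)) out$novelty <- report$novelty
  if (!is.null(report$match_table)) {
    mt <- report$match_table
    attr(mt, "best_identity") <- NULL
    out$match_table <- as.data.frame(mt)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  stage funnel:\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("    %-22s %d\n", x$stages$stage[i], x$stages$n_records[i]))
  print(x$tiered)
  if (!is.null(x$lower_bound))
    cat("  conservative lower bound:", x$lower_bound$count, "SOTUs\n")
  if (!is.null(x$rarefaction))
    cat(sprintf("  d_sotu = %.3f\n", x$rarefaction$d_sotu))
  invisible(x)
}
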
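# Percent identity between sequences and the reference-replacement logic.
# The identity definition implemented here is the single contract every
# other module uses.

#' Semi-global percent identity between two sequences
#'
#' Aligns the two sequences with a semi-global (overlap) alignment under
#' scoring match = +1, mismatch = -1, gap = -1 per position, with terminal
#' gaps free. Identity is the number of matching columns divided by the
#' number of alignment columns, excluding the columns contributed by the
#' unaligned terminal overhangs. IUPAC ambiguity codes match only on exact
#' symbol equality; anything else is a mismatch. Tie-breaking is
#' deterministic and order-independent: among all maximal-score
#' alignments, the one with the most matches and then the fewest columns
#' is reported, so \code{identity(a, b) == identity(b, a)} holds even for
#' distant pairs with many co-optimal alignments.
#'
#' This dialect suits datasets whose amplicon regions are only partially
#' overlapping: a sequence fully contained in another at equal bases
#' scores 100.
#'
#' @param a,b non-empty, gap-free DNA strings.
#' @return an object of class \code{identity_result}: list with
#'   \code{identity_pct} (in [0, 100]), \code{matches},
#'   \code{scored_columns} and the alignment \code{score}. When the optimal
#'   alignment has no scored columns (no overlap), identity is 0.
#' @examples
#' pairwise_identity("ACGTACGTAC", "ACGTACGTAT")$identity_pct  # 90
#' pairwise_identity("ACGT", "TTACGTTT")$identity_pct          # 100
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (grepl("[-.]", a) || grepl("[-.]", b))
    stop("sequences must be gap-free")
  r <- identity_cpp(normalize_sequence(a), normalize_sequence(b))
  class(r) <- "identity_result"
  r
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("identity %.2f%% (%d/%d scored columns, score %d)\n",
              x$identity_pct, x$matches, x$scored_columns, x$score))
  invisible(x)
}

#' Best reference hit for a query sequence
#'
#' Returns the reference with maximal percent identity to the query; ties
#' are broken by the lexicographically smallest reference id.
#'
#' @param query a sequence string, or a one-row \code{seq_records} slice.
#' @param db a \code{\link{reference_db}} (or \code{seq_records} used as a
#'   plain sequence collection).
#' @return list with \code{ref_id} and \code{identity} (an
#'   \code{identity_result}), or \code{NULL} when the database is empty.
#' @export
best_hit <- function(query, db) {
  recs <- if (inherits(db, "reference_db")) db$records else db
  if (is.null(recs) || nrow(recs) == 0) return(NULL)
  qseq <- if (is.character(query)) query else query$sequence[1]
  ord <- order(recs$id)
  ids <- recs$id[ord]
  identities <- identity_to_all_cpp(normalize_sequence(qseq),
                                    recs$sequence[ord])
  k <- which.max(identities)  # first max in id order = smallest id on ties
  list(ref_id = ids[k], identity = pairwise_identity(qseq, recs$sequence[ord][k]))
}

#' Replace near-reference OTUs by their reference sequence
#'
#' Every record whose best reference hit exceeds \code{threshold_pct}
#' (strictly) has its sequence replaced by the reference sequence;
#' provenance (samples, abundance) and the \code{amplicon} source are
#' retained. Records replaced by the same reference then collapse via
#' \code{\link{dereplicate}}. Total abundance is conserved.
#'
#' @param records a \code{seq_records} object.
#' @param db a \code{\link{reference_db}}.
#' @param threshold_pct replacement threshold (default 98; replacement
#'   requires identity strictly greater).
#' @return list with \code{records} (the updated, merged set; attribute
#'   \code{"id_map"} maps input ids to output ids) and \code{log}
#'   (data.frame otu_id, ref_id, identity_pct of each replacement).
#' @export
replace_by_reference <- function(records, db, threshold_pct = 98) {
  stopifnot(inherits(db, "reference_db"))
  ord <- order(db$records$id)
  ref_ids <- db$records$id[ord]
  ref_seqs <- db$records$sequence[ord]
  log_rows <- list()
  for (i in seq_len(nrow(records))) {
    identities <- identity_to_all_cpp(records$sequence[i], ref_seqs)
    k <- which.max(identities)
    if (identities[k] > threshold_pct + 1e-9) {
      log_rows[[length(log_rows) + 1]] <-
        data.frame(otu_id = records$id[i], ref_id = ref_ids[k],
                   identity_pct = identities[k], stringsAsFactors = FALSE)
      records$sequence[i] <- ref_seqs[k]
    }
  }
  merged <- dereplicate(records)
  log <- if (length(log_rows)) do.call(rbind, log_rows)
         else data.frame(otu_id = character(), ref_id = character(),
                         identity_pct = numeric(), stringsAsFactors = FALSE)
  list(records = merged, log = log)
}

#' Append reference sequences not represented in the dataset
#'
#' Every reference for which no dataset record exceeds
#' \code{threshold_pct} identity is appended as a new record with source
#' \code{"appended_reference"}, abundance 1 and sample set
#' \code{"refdb"} — it represents biodiversity absent from the survey.
#'
#' @param records a \code{seq_records} object.
#' @param db a \code{\link{reference_db}}.
#' @param threshold_pct match threshold (default 98, strict).
#' @return the extended \code{seq_records}.
#' @export
append_unmatched_refs <- function(records, db, threshold_pct = 98) {
  stopifnot(inherits(db, "reference_db"))
  best <- if (nrow(records) == 0) rep(0, nrow(db$records))
          else best_identity_many_cpp(db$records$sequence, records$sequence)
  unmatched <- which(best <= threshold_pct + 1e-9)
  if (length(unmatched) == 0) return(records)
  add <- seq_records(id = db$records$id[unmatched],
                     sequence = db$records$sequence[unmatched],
                     samples = list("refdb"), abundance = 1L,
                     source = "appended_reference")
  out <- rbind(records, add)
  rownames(out) <- NULL
  class(out) <- c("seq_records", "data.frame")
  validate_seq_records(out)
  out
}

#' Assign taxonomy to a query by its best reference hit
#'
#' Copies the best hit's taxonomy truncated according to which identity
#' threshold the hit meets (boundaries are \code{>=}): at or above the
#' species threshold the full label is kept; at or above the genus
#' threshold, genus depth (species unknown); at or above the family
#' threshold, family depth; below that, every rank under domain is
#' unknown.
#'
#' @param query sequence string or one-row \code{seq_records} slice.
#' @param db a \code{\link{reference_db}}.
#' @param thresholds named numeric vector with elements \code{species},
#'   \code{genus}, \code{family} (default 97/93/89).
#' @return one-row data.frame with the seven rank columns plus
#'   \code{ref_id} and \code{identity_pct}.
#' @export
assign_taxonomy <- function(query, db,
                            thresholds = c(species = 97, genus = 93,
                                           family = 89)) {
  hit <- best_hit(query, db)
  if (is.null(hit)) stop("reference database is empty")
  tx <- db$taxonomy[db$taxonomy$id == hit$ref_id, TAXONOMY_RANKS]
  id <- hit$identity$identity_pct
  depth <- if (id >= thresholds[["species"]] - 1e-9) "species"
           else if (id >= thresholds[["genus"]] - 1e-9) "genus"
           else if (id >= thresholds[["family"]] - 1e-9) "family"
           else "domain"
  keep <- seq_len(match(depth, TAXONOMY_RANKS))
  for (k in setdiff(seq_along(TAXONOMY_RANKS), keep))
    tx[[TAXONOMY_RANKS[k]]] <- unk_label(TAXONOMY_RANKS[k])
  tx$ref_id <- hit$ref_id
  tx$identity_pct <- id
  rownames(tx) <- NULL
  tx
}
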
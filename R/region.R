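# Region extraction and the information filter: from aligned OTUs to the
# analysis-ready, dereplicated sub-region set.

#' Define an alignment region and its information requirement
#'
#' Coordinates are 1-based inclusive alignment columns. The defaults are
#' the common V4/V5 region in reference-alignment coordinates
#' (columns 10300 to 25300) and a minimum of 244 informative (non-gap)
#' bases, the number of Escherichia coli 16S rRNA bases falling inside
#' that region.
#'
#' @param start_col first alignment column (1-based, inclusive).
#' @param end_col last alignment column (1-based, inclusive).
#' @param min_informative_bases minimum number of non-gap characters a
#'   record must carry inside the region to be kept (boundary is `>=`).
#' @return an object of class \code{region_spec}.
#' @export
region_spec <- function(start_col = 10300L, end_col = 25300L,
                        min_informative_bases = 244L) {
  start_col <- as.integer(start_col); end_col <- as.integer(end_col)
  min_informative_bases <- as.integer(min_informative_bases)
  if (start_col < 1 || end_col < start_col)
    stop("need 1 <= start_col <= end_col")
  if (min_informative_bases < 1) stop("min_informative_bases must be >= 1")
  structure(list(start_col = start_col, end_col = end_col,
                 min_informative_bases = min_informative_bases),
            class = "region_spec")
}

check_region_bounds <- function(aligned, spec) {
  alen <- alignment_length(aligned)
  if (spec$end_col > alen)
    stop("region ", spec$start_col, ":", spec$end_col,
         " outside alignment of length ", alen)
}

#' Extract an alignment region and collapse its gaps
#'
#' Cuts the specified columns out of each aligned record and removes all
#' gap characters, yielding plain sequence records. Optional provenance
#' columns (\code{abundance}, \code{samples}, \code{source}) on the aligned
#' set are carried through unchanged; otherwise abundance 1 and a
#' self-referential sample set are used.
#'
#' @param aligned an \code{aligned_seqs} object.
#' @param spec a \code{\link{region_spec}}.
#' @return a \code{\link{seq_records}} object (records whose region is all
#'   gaps are dropped, since a sequence record cannot be empty; apply
#'   \code{\link{filter_by_information}} first to audit them).
#' @export
extract_region <- function(aligned, spec) {
  check_region_bounds(aligned, spec)
  sub <- substr(aligned$aligned, spec$start_col, spec$end_col)
  seqs <- gsub("[-.]", "", sub)
  keep <- nzchar(seqs)
  ab <- if ("abundance" %in% names(aligned)) aligned$abundance else 1L
  smp <- if ("samples" %in% names(aligned)) aligned$samples
         else as.list(aligned$id)
  src <- if ("source" %in% names(aligned)) aligned$source else "amplicon"
  seq_records(id = aligned$id[keep], sequence = seqs[keep],
              samples = if (is.list(smp)) smp[keep] else smp,
              abundance = if (length(ab) > 1) ab[keep] else ab,
              source = if (length(src) > 1) src[keep] else src)
}

#' Count informative (non-gap) characters inside a region
#'
#' Ambiguity codes count as informative: the filter measures information
#' quantity, not quality.
#'
#' @param aligned an \code{aligned_seqs} object.
#' @param spec a \code{\link{region_spec}}.
#' @return integer vector, one count per record.
#' @export
count_informative <- function(aligned, spec) {
  check_region_bounds(aligned, spec)
  sub <- substr(aligned$aligned, spec$start_col, spec$end_col)
  nchar(gsub("[-.]", "", sub))
}

#' Partition aligned records by the minimum-information rule
#'
#' A record is kept iff it has at least \code{min_informative_bases}
#' non-gap characters inside the region (records with exactly the minimum
#' pass). Both parts are returned for audit logging.
#'
#' @param aligned an \code{aligned_seqs} object.
#' @param spec a \code{\link{region_spec}}.
#' @return list with elements \code{kept} and \code{discarded}, both
#'   \code{aligned_seqs} subsets of the input.
#' @export
filter_by_information <- function(aligned, spec) {
  n <- count_informative(aligned, spec)
  keep <- n >= spec$min_informative_bases
  split_aligned <- function(idx) {
    y <- aligned[idx, , drop = FALSE]
    rownames(y) <- NULL
    attr(y, "alignment_length") <- alignment_length(aligned)
    class(y) <- class(aligned)
    y
  }
  list(kept = split_aligned(keep), discarded = split_aligned(!keep))
}

#' Dereplicate identical sequences
#'
#' Exact full-length string equality defines the groups. Each group
#' collapses to one record carrying the summed abundance and the union of
#' sample ids; the representative id is the id of the highest-abundance
#' input record (ties broken by the lexicographically smallest id). The
#' mapping from input ids to representative ids is attached as attribute
#' \code{"id_map"}.
#'
#' @param records a \code{\link{seq_records}} object (gap-free).
#' @return a dereplicated \code{seq_records} object, ordered by decreasing
#'   abundance then id.
#' @export
dereplicate <- function(records) {
  validate_seq_records(records)
  groups <- split(seq_len(nrow(records)), records$sequence)
  out <- lapply(groups, function(idx) {
    g <- records[idx, , drop = FALSE]
    rep_i <- order(-g$abundance, g$id)[1]
    list(id = g$id[rep_i], sequence = g$sequence[1],
         abundance = sum(g$abundance),
         samples = sort(unique(unlist(g$samples))),
         source = g$source[rep_i], members = g$id)
  })
  res <- seq_records(id = vapply(out, `[[`, "", "id"),
                     sequence = vapply(out, `[[`, "", "sequence"),
                     samples = lapply(out, `[[`, "samples"),
                     abundance = vapply(out, function(o) o$abundance, 0),
                     source = vapply(out, `[[`, "", "source"))
  ord <- order(-res$abundance, res$id)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("seq_records", "data.frame")
  reps <- vapply(out, `[[`, "", "id")
  members <- lapply(out, `[[`, "members")
  id_map <- setNames(rep(unname(reps), lengths(members)),
                     unlist(members, use.names = FALSE))
  attr(res, "id_map") <- id_map
  res
}
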
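# File formats: FASTA (plain and aligned), TSV provenance and sample
# metadata, JSON reports. FASTA parsing is delegated to Biostrings; the
# ";size=N" abundance dialect (USEARCH/VSEARCH convention) is handled here.

#' Read a FASTA file into sequence records
#'
#' Lower-case bases are upper-cased and RNA \code{U} is mapped to \code{T}
#' at read time. With \code{size_annotations = TRUE}, headers of the form
#' \code{id;size=N} set the record abundance to \code{N}; otherwise every
#' record gets abundance 1. Each record's sample set is initialised to its
#' own id; use \code{\link{attach_provenance}} to overlay a provenance
#' table.
#'
#' @param path path to a FASTA file.
#' @param size_annotations logical; parse \code{;size=N} annotations.
#' @return a \code{\link{seq_records}} object.
#' @export
read_fasta <- function(path, size_annotations = FALSE) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in ", path)
  headers <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (any(!nzchar(seqs)))
    stop("empty sequence for record ", headers[!nzchar(seqs)][1])
  abundance <- rep(1L, length(seqs))
  ids <- headers
  if (size_annotations) {
    has_size <- grepl(";size=", headers, fixed = TRUE)
    ok <- grepl("^(.+);size=([0-9]+);?$", headers)
    if (any(has_size & !ok))
      stop("malformed size annotation in header: ", headers[has_size & !ok][1])
    ids[ok] <- sub("^(.+);size=([0-9]+);?$", "\\1", headers[ok])
    abundance[ok] <- as.integer(sub("^(.+);size=([0-9]+);?$", "\\2",
                                    headers[ok]))
  }
  seq_records(id = ids, sequence = seqs, samples = as.list(ids),
              abundance = abundance, source = "amplicon")
}

#' Write sequence records to FASTA
#'
#' @param records a \code{seq_records} object.
#' @param path output path.
#' @param size_annotations logical; write \code{;size=N} abundance
#'   annotations (default TRUE), so that
#'   \code{read_fasta(write_fasta(x), size_annotations = TRUE)} round-trips
#'   sequences and abundances exactly.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, size_annotations = TRUE) {
  validate_seq_records(records)
  headers <- if (size_annotations)
    sprintf("%s;size=%d", records$id, records$abundance) else records$id
  set <- Biostrings::BStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Both \code{-} and \code{.} are accepted as gap characters and preserved
#' verbatim. All records must share one alignment length.
#'
#' @param path path to an aligned FASTA file.
#' @return a \code{data.frame} of class \code{aligned_seqs} with columns
#'   \code{id} and \code{aligned}, and attribute \code{alignment_length}.
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  aligned_seqs(ids, seqs)
}

#' Construct an aligned sequence set
#'
#' @param id character vector of record ids.
#' @param aligned character vector of aligned sequences (gaps \code{-} or
#'   \code{.}), all of equal length.
#' @return an \code{aligned_seqs} data.frame.
#' @export
aligned_seqs <- function(id, aligned) {
  id <- unname(as.character(id))
  aligned <- unname(as.character(aligned))
  widths <- nchar(aligned)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1]
    stop("ragged alignment: record ", id[bad], " has length ", widths[bad],
         ", expected ", widths[1])
  }
  x <- data.frame(id = as.character(id), aligned = normalize_sequence(aligned),
                  stringsAsFactors = FALSE)
  attr(x, "alignment_length") <- widths[1]
  class(x) <- c("aligned_seqs", "data.frame")
  x
}

#' Alignment length of an aligned sequence set
#' @param x an \code{aligned_seqs} object.
#' @return integer alignment length.
#' @export
alignment_length <- function(x) attr(x, "alignment_length")

#' Read a per-OTU provenance table
#'
#' A TSV with header \code{otu_id}, \code{sample_id}, \code{count}.
#' Duplicate (otu, sample) rows are summed; the total count is conserved.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns \code{otu_id}, \code{sample_id},
#'   \code{count} (positive integers, one row per pair).
#' @export
read_provenance_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("otu_id", "sample_id", "count")
  if (!all(need %in% names(x)))
    stop("provenance table must have columns otu_id, sample_id, count")
  if (any(is.na(x$count)) || any(x$count <= 0))
    stop("provenance counts must be positive integers (offending otu: ",
         x$otu_id[which(is.na(x$count) | x$count <= 0)[1]], ")")
  agg <- stats::aggregate(count ~ otu_id + sample_id, data = x, FUN = sum)
  agg <- agg[order(agg$otu_id, agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg$count <- as.integer(agg$count)
  agg
}

#' Write a provenance table
#' @param provenance data.frame with otu_id, sample_id, count.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_provenance_table <- function(provenance, path) {
  write.table(provenance, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample to environment mapping)
#'
#' A TSV with header \code{sample_id}, \code{environment}. The environment
#' vocabulary is the closed set host, plant, soil, freshwater,
#' saline_water, other; unknown labels are mapped to \code{"other"} with a
#' warning.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns \code{sample_id}, \code{environment}.
#' @export
read_sample_metadata <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "environment") %in% names(x)))
    stop("sample metadata must have columns sample_id, environment")
  sample_metadata(x$sample_id, x$environment)
}

#' Construct sample metadata
#' @param sample_id character vector of sample ids (unique).
#' @param environment character vector of environment labels.
#' @return data.frame with columns \code{sample_id}, \code{environment}.
#' @export
sample_metadata <- function(sample_id, environment) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample id: ", sample_id[duplicated(sample_id)][1])
  unknown <- !(environment %in% ENVIRONMENTS)
  if (any(unknown)) {
    warning("unknown environment label(s) mapped to 'other': ",
            paste(unique(environment[unknown]), collapse = ", "))
    environment[unknown] <- "other"
  }
  data.frame(sample_id = as.character(sample_id),
             environment = environment, stringsAsFactors = FALSE)
}

#' Write a computed report as JSON
#' @param x a report object (list or data.frame).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
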
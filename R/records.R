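# Core containers: sequence records with provenance, aligned sequence sets,
# and taxonomically labelled reference databases.

IUPAC_CHARS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                 "V", "H", "D", "B", "N")

normalize_sequence <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Build a set of sequence records
#'
#' The atom of the pipeline: one OTU (or reference) sequence together with
#' its provenance — the set of samples it was observed in and its total
#' abundance. Sequences are upper-cased and RNA \code{U} is mapped to
#' \code{T} so that all downstream identity computations see one alphabet.
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of gap-free DNA sequences
#'   (IUPAC ambiguity codes allowed).
#' @param samples list of character vectors (one per record) of sample ids;
#'   a single character vector is recycled element-wise.
#' @param abundance integer vector of total counts (>= 1).
#' @param source one of \code{"amplicon"}, \code{"reference"},
#'   \code{"appended_reference"} per record.
#' @return a \code{data.frame} of class \code{seq_records} with columns
#'   \code{id}, \code{sequence}, \code{abundance}, \code{source} and a
#'   list-column \code{samples}.
#' @export
seq_records <- function(id, sequence, samples, abundance = 1L,
                        source = "amplicon") {
  n <- length(id)
  if (length(sequence) != n)
    stop("id and sequence must have equal length")
  if (!is.list(samples)) samples <- as.list(samples)
  samples <- rep_len(samples, n)
  abundance <- rep_len(as.integer(abundance), n)
  source <- rep_len(source, n)
  sequence <- normalize_sequence(sequence)
  x <- data.frame(id = as.character(id), sequence = sequence,
                  abundance = abundance, source = source,
                  stringsAsFactors = FALSE)
  x$samples <- lapply(samples, function(s) sort(unique(as.character(s))))
  class(x) <- c("seq_records", "data.frame")
  validate_seq_records(x)
  x
}

validate_seq_records <- function(x) {
  stopifnot(is.data.frame(x))
  if (anyDuplicated(x$id))
    stop("duplicate record ids: ", x$id[duplicated(x$id)][1])
  if (any(!nzchar(x$sequence)))
    stop("empty sequence in record ", x$id[!nzchar(x$sequence)][1])
  bad <- grepl("[-.]", x$sequence)
  if (any(bad))
    stop("gap characters in record ", x$id[bad][1],
         " (gaps only exist in aligned records)")
  chars <- unique(strsplit(paste(x$sequence, collapse = ""), "")[[1]])
  if (length(setdiff(chars, IUPAC_CHARS)) > 0)
    stop("non-IUPAC characters in sequences: ",
         paste(setdiff(chars, IUPAC_CHARS), collapse = ", "))
  if (any(x$abundance < 1))
    stop("abundance must be >= 1 (record ", x$id[x$abundance < 1][1], ")")
  if (any(lengths(x$samples) == 0))
    stop("record ", x$id[lengths(x$samples) == 0][1], " has no samples")
  invisible(x)
}

#' @export
print.seq_records <- function(x, ...) {
  cat("<seq_records> ", nrow(x), " records, total abundance ",
      sum(x$abundance), "\n", sep = "")
  cat("  sources: ", paste(names(table(x$source)), table(x$source),
                           sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Attach per-sample provenance to records
#'
#' Replaces each record's sample set and total abundance by the values
#' implied by a long provenance table (as read by
#' \code{\link{read_provenance_table}}). Records absent from the table are
#' left unchanged.
#'
#' @param records a \code{seq_records} object.
#' @param provenance data.frame with columns \code{otu_id},
#'   \code{sample_id}, \code{count}.
#' @return the updated \code{seq_records}.
#' @export
attach_provenance <- function(records, provenance) {
  sp <- split(provenance, provenance$otu_id)
  idx <- match(records$id, names(sp))
  for (i in which(!is.na(idx))) {
    rows <- sp[[idx[i]]]
    records$samples[[i]] <- sort(unique(rows$sample_id))
    records$abundance[i] <- as.integer(sum(rows$count))
  }
  records
}

#' Taxonomically labelled reference database
#'
#' Holds gap-free, expert-labelled reference sequences used for
#' reference replacement, threshold calibration and taxonomy assignment.
#'
#' @param records a \code{seq_records} object (source is forced to
#'   \code{"reference"}).
#' @param taxonomy data.frame with column \code{id} plus the seven rank
#'   columns domain, phylum, class, order, family, genus, species. Unknown
#'   ranks use \code{\link{unk_label}} placeholders.
#' @return an object of class \code{reference_db}.
#' @export
reference_db <- function(records, taxonomy) {
  stopifnot(is.data.frame(taxonomy), "id" %in% names(taxonomy))
  missing_rank <- setdiff(TAXONOMY_RANKS, names(taxonomy))
  if (length(missing_rank) > 0)
    stop("taxonomy is missing rank columns: ",
         paste(missing_rank, collapse = ", "))
  absent <- setdiff(records$id, taxonomy$id)
  if (length(absent) > 0)
    stop("no taxonomy entry for reference record: ", absent[1])
  # enforce: if a rank is unknown, all lower ranks are unknown
  tx <- taxonomy[TAXONOMY_RANKS]
  for (k in seq_len(length(TAXONOMY_RANKS) - 1)) {
    hole <- is_unk(tx[[k]]) & !is_unk(tx[[k + 1]])
    if (any(hole))
      stop("taxonomy for ", taxonomy$id[hole][1], " has a labelled ",
           TAXONOMY_RANKS[k + 1], " under an unknown ", TAXONOMY_RANKS[k])
  }
  records$source <- "reference"
  validate_seq_records(records)
  structure(list(records = records,
                 taxonomy = taxonomy[c("id", TAXONOMY_RANKS)]),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("<reference_db> ", nrow(x$records), " labelled reference sequences\n",
      sep = "")
  for (r in c("family", "genus", "species")) {
    lab <- x$taxonomy[[r]]
    cat("  ", r, ": ", length(unique(lab[!is_unk(lab)])), " named taxa\n",
        sep = "")
  }
  invisible(x)
}
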
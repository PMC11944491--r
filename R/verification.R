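# Occupancy-stratified verification of species-cluster representatives
# against a second (metagenome-derived) sequence collection.

OCCUPANCY_CLASSES <- c("singleton", "doubleton", "tripleton", "moreton")

#' Truncating percentage formatter
#'
#' Formats matched/total as a percentage using truncation (floor), not
#' rounding: one decimal place when the value is below 1\%, otherwise an
#' integer percent (so 61.94\% prints as \code{"61\%"} and 0.749\% as
#' \code{"0.7\%"}). Naive rounding does not reproduce this convention.
#'
#' @param matched,total non-negative counts, \code{matched <= total},
#'   \code{total > 0}; vectorised.
#' @return character vector of formatted percentages.
#' @export
format_percent <- function(matched, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(matched < 0 | matched > total)) stop("need 0 <= matched <= total")
  v <- 100 * matched / total
  ifelse(matched == 0, "0%",
         ifelse(v < 1,
                sprintf("%.1f%%", floor(v * 10 + 1e-9) / 10),
                sprintf("%d%%", as.integer(floor(v + 1e-9)))))
}

#' Occupancy-stratified match rates against a target collection
#'
#' Computes, once per representative, the best-hit identity against the
#' target collection, then counts representatives matched at each cutoff
#' (identity \code{>=} cutoff), aggregated by occupancy class. Because a
#' single best identity is thresholded, matched counts are non-decreasing
#' as the cutoff decreases, by construction.
#'
#' @param sotu_reps a \code{\link{seq_records}} object of cluster
#'   representatives.
#' @param occupancy named character vector (by representative id) with
#'   values singleton/doubleton/tripleton/moreton, e.g. from
#'   \code{\link{occupancy_classes}}.
#' @param target_db a \code{seq_records}, \code{reference_db} or plain
#'   character vector of target sequences.
#' @param cutoffs identity cutoffs in percent (default 99, 97, 93, 89).
#' @return a \code{data.frame} of class \code{match_table}: one row per
#'   occupancy class plus a Total row; columns \code{class}, \code{total},
#'   then per cutoff \code{matched_<c>} (count) and \code{pct_<c>}
#'   (formatted percentage). Attribute \code{"best_identity"} carries the
#'   per-representative best identities.
#' @export
match_rates <- function(sotu_reps, occupancy, target_db,
                        cutoffs = c(99, 97, 93, 89)) {
  targets <- if (inherits(target_db, "reference_db")) target_db$records$sequence
             else if (is.data.frame(target_db)) target_db$sequence
             else as.character(target_db)
  missing_occ <- setdiff(sotu_reps$id, names(occupancy))
  if (length(missing_occ) > 0)
    stop("no occupancy class for representative: ", missing_occ[1])
  occ <- factor(unname(occupancy[sotu_reps$id]), levels = OCCUPANCY_CLASSES)
  if (anyNA(occ)) stop("invalid occupancy class value")
  if (length(targets) == 0) {
    warning("empty target collection: all matched counts are zero")
    best <- rep(0, nrow(sotu_reps))
  } else {
    best <- best_identity_many_cpp(sotu_reps$sequence, targets)
  }
  names(best) <- sotu_reps$id
  rows <- lapply(OCCUPANCY_CLASSES, function(cl) {
    sel <- best[occ == cl]
    row <- data.frame(class = cl, total = length(sel),
                      stringsAsFactors = FALSE)
    for (c in cutoffs)
      row[[paste0("matched_", c)]] <- sum(sel >= c - 1e-9)
    row
  })
  tab <- do.call(rbind, rows)
  total_row <- data.frame(class = "Total", total = sum(tab$total),
                          stringsAsFactors = FALSE)
  for (c in cutoffs)
    total_row[[paste0("matched_", c)]] <- sum(tab[[paste0("matched_", c)]])
  tab <- rbind(tab, total_row)
  for (c in cutoffs)
    tab[[paste0("pct_", c)]] <-
      ifelse(tab$total > 0,
             format_percent(pmin(tab[[paste0("matched_", c)]], tab$total),
                            pmax(tab$total, 1)),
             NA_character_)
  rownames(tab) <- NULL
  attr(tab, "cutoffs") <- cutoffs
  attr(tab, "best_identity") <- best
  class(tab) <- c("match_table", "data.frame")
  tab
}

#' Build a match table directly from matched counts
#'
#' Reconstructs the verification table (Total row and formatted
#' percentages) from per-class totals and matched counts — useful for
#' checking the internal arithmetic of a published table.
#'
#' @param totals named integer vector of per-class representative counts
#'   (names singleton/doubleton/tripleton/moreton).
#' @param matched matrix with one row per occupancy class (same order as
#'   \code{totals}) and one column per cutoff.
#' @param cutoffs identity cutoffs matching the matrix columns.
#' @return a \code{match_table} data.frame as in \code{\link{match_rates}}.
#' @export
match_table_from_counts <- function(totals, matched,
                                    cutoffs = c(99, 97, 93, 89)) {
  stopifnot(length(totals) == nrow(matched), ncol(matched) == length(cutoffs))
  tab <- data.frame(class = names(totals), total = unname(totals),
                    stringsAsFactors = FALSE)
  for (k in seq_along(cutoffs))
    tab[[paste0("matched_", cutoffs[k])]] <- matched[, k]
  total_row <- data.frame(class = "Total", total = sum(totals),
                          stringsAsFactors = FALSE)
  for (k in seq_along(cutoffs))
    total_row[[paste0("matched_", cutoffs[k])]] <- sum(matched[, k])
  tab <- rbind(tab, total_row)
  for (c in cutoffs)
    tab[[paste0("pct_", c)]] <- format_percent(tab[[paste0("matched_", c)]],
                                               tab$total)
  rownames(tab) <- NULL
  attr(tab, "cutoffs") <- cutoffs
  class(tab) <- c("match_table", "data.frame")
  tab
}

#' @export
print.match_table <- function(x, ...) {
  cutoffs <- attr(x, "cutoffs")
  cat("<match_table> cutoffs:", paste0(cutoffs, "%", collapse = " "), "\n")
  show <- data.frame(class = x$class, total = x$total)
  for (c in cutoffs)
    show[[paste0(c, "%")]] <- sprintf("%d (%s)", x[[paste0("matched_", c)]],
                                      x[[paste0("pct_", c)]])
  print(show, row.names = FALSE)
  invisible(x)
}
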
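evidence_cols <- c("sample_id", "read_id", "kind",
                   "chromA", "posA", "strandA", "spanA",
                   "chromB", "posB", "strandB", "spanB",
                   "donor_pos", "acceptor_pos", "overhangA", "overhangB")

evidence_col_types <- function() {
  readr::cols(
    sample_id = readr::col_character(),
    read_id = readr::col_character(),
    kind = readr::col_character(),
    chromA = readr::col_character(),
    posA = readr::col_integer(),
    strandA = readr::col_character(),
    spanA = readr::col_integer(),
    chromB = readr::col_character(),
    posB = readr::col_integer(),
    strandB = readr::col_character(),
    spanB = readr::col_integer(),
    donor_pos = readr::col_integer(),
    acceptor_pos = readr::col_integer(),
    overhangA = readr::col_integer(),
    overhangB = readr::col_integer()
  )
}

#' Read per-sample chimeric evidence
#'
#' Parses the package's chimeric-evidence TSV dialect, which models the
#' chimeric output of a spliced aligner as two read-level evidence classes:
#' `pair` (a sequenced fragment whose ends map to two loci) and `split` (a
#' single read spanning the fusion junction, with the junction coordinate
#' on each side and the aligned overhang length on each side). All
#' positions are 1-based; strands are the genome strand of each aligned
#' segment in the orientation the fragment was read.
#'
#' Records violating structural invariants (split records missing junction
#' fields or with an overhang < 1 nt, pair records carrying junction
#' fields, or both loci at the identical position and strand) are dropped
#' and counted; the count is returned as attribute `n_rejected` so that
#' `n_input == n_emitted + n_rejected` always holds. An unknown `kind`
#' token is a parse error, not a rejection.
#'
#' @param path Evidence TSV path.
#' @param sample_id Optional sample id; when given, overrides the file's
#'   `sample_id` column (and errors if the file disagrees on a non-missing
#'   value is not required — the column may be absent-equivalent).
#' @param quiet Suppress the rejected-record message.
#' @return A tibble of evidence records with attribute `n_rejected`.
#' @examples
#' p <- tempfile(); write_evidence(tibble::tibble(
#'   sample_id = "s1", read_id = "r1", kind = "pair",
#'   chromA = "chr1", posA = 100L, strandA = "+", spanA = 50L,
#'   chromB = "chr1", posB = 5000L, strandB = "+", spanB = 50L,
#'   donor_pos = NA_integer_, acceptor_pos = NA_integer_,
#'   overhangA = NA_integer_, overhangB = NA_integer_), p)
#' nrow(read_evidence(p))
#' @export
read_evidence <- function(path, sample_id = NULL, quiet = FALSE) {
  ev <- readr::read_tsv(path, col_types = evidence_col_types())
  if (nrow(ev) == 0L) {
    ev <- as_tibble(setNames(
      lapply(evidence_cols, function(x) ev[[x]] %||% character(0)),
      evidence_cols))
    attr(ev, "n_rejected") <- 0L
    return(ev)
  }
  missing_cols <- setdiff(evidence_cols, names(ev))
  if (length(missing_cols)) {
    abort(paste0("evidence file missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "kinfuse_parse_error")
  }
  ev <- ev[, evidence_cols]
  if (!is.null(sample_id)) ev$sample_id <- sample_id

  bad_kind <- !ev$kind %in% c("pair", "split")
  if (any(bad_kind)) {
    abort(sprintf("unknown evidence kind token '%s' in %s",
                  ev$kind[which(bad_kind)[1]], path),
          class = "kinfuse_parse_error")
  }

  is_split <- ev$kind == "split"
  junction_fields <- cbind(ev$donor_pos, ev$acceptor_pos,
                           ev$overhangA, ev$overhangB)
  has_any_junction <- rowSums(!is.na(junction_fields)) > 0L
  has_all_junction <- rowSums(!is.na(junction_fields)) == 4L

  reject <- logical(nrow(ev))
  # split records must carry a complete junction with both overhangs >= 1
  reject[is_split & !has_all_junction] <- TRUE
  reject[is_split & has_all_junction &
           (ev$overhangA < 1L | ev$overhangB < 1L)] <- TRUE
  # pair records carry no junction
  reject[!is_split & has_any_junction] <- TRUE
  # the two loci must be distinguishable
  same_locus <- ev$chromA == ev$chromB & ev$posA == ev$posB &
    ev$strandA == ev$strandB
  reject[same_locus] <- TRUE

  n_rejected <- sum(reject)
  if (n_rejected > 0L && !quiet) {
    inform(sprintf("read_evidence: dropped %d record(s) failing structural invariants",
                   n_rejected))
  }
  out <- ev[!reject, , drop = FALSE]
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write chimeric evidence in the package dialect
#'
#' @param evidence Evidence tibble (see [read_evidence()] for columns).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  stopifnot(all(evidence_cols %in% names(evidence)))
  readr::write_tsv(evidence[, evidence_cols], path)
  invisible(path)
}
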
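#' Flag fusions detected at improbable frequencies within a cohort
#'
#' Two cohort-level false-positive patterns are flagged (never silently
#' removed, mirroring a flag-then-review flow): (1) a gene pair present in
#' strictly more than `improbable_prevalence` (default 95%) of the cohort's
#' samples; (2) a pair where *each* partner participates in at least two
#' distinct fusion pairs cohort-wide and is itself involved in fusions in
#' strictly more than `promiscuity_prevalence` (default 25%) of samples.
#' Sample counts are distinct samples; multiple breakpoints of the same
#' pair within one sample count once.
#'
#' @param candidates Candidate tibble (one cohort), as from
#'   [detect_sample()] rows bound across samples.
#' @param n_samples Number of samples in the cohort (not just samples with
#'   calls).
#' @param config A `fusion_filter_config`.
#' @return `candidates` with `improbable_frequency` and/or
#'   `promiscuous_partners` appended to `flags`.
#' @export
flag_improbable <- function(candidates, n_samples,
                            config = fusion_filter_config()) {
  if (n_samples <= 0L) abort("n_samples must be positive",
                             class = "kinfuse_input_error")
  if (nrow(candidates) == 0L) return(candidates)

  pair_samples <- candidates |>
    distinct(.data$gene5, .data$gene3, .data$sample_id) |>
    count(.data$gene5, .data$gene3, name = "n_carrier_samples")

  long <- dplyr::bind_rows(
    candidates |> distinct(.data$gene5, .data$gene3, .data$sample_id) |>
      mutate(gene = .data$gene5),
    candidates |> distinct(.data$gene5, .data$gene3, .data$sample_id) |>
      mutate(gene = .data$gene3)
  )
  per_gene <- long |>
    group_by(.data$gene) |>
    summarise(n_pairs = n_distinct(paste(.data$gene5, .data$gene3)),
              n_samples_involved = n_distinct(.data$sample_id))
  promiscuous_gene <- per_gene$gene[
    per_gene$n_pairs >= 2L &
      per_gene$n_samples_involved > config$promiscuity_prevalence * n_samples
  ]

  carriers <- pair_samples$n_carrier_samples[
    match(paste(candidates$gene5, candidates$gene3),
          paste(pair_samples$gene5, pair_samples$gene3))
  ]
  improbable <- carriers > config$improbable_prevalence * n_samples
  promiscuous <- candidates$gene5 %in% promiscuous_gene &
    candidates$gene3 %in% promiscuous_gene

  candidates$flags <- add_flag(candidates$flags, "improbable_frequency", improbable)
  candidates$flags <- add_flag(candidates$flags, "promiscuous_partners", promiscuous)
  candidates
}

add_flag <- function(flags, flag, where) {
  flags[where] <- ifelse(flags[where] == "", flag,
                         paste(flags[where], flag, sep = ";"))
  flags
}

has_flag <- function(flags) flags != "" & !is.na(flags)

#' Build a panel of normals from normal-sample evidence files
#'
#' Runs the identical detection procedure ([detect_sample()], same
#' configuration) on each normal sample and counts, per ordered gene pair,
#' the number of distinct normal samples in which the pair was detected.
#'
#' @param evidence_paths Named character vector of evidence TSV paths
#'   (names are normal sample ids; unnamed paths get their file sample id).
#' @param db A `gene_db`.
#' @param config A `fusion_filter_config` (must match the tumour runs).
#' @param paralogs Optional paralog table.
#' @return A tibble `gene5`, `gene3`, `n_normal_samples`.
#' @export
build_normals_panel <- function(evidence_paths, db,
                                config = fusion_filter_config(),
                                paralogs = NULL) {
  calls <- purrr::map(unname(evidence_paths), function(p) {
    ev <- read_evidence(p, quiet = TRUE)
    detect_sample(ev, db, config, paralogs)
  })
  all_calls <- bind_rows(calls)
  if (nrow(all_calls) == 0L) {
    return(tibble(gene5 = character(0), gene3 = character(0),
                  n_normal_samples = integer(0)))
  }
  all_calls |>
    distinct(.data$gene5, .data$gene3, .data$sample_id) |>
    count(.data$gene5, .data$gene3, name = "n_normal_samples")
}

#' Read a precomputed panel-of-normals TSV
#'
#' @param path TSV with columns `gene5`, `gene3`, `n_normal_samples`.
#' @return A panel tibble.
#' @export
read_normals_panel <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene5 = readr::col_character(), gene3 = readr::col_character(),
    n_normal_samples = readr::col_integer()
  ))
}

#' Remove fusions recurrent in a panel of normals
#'
#' Candidates whose ordered gene pair was detected (by the same procedure
#' and configuration) in at least `config$normals_min_samples` normal
#' samples are removed; pairs seen in fewer normals, or absent from the
#' panel, are kept.
#'
#' @param candidates Candidate tibble.
#' @param panel Panel tibble from [build_normals_panel()] or
#'   [read_normals_panel()].
#' @param config A `fusion_filter_config`.
#' @return Filtered candidate tibble; attribute `n_removed` counts removed
#'   rows.
#' @export
apply_normals_panel <- function(candidates, panel,
                                config = fusion_filter_config()) {
  if (nrow(candidates) == 0L || nrow(panel) == 0L) {
    attr(candidates, "n_removed") <- 0L
    return(candidates)
  }
  hot <- panel[panel$n_normal_samples >= config$normals_min_samples,
               c("gene5", "gene3"), drop = FALSE]
  keep <- !(paste(candidates$gene5, candidates$gene3) %in%
              paste(hot$gene5, hot$gene3))
  out <- candidates[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Select recurrent kinase fusions pooled across all cohorts
#'
#' Keeps fusions with a kinase partner whose recurrence, counted as
#' distinct tumour samples pooled across ALL cohorts, reaches
#' `config$recurrence_min` (default 2). Two counting modes: `"kinase"`
#' (default) counts every fusion of the same kinase gene regardless of
#' partner, aggregating a kinase's evidence across partners; `"pair"`
#' counts the ordered gene pair. Candidates carrying flags (improbable
#' frequency, promiscuity, homology, support) are excluded from the counts
#' and from the returned set.
#'
#' @param candidates Candidate tibble spanning all cohorts (with a `flags`
#'   column and, optionally, `cohort`).
#' @param db A `gene_db` (source of `is_kinase`).
#' @param config A `fusion_filter_config`.
#' @param mode `"kinase"` or `"pair"`.
#' @return The recurrent kinase-fusion candidates, with columns
#'   `kinase_gene`, `kinase_symbol` and `recurrence_n` appended.
#' @export
select_recurrent_kinase <- function(candidates, db,
                                    config = fusion_filter_config(),
                                    mode = c("kinase", "pair")) {
  mode <- match.arg(mode)
  out_cols <- function(x) mutate(x, kinase_gene = character(nrow(x)),
                                 kinase_symbol = character(nrow(x)),
                                 recurrence_n = integer(nrow(x)))
  if (nrow(candidates) == 0L) return(out_cols(candidates))
  kin <- db$genes$gene_id[db$genes$is_kinase]
  ok <- candidates[!has_flag(candidates$flags), , drop = FALSE]
  ok <- ok[ok$gene5 %in% kin | ok$gene3 %in% kin, , drop = FALSE]
  if (nrow(ok) == 0L) return(out_cols(ok))
  # the kinase partner; 3' wins when both are kinases (the activated side)
  ok$kinase_gene <- ifelse(ok$gene3 %in% kin, ok$gene3, ok$gene5)
  ok$kinase_symbol <- db$genes$symbol[match(ok$kinase_gene, db$genes$gene_id)]
  key <- if (mode == "kinase") ok$kinase_gene else paste(ok$gene5, ok$gene3)
  rec <- tibble(key = key, sample_id = ok$sample_id) |>
    distinct() |>
    count(.data$key, name = "recurrence_n")
  ok$recurrence_n <- rec$recurrence_n[match(key, rec$key)]
  ok[ok$recurrence_n >= config$recurrence_min, , drop = FALSE]
}

#' Per-cohort summary statistics
#'
#' Reports, per cohort: sample count, number of kinase-fusion calls,
#' kinase fusions per sample, and the percentage of samples harbouring at
#' least one recurrent kinase fusion. When candidates carry a `category`
#' column (novelty labels), per-category counts are appended.
#'
#' @param candidates Candidate tibble across samples with a `cohort`
#'   column (all retained calls).
#' @param sample_sheet Tibble with `sample_id`, `cohort` covering every
#'   sample (including fusion-free ones).
#' @param recurrent Recurrent-set tibble from [select_recurrent_kinase()]
#'   (may be empty or `NULL`).
#' @param db A `gene_db`.
#' @return A tibble, one row per cohort.
#' @export
cohort_summary <- function(candidates, sample_sheet, recurrent = NULL, db) {
  kin <- db$genes$gene_id[db$genes$is_kinase]
  base <- sample_sheet |> count(.data$cohort, name = "n_samples")
  kin_calls <- candidates[candidates$gene5 %in% kin |
                            candidates$gene3 %in% kin, , drop = FALSE]
  if (!"cohort" %in% names(kin_calls)) {
    kin_calls <- left_join(kin_calls,
                           sample_sheet[, c("sample_id", "cohort")],
                           by = "sample_id")
  }
  per <- kin_calls |> count(.data$cohort, name = "n_kinase_fusions")
  out <- base |>
    left_join(per, by = "cohort") |>
    mutate(n_kinase_fusions = dplyr::coalesce(.data$n_kinase_fusions, 0L),
           fusions_per_sample = ifelse(.data$n_samples > 0,
                                       .data$n_kinase_fusions / .data$n_samples, 0))
  rec_samples <- if (!is.null(recurrent) && nrow(recurrent) > 0L) {
    rc <- recurrent
    if (!"cohort" %in% names(rc)) {
      rc <- left_join(rc, sample_sheet[, c("sample_id", "cohort")],
                      by = "sample_id")
    }
    rc |>
      distinct(.data$cohort, .data$sample_id) |>
      count(.data$cohort, name = "n_samples_recurrent")
  } else {
    tibble(cohort = character(0), n_samples_recurrent = integer(0))
  }
  out <- out |>
    left_join(rec_samples, by = "cohort") |>
    mutate(n_samples_recurrent = dplyr::coalesce(.data$n_samples_recurrent, 0L),
           pct_samples_recurrent = ifelse(.data$n_samples > 0,
                                          100 * .data$n_samples_recurrent / .data$n_samples,
                                          0))
  if ("category" %in% names(candidates)) {
    cats <- candidates |>
      count(.data$cohort, .data$category) |>
      tidyr::pivot_wider(names_from = "category", values_from = "n",
                         names_prefix = "n_", values_fill = 0L)
    out <- left_join(out, cats, by = "cohort")
  }
  out
}
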
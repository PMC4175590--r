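#' Run the full fusion-discovery pipeline over a sample sheet
#'
#' Orchestrates detection, cohort filtering, recurrence selection and
#' functional annotation: per-sample candidate calling from chimeric
#' evidence, improbable-frequency flagging within each cohort, panel-of-
#' normals exclusion, selection of recurrent kinase fusions pooled across
#' cohorts, and annotation with junction class, reading frame, kinase-
#' domain conservation, motifs, artifact flags and verdicts. All outputs
#' are written to `out_dir` together with a run manifest (configuration
#' snapshot, per-stage record counts, file checksums); outputs carry no
#' timestamps, so a rerun on identical inputs is byte-identical.
#'
#' @param sample_sheet Tibble (or TSV path) with columns `sample_id`,
#'   `cohort`, `evidence` (path to each sample's evidence TSV).
#' @param gtf,genome,registry Annotation inputs ([load_annotation()]).
#' @param expression Optional expression TSV path (genes x samples).
#' @param normals Optional panel of normals: a directory of evidence
#'   TSVs, a character vector of evidence paths, a precomputed panel TSV
#'   path, or a panel tibble.
#' @param out_dir Output directory.
#' @param config A `fusion_filter_config`.
#' @param mode Recurrence counting mode, `"kinase"` (default) or
#'   `"pair"`.
#' @param motif_table,paralogs,coils Passed to the annotation stage.
#' @return A `kinfuse_run` object (list of stage tibbles plus the
#'   manifest), with [tidy()], [glance()] and [autoplot()] methods.
#' @export
run_fusion_pipeline <- function(sample_sheet, gtf, genome, registry,
                                expression = NULL, normals = NULL,
                                out_dir,
                                config = fusion_filter_config(),
                                mode = c("kinase", "pair"),
                                motif_table = NULL, paralogs = NULL,
                                coils = coils_parameters()) {
  mode <- match.arg(mode)
  if (is.character(sample_sheet) && length(sample_sheet) == 1L) {
    sample_sheet <- load_sample_sheet(sample_sheet)
  }
  need <- c("sample_id", "cohort", "evidence")
  if (!all(need %in% names(sample_sheet))) {
    abort("sample sheet needs columns sample_id, cohort, evidence",
          class = "kinfuse_input_error")
  }
  missing_files <- sample_sheet$sample_id[!file.exists(sample_sheet$evidence)]
  if (length(missing_files)) {
    abort(paste0("evidence file missing for sample(s): ",
                 paste(missing_files, collapse = ", ")),
          class = "kinfuse_input_error")
  }
  dir.create(file.path(out_dir, "candidates"), recursive = TRUE,
             showWarnings = FALSE)

  db <- load_annotation(gtf, registry, genome)
  expr <- if (!is.null(expression)) load_expression(expression, sample_sheet)

  counts <- list()
  per_sample <- purrr::map(seq_len(nrow(sample_sheet)), function(i) {
    s <- sample_sheet$sample_id[i]
    ev <- read_evidence(sample_sheet$evidence[i], sample_id = s, quiet = TRUE)
    cand <- detect_sample(ev, db, config, paralogs)
    write_candidates(cand,
                     tsv = file.path(out_dir, "candidates", paste0(s, ".tsv")),
                     bedpe = file.path(out_dir, "candidates", paste0(s, ".bedpe")))
    cand
  })
  candidates <- bind_rows(per_sample) |>
    left_join(sample_sheet[, c("sample_id", "cohort")], by = "sample_id")
  counts$evidence_samples <- nrow(sample_sheet)
  counts$candidates <- nrow(candidates)

  cohort_sizes <- sample_sheet |> count(.data$cohort, name = "n_samples")
  flagged <- if (nrow(candidates) == 0L) candidates else candidates |>
    tidyr::nest(.by = "cohort") |>
    mutate(data = purrr::map2(.data$data, .data$cohort, function(d, co) {
      n <- cohort_sizes$n_samples[cohort_sizes$cohort == co]
      flag_improbable(mutate(d, cohort = co), n, config)
    })) |>
    select("data") |>
    tidyr::unnest("data")

  panel <- normalise_panel(normals, db, config, paralogs)
  filtered <- apply_normals_panel(flagged, panel, config)
  counts$removed_by_normals <- attr(filtered, "n_removed") %||% 0L

  recurrent <- select_recurrent_kinase(filtered, db, config, mode)
  counts$recurrent_kinase <- nrow(recurrent)

  annotations <- annotate_fusions(recurrent, db, config, expr, motif_table,
                                  coils, paralogs)
  counts$candidate_drivers <- sum(annotations$verdict == "candidate_driver")

  summary_tab <- cohort_summary(filtered, sample_sheet, recurrent, db)

  readr::write_tsv(candidates, file.path(out_dir, "all_candidates.tsv"))
  readr::write_tsv(filtered, file.path(out_dir, "filtered_candidates.tsv"))
  readr::write_tsv(recurrent, file.path(out_dir, "recurrent_kinase_fusions.tsv"))
  readr::write_tsv(annotations, file.path(out_dir, "annotations.tsv"))
  write_annotation_json(annotations, file.path(out_dir, "annotations.json"))
  readr::write_tsv(summary_tab, file.path(out_dir, "cohort_summary.tsv"))

  manifest <- run_manifest(out_dir, config, mode, counts)
  res <- structure(list(candidates = candidates, flagged = flagged,
                        filtered = filtered, recurrent = recurrent,
                        annotations = annotations, summary = summary_tab,
                        sample_sheet = sample_sheet, config = config,
                        mode = mode, counts = counts, out_dir = out_dir,
                        manifest = manifest),
                   class = "kinfuse_run")
  res
}

normalise_panel <- function(normals, db, config, paralogs) {
  if (is.null(normals)) {
    return(tibble(gene5 = character(0), gene3 = character(0),
                  n_normal_samples = integer(0)))
  }
  if (is.data.frame(normals)) return(normals)
  if (length(normals) == 1L && dir.exists(normals)) {
    normals <- list.files(normals, pattern = "\\.tsv$", full.names = TRUE)
    return(build_normals_panel(normals, db, config, paralogs))
  }
  if (length(normals) == 1L && file.exists(normals)) {
    hdr <- names(readr::read_tsv(normals, n_max = 0,
                                 col_types = readr::cols()))
    if ("n_normal_samples" %in% hdr) return(read_normals_panel(normals))
  }
  build_normals_panel(normals, db, config, paralogs)
}

run_manifest <- function(out_dir, config, mode, counts) {
  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE),
    "run_manifest.json"))
  sums <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(
    tool = "kinfuse",
    version = as.character(utils::packageVersion("kinfuse")),
    mode = mode,
    config = unclass(config),
    counts = counts,
    outputs = tibble(file = files, md5 = sums)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.kinfuse_run <- function(x, ...) {
  cat(sprintf(
    "<kinfuse_run> %d samples: %d candidates -> %d after normals panel -> %d recurrent kinase fusions -> %d candidate drivers\n",
    x$counts$evidence_samples, x$counts$candidates,
    nrow(x$filtered), x$counts$recurrent_kinase, x$counts$candidate_drivers))
  invisible(x)
}

#' Tidy the annotated fusion calls of a pipeline run
#'
#' @param x A `kinfuse_run`.
#' @param ... Unused.
#' @return The annotation tibble, one row per recurrent kinase-fusion call.
#' @export
tidy.kinfuse_run <- function(x, ...) as_tibble(x$annotations)

#' One-row summary of a pipeline run
#'
#' @param x A `kinfuse_run`.
#' @param ... Unused.
#' @return A one-row tibble: sample and call counts, kinase fusions per
#'   sample, and the percentage of samples with a recurrent kinase fusion.
#' @export
glance.kinfuse_run <- function(x, ...) {
  n_samples <- nrow(x$sample_sheet)
  rec_samples <- n_distinct(x$recurrent$sample_id)
  kin_fusions <- sum(x$summary$n_kinase_fusions)
  tibble(
    n_samples = n_samples,
    n_candidates = x$counts$candidates,
    n_removed_by_normals = x$counts$removed_by_normals,
    n_recurrent_kinase = x$counts$recurrent_kinase,
    n_candidate_drivers = x$counts$candidate_drivers,
    kinase_fusions_per_sample = ifelse(n_samples > 0,
                                       kin_fusions / n_samples, 0),
    pct_samples_recurrent = ifelse(n_samples > 0,
                                   100 * rec_samples / n_samples, 0)
  )
}

#' Plot verdict counts of a pipeline run
#'
#' @param object A `kinfuse_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinfuse_run <- function(object, ...) {
  ann <- object$annotations
  if (nrow(ann) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No recurrent kinase fusions"))
  }
  ann |>
    count(.data$verdict) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$verdict, y = .data$n,
                                 fill = .data$verdict)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "recurrent kinase fusions",
                  title = "Verdicts of recurrent kinase fusions") +
    ggplot2::theme_minimal()
}

#' Scatter plot of read support per candidate fusion
#'
#' Chimeric-pair versus split-read support, with the support tiers drawn
#' as reference lines; useful for eyeballing how far calls sit from the
#' retention boundaries.
#'
#' @param candidates Candidate tibble (e.g. `run$candidates`).
#' @param config A `fusion_filter_config` (for the tier lines).
#' @return A ggplot.
#' @export
plot_fusion_support <- function(candidates, config = fusion_filter_config()) {
  ggplot2::ggplot(candidates,
                  ggplot2::aes(x = .data$n_chimeric, y = .data$n_split)) +
    ggplot2::geom_jitter(width = 0.15, height = 0.15, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(config$min_chimeric_2split,
                                       config$min_chimeric_1split,
                                       config$min_chimeric_0split),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "chimeric pairs", y = "split reads",
                  title = "Read support per candidate fusion") +
    ggplot2::theme_minimal()
}

#' Per-cohort kinase-fusion burden plot
#'
#' @param summary_tab Output of [cohort_summary()] (or `run$summary`).
#' @return A ggplot.
#' @export
plot_cohort_summary <- function(summary_tab) {
  ggplot2::ggplot(summary_tab,
                  ggplot2::aes(x = .data$cohort,
                               y = .data$fusions_per_sample)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "kinase fusions per sample",
                  title = "Kinase-fusion burden by cohort") +
    ggplot2::theme_minimal()
}
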
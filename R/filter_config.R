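#' Filtering thresholds for fusion detection and cohort filtering
#'
#' Collects every numeric threshold used by the pipeline in one auditable
#' object. The defaults encode the published heuristics this package
#' implements: tiered chimeric-read support conditioned on the number of
#' split reads (5 chimeric reads with >=2 split reads, 10 with exactly 1,
#' 20 with none), a minimum split-read junction overhang of 15 nt on each
#' side, cohort-level improbable-frequency flags (fusions in >95% of a
#' cohort; fusions whose partners are each promiscuously fused in >25% of
#' samples), exclusion of fusions seen in >=5 panel-of-normals samples, and
#' a cross-cohort recurrence requirement of n >= 2 tumour samples.
#'
#' @param min_chimeric_2split Minimum chimeric pairs when >= 2 split reads
#'   support the junction. Default 5.
#' @param min_chimeric_1split Minimum chimeric pairs when exactly 1 split
#'   read is present. Default 10.
#' @param min_chimeric_0split Minimum chimeric pairs when no split read is
#'   present. Default 20.
#' @param min_overhang Minimum junction overhang (nt) required on *each*
#'   side of a split read for it to count as split support. Default 15.
#' @param improbable_prevalence A gene pair seen in strictly more than this
#'   fraction of a cohort's samples is flagged as an improbable-frequency
#'   false positive. Default 0.95.
#' @param promiscuity_prevalence Strict sample-prevalence fraction for the
#'   dual-partner promiscuity clause. Default 0.25.
#' @param normals_min_samples A gene pair detected in at least this many
#'   panel-of-normals samples is excluded. Default 5.
#' @param recurrence_min Minimum number of tumour samples (pooled across all
#'   cohorts) in which a kinase fusion must occur to be called recurrent.
#'   Default 2.
#' @param homology_kmer k-mer length (nt) for the partner-homology screen.
#'   Default 24.
#' @param homology_share_frac Minimum shared fraction of distinct k-mers
#'   (max over both directions) for a pair to be called homologous.
#'   Default 0.05.
#' @param trans_splice_z Expression z-score at or above which a partner of a
#'   split-read-free, junction-unresolved fusion is flagged as a putative
#'   trans-splicing artifact. Default 3.
#'
#' @return A list of class `fusion_filter_config`.
#' @examples
#' cfg <- fusion_filter_config()
#' cfg$min_chimeric_0split
#' @export
fusion_filter_config <- function(min_chimeric_2split = 5L,
                                 min_chimeric_1split = 10L,
                                 min_chimeric_0split = 20L,
                                 min_overhang = 15L,
                                 improbable_prevalence = 0.95,
                                 promiscuity_prevalence = 0.25,
                                 normals_min_samples = 5L,
                                 recurrence_min = 2L,
                                 homology_kmer = 24L,
                                 homology_share_frac = 0.05,
                                 trans_splice_z = 3.0) {
  cfg <- list(
    min_chimeric_2split = as.integer(min_chimeric_2split),
    min_chimeric_1split = as.integer(min_chimeric_1split),
    min_chimeric_0split = as.integer(min_chimeric_0split),
    min_overhang = as.integer(min_overhang),
    improbable_prevalence = as.numeric(improbable_prevalence),
    promiscuity_prevalence = as.numeric(promiscuity_prevalence),
    normals_min_samples = as.integer(normals_min_samples),
    recurrence_min = as.integer(recurrence_min),
    homology_kmer = as.integer(homology_kmer),
    homology_share_frac = as.numeric(homology_share_frac),
    trans_splice_z = as.numeric(trans_splice_z)
  )
  counts <- c("min_chimeric_2split", "min_chimeric_1split",
              "min_chimeric_0split", "min_overhang",
              "normals_min_samples", "recurrence_min", "homology_kmer")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L) {
      abort(sprintf("`%s` must be a non-negative count, got %s", nm, cfg[[nm]]),
            class = "kinfuse_config_error")
    }
  }
  fracs <- c("improbable_prevalence", "promiscuity_prevalence",
             "homology_share_frac")
  for (nm in fracs) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1], got %s", nm, cfg[[nm]]),
            class = "kinfuse_config_error")
    }
  }
  structure(cfg, class = "fusion_filter_config")
}

#' @export
print.fusion_filter_config <- function(x, ...) {
  cat("<fusion_filter_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Read a filter configuration from a YAML-like key: value file
#'
#' Flat `key: value` text, one threshold per line; unknown keys error so a
#' run manifest can always be traced back to an exact configuration.
#'
#' @param path Path to the config file.
#' @return A `fusion_filter_config`.
#' @export
read_filter_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[[1]]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")), character(1))
  known <- names(formals(fusion_filter_config))
  bad <- setdiff(keys, known)
  if (length(bad)) {
    abort(paste0("Unknown filter-config key(s): ", paste(bad, collapse = ", ")),
          class = "kinfuse_config_error")
  }
  args <- lapply(setNames(vals, keys), as.numeric)
  do.call(fusion_filter_config, args)
}

#' Write a filter configuration to a flat text file
#'
#' @param config A `fusion_filter_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_config <- function(config, path) {
  stopifnot(inherits(config, "fusion_filter_config"))
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, format, character(1))), path)
  invisible(path)
}
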
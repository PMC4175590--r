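#' Parameters for the sliding-window coiled-coil scan
#'
#' The scan follows the classic sliding-window heptad-propensity approach:
#' within each window the score is the geometric mean of per-residue
#' propensities at the best of the seven heptad registers, each residue
#' takes the maximum score over the windows covering it, and the score is
#' converted to a coiled-coil probability by the ratio of two Gaussian
#' densities (one fitted to coiled-coil scores, one to globular scores,
#' with a prior weight on the globular class reflecting the rarity of
#' coiled coils).
#'
#' The propensity table shipped with the package
#' (`coils_propensities_synthetic.tsv`) is a synthetic table constructed
#' from the hydrophobic-core logic of heptad repeats (apolar residues
#' favoured at `a`/`d`, charged/polar residues at the outer positions,
#' helix breakers penalised everywhere); it is not the original published
#' matrix. The default score statistics were calibrated by simulation on
#' this table; published tables can be supplied via `propensity_file`, in
#' which case matching `cc_stats`/`g_stats` should be given too.
#'
#' @param window Window length in residues; default 28 (four heptads).
#' @param propensity_file TSV with columns `residue`, `a`..`g`; default the
#'   shipped synthetic table.
#' @param cc_stats,g_stats Mean and sd of window scores in the coiled-coil
#'   and globular reference distributions.
#' @param g_weight Prior weight on the globular class in the probability
#'   ratio. Default 30.
#' @return A list of class `coils_parameters`.
#' @export
coils_parameters <- function(window = 28L,
                             propensity_file = system.file(
                               "extdata", "coils_propensities_synthetic.tsv",
                               package = "kinfuse"),
                             cc_stats = c(mean = 1.507, sd = 0.101),
                             g_stats = c(mean = 0.885, sd = 0.123),
                             g_weight = 30) {
  tab <- readr::read_tsv(propensity_file, col_types = readr::cols(
    residue = readr::col_character(), .default = readr::col_double()
  ))
  mat <- as.matrix(tab[, c("a", "b", "c", "d", "e", "f", "g")])
  rownames(mat) <- tab$residue
  if (any(mat <= 0)) abort("all propensities must be > 0",
                           class = "kinfuse_config_error")
  structure(list(window = as.integer(window), propensity = mat,
                 cc_stats = cc_stats, g_stats = g_stats,
                 g_weight = g_weight),
            class = "coils_parameters")
}

#' Scan a protein sequence for coiled-coil motifs
#'
#' @param seq Amino-acid sequence (single-letter codes; residues absent
#'   from the propensity table score neutrally at 1).
#' @param params A [coils_parameters()] object.
#' @return A list with `prob` (per-residue coiled-coil probability),
#'   `score` (per-residue best window score) and `motifs`, a tibble of
#'   maximal intervals with probability >= 0.5 (`start`, `end`,
#'   `max_prob`). Sequences shorter than the window yield all-zero
#'   probabilities and no motifs.
#' @examples
#' cc <- strrep("LEALKEK", 6)
#' coils_scan(cc)$motifs
#' @export
coils_scan <- function(seq, params = coils_parameters()) {
  res <- strsplit(toupper(seq), "")[[1]]
  n <- length(res)
  w <- params$window
  no_motif <- tibble(start = integer(0), end = integer(0),
                     max_prob = numeric(0))
  if (n < w) {
    return(list(prob = numeric(n), score = numeric(n), motifs = no_motif))
  }
  logp <- log(params$propensity)
  idx <- match(res, rownames(logp))
  # log propensity of residue i at heptad position h, unknown residues neutral
  lp <- matrix(0, nrow = n, ncol = 7L)
  known <- !is.na(idx)
  lp[known, ] <- logp[idx[known], , drop = FALSE]

  n_win <- n - w + 1L
  win_score <- rep(-Inf, n_win)
  # register r places residue (i + r) at heptad position ((i + r - 1) %% 7) + 1
  for (r in 0:6) {
    h <- ((seq_len(n) + r - 1L) %% 7L) + 1L
    v <- lp[cbind(seq_len(n), h)]
    cs <- c(0, cumsum(v))
    sums <- (cs[(w + 1L):(n + 1L)] - cs[1:n_win]) / w
    win_score <- pmax(win_score, sums)
  }
  win_score <- exp(win_score)

  score <- numeric(n)
  for (i in seq_len(n_win)) {
    rng <- i:(i + w - 1L)
    score[rng] <- pmax(score[rng], win_score[i])
  }

  f_cc <- dnorm(score, params$cc_stats[["mean"]], params$cc_stats[["sd"]])
  f_g <- dnorm(score, params$g_stats[["mean"]], params$g_stats[["sd"]])
  prob <- f_cc / (f_cc + params$g_weight * f_g)
  prob[score == 0] <- 0

  hit <- prob >= 0.5
  motifs <- no_motif
  if (any(hit)) {
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    motifs <- tibble(start = starts[keep], end = ends[keep]) |>
      mutate(max_prob = purrr::map2_dbl(.data$start, .data$end,
                                        ~max(prob[.x:.y])))
  }
  list(prob = prob, score = score, motifs = motifs)
}
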
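# Evidence-record constructors against the toy annotation. Records are
# written in either the sense or antisense representation of the fusion
# transcript, mirroring how a read from either strand would be reported.

toy_donor <- function(g, k) if (g$strand == "+") g$exons$end[k] else g$exons$start[k]
toy_acceptor <- function(g, k) if (g$strand == "+") g$exons$start[k] else g$exons$end[k]
flip <- function(s) ifelse(s == "+", "-", "+")

ev_row <- function(...) {
  tibble::tibble(...)
}

ev_pair <- function(sample, read, g5, g3, antisense = FALSE, w = 50L) {
  p5 <- g5$exons$start[2]; p3 <- g3$exons$start[2]
  if (!antisense) {
    ev_row(sample_id = sample, read_id = read, kind = "pair",
           chromA = g5$chrom, posA = p5, strandA = g5$strand, spanA = w,
           chromB = g3$chrom, posB = p3, strandB = g3$strand, spanB = w,
           donor_pos = NA_integer_, acceptor_pos = NA_integer_,
           overhangA = NA_integer_, overhangB = NA_integer_)
  } else {
    ev_row(sample_id = sample, read_id = read, kind = "pair",
           chromA = g3$chrom, posA = p3, strandA = flip(g3$strand), spanA = w,
           chromB = g5$chrom, posB = p5, strandB = flip(g5$strand), spanB = w,
           donor_pos = NA_integer_, acceptor_pos = NA_integer_,
           overhangA = NA_integer_, overhangB = NA_integer_)
  }
}

ev_split <- function(sample, read, g5, g3, bp5, bp3, oh5 = 20L, oh3 = 20L,
                     antisense = FALSE) {
  seg5 <- if (g5$strand == "+") bp5 - oh5 + 1L else bp5
  seg3 <- if (g3$strand == "+") bp3 else bp3 - oh3 + 1L
  if (!antisense) {
    ev_row(sample_id = sample, read_id = read, kind = "split",
           chromA = g5$chrom, posA = seg5, strandA = g5$strand, spanA = oh5,
           chromB = g3$chrom, posB = seg3, strandB = g3$strand, spanB = oh3,
           donor_pos = bp5, acceptor_pos = bp3,
           overhangA = oh5, overhangB = oh3)
  } else {
    ev_row(sample_id = sample, read_id = read, kind = "split",
           chromA = g3$chrom, posA = seg3, strandA = flip(g3$strand), spanA = oh3,
           chromB = g5$chrom, posB = seg5, strandB = flip(g5$strand), spanB = oh5,
           donor_pos = bp3, acceptor_pos = bp5,
           overhangA = oh3, overhangB = oh5)
  }
}

# n_chimeric pairs + n_split splits for one fusion, unique read ids
ev_fusion <- function(sample, g5, g3, n_chimeric, n_split,
                      bp5 = toy_donor(g5, 2), bp3 = toy_acceptor(g3, 2),
                      prefix = "r") {
  rows <- list()
  if (n_split > 0) {
    for (k in seq_len(n_split)) {
      rows[[length(rows) + 1L]] <-
        ev_split(sample, sprintf("%s_s%d", prefix, k), g5, g3, bp5, bp3,
                 antisense = k %% 2L == 0L)
    }
  }
  if (n_chimeric > 0) {
    for (k in seq_len(n_chimeric)) {
      rows[[length(rows) + 1L]] <-
        ev_pair(sample, sprintf("%s_p%d", prefix, k), g5, g3,
                antisense = k %% 2L == 0L)
    }
  }
  dplyr::bind_rows(rows)
}

# minimal candidate row for annotation-stage tests
toy_candidate <- function(sample, g5, g3, n_chimeric, n_split, bp5, bp3) {
  tibble::tibble(sample_id = sample, gene5 = g5$gene_id, gene3 = g3$gene_id,
                 symbol5 = g5$symbol, symbol3 = g3$symbol,
                 chrom5 = g5$chrom, strand5 = g5$strand,
                 chrom3 = g3$chrom, strand3 = g3$strand,
                 n_chimeric = as.integer(n_chimeric),
                 n_split = as.integer(n_split),
                 breakpoint5 = as.integer(bp5), breakpoint3 = as.integer(bp3),
                 flags = "")
}
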
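#' Assign an aligned locus to a gene by exonic overlap
#'
#' A locus (the aligned span of one read end or split segment) is assigned
#' to the gene whose exon union it overlaps by the most nucleotides.
#' Intergenic spans return `NA`; an exact tie between two genes also
#' returns `NA` (ambiguous evidence is discarded rather than double
#' counted).
#'
#' @param db A `gene_db`.
#' @param chrom,pos,span Locus: chromosome, 1-based start, span length (nt).
#' @return Gene id, or `NA_character_`.
#' @export
assign_locus_to_gene <- function(db, chrom, pos, span) {
  assign_loci(db, chrom, pos, span)$gene_id[[1]]
}

# vectorised assignment; returns tibble(gene_id, tied)
assign_loci <- function(db, chrom, pos, span) {
  n <- length(pos)
  loci <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = span))
  hits <- GenomicRanges::findOverlaps(loci, db$exon_union, ignore.strand = TRUE)
  gene_id <- rep(NA_character_, n)
  tied <- logical(n)
  if (length(hits) > 0L) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- GenomicRanges::pintersect(loci[qh], db$exon_union[sh])
    per_hit <- tibble(q = qh, gene = db$exon_union$gene_id[sh],
                      w = GenomicRanges::width(ov))
    best <- per_hit |>
      group_by(.data$q, .data$gene) |>
      summarise(w = sum(.data$w), .groups = "drop_last") |>
      arrange(dplyr::desc(.data$w), .by_group = TRUE) |>
      summarise(gene = first(.data$gene),
                tie = n() > 1L && .data$w[1] == .data$w[2],
                .groups = "drop")
    gene_id[best$q] <- ifelse(best$tie, NA_character_, best$gene)
    tied[best$q] <- best$tie
  }
  tibble(gene_id = gene_id, tied = tied)
}

#' Orient a chimeric observation as a 5'->3' gene fusion
#'
#' Compares the aligned strand of each locus with the strand of its gene to
#' find the unique ordering consistent with a proper 5'->3' fusion
#' transcript. A fragment sequenced from the sense strand of the fusion
#' transcript traverses the 5' partner first with both segments aligned on
#' their genes' strands; the antisense representation flips both aligned
#' strands and traverses the partners in reverse. A mixed configuration
#' (one segment sense, the other antisense) is strand-discordant and
#' rejected; if any strand is `"*"` (unstranded) both orderings remain
#' consistent and the observation is rejected as ambiguous.
#'
#' @param gene_strand_a,gene_strand_b Strand (`"+"`/`"-"`) of the gene at
#'   locus A / locus B.
#' @param aligned_strand_a,aligned_strand_b Aligned strand of the segment
#'   at locus A / locus B (may be `"*"`).
#' @return Character vector over `{"AB", "BA", NA}`: `"AB"` means locus A's
#'   gene is the 5' partner.
#' @export
orient_pair <- function(gene_strand_a, gene_strand_b,
                        aligned_strand_a, aligned_strand_b) {
  ambiguous <- gene_strand_a == "*" | gene_strand_b == "*" |
    aligned_strand_a == "*" | aligned_strand_b == "*"
  match_a <- aligned_strand_a == gene_strand_a
  match_b <- aligned_strand_b == gene_strand_b
  out <- rep(NA_character_, length(match_a))
  out[match_a & match_b] <- "AB"
  out[!match_a & !match_b] <- "BA"
  out[ambiguous] <- NA_character_
  out
}

#' Partner-homology screen
#'
#' Two genes are called homologous when the fraction of one gene's distinct
#' k-mers (canonical-transcript sequence, k = `config$homology_kmer`) found
#' in the other reaches `config$homology_share_frac`, taking the maximum
#' over both directions, or when the pair is listed in a user-supplied
#' paralog table. Fusions between homologous partners are alignment-
#' artifact prone and discarded at detection.
#'
#' @param db A `gene_db` with genome sequence attached.
#' @param gene_a,gene_b Gene ids.
#' @param config A `fusion_filter_config`.
#' @param paralogs Optional two-column table of gene-id pairs treated as
#'   homologous regardless of sequence.
#' @return Logical scalar. Missing sequence is treated as non-homologous
#'   with a warning.
#' @export
mark_homologous <- function(db, gene_a, gene_b,
                            config = fusion_filter_config(),
                            paralogs = NULL) {
  if (!is.null(paralogs)) {
    pa <- as.matrix(paralogs[, 1:2])
    listed <- any((pa[, 1] == gene_a & pa[, 2] == gene_b) |
                    (pa[, 1] == gene_b & pa[, 2] == gene_a))
    if (listed) return(TRUE)
  }
  seq_a <- gene_canonical_seq(db, gene_a)
  seq_b <- gene_canonical_seq(db, gene_b)
  if (is.null(seq_a) || is.null(seq_b)) {
    warn(sprintf("no sequence for %s/%s; treating pair as non-homologous",
                 gene_a, gene_b))
    return(FALSE)
  }
  kmer_share(seq_a, seq_b, config$homology_kmer) >= config$homology_share_frac
}

gene_canonical_seq <- function(db, gene_id) {
  if (is.null(db$genome)) return(NULL)
  tx <- canonical_tx(db, gene_id)
  if (is.na(tx)) return(NULL)
  tx_sequence(db, tx)
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

kmer_share <- function(seq_a, seq_b, k) {
  ka <- kmer_set(seq_a, k)
  kb <- kmer_set(seq_b, k)
  if (length(ka) == 0L || length(kb) == 0L) return(0)
  max(mean(ka %in% kb), mean(kb %in% ka))
}

empty_candidates <- function() {
  tibble(sample_id = character(0), gene5 = character(0), gene3 = character(0),
         symbol5 = character(0), symbol3 = character(0),
         chrom5 = character(0), strand5 = character(0),
         chrom3 = character(0), strand3 = character(0),
         n_chimeric = integer(0), n_split = integer(0),
         breakpoint5 = integer(0), breakpoint3 = integer(0),
         flags = character(0))
}

#' Call candidate fusions in one sample
#'
#' Groups a sample's chimeric evidence by ordered 5'/3' gene pair and
#' applies the per-sample filters: read ends are assigned to genes by
#' maximal exonic overlap; each observation must orient consistently as a
#' 5'->3' fusion ([orient_pair()]); a split read counts only when both
#' junction overhangs reach `config$min_overhang` nt; pairs of homologous
#' partners (and of genomically overlapping homologous partners) are
#' flagged and discarded; and the tiered support rule retains a pair only
#' when (n_split >= 2 and n_chimeric >= 5) or (n_split == 1 and
#' n_chimeric >= 10) or (n_split == 0 and n_chimeric >= 20), under default
#' thresholds. A read id contributes at most once per gene pair; when the
#' same fragment yields both a split and a pair representation the split
#' outranks the pair.
#'
#' Breakpoints are the modal split-read junction; ties break first by the
#' junction with the greatest total overhang, then by smallest genomic
#' coordinate.
#'
#' @param evidence Evidence tibble for one sample ([read_evidence()]).
#' @param db A `gene_db`.
#' @param config A `fusion_filter_config`.
#' @param paralogs Optional paralog table (see [mark_homologous()]).
#' @param keep_flagged Keep candidates carrying flags
#'   (`below_support`, `homologous_partners`, `overlapping_homologs`)
#'   instead of dropping them. Default `FALSE`.
#' @return A tibble of fusion candidates with per-pair support counts,
#'   breakpoints and flags; attribute `dropped` counts evidence discarded
#'   at each step.
#' @export
detect_sample <- function(evidence, db, config = fusion_filter_config(),
                          paralogs = NULL, keep_flagged = FALSE) {
  if (nrow(evidence) == 0L) return(empty_candidates())
  if (n_distinct(evidence$sample_id) > 1L) {
    abort("detect_sample expects evidence from a single sample",
          class = "kinfuse_input_error")
  }
  dropped <- c(unassigned = 0L, ambiguous_assignment = 0L, same_gene = 0L,
               strand_discordant = 0L, short_overhang = 0L)

  a <- assign_loci(db, evidence$chromA, evidence$posA, evidence$spanA)
  b <- assign_loci(db, evidence$chromB, evidence$posB, evidence$spanB)
  ev <- evidence
  ev$geneA <- a$gene_id
  ev$geneB <- b$gene_id
  dropped[["ambiguous_assignment"]] <- sum((a$tied | b$tied))
  unassigned <- is.na(ev$geneA) | is.na(ev$geneB)
  dropped[["unassigned"]] <- sum(unassigned) - dropped[["ambiguous_assignment"]]
  ev <- ev[!unassigned, , drop = FALSE]
  same <- ev$geneA == ev$geneB
  dropped[["same_gene"]] <- sum(same)
  ev <- ev[!same, , drop = FALSE]
  if (nrow(ev) == 0L) return(with_dropped(empty_candidates(), dropped))

  glook <- db$genes
  strand_of <- glook$strand[match(ev$geneA, glook$gene_id)]
  strand_of_b <- glook$strand[match(ev$geneB, glook$gene_id)]
  ord <- orient_pair(strand_of, strand_of_b, ev$strandA, ev$strandB)
  dropped[["strand_discordant"]] <- sum(is.na(ord))
  ev <- ev[!is.na(ord), , drop = FALSE]
  ord <- ord[!is.na(ord)]
  if (nrow(ev) == 0L) return(with_dropped(empty_candidates(), dropped))

  ab <- ord == "AB"
  ev$gene5 <- ifelse(ab, ev$geneA, ev$geneB)
  ev$gene3 <- ifelse(ab, ev$geneB, ev$geneA)
  # junction coordinate on each gene's side follows the segment order in the
  # record: donor_pos sits on locus A, acceptor_pos on locus B
  ev$bp5 <- ifelse(ab, ev$donor_pos, ev$acceptor_pos)
  ev$bp3 <- ifelse(ab, ev$acceptor_pos, ev$donor_pos)

  is_split <- ev$kind == "split"
  short <- is_split & (ev$overhangA < config$min_overhang |
                         ev$overhangB < config$min_overhang)
  dropped[["short_overhang"]] <- sum(short)
  ev <- ev[!short, , drop = FALSE]
  if (nrow(ev) == 0L) return(with_dropped(empty_candidates(), dropped))

  # one fragment, one contribution per gene pair; split outranks pair
  ev <- ev |>
    mutate(.is_split = .data$kind == "split") |>
    arrange(.data$gene5, .data$gene3, .data$read_id,
            dplyr::desc(.data$.is_split)) |>
    distinct(.data$gene5, .data$gene3, .data$read_id, .keep_all = TRUE)

  tallies <- ev |>
    group_by(.data$gene5, .data$gene3) |>
    summarise(sample_id = first(.data$sample_id),
              n_chimeric = sum(!.data$.is_split),
              n_split = sum(.data$.is_split), .groups = "drop")

  bps <- ev |>
    filter(.data$.is_split) |>
    group_by(.data$gene5, .data$gene3, .data$bp5, .data$bp3) |>
    summarise(n_reads = n(),
              total_overhang = sum(.data$overhangA + .data$overhangB),
              .groups = "drop") |>
    group_by(.data$gene5, .data$gene3) |>
    arrange(dplyr::desc(.data$n_reads), dplyr::desc(.data$total_overhang),
            .data$bp5, .data$bp3, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select("gene5", "gene3", breakpoint5 = "bp5", breakpoint3 = "bp3")

  cand <- tallies |>
    left_join(bps, by = c("gene5", "gene3")) |>
    mutate(
      symbol5 = glook$symbol[match(.data$gene5, glook$gene_id)],
      symbol3 = glook$symbol[match(.data$gene3, glook$gene_id)],
      chrom5 = glook$chrom[match(.data$gene5, glook$gene_id)],
      strand5 = glook$strand[match(.data$gene5, glook$gene_id)],
      chrom3 = glook$chrom[match(.data$gene3, glook$gene_id)],
      strand3 = glook$strand[match(.data$gene3, glook$gene_id)]
    )

  # homology and support flags
  homol <- vapply(seq_len(nrow(cand)), function(i) {
    mark_homologous(db, cand$gene5[i], cand$gene3[i], config, paralogs)
  }, logical(1))
  span_overlap <- span_intersects(glook, cand$gene5, cand$gene3)
  support_ok <- (cand$n_split >= 2L & cand$n_chimeric >= config$min_chimeric_2split) |
    (cand$n_split == 1L & cand$n_chimeric >= config$min_chimeric_1split) |
    (cand$n_split == 0L & cand$n_chimeric >= config$min_chimeric_0split)

  flags <- mapply(function(h, ov, ok) {
    f <- character(0)
    if (h) f <- c(f, "homologous_partners")
    if (h && ov) f <- c(f, "overlapping_homologs")
    if (!ok) f <- c(f, "below_support")
    paste(f, collapse = ";")
  }, homol, span_overlap, support_ok)
  cand$flags <- flags

  cand <- cand[, names(empty_candidates())]
  if (!keep_flagged) cand <- cand[cand$flags == "", , drop = FALSE]
  cand <- arrange(cand, .data$gene5, .data$gene3)
  with_dropped(cand, dropped)
}

with_dropped <- function(x, dropped) {
  attr(x, "dropped") <- dropped
  x
}

span_intersects <- function(genes, gene5, gene3) {
  i5 <- match(gene5, genes$gene_id)
  i3 <- match(gene3, genes$gene_id)
  genes$chrom[i5] == genes$chrom[i3] &
    genes$start[i5] <= genes$end[i3] & genes$start[i3] <= genes$end[i5]
}

#' Write candidate fusions as TSV and breakpoints as BEDPE
#'
#' The BEDPE uses the format's native 0-based half-open coordinates; only
#' candidates with split-read breakpoints are emitted there.
#'
#' @param candidates Candidate tibble from [detect_sample()].
#' @param tsv,bedpe Output paths (either may be `NULL` to skip).
#' @return Invisibly, the candidate tibble.
#' @export
write_candidates <- function(candidates, tsv = NULL, bedpe = NULL) {
  if (!is.null(tsv)) readr::write_tsv(candidates, tsv)
  if (!is.null(bedpe)) {
    bp <- candidates[!is.na(candidates$breakpoint5), , drop = FALSE]
    bed <- tibble(
      chrom1 = bp$chrom5, start1 = bp$breakpoint5 - 1L, end1 = bp$breakpoint5,
      chrom2 = bp$chrom3, start2 = bp$breakpoint3 - 1L, end2 = bp$breakpoint3,
      name = paste0(bp$symbol5, "--", bp$symbol3),
      score = bp$n_split, strand1 = bp$strand5, strand2 = bp$strand3
    )
    readr::write_tsv(bed, bedpe, col_names = FALSE)
  }
  invisible(candidates)
}
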
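#' Classify a fusion junction against annotated exon boundaries
#'
#' A junction is `exon_exon` when both split-read breakpoints coincide with
#' annotated exon boundaries taken in transcription orientation (the 5'
#' breakpoint with a donor boundary — the transcription-wise end of an exon
#' of the 5' gene — and the 3' breakpoint with an acceptor boundary — the
#' transcription-wise start of an exon of the 3' gene, over any transcript
#' of each gene). It is `exon_cryptic` when exactly one side coincides
#' (the other side uses a cryptic exon), and `unresolved` when neither
#' does or when the candidate has no split reads (and hence no
#' base-resolution breakpoint). Artifactual chimeras typically lack a
#' clean exon-exon breakpoint and split-read support, so `unresolved`
#' feeds the artifact logic downstream.
#'
#' @param db A `gene_db`.
#' @param gene5,gene3 Gene ids of the ordered partners.
#' @param breakpoint5,breakpoint3 Genomic junction coordinates (may be NA).
#' @param n_split Number of supporting split reads.
#' @return One of `"exon_exon"`, `"exon_cryptic"`, `"unresolved"`.
#' @export
classify_junction <- function(db, gene5, gene3, breakpoint5, breakpoint3,
                              n_split) {
  if (is.na(n_split) || n_split == 0L ||
      is.na(breakpoint5) || is.na(breakpoint3)) {
    return("unresolved")
  }
  ex5 <- db$exons[db$exons$gene_id == gene5, , drop = FALSE]
  ex3 <- db$exons[db$exons$gene_id == gene3, , drop = FALSE]
  donor_ok <- any(ifelse(ex5$strand == "+", ex5$end, ex5$start) == breakpoint5)
  acceptor_ok <- any(ifelse(ex3$strand == "+", ex3$start, ex3$end) == breakpoint3)
  if (donor_ok && acceptor_ok) "exon_exon"
  else if (donor_ok || acceptor_ok) "exon_cryptic"
  else "unresolved"
}

#' Build the chimeric transcript model for a fusion candidate
#'
#' Concatenates the 5' partner's canonical-transcript exonic sequence up to
#' the 5' breakpoint with the 3' partner's canonical-transcript exonic
#' sequence from the 3' breakpoint onward, both in transcription
#' orientation (minus-strand exons are reverse-complemented by the
#' transcript machinery). The canonical transcript of each gene is the one
#' with the longest CDS, ties broken by lexicographic transcript id.
#' Records how much of each partner's CDS and UTR is retained; this
#' bookkeeping drives frame prediction and kinase-domain assessment.
#'
#' @param db A `gene_db` with genome sequence.
#' @param gene5,gene3 Gene ids.
#' @param breakpoint5,breakpoint3 Genomic junction coordinates.
#' @return A `fusion_transcript` list, or `NULL` with a warning if either
#'   breakpoint falls outside every exon of the chosen canonical
#'   transcript (annotation is then aborted for the candidate).
#' @export
build_fusion_transcript <- function(db, gene5, gene3,
                                    breakpoint5, breakpoint3) {
  tx5 <- canonical_tx(db, gene5)
  tx3 <- canonical_tx(db, gene3)
  j5 <- genomic_to_tx(db, tx5, breakpoint5)
  j3 <- genomic_to_tx(db, tx3, breakpoint3)
  if (is.na(j5) || is.na(j3)) {
    warn(sprintf("breakpoint outside canonical-transcript exons for %s--%s",
                 gene5, gene3))
    return(NULL)
  }
  seq5 <- tx_sequence(db, tx5)
  seq3 <- tx_sequence(db, tx3)
  cds5 <- tx_cds_span(db, tx5)
  cds3 <- tx_cds_span(db, tx3)
  len3 <- nchar(seq3)

  retained5_cds <- if (is.null(cds5)) 0L else
    max(0L, min(j5, cds5[2]) - cds5[1] + 1L)
  cds3_total <- if (is.null(cds3)) 0L else cds3[2] - cds3[1] + 1L
  cds3_before <- if (is.null(cds3)) 0L else
    max(0L, min(j3 - 1L, cds3[2]) - cds3[1] + 1L)
  retained3_cds <- if (is.null(cds3) || j3 > cds3[2]) 0L else
    cds3_total - cds3_before

  fusion_seq <- paste0(substr(seq5, 1L, j5), substr(seq3, j3, len3))

  structure(list(
    gene5 = gene5, gene3 = gene3, tx5 = tx5, tx3 = tx3,
    j5 = j5, j3 = j3, seq = fusion_seq,
    seq5_len = nchar(seq5), seq3_len = len3,
    cds5 = cds5, cds3 = cds3,
    retained5_cds = retained5_cds,
    cds5_total = if (is.null(cds5)) 0L else cds5[2] - cds5[1] + 1L,
    cds3_before = cds3_before, cds3_total = cds3_total,
    retained3_cds = retained3_cds
  ), class = "fusion_transcript")
}

#' @export
print.fusion_transcript <- function(x, ...) {
  cat(sprintf("<fusion_transcript> %s(%s, %d nt) :: %s(%s, %d nt); 5' CDS retained %d/%d nt, 3' CDS retained %d/%d nt\n",
              x$gene5, x$tx5, x$j5, x$gene3, x$tx3, x$seq3_len - x$j3 + 1L,
              x$retained5_cds, x$cds5_total, x$retained3_cds, x$cds3_total))
  invisible(x)
}

#' Predict the reading-frame status of a fusion transcript
#'
#' `promoter_fusion`: the 5' partner contributes only untranslated
#' sequence and the complete 3' coding sequence lies downstream of the
#' junction — the 3' gene's intact protein is placed under the partner's
#' promoter. `in_frame`: the retained 5' coding sequence joins the 3'
#' coding sequence in its annotated phase with no intervening stop codon,
#' verified by translating the constructed transcript from the 5' start
#' codon through the junction. `no_cds`: neither partner contributes
#' coding sequence. Everything else is `out_of_frame`. The partner
#' contribution is the number of whole codons the 5' partner retains.
#'
#' @param ft A `fusion_transcript` from [build_fusion_transcript()].
#' @return List with `frame_status` and `partner_contrib_aa`.
#' @export
predict_frame <- function(ft) {
  contrib <- ft$retained5_cds %/% 3L
  if (ft$retained5_cds == 0L && ft$retained3_cds == 0L) {
    return(list(frame_status = "no_cds", partner_contrib_aa = 0L))
  }
  if (ft$retained5_cds == 0L) {
    if (ft$cds3_total > 0L && ft$cds3_before == 0L &&
        ft$retained3_cds == ft$cds3_total) {
      return(list(frame_status = "promoter_fusion", partner_contrib_aa = 0L))
    }
    return(list(frame_status = "out_of_frame", partner_contrib_aa = 0L))
  }
  if (ft$retained3_cds == 0L) {
    return(list(frame_status = "out_of_frame", partner_contrib_aa = contrib))
  }

  # phase arithmetic: offset of the first retained 3' CDS base within the
  # fused open reading frame must match its native CDS phase
  c5s <- ft$cds5[1]
  first3_cds <- max(ft$j3, ft$cds3[1])                  # seq3 coordinate
  upstream_len <- (ft$j5 - c5s + 1L) + (first3_cds - ft$j3)
  frame_ok <- (upstream_len %% 3L) == (ft$cds3_before %% 3L)
  if (!frame_ok) {
    return(list(frame_status = "out_of_frame", partner_contrib_aa = contrib))
  }

  # stop-codon scan from the 5' start codon through the junction: the first
  # stop reached must be at (or beyond) the 3' gene's native stop
  orf <- substring(ft$seq, c5s)
  orf <- substr(orf, 1L, 3L * (nchar(orf) %/% 3L))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(orf), if.fuzzy.codon = "X"))
  stops <- which(strsplit(aa, "")[[1]] == "*")
  native3_stop_start <- ft$j5 + (ft$cds3[2] + 1L - ft$j3 + 1L)  # fusion coord
  stop_codon_idx <- (native3_stop_start - c5s) %/% 3L + 1L
  premature <- any(stops < stop_codon_idx)
  list(frame_status = if (premature) "out_of_frame" else "in_frame",
       partner_contrib_aa = contrib)
}

#' Assess conservation of the kinase catalytic domain in a fusion
#'
#' Given the registry's domain interval `[domain_start, domain_end]`
#' (1-based amino-acid coordinates on the kinase's native protein), the
#' status is `complete` when the fusion retains the whole interval,
#' `truncated` when it retains part of it, and `absent` when none of it
#' remains. For a 3' kinase the fusion retains the native residues from
#' the first fully retained codon after the breakpoint to the C terminus;
#' for a 5' kinase it retains the N-terminal residues encoded by whole
#' retained codons. Only complete conservation is compatible with an
#' activating fusion.
#'
#' @param ft A `fusion_transcript`.
#' @param domain_start,domain_end Domain interval (aa). `NA` yields
#'   `"absent"` with a warning.
#' @param kinase_side `"3"` if the kinase is the 3' partner (the usual
#'   activating configuration), `"5"` otherwise.
#' @return One of `"complete"`, `"truncated"`, `"absent"`.
#' @export
check_kinase_domain <- function(ft, domain_start, domain_end,
                                kinase_side = c("3", "5")) {
  kinase_side <- match.arg(kinase_side)
  if (is.na(domain_start) || is.na(domain_end)) {
    warn("kinase domain coordinates missing from registry; status 'absent'")
    return("absent")
  }
  if (kinase_side == "3") {
    if (ft$retained3_cds == 0L) return("absent")
    prot_len <- ft$cds3_total %/% 3L
    first_full <- ft$cds3_before %/% 3L + 1L + as.integer(ft$cds3_before %% 3L > 0L)
    if (first_full > prot_len) return("absent")
    if (first_full <= domain_start) "complete"
    else if (first_full <= domain_end) "truncated"
    else "absent"
  } else {
    last_full <- ft$retained5_cds %/% 3L
    if (last_full < domain_start) "absent"
    else if (last_full >= domain_end) "complete"
    else "truncated"
  }
}

# native protein sequence of a gene's canonical transcript
gene_protein <- function(db, gene_id) {
  tx <- canonical_tx(db, gene_id)
  if (is.na(tx)) return(NULL)
  cds <- tx_cds_span(db, tx)
  if (is.null(cds)) return(NULL)
  nt <- substr(tx_sequence(db, tx), cds[1], cds[2])
  nt <- substr(nt, 1L, 3L * (nchar(nt) %/% 3L))
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "X"))
}
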
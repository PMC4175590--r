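#' Expression z-score of a gene in a sample, within its cohort
#'
#' `(value - cohort mean) / cohort sd`, with the unbiased (n-1) standard
#' deviation taken over all samples of the sample's cohort. A very high
#' z-score of a fusion partner is the signature of trans-splicing
#' library artifacts (non-genomic chimeras from highly expressed genes)
#' and, conversely, corroborates promoter fusions that drive
#' overexpression of the intact downstream gene.
#'
#' @param expr An `expression_matrix` from [load_expression()].
#' @param gene Gene id (row of the matrix).
#' @param sample Sample id (column); its cohort must have >= 3 samples.
#' @return Numeric z-score; 0 with a warning when the cohort sd is 0.
#' @examples
#' sheet <- tibble::tibble(sample_id = c("s1", "s2", "s3"), cohort = "t")
#' m <- tempfile(); readr::write_tsv(tibble::tibble(
#'   gene_id = "g1", s1 = 1, s2 = 2, s3 = 3), m)
#' expression_zscore(load_expression(m, sheet), "g1", "s3")  # 1
#' @export
expression_zscore <- function(expr, gene, sample) {
  if (!gene %in% rownames(expr$mat)) {
    abort(sprintf("gene %s absent from expression matrix", gene),
          class = "kinfuse_input_error")
  }
  if (!sample %in% expr$samples$sample_id) {
    abort(sprintf("sample %s absent from expression matrix", sample),
          class = "kinfuse_input_error")
  }
  cohort <- expr$samples$cohort[expr$samples$sample_id == sample][[1]]
  cols <- expr$samples$sample_id[expr$samples$cohort == cohort]
  if (length(cols) < 3L) {
    abort(sprintf("cohort %s has fewer than 3 samples", cohort),
          class = "kinfuse_input_error")
  }
  vals <- expr$mat[gene, cols]
  s <- sd(vals)
  if (is.na(s) || s == 0) {
    warn(sprintf("zero expression variance for %s in cohort %s; z = 0",
                 gene, cohort))
    return(0)
  }
  (expr$mat[gene, sample] - mean(vals)) / s
}

#' Artifact flags for an annotated fusion candidate
#'
#' `homologous_repeat`: the partners share homologous sequence
#' ([mark_homologous()]), the classic alignment-artifact cause.
#' `trans_splice_suspect`: an expression z-score of either partner at or
#' above `config$trans_splice_z` *and* no split-read support *and* an
#' unresolved junction — the joint signature of trans-spliced library
#' chimeras, which arise from highly expressed genes and lack a clean
#' exon-exon breakpoint. Genes absent from the expression matrix skip the
#' trans-splice test with a warning.
#'
#' @param db A `gene_db`.
#' @param gene5,gene3 Partner gene ids.
#' @param sample_id Sample carrying the candidate.
#' @param n_split Split-read support of the candidate.
#' @param junction_class From [classify_junction()].
#' @param expr An `expression_matrix` or `NULL` (skips trans-splice test).
#' @param config A `fusion_filter_config`.
#' @param paralogs Optional paralog table.
#' @return Character vector of flags (possibly empty).
#' @export
flag_artifacts <- function(db, gene5, gene3, sample_id, n_split,
                           junction_class, expr = NULL,
                           config = fusion_filter_config(),
                           paralogs = NULL) {
  flags <- character(0)
  if (mark_homologous(db, gene5, gene3, config, paralogs)) {
    flags <- c(flags, "homologous_repeat")
  }
  if (!is.null(expr) && n_split == 0L && junction_class == "unresolved") {
    z <- vapply(c(gene5, gene3), function(g) {
      if (!g %in% rownames(expr$mat)) {
        warn(sprintf("gene %s absent from expression matrix; trans-splice test skipped", g))
        return(NA_real_)
      }
      expression_zscore(expr, g, sample_id)
    }, numeric(1))
    if (any(z >= config$trans_splice_z, na.rm = TRUE)) {
      flags <- c(flags, "trans_splice_suspect")
    }
  }
  flags
}

#' Final driver/passenger/artifact verdict for a fusion
#'
#' `artifact` when any artifact flag is set; otherwise `candidate_driver`
#' when the fusion is recurrent, has an intergenic junction (exon-exon or
#' exon-cryptic), a predicted in-frame coding sequence or promoter-fusion
#' configuration, and complete conservation of the kinase catalytic
#' domain; otherwise `passenger`. A promoter fusion satisfies the coding
#' criterion because the intact wild-type coding sequence of the 3' gene
#' is expressed.
#'
#' @param junction_class,frame_status,kinase_domain_status Annotation
#'   fields.
#' @param artifact_flags Character vector (possibly empty).
#' @param recurrent Logical: seen in >= the recurrence threshold of tumour
#'   samples pooled across cohorts.
#' @return `"candidate_driver"`, `"passenger"` or `"artifact"`.
#' @export
classify_verdict <- function(junction_class, frame_status,
                             kinase_domain_status, artifact_flags,
                             recurrent) {
  if (length(artifact_flags) > 0L && any(nzchar(artifact_flags))) {
    return("artifact")
  }
  driver <- isTRUE(recurrent) &&
    junction_class %in% c("exon_exon", "exon_cryptic") &&
    frame_status %in% c("in_frame", "promoter_fusion") &&
    identical(kinase_domain_status, "complete")
  if (driver) "candidate_driver" else "passenger"
}

#' Load a motif-interval table
#'
#' User-extensible table of dimerization or other motifs on native partner
#' proteins (e.g. LisH), used to report motifs retained by the partner's
#' contribution to the fusion. Columns: `gene` (gene id or symbol),
#' `motif_name`, `aa_start`, `aa_end`.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
load_motif_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), motif_name = readr::col_character(),
    aa_start = readr::col_integer(), aa_end = readr::col_integer()
  ))
}

#' Annotate recurrent kinase-fusion candidates
#'
#' Applies the manual-review rule set to each candidate: junction
#' classification against annotated exon boundaries, fusion-transcript
#' construction on canonical transcripts, reading-frame prediction,
#' kinase-domain conservation, coiled-coil scanning of the partner's
#' retained protein segment (plus any user-supplied motif intervals fully
#' retained), artifact flagging, and the final
#' driver/passenger/artifact verdict.
#'
#' @param candidates Candidate tibble, normally the output of
#'   [select_recurrent_kinase()] (columns `kinase_gene` and `recurrence_n`
#'   are used when present; otherwise the kinase partner is looked up in
#'   `db` and recurrence taken from the `recurrent` argument).
#' @param db A `gene_db` with genome sequence.
#' @param config A `fusion_filter_config`.
#' @param expr Optional `expression_matrix` for the trans-splice test and
#'   partner overexpression reporting.
#' @param motif_table Optional motif-interval tibble
#'   ([load_motif_table()]).
#' @param coils A [coils_parameters()] object.
#' @param paralogs Optional paralog table.
#' @param recurrent Logical default used when `recurrence_n` is absent.
#' @return The candidate tibble with annotation columns appended:
#'   `junction_class`, `frame_status`, `partner_contrib_aa`,
#'   `kinase_domain_status`, `partner_gene`, `partner_symbol`,
#'   `partner_coiled_coil`, `motif_calls`, `partner_expression_z`,
#'   `artifact_flags`, `verdict`.
#' @export
annotate_fusions <- function(candidates, db,
                             config = fusion_filter_config(),
                             expr = NULL, motif_table = NULL,
                             coils = coils_parameters(),
                             paralogs = NULL, recurrent = TRUE) {
  n <- nrow(candidates)
  ann <- tibble(
    junction_class = character(n), frame_status = character(n),
    partner_contrib_aa = integer(n), kinase_domain_status = character(n),
    partner_gene = character(n), partner_symbol = character(n),
    partner_coiled_coil = logical(n), motif_calls = character(n),
    partner_expression_z = numeric(n), artifact_flags = character(n),
    verdict = character(n)
  )
  if (n == 0L) return(dplyr::bind_cols(candidates, ann))
  kin <- db$genes$gene_id[db$genes$is_kinase]

  for (i in seq_len(n)) {
    cand <- candidates[i, ]
    kinase_gene <- if ("kinase_gene" %in% names(cand)) cand$kinase_gene else
      if (cand$gene3 %in% kin) cand$gene3 else cand$gene5
    kinase_side <- if (identical(kinase_gene, cand$gene3)) "3" else "5"
    partner_gene <- if (kinase_side == "3") cand$gene5 else cand$gene3
    is_recurrent <- if ("recurrence_n" %in% names(cand)) {
      cand$recurrence_n >= config$recurrence_min
    } else isTRUE(recurrent)

    jc <- classify_junction(db, cand$gene5, cand$gene3,
                            cand$breakpoint5, cand$breakpoint3, cand$n_split)
    frame <- "no_cds"; contrib <- 0L; kd <- "absent"
    coiled <- FALSE; motifs <- character(0)
    if (jc != "unresolved") {
      ft <- build_fusion_transcript(db, cand$gene5, cand$gene3,
                                    cand$breakpoint5, cand$breakpoint3)
      if (is.null(ft)) {
        jc <- "unresolved"
      } else {
        fr <- predict_frame(ft)
        frame <- fr$frame_status
        contrib <- fr$partner_contrib_aa
        gi <- match(kinase_gene, db$genes$gene_id)
        kd <- check_kinase_domain(ft, db$genes$domain_start_aa[gi],
                                  db$genes$domain_end_aa[gi], kinase_side)
        seg <- partner_retained_peptide(db, ft, kinase_side)
        if (!is.null(seg) && nchar(seg$peptide) > 0L) {
          cc <- coils_scan(seg$peptide, coils)
          if (nrow(cc$motifs) > 0L) {
            coiled <- TRUE
            motifs <- c(motifs, sprintf(
              "coiled_coil:%d-%d(%.2f)",
              cc$motifs$start + seg$offset, cc$motifs$end + seg$offset,
              cc$motifs$max_prob))
          }
          if (!is.null(motif_table)) {
            psym <- db$genes$symbol[match(partner_gene, db$genes$gene_id)]
            mt <- motif_table[motif_table$gene %in% c(partner_gene, psym), ,
                              drop = FALSE]
            keep <- mt$aa_start > seg$offset &
              mt$aa_end <= seg$offset + nchar(seg$peptide)
            motifs <- c(motifs, sprintf("%s:%d-%d", mt$motif_name[keep],
                                        mt$aa_start[keep], mt$aa_end[keep]))
          }
        }
      }
    }
    af <- flag_artifacts(db, cand$gene5, cand$gene3, cand$sample_id,
                         cand$n_split, jc, expr, config, paralogs)
    z <- NA_real_
    if (!is.null(expr) && partner_gene %in% rownames(expr$mat) &&
        cand$sample_id %in% expr$samples$sample_id) {
      z <- expression_zscore(expr, partner_gene, cand$sample_id)
    }
    ann$junction_class[i] <- jc
    ann$frame_status[i] <- frame
    ann$partner_contrib_aa[i] <- contrib
    ann$kinase_domain_status[i] <- kd
    ann$partner_gene[i] <- partner_gene
    ann$partner_symbol[i] <- db$genes$symbol[match(partner_gene, db$genes$gene_id)]
    ann$partner_coiled_coil[i] <- coiled
    ann$motif_calls[i] <- paste(motifs, collapse = ";")
    ann$partner_expression_z[i] <- z
    ann$artifact_flags[i] <- paste(af, collapse = ";")
    ann$verdict[i] <- classify_verdict(jc, frame, kd, af, is_recurrent)
  }
  dplyr::bind_cols(candidates, ann)
}

# retained segment of the non-kinase partner's native protein, with the
# offset of its first residue on that protein (0-based)
partner_retained_peptide <- function(db, ft, kinase_side) {
  partner <- if (kinase_side == "3") ft$gene5 else ft$gene3
  prot <- gene_protein(db, partner)
  if (is.null(prot)) return(NULL)
  if (kinase_side == "3") {
    l <- ft$retained5_cds %/% 3L
    list(peptide = substr(prot, 1L, l), offset = 0L)
  } else {
    f <- ft$cds3_before %/% 3L + 1L + as.integer(ft$cds3_before %% 3L > 0L)
    if (f > nchar(prot)) return(list(peptide = "", offset = nchar(prot)))
    list(peptide = substring(prot, f), offset = f - 1L)
  }
}

#' Write per-fusion annotation reports as JSON
#'
#' @param annotations Annotated tibble from [annotate_fusions()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotation_json <- function(annotations, path) {
  jsonlite::write_json(annotations, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
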
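#' Load gene annotation, genome sequence and kinase registry
#'
#' Reads a Gencode-style GTF (gene/transcript/exon and optionally CDS
#' records carrying `gene_id`/`transcript_id` attributes) into the indexed
#' gene set used by the detection and annotation stages. A kinase registry
#' maps gene symbols to kinase catalytic-domain protein coordinates
#' (1-based inclusive amino-acid positions); domain discovery itself (e.g.
#' Pfam searches) is out of scope — the registry is an input. An optional
#' genome FASTA supplies sequence for homology screening, fusion-transcript
#' construction and frame prediction.
#'
#' Internally all coordinates are 1-based inclusive (the IRanges
#' convention); BEDPE output converts to 0-based half-open at write time.
#'
#' @param gtf Path to a GTF file.
#' @param registry Optional path to a kinase registry TSV with columns
#'   `symbol`, `domain_start_aa`, `domain_end_aa`, `domain_name`. Registry
#'   symbols absent from the GTF are skipped with a warning.
#' @param genome Optional path to a genome FASTA (one record per
#'   chromosome).
#' @return A `gene_db` object: a list with tibbles `genes`, `transcripts`,
#'   `exons`, `cds`, a reduced per-gene exon-union `GRanges`, a gene-span
#'   `GRanges`, and the genome as a `DNAStringSet` (or `NULL`).
#' @examples
#' dir <- tempfile(); sim <- simulate_annotation(sim_config(n_genes = 4), dir)
#' db <- load_annotation(sim$gtf, sim$registry, sim$genome)
#' db$genes
#' @export
load_annotation <- function(gtf, registry = NULL, genome = NULL) {
  check_gtf_lines(gtf)
  gr <- rtracklayer::import(gtf, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  need <- c("type", "gene_id")
  if (!all(need %in% names(meta))) {
    abort("GTF lacks required attributes (type, gene_id)",
          class = "kinfuse_parse_error")
  }

  is_gene <- meta$type == "gene"
  if (!any(is_gene)) abort("GTF contains no gene records",
                           class = "kinfuse_parse_error")
  symbol <- if ("gene_name" %in% names(meta)) meta$gene_name else meta$gene_id
  genes <- tibble(
    gene_id = meta$gene_id[is_gene],
    symbol = symbol[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene]
  )
  if (anyDuplicated(genes$gene_id)) {
    abort("duplicated gene_id in GTF", class = "kinfuse_parse_error")
  }

  is_exon <- meta$type == "exon"
  exons <- tibble(
    tx_id = meta$transcript_id[is_exon],
    gene_id = meta$gene_id[is_exon],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_exon],
    strand = as.character(GenomicRanges::strand(gr))[is_exon],
    start = GenomicRanges::start(gr)[is_exon],
    end = GenomicRanges::end(gr)[is_exon]
  )
  if (nrow(exons) == 0L) abort("GTF contains no exon records",
                               class = "kinfuse_parse_error")
  # transcription order: 5' exon first
  exons <- exons |>
    group_by(.data$tx_id) |>
    arrange(if_else(.data$strand == "-", -.data$start, .data$start),
            .by_group = TRUE) |>
    mutate(rank = row_number()) |>
    ungroup()

  is_cds <- meta$type == "CDS"
  cds <- tibble(
    tx_id = meta$transcript_id[is_cds],
    gene_id = meta$gene_id[is_cds],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_cds],
    start = GenomicRanges::start(gr)[is_cds],
    end = GenomicRanges::end(gr)[is_cds]
  )

  validate_gene_models(genes, exons, cds, meta, gr)

  cds_len <- cds |>
    group_by(.data$tx_id) |>
    summarise(cds_len = sum(.data$end - .data$start + 1L))
  transcripts <- exons |>
    distinct(.data$tx_id, .data$gene_id) |>
    left_join(cds_len, by = "tx_id") |>
    mutate(cds_len = dplyr::coalesce(.data$cds_len, 0L)) |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$cds_len), .data$tx_id, .by_group = TRUE) |>
    mutate(canonical = row_number() == 1L) |>
    ungroup()

  genes$is_kinase <- FALSE
  genes$domain_start_aa <- NA_integer_
  genes$domain_end_aa <- NA_integer_
  genes$domain_name <- NA_character_
  if (!is.null(registry)) {
    reg <- readr::read_tsv(registry, col_types = readr::cols(
      symbol = readr::col_character(),
      domain_start_aa = readr::col_integer(),
      domain_end_aa = readr::col_integer(),
      domain_name = readr::col_character()
    ))
    missing <- setdiff(reg$symbol, genes$symbol)
    if (length(missing)) {
      warn(paste0("kinase registry symbols absent from GTF, skipped: ",
                  paste(missing, collapse = ", ")))
      reg <- reg[!reg$symbol %in% missing, , drop = FALSE]
    }
    idx <- match(genes$symbol, reg$symbol)
    hit <- !is.na(idx)
    genes$is_kinase[hit] <- TRUE
    genes$domain_start_aa[hit] <- reg$domain_start_aa[idx[hit]]
    genes$domain_end_aa[hit] <- reg$domain_end_aa[idx[hit]]
    genes$domain_name[hit] <- reg$domain_name[idx[hit]]
  }

  genome_seq <- NULL
  if (!is.null(genome)) {
    genome_seq <- Biostrings::readDNAStringSet(genome)
    names(genome_seq) <- sub("\\s.*$", "", names(genome_seq))
  }

  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, gene_id = genes$gene_id
  )
  exon_gr <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start, exons$end),
    gene_id = exons$gene_id
  )
  red <- GenomicRanges::reduce(
    GenomicRanges::split(exon_gr, exon_gr$gene_id)
  )
  exon_union <- unlist(red, use.names = FALSE)
  exon_union$gene_id <- rep(names(red), lengths(red))

  structure(
    list(genes = genes, transcripts = transcripts, exons = exons, cds = cds,
         gene_gr = gene_gr, exon_union = exon_union, genome = genome_seq),
    class = "gene_db"
  )
}

#' @export
print.gene_db <- function(x, ...) {
  cat(sprintf("<gene_db> %d genes (%d kinases), %d transcripts%s\n",
              nrow(x$genes), sum(x$genes$is_kinase), nrow(x$transcripts),
              if (is.null(x$genome)) "" else ", genome attached"))
  invisible(x)
}

# malformed-line pre-scan so parse errors name the offending line
check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, integer(1))
  bad <- which(body)[nfield < 9L]
  if (length(bad)) {
    abort(sprintf("malformed GTF line %d in %s: expected 9 tab-separated fields",
                  bad[[1]], path),
          class = "kinfuse_parse_error")
  }
  invisible(TRUE)
}

validate_gene_models <- function(genes, exons, cds, meta, gr) {
  ex <- left_join(exons, genes, by = "gene_id", suffix = c("", ".gene"))
  off <- ex$start < ex$start.gene | ex$end > ex$end.gene
  if (any(off)) {
    abort(sprintf("exon of transcript %s extends past the span of gene %s",
                  ex$tx_id[which(off)[1]], ex$gene_id[which(off)[1]]),
          class = "kinfuse_invariant_error")
  }
  # exons within a transcript must not overlap
  ovl <- exons |>
    arrange(.data$tx_id, .data$start) |>
    group_by(.data$tx_id) |>
    mutate(clash = .data$start <= dplyr::lag(.data$end, default = -1L)) |>
    ungroup()
  if (any(ovl$clash)) {
    abort(sprintf("overlapping exons within transcript %s",
                  ovl$tx_id[which(ovl$clash)[1]]),
          class = "kinfuse_invariant_error")
  }
  if (nrow(cds) > 0L) {
    cds_gr <- GenomicRanges::GRanges(cds$chrom, IRanges::IRanges(cds$start, cds$end))
    ex_gr <- GenomicRanges::GRanges(exons$chrom, IRanges::IRanges(exons$start, exons$end))
    cov <- GenomicRanges::countOverlaps(cds_gr, ex_gr, type = "within")
    if (any(cov == 0L)) {
      abort(sprintf("CDS of transcript %s not contained in its exons",
                    cds$tx_id[which(cov == 0L)[1]]),
            class = "kinfuse_invariant_error")
    }
    # where a stop codon is annotated, total CDS length must be a codon multiple
    has_stop <- unique(meta$transcript_id[meta$type == "stop_codon"])
    if (length(has_stop)) {
      bad <- cds |>
        filter(.data$tx_id %in% has_stop) |>
        group_by(.data$tx_id) |>
        summarise(len = sum(.data$end - .data$start + 1L)) |>
        filter(.data$len %% 3L != 0L)
      if (nrow(bad)) {
        abort(sprintf("CDS length of transcript %s is not a multiple of 3",
                      bad$tx_id[[1]]),
              class = "kinfuse_invariant_error")
      }
    }
  }
  invisible(TRUE)
}

#' Genes whose span overlaps a genomic interval
#'
#' @param db A `gene_db`.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive interval (point query when `end`
#'   omitted).
#' @return Character vector of gene ids.
#' @export
genes_overlapping <- function(db, chrom, start, end = start) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, db$gene_gr, ignore.strand = TRUE)
  unique(db$gene_gr$gene_id[S4Vectors::subjectHits(hits)])
}

# --- per-transcript helpers --------------------------------------------------

canonical_tx <- function(db, gene_id) {
  tx <- db$transcripts$tx_id[db$transcripts$gene_id == gene_id &
                               db$transcripts$canonical]
  if (length(tx) == 0L) NA_character_ else tx[[1]]
}

# exons of a transcript in transcription order, with cumulative tx offsets
tx_exon_table <- function(db, tx_id) {
  ex <- db$exons[db$exons$tx_id == tx_id, , drop = FALSE]
  ex <- ex[order(ex$rank), , drop = FALSE]
  w <- ex$end - ex$start + 1L
  ex$tx_start <- cumsum(c(0L, w[-length(w)])) + 1L
  ex$tx_end <- cumsum(w)
  ex
}

# genomic position -> transcript coordinate (NA if not exonic in this tx)
genomic_to_tx <- function(db, tx_id, pos) {
  ex <- tx_exon_table(db, tx_id)
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0L) return(NA_integer_)
  e <- ex[hit[[1]], ]
  if (e$strand == "+") e$tx_start + (pos - e$start) else e$tx_start + (e$end - pos)
}

# spliced transcript sequence in transcription orientation (character scalar)
tx_sequence <- function(db, tx_id) {
  if (is.null(db$genome)) abort("gene_db has no genome sequence attached",
                                class = "kinfuse_input_error")
  ex <- tx_exon_table(db, tx_id)
  chrom_seq <- db$genome[[ex$chrom[[1]]]]
  pieces <- Biostrings::DNAStringSet(
    lapply(seq_len(nrow(ex)),
           function(i) Biostrings::subseq(chrom_seq, ex$start[i], ex$end[i]))
  )
  # exon table is in transcription order: on minus strand each genomic piece
  # reads 3'->5', so reverse-complement piece-wise before splicing
  if (ex$strand[[1]] == "-") pieces <- Biostrings::reverseComplement(pieces)
  paste(as.character(pieces), collapse = "")
}

# CDS interval of a transcript in transcript coordinates: c(start, end) or NULL
tx_cds_span <- function(db, tx_id) {
  cd <- db$cds[db$cds$tx_id == tx_id, , drop = FALSE]
  if (nrow(cd) == 0L) return(NULL)
  ends <- c(
    vapply(cd$start, function(p) genomic_to_tx(db, tx_id, p), integer(1)),
    vapply(cd$end, function(p) genomic_to_tx(db, tx_id, p), integer(1))
  )
  c(min(ends), max(ends))
}

# --- expression --------------------------------------------------------------

#' Load a gene-by-sample expression matrix with cohort labels
#'
#' Expects a TSV with a `gene_id` column followed by one column per sample
#' (FPKM-like non-negative values), plus a sample sheet assigning each
#' sample to a cohort (tumour type).
#'
#' @param path Expression TSV path.
#' @param sample_sheet A tibble with columns `sample_id` and `cohort`, or a
#'   path to such a TSV.
#' @return An `expression_matrix`: list with numeric matrix `mat` (genes x
#'   samples) and tibble `samples`.
#' @export
load_expression <- function(path, sample_sheet) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ))
  if (anyDuplicated(tab$gene_id)) {
    abort("duplicated gene id in expression table",
          class = "kinfuse_input_error")
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$gene_id
  if (any(mat < 0, na.rm = TRUE)) {
    abort("negative value in expression table", class = "kinfuse_input_error")
  }
  if (is.character(sample_sheet)) sample_sheet <- load_sample_sheet(sample_sheet)
  missing <- setdiff(colnames(mat), sample_sheet$sample_id)
  if (length(missing)) {
    abort(paste0("samples without cohort label: ", paste(missing, collapse = ", ")),
          class = "kinfuse_input_error")
  }
  samples <- sample_sheet[match(colnames(mat), sample_sheet$sample_id),
                          c("sample_id", "cohort")]
  structure(list(mat = mat, samples = as_tibble(samples)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, %d cohort(s)\n",
              nrow(x$mat), ncol(x$mat), dplyr::n_distinct(x$samples$cohort)))
  invisible(x)
}

#' Load a sample sheet
#'
#' @param path TSV with columns `sample_id`, `cohort` and optionally
#'   `evidence` (path to the sample's chimeric-evidence file).
#' @return A tibble.
#' @export
load_sample_sheet <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}
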
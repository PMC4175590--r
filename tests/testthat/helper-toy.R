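# Hand-specified toy annotation: seven genes on two chromosomes with known
# exon/CDS layouts, built independently of the package's simulator so that
# frame/domain expectations can be derived by hand and by the pure-R
# translation oracle below.
#
# Layout per gene (transcription order): exon 1 = pure 5'UTR; coding exons
# in whole codons; last exon = CDS tail + stop codon + 3'UTR.
#
#   A chr1 +  101-720   CDS 210 nt (70 aa)                exons 101-200, 301-420, 601-720
#   B chr1 +  5001-6000 CDS 540 nt (180 aa) kinase 20-120 exons 5001-5100, 5201-5500, 5701-6000
#   F chr1 +  8001-8700 CDS 180 nt, homolog of E
#   E chr2 +  1001-1620 CDS 180 nt
#   G chr2 +  1401-2300 CDS 180 nt, homolog of E, span overlaps E
#   D chr2 -  5001-5520 CDS 180 nt
#   C chr2 -  8001-9100 CDS 450 nt (150 aa) kinase 10-100 exons (tx order) 9001-9100, 8601-8900, 8001-8400

toy_cache <- new.env(parent = emptyenv())

GENETIC_CODE_1 <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(sapply(b, function(x) sapply(b, function(y) paste0(x, y, b))))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  paste(GENETIC_CODE_1[substring(nt, 3 * (1:n) - 2, 3 * (1:n))],
        collapse = "")
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

toy_sense_codons <- function(n, seed) {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sense <- setdiff(all64, c("TAA", "TAG", "TGA"))
  withr::with_seed(seed, sample(sense, n, replace = TRUE))
}

toy_rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# build one fixed gene; lengths are exact, nothing random but the sequence
toy_gene <- function(name, chrom, strand, offset, utr5, cds_exons, introns,
                     utr3, codons, seed) {
  n_cds_exons <- length(cds_exons)
  tail_cds <- cds_exons[n_cds_exons]
  exon_len <- c(utr5, cds_exons[-n_cds_exons], tail_cds + 3L + utr3)
  n_ex <- length(exon_len)
  seg_len <- integer(2L * n_ex - 1L)
  seg_len[seq(1, by = 2, length.out = n_ex)] <- exon_len
  seg_len[seq(2, by = 2, length.out = n_ex - 1L)] <- introns
  total <- sum(seg_len)
  gene_start <- offset; gene_end <- offset + total - 1L
  cum <- cumsum(c(0L, seg_len))
  if (strand == "+") {
    seg_start <- gene_start + cum[-length(cum)]
    seg_end <- gene_start + cum[-1L] - 1L
  } else {
    seg_end <- gene_end - cum[-length(cum)]
    seg_start <- gene_end - cum[-1L] + 1L
  }
  ex_i <- seq(1, by = 2, length.out = n_ex)
  exons <- data.frame(rank = seq_len(n_ex), len = exon_len,
                      start = seg_start[ex_i], end = seg_end[ex_i])
  cds <- do.call(rbind, lapply(2:n_ex, function(k) {
    if (k < n_ex) data.frame(start = exons$start[k], end = exons$end[k])
    else if (strand == "+") data.frame(start = exons$start[k],
                                       end = exons$start[k] + tail_cds - 1L)
    else data.frame(start = exons$end[k] - tail_cds + 1L,
                    end = exons$end[k])
  }))
  stop_codon <- if (strand == "+") {
    c(exons$start[n_ex] + tail_cds, exons$start[n_ex] + tail_cds + 2L)
  } else {
    c(exons$end[n_ex] - tail_cds - 2L, exons$end[n_ex] - tail_cds)
  }
  tx_seq <- paste0(toy_rand_dna(utr5, seed), paste(codons, collapse = ""),
                   "TAA", toy_rand_dna(exon_len[n_ex] - tail_cds - 3L, seed + 1L))
  list(name = name, gene_id = paste0("G_", name), symbol = paste0("GENE_", name),
       chrom = chrom, strand = strand, gene_start = gene_start,
       gene_end = gene_end, exons = exons, cds = cds,
       stop_codon = stop_codon, tx_seq = tx_seq, codons = codons,
       cds_len = length(codons) * 3L)
}

toy_build <- function() {
  codA <- toy_sense_codons(70, 11)
  codB <- toy_sense_codons(180, 12)
  codC <- toy_sense_codons(150, 13)
  codD <- toy_sense_codons(60, 14)
  codE <- toy_sense_codons(60, 15)
  codF <- codE; codF[c(5, 25)] <- c("GCT", "CAT")
  codG <- codE
  genes <- list(
    A = toy_gene("A", "chr1", "+", 101L, 100L, c(120L, 90L), c(100L, 180L),
                 27L, codA, 21),
    B = toy_gene("B", "chr1", "+", 5001L, 100L, c(300L, 240L), c(100L, 200L),
                 57L, codB, 23),
    F = toy_gene("F", "chr1", "+", 8001L, 100L, c(120L, 60L), c(100L, 180L),
                 137L, codF, 25),
    E = toy_gene("E", "chr2", "+", 1001L, 100L, c(120L, 60L), c(100L, 100L),
                 137L, codE, 27),
    G = toy_gene("G", "chr2", "+", 1401L, 100L, c(120L, 60L), c(300L, 180L),
                 137L, codG, 29),
    D = toy_gene("D", "chr2", "-", 5001L, 100L, c(120L, 60L), c(100L, 100L),
                 37L, codD, 31),
    C = toy_gene("C", "chr2", "-", 8001L, 100L, c(300L, 150L), c(100L, 200L),
                 247L, codC, 33)
  )

  dir <- file.path(tempdir(), "kinfuse-toy-fixture")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chrom_seq <- list(chr1 = toy_rand_dna(12000, 1), chr2 = toy_rand_dna(12000, 2))
  for (g in genes) {
    s <- chrom_seq[[g$chrom]]
    lens <- g$exons$len
    ends <- cumsum(lens); starts <- ends - lens + 1L
    for (k in seq_along(lens)) {
      piece <- substr(g$tx_seq, starts[k], ends[k])
      if (g$strand == "-") piece <- oracle_revcomp(piece)
      substr(s, g$exons$start[k], g$exons$end[k]) <- piece
    }
    chrom_seq[[g$chrom]] <- s
  }
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">chr1", chrom_seq$chr1, ">chr2", chrom_seq$chr2), fa)

  gtf <- file.path(dir, "toy.gtf")
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, start, end,
            strand, attrs)
  }
  lines <- unlist(lapply(genes, function(g) {
    tx <- paste0("T_", g$name)
    ga <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$symbol)
    ta <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                  g$gene_id, tx, g$symbol)
    c(fmt(g$chrom, "gene", g$gene_start, g$gene_end, g$strand, ga),
      fmt(g$chrom, "transcript", g$gene_start, g$gene_end, g$strand, ta),
      vapply(seq_len(nrow(g$exons)), function(k)
        fmt(g$chrom, "exon", g$exons$start[k], g$exons$end[k], g$strand, ta),
        character(1)),
      vapply(seq_len(nrow(g$cds)), function(k)
        fmt(g$chrom, "CDS", g$cds$start[k], g$cds$end[k], g$strand, ta),
        character(1)),
      fmt(g$chrom, "stop_codon", g$stop_codon[1], g$stop_codon[2], g$strand, ta))
  }))
  writeLines(lines, gtf)

  registry <- file.path(dir, "registry.tsv")
  writeLines(c("symbol\tdomain_start_aa\tdomain_end_aa\tdomain_name",
               "GENE_B\t20\t120\tkinase_catalytic",
               "GENE_C\t10\t100\tkinase_catalytic"), registry)

  db <- load_annotation(gtf, registry, fa)
  list(genes = genes, db = db, gtf = gtf, fa = fa, registry = registry,
       chrom_seq = chrom_seq, dir = dir)
}

toy <- function() {
  if (is.null(toy_cache$toy)) toy_cache$toy <- toy_build()
  toy_cache$toy
}

# --- independent oracles (no package internals) ------------------------------

# spliced transcript sequence from the helper's own gene spec
oracle_tx_seq <- function(toy, name) toy$genes[[name]]$tx_seq

# genomic -> transcript coordinate from the helper's own spec
oracle_g2t <- function(g, pos) {
  lens <- g$exons$len
  offs <- cumsum(c(0L, lens[-length(lens)]))
  for (k in seq_len(nrow(g$exons))) {
    if (pos >= g$exons$start[k] && pos <= g$exons$end[k]) {
      return(if (g$strand == "+") offs[k] + pos - g$exons$start[k] + 1L
             else offs[k] + g$exons$end[k] - pos + 1L)
    }
  }
  NA_integer_
}

# brute-force frame call: splice, fuse, translate, scan for stops
oracle_frame <- function(toy, name5, name3, bp5, bp3) {
  g5 <- toy$genes[[name5]]; g3 <- toy$genes[[name3]]
  j5 <- oracle_g2t(g5, bp5); j3 <- oracle_g2t(g3, bp3)
  s5 <- g5$tx_seq; s3 <- g3$tx_seq
  utr5_5 <- g5$exons$len[1]; utr5_3 <- g3$exons$len[1]
  cds5 <- c(utr5_5 + 1L, utr5_5 + g5$cds_len)
  cds3 <- c(utr5_3 + 1L, utr5_3 + g3$cds_len)
  ret5 <- max(0L, min(j5, cds5[2]) - cds5[1] + 1L)
  before3 <- max(0L, min(j3 - 1L, cds3[2]) - cds3[1] + 1L)
  ret3 <- if (j3 > cds3[2]) 0L else g3$cds_len - before3
  if (ret5 == 0L && ret3 == 0L) return("no_cds")
  if (ret5 == 0L) {
    return(if (before3 == 0L && ret3 == g3$cds_len) "promoter_fusion"
           else "out_of_frame")
  }
  if (ret3 == 0L) return("out_of_frame")
  fused <- paste0(substr(s5, 1, j5), substring(s3, j3))
  orf <- substring(fused, cds5[1])
  aa <- oracle_translate(substr(orf, 1, 3 * (nchar(orf) %/% 3)))
  # position of the 3' gene's own stop codon within the fused ORF
  native_stop_nt <- (j5 - cds5[1] + 1L) + (cds3[2] + 1L - j3 + 1L)
  if ((native_stop_nt - 1L) %% 3L != 0L) return("out_of_frame")
  stop_codon_idx <- (native_stop_nt - 1L) %/% 3L + 1L
  stars <- which(strsplit(aa, "")[[1]] == "*")
  if (any(stars < stop_codon_idx)) "out_of_frame" else "in_frame"
}
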
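SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a small genome of
#' multi-exon genes (first exon pure 5'UTR, coding sequence starting at
#' exon 2, coding exon lengths in whole codons, a stop codon and 3'UTR in
#' the last exon), a kinase subset with registry domain intervals, a
#' tumour cohort and a panel of normals, and a table of planted fusions
#' spanning the event classes the pipeline must separate: drivers
#' (in-frame or promoter fusions of intact kinase domains), passengers
#' (frameshifted or domain-truncating junctions), panel-of-normals
#' artifacts, a trans-splicing artifact (pair-only evidence plus extreme
#' partner expression in one carrier), and a homologous decoy pair.
#' Support counts sit above the read-support tiers for planted events and
#' below all tiers for background noise.
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param n_samples Tumour samples. Default 20.
#' @param n_normals Panel-of-normals samples. Default 10.
#' @param n_genes Genes in the synthetic annotation (>= 2). The full
#'   planted grid needs >= 36.
#' @param cohorts Cohort labels recycled over the tumour samples.
#' @param noise_pairs_per_sample Background gene pairs per sample, each
#'   with 1..`noise_max_reads` chimeric pairs (below every support tier).
#' @param noise_max_reads Maximum background read support. Default 3.
#' @param planted Planted-fusion tibble (columns `gene5_idx`, `gene3_idx`,
#'   `role`, `frame_intent`, `n_chimeric`, `n_split`, `prevalence`,
#'   `n_normals_carrying`); defaults to the full grid when `n_genes`
#'   allows, otherwise empty.
#' @param kinase_idx Indices of kinase genes; defaults match the planted
#'   grid.
#' @param homolog_pairs Two-column matrix/tibble of gene-index pairs built
#'   as homologs (the second gene's coding sequence copies the first's).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 20L, n_normals = 10L,
                       n_genes = 40L, cohorts = "cohortA",
                       noise_pairs_per_sample = 3L, noise_max_reads = 3L,
                       planted = NULL, kinase_idx = NULL,
                       homolog_pairs = NULL) {
  if (n_genes < 2L) abort("n_genes must be >= 2", class = "kinfuse_config_error")
  full_grid <- is.null(planted) && n_genes >= 36L
  if (is.null(planted)) {
    planted <- if (full_grid) default_planted() else empty_planted()
  }
  if (nrow(planted) > 0L) {
    if (any(planted$n_chimeric < 0L | planted$n_split < 0L)) {
      abort("planted support counts must be >= 0", class = "kinfuse_config_error")
    }
    if (any(planted$prevalence < 0 | planted$prevalence > 1)) {
      abort("planted prevalence must lie in [0, 1]", class = "kinfuse_config_error")
    }
    if (max(c(planted$gene5_idx, planted$gene3_idx)) > n_genes) {
      abort("planted fusion references a gene index beyond n_genes",
            class = "kinfuse_config_error")
    }
  }
  if (is.null(kinase_idx)) {
    kinase_idx <- if (full_grid) c(16L, 21L:33L) else
      unique(pmin(n_genes, seq(2L, n_genes, by = 2L)))
  }
  if (is.null(homolog_pairs)) {
    homolog_pairs <- if (full_grid) matrix(c(15L, 16L), ncol = 2) else
      matrix(integer(0), ncol = 2)
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 n_normals = as.integer(n_normals),
                 n_genes = as.integer(n_genes), cohorts = cohorts,
                 noise_pairs_per_sample = as.integer(noise_pairs_per_sample),
                 noise_max_reads = as.integer(noise_max_reads),
                 planted = planted, kinase_idx = as.integer(kinase_idx),
                 homolog_pairs = homolog_pairs),
            class = "sim_config")
}

empty_planted <- function() {
  tibble(gene5_idx = integer(0), gene3_idx = integer(0), role = character(0),
         frame_intent = character(0), n_chimeric = integer(0),
         n_split = integer(0), prevalence = numeric(0),
         n_normals_carrying = integer(0))
}

#' The default planted-fusion grid
#'
#' Six drivers (four in-frame, two promoter fusions), four passengers (two
#' frameshifted, two kinase-domain-truncating), two panel-of-normals
#' artifacts, one trans-splicing artifact and one homologous decoy, each
#' carried by 10% of a 20-sample cohort (2 samples) with read support
#' above the tiers.
#'
#' @return A tibble (see [sim_config()]).
#' @export
default_planted <- function() {
  tibble(
    gene5_idx = c(1:6, 7:10, 11:12, 13L, 15L),
    gene3_idx = c(21:26, 27:30, 31:32, 33L, 16L),
    role = c(rep("driver", 6), rep("passenger_frame", 2),
             rep("passenger_domain", 2), rep("normals_artifact", 2),
             "trans_splice", "homolog_decoy"),
    frame_intent = c(rep("in_frame", 4), rep("promoter", 2),
                     rep("out_of_frame", 2), rep("domain_truncated", 2),
                     rep("in_frame", 2), "none", "in_frame"),
    n_chimeric = c(rep(8L, 12), 20L, 8L),
    n_split = c(rep(3L, 12), 0L, 3L),
    prevalence = rep(0.1, 14),
    n_normals_carrying = c(rep(0L, 10), 5L, 5L, 0L, 0L)
  )
}

#' Generate a synthetic annotation: GTF, genome FASTA and kinase registry
#'
#' Genes have 3-6 exons on mixed strands with valid coding phases (every
#' coding exon a whole number of codons, no internal stop codons, an
#' annotated stop codon after the CDS); a configurable subset are kinases
#' with registry domain intervals (kinases fused as domain-truncation
#' passengers get an early-starting domain so an exon-3 acceptor junction
#' truncates it); homolog pairs share coding sequence by construction.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A `sim_annotation` list: file paths (`gtf`, `genome`,
#'   `registry`) and the internal gene layout tables used by
#'   [simulate_evidence()].
#' @export
simulate_annotation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(config$seed, simulate_annotation_impl(config, dir))
}

simulate_annotation_impl <- function(config, dir) {
  ng <- config$n_genes
  early_domain <- config$planted$gene3_idx[config$planted$role == "passenger_domain"]
  homolog_of <- rep(NA_integer_, ng)
  if (nrow(config$homolog_pairs) > 0L) {
    hp <- as.matrix(config$homolog_pairs)
    homolog_of[hp[, 2]] <- hp[, 1]
  }

  genes <- vector("list", ng)
  chrom_of <- ifelse(seq_len(ng) %% 2L == 1L, "chr1", "chr2")
  offsets <- c(chr1 = 2000L, chr2 = 2000L)
  for (i in seq_len(ng)) {
    src <- homolog_of[i]
    template <- if (!is.na(src)) genes[[src]] else NULL
    g <- build_sim_gene(i, chrom_of[i], offsets[[chrom_of[i]]],
                        template = template)
    offsets[[chrom_of[i]]] <- g$gene_end + sample(2000:4000, 1)
    genes[[i]] <- g
  }

  gene_tab <- purrr::map_dfr(genes, function(g) {
    tibble(idx = g$idx, gene_id = g$gene_id, symbol = g$symbol,
           chrom = g$chrom, strand = g$strand,
           start = g$gene_start, end = g$gene_end,
           cds_len = g$cds_len, prot_len = g$cds_len %/% 3L)
  })

  # registry: kinase domain intervals in protein coordinates
  reg <- purrr::map_dfr(config$kinase_idx, function(i) {
    plen <- gene_tab$prot_len[gene_tab$idx == i]
    if (i %in% early_domain) {
      tibble(symbol = gene_tab$symbol[gene_tab$idx == i],
             domain_start_aa = 10L, domain_end_aa = plen - 10L,
             domain_name = "kinase_catalytic")
    } else {
      tibble(symbol = gene_tab$symbol[gene_tab$idx == i],
             domain_start_aa = max(5L, round(0.3 * plen)),
             domain_end_aa = round(0.85 * plen),
             domain_name = "kinase_catalytic")
    }
  })

  # genome: random background, exon regions overwritten with designed seq
  chrom_len <- vapply(c("chr1", "chr2"), function(ch) {
    mx <- max(gene_tab$end[gene_tab$chrom == ch], 0L)
    mx + 2000L
  }, integer(1))
  chrom_seq <- lapply(chrom_len, random_dna)
  for (g in genes) {
    s <- chrom_seq[[g$chrom]]
    pieces <- split_by_lengths(g$tx_seq, g$exons$len)
    for (k in seq_len(nrow(g$exons))) {
      piece <- pieces[[k]]
      if (g$strand == "-") piece <- revcomp(piece)
      substr(s, g$exons$start[k], g$exons$end[k]) <- piece
    }
    chrom_seq[[g$chrom]] <- s
  }

  gtf_path <- file.path(dir, "annotation.gtf")
  genome_path <- file.path(dir, "genome.fa")
  registry_path <- file.path(dir, "kinase_registry.tsv")
  write_sim_gtf(genes, gtf_path)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(chrom_seq)), genome_path, width = 70L)
  readr::write_tsv(reg, registry_path)

  structure(list(gtf = gtf_path, genome = genome_path,
                 registry = registry_path, genes = gene_tab,
                 layouts = genes, config = config),
            class = "sim_annotation")
}

split_by_lengths <- function(s, lens) {
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  mapply(function(a, b) substr(s, a, b), starts, ends)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# one gene: exon layout in transcription order plus designed sequence
build_sim_gene <- function(idx, chrom, offset, template = NULL) {
  if (!is.null(template)) {
    exon_len <- template$exons$len
    n_ex <- length(exon_len)
    tail_cds <- template$tail_cds
    cds_codons <- template$cds_codons
    swap <- seq(1L, length(cds_codons), by = 30L)
    cds_codons[swap] <- sample(SENSE_CODONS, length(swap), replace = TRUE)
  } else {
    n_ex <- sample(3:6, 1)
    utr5 <- sample(90:180, 1)
    mid <- if (n_ex > 3L) 3L * sample(40:140, n_ex - 3L, replace = TRUE) else integer(0)
    # exon 2 always coding so every gene offers an early in-frame boundary
    e2 <- 3L * sample(40:140, 1)
    tail_cds <- 3L * sample(20:60, 1)
    utr3 <- sample(120:240, 1)
    exon_len <- c(utr5, e2, mid, tail_cds + 3L + utr3)
    cds_codons <- sample(SENSE_CODONS, (e2 + sum(mid) + tail_cds) %/% 3L,
                         replace = TRUE)
  }
  strand <- sample(c("+", "-"), 1)
  introns <- sample(200:800, n_ex - 1L, replace = TRUE)

  seg_len <- integer(2L * n_ex - 1L)
  seg_len[seq(1L, by = 2L, length.out = n_ex)] <- exon_len
  seg_len[seq(2L, by = 2L, length.out = n_ex - 1L)] <- introns
  total <- sum(seg_len)
  gene_start <- offset
  gene_end <- offset + total - 1L
  cum <- cumsum(c(0L, seg_len))
  if (strand == "+") {
    seg_start <- gene_start + cum[-length(cum)]
    seg_end <- gene_start + cum[-1L] - 1L
  } else {
    seg_end <- gene_end - cum[-length(cum)]
    seg_start <- gene_end - cum[-1L] + 1L
  }
  ex_i <- seq(1L, by = 2L, length.out = n_ex)
  exons <- tibble(rank = seq_len(n_ex), len = exon_len,
                  start = seg_start[ex_i], end = seg_end[ex_i])

  utr5_len <- exon_len[1]
  cds_len <- length(cds_codons) * 3L
  tx_seq <- paste0(random_dna(utr5_len),
                   paste(cds_codons, collapse = ""),
                   sample(c("TAA", "TAG", "TGA"), 1),
                   random_dna(exon_len[n_ex] - tail_cds - 3L))

  # CDS genomic intervals per exon (transcription order); exon 1 is UTR-only
  cds <- purrr::map_dfr(2:n_ex, function(k) {
    if (k < n_ex) {
      tibble(start = exons$start[k], end = exons$end[k])
    } else if (strand == "+") {
      tibble(start = exons$start[k], end = exons$start[k] + tail_cds - 1L)
    } else {
      tibble(start = exons$end[k] - tail_cds + 1L, end = exons$end[k])
    }
  })
  stop_codon <- if (strand == "+") {
    c(exons$start[n_ex] + tail_cds, exons$start[n_ex] + tail_cds + 2L)
  } else {
    c(exons$end[n_ex] - tail_cds - 2L, exons$end[n_ex] - tail_cds)
  }

  list(idx = idx, gene_id = sprintf("G%03d", idx),
       symbol = sprintf("GENE%03d", idx), chrom = chrom, strand = strand,
       gene_start = gene_start, gene_end = gene_end, exons = exons,
       cds = cds, stop_codon = stop_codon, tail_cds = tail_cds,
       cds_len = cds_len, cds_codons = cds_codons, tx_seq = tx_seq)
}

write_sim_gtf <- function(genes, path) {
  fmt <- function(chrom, src, type, start, end, strand, attrs) {
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, src, type, start, end, strand, attrs)
  }
  lines <- unlist(lapply(genes, function(g) {
    tx_id <- sprintf("T%03d", g$idx)
    ga <- sprintf('gene_id "%s"; gene_name "%s";', g$gene_id, g$symbol)
    ta <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                  g$gene_id, tx_id, g$symbol)
    c(fmt(g$chrom, "sim", "gene", g$gene_start, g$gene_end, g$strand, ga),
      fmt(g$chrom, "sim", "transcript", g$gene_start, g$gene_end, g$strand, ta),
      vapply(seq_len(nrow(g$exons)), function(k) {
        fmt(g$chrom, "sim", "exon", g$exons$start[k], g$exons$end[k],
            g$strand, ta)
      }, character(1)),
      vapply(seq_len(nrow(g$cds)), function(k) {
        fmt(g$chrom, "sim", "CDS", g$cds$start[k], g$cds$end[k], g$strand, ta)
      }, character(1)),
      fmt(g$chrom, "sim", "stop_codon", g$stop_codon[1], g$stop_codon[2],
          g$strand, ta))
  }))
  writeLines(lines, path)
}

# --- breakpoint selection by frame intent ------------------------------------

# transcription-wise end of exon k (donor boundary)
donor_boundary <- function(g, k) {
  if (g$strand == "+") g$exons$end[k] else g$exons$start[k]
}

# transcription-wise start of exon k (acceptor boundary)
acceptor_boundary <- function(g, k) {
  if (g$strand == "+") g$exons$start[k] else g$exons$end[k]
}

# shift a position n nt upstream in transcription direction
shift_upstream <- function(g, pos, n) {
  if (g$strand == "+") pos - n else pos + n
}

sim_breakpoints <- function(g5, g3, frame_intent) {
  switch(frame_intent,
    in_frame = list(bp5 = donor_boundary(g5, 2L),
                    bp3 = acceptor_boundary(g3, 2L),
                    bp3_exon = 2L, bp5_exon = 2L),
    promoter = list(bp5 = donor_boundary(g5, 1L),
                    bp3 = acceptor_boundary(g3, 2L),
                    bp3_exon = 2L, bp5_exon = 1L),
    out_of_frame = list(bp5 = shift_upstream(g5, donor_boundary(g5, 2L), 1L),
                        bp3 = acceptor_boundary(g3, 2L),
                        bp3_exon = 2L, bp5_exon = 2L),
    domain_truncated = list(bp5 = donor_boundary(g5, 2L),
                            bp3 = acceptor_boundary(g3, 3L),
                            bp3_exon = 3L, bp5_exon = 2L),
    none = list(bp5 = NA_integer_, bp3 = NA_integer_,
                bp3_exon = NA_integer_, bp5_exon = NA_integer_)
  )
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# split-read record(s) for a junction, randomly in the sense or antisense
# representation of the fusion transcript
sim_split_records <- function(sample_id, prefix, n, g5, g3, bp) {
  if (n == 0L) return(NULL)
  purrr::map_dfr(seq_len(n), function(k) {
    oh5 <- sample(15:35, 1); oh3 <- sample(15:35, 1)
    seg5_start <- if (g5$strand == "+") bp$bp5 - oh5 + 1L else bp$bp5
    seg3_start <- if (g3$strand == "+") bp$bp3 else bp$bp3 - oh3 + 1L
    sense <- runif(1) < 0.5
    if (sense) {
      tibble(sample_id = sample_id, read_id = sprintf("%s_split%d", prefix, k),
             kind = "split", chromA = g5$chrom, posA = seg5_start,
             strandA = g5$strand, spanA = oh5,
             chromB = g3$chrom, posB = seg3_start, strandB = g3$strand,
             spanB = oh3, donor_pos = bp$bp5, acceptor_pos = bp$bp3,
             overhangA = oh5, overhangB = oh3)
    } else {
      tibble(sample_id = sample_id, read_id = sprintf("%s_split%d", prefix, k),
             kind = "split", chromA = g3$chrom, posA = seg3_start,
             strandA = flip_strand(g3$strand), spanA = oh3,
             chromB = g5$chrom, posB = seg5_start,
             strandB = flip_strand(g5$strand), spanB = oh5,
             donor_pos = bp$bp3, acceptor_pos = bp$bp5,
             overhangA = oh3, overhangB = oh5)
    }
  })
}

# mate-pair records between coding exons of the two genes
sim_pair_records <- function(sample_id, prefix, n, g5, g3) {
  if (n == 0L) return(NULL)
  mate_in_exon <- function(g) {
    k <- 2L  # always-coding exon, comfortably longer than the mate
    w <- min(50L, g$exons$len[k])
    list(start = g$exons$start[k] +
           sample.int(g$exons$len[k] - w + 1L, 1) - 1L, w = w)
  }
  purrr::map_dfr(seq_len(n), function(k) {
    m5 <- mate_in_exon(g5); m3 <- mate_in_exon(g3)
    sense <- runif(1) < 0.5
    if (sense) {
      tibble(sample_id = sample_id, read_id = sprintf("%s_pair%d", prefix, k),
             kind = "pair", chromA = g5$chrom, posA = m5$start,
             strandA = g5$strand, spanA = m5$w,
             chromB = g3$chrom, posB = m3$start, strandB = g3$strand,
             spanB = m3$w, donor_pos = NA_integer_,
             acceptor_pos = NA_integer_, overhangA = NA_integer_,
             overhangB = NA_integer_)
    } else {
      tibble(sample_id = sample_id, read_id = sprintf("%s_pair%d", prefix, k),
             kind = "pair", chromA = g3$chrom, posA = m3$start,
             strandA = flip_strand(g3$strand), spanA = m3$w,
             chromB = g5$chrom, posB = m5$start,
             strandB = flip_strand(g5$strand), spanB = m5$w,
             donor_pos = NA_integer_, acceptor_pos = NA_integer_,
             overhangA = NA_integer_, overhangB = NA_integer_)
    }
  })
}

#' Generate per-sample chimeric evidence, expression and a normals panel
#'
#' Emits one evidence TSV per tumour sample and per normal sample, an
#' FPKM-like expression matrix with a sample sheet, and a ground-truth
#' manifest (JSON). Planted fusions appear with exactly the configured
#' support in their carrier samples; split reads carry admissible
#' overhangs and junctions consistent with the configured frame intent;
#' background noise pairs stay below every support tier; the
#' trans-splicing artifact gets pair-only evidence plus extreme partner
#' expression in its first carrier; normals artifacts recur in the
#' configured number of normal samples.
#'
#' @param sim A `sim_annotation` from [simulate_annotation()].
#' @param dir Output directory.
#' @return A list: `sample_sheet` (tibble with `sample_id`, `cohort`,
#'   `evidence`), `normals` (named evidence paths), `expression` and
#'   `sample_sheet_path`, `ground_truth` tibble, `manifest` path.
#' @export
simulate_evidence <- function(sim, dir) {
  dir.create(file.path(dir, "samples"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "normals"), recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(sim$config$seed + 1L, simulate_evidence_impl(sim, dir))
}

simulate_evidence_impl <- function(sim, dir) {
  config <- sim$config
  layouts <- sim$layouts
  samples <- sprintf("S%02d", seq_len(config$n_samples))
  normals <- sprintf("N%02d", seq_len(config$n_normals))
  cohort <- rep_len(config$cohorts, config$n_samples)

  planted <- config$planted
  planted$fusion_id <- sprintf("F%02d", seq_len(nrow(planted)))
  carriers <- purrr::map(seq_len(nrow(planted)), function(i) {
    k <- max(1L, round(planted$prevalence[i] * config$n_samples))
    sort(sample(samples, k))
  })
  normal_carriers <- purrr::map(seq_len(nrow(planted)), function(i) {
    k <- planted$n_normals_carrying[i]
    if (k > 0L) sort(sample(normals, k)) else character(0)
  })

  planted_keys <- paste(planted$gene5_idx, planted$gene3_idx)
  noise_for <- function(sample_id) {
    out <- NULL
    for (j in seq_len(config$noise_pairs_per_sample)) {
      repeat {
        pr <- sample(config$n_genes, 2L)
        if (!paste(pr[1], pr[2]) %in% planted_keys) break
      }
      n_reads <- sample.int(config$noise_max_reads, 1)
      out <- bind_rows(out, sim_pair_records(
        sample_id, sprintf("noise%d", j), n_reads,
        layouts[[pr[1]]], layouts[[pr[2]]]))
    }
    out
  }

  fusion_evidence <- function(sample_id, i) {
    g5 <- layouts[[planted$gene5_idx[i]]]
    g3 <- layouts[[planted$gene3_idx[i]]]
    bp <- sim_breakpoints(g5, g3, planted$frame_intent[i])
    bind_rows(
      sim_split_records(sample_id, planted$fusion_id[i], planted$n_split[i],
                        g5, g3, bp),
      sim_pair_records(sample_id, planted$fusion_id[i],
                       planted$n_chimeric[i], g5, g3)
    )
  }

  sample_paths <- setNames(
    file.path(dir, "samples", paste0(samples, ".tsv")), samples)
  for (s in samples) {
    ev <- noise_for(s)
    for (i in seq_len(nrow(planted))) {
      if (s %in% carriers[[i]]) ev <- bind_rows(ev, fusion_evidence(s, i))
    }
    if (is.null(ev)) ev <- empty_evidence()
    write_evidence(ev, sample_paths[[s]])
  }

  normal_paths <- setNames(
    file.path(dir, "normals", paste0(normals, ".tsv")), normals)
  for (s in normals) {
    ev <- noise_for(s)
    for (i in seq_len(nrow(planted))) {
      if (s %in% normal_carriers[[i]]) ev <- bind_rows(ev, fusion_evidence(s, i))
    }
    if (is.null(ev)) ev <- empty_evidence()
    write_evidence(ev, normal_paths[[s]])
  }

  # FPKM-like log-normal expression; the trans-splice pair is driven to an
  # extreme level in its first carrier (and mildly raised in the others)
  base <- stats::rlnorm(config$n_genes, meanlog = 3, sdlog = 0.5)
  mat <- sapply(samples, function(s) {
    base * stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 0.4)
  })
  rownames(mat) <- sim$genes$gene_id
  ts <- which(planted$role == "trans_splice")
  for (i in ts) {
    carr <- carriers[[i]]
    gidx <- c(planted$gene5_idx[i], planted$gene3_idx[i])
    if (length(carr) >= 1L) mat[gidx, carr[1]] <- mat[gidx, carr[1]] * 1000
    if (length(carr) >= 2L) {
      mat[gidx, carr[-1]] <- mat[gidx, carr[-1]] * 3
    }
  }
  expr_path <- file.path(dir, "expression.tsv")
  readr::write_tsv(
    dplyr::bind_cols(tibble(gene_id = rownames(mat)),
                     as_tibble(round(mat, 4))), expr_path)

  sheet <- tibble(sample_id = samples, cohort = cohort,
                  evidence = unname(sample_paths))
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  readr::write_tsv(sheet, sheet_path)

  gt <- planted
  gt$gene5 <- sim$genes$gene_id[match(gt$gene5_idx, sim$genes$idx)]
  gt$gene3 <- sim$genes$gene_id[match(gt$gene3_idx, sim$genes$idx)]
  bps <- purrr::map(seq_len(nrow(gt)), function(i) {
    sim_breakpoints(layouts[[gt$gene5_idx[i]]], layouts[[gt$gene3_idx[i]]],
                    gt$frame_intent[i])
  })
  gt$breakpoint5 <- purrr::map_int(bps, "bp5")
  gt$breakpoint3 <- purrr::map_int(bps, "bp3")
  gt$carriers <- purrr::map_chr(carriers, paste, collapse = ",")
  gt$normal_carriers <- purrr::map_chr(normal_carriers, paste, collapse = ",")
  gt$expected_verdict <- dplyr::case_match(
    gt$role,
    "driver" ~ "candidate_driver",
    c("passenger_frame", "passenger_domain") ~ "passenger",
    "trans_splice" ~ "artifact_or_excluded",
    .default = "excluded_before_annotation"
  )

  manifest_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(seed = config$seed, n_samples = config$n_samples,
         n_normals = config$n_normals, ground_truth = gt),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(sample_sheet = sheet, sample_sheet_path = sheet_path,
       normals = normal_paths, expression = expr_path,
       ground_truth = gt, manifest = manifest_path)
}

empty_evidence <- function() {
  tibble(sample_id = character(0), read_id = character(0), kind = character(0),
         chromA = character(0), posA = integer(0), strandA = character(0),
         spanA = integer(0), chromB = character(0), posB = integer(0),
         strandB = character(0), spanB = integer(0),
         donor_pos = integer(0), acceptor_pos = integer(0),
         overhangA = integer(0), overhangB = integer(0))
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [simulate_annotation()] then
#' [simulate_evidence()].
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return A list combining both return values (`annotation` holds the
#'   `sim_annotation`).
#' @export
simulate_cohort <- function(config, dir) {
  sim <- simulate_annotation(config, dir)
  ev <- simulate_evidence(sim, dir)
  c(list(annotation = sim), ev)
}
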
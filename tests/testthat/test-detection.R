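test_that("loci are assigned to the gene with the largest exonic overlap", {
  t <- toy(); db <- t$db
  a <- t$genes$A
  # fully inside one exon
  expect_equal(assign_locus_to_gene(db, "chr1", a$exons$start[2], 50L), "G_A")
  # intergenic space
  expect_equal(assign_locus_to_gene(db, "chr1", 2500L, 50L), NA_character_)
  # span bridging E's exon 3 and G's exon 2 territory on chr2: E exon3 is
  # 1421-1620, G exon2 is 1801-1920; a 1581-1880 span overlaps E by 40 nt
  # and G by 80 nt -> G wins (brute-force overlap count: 1581-1620 vs
  # 1801-1880)
  expect_equal(assign_locus_to_gene(db, "chr2", 1581L, 300L), "G_G")
  # and shifted so the overlap is 40 vs 10 -> E wins
  expect_equal(assign_locus_to_gene(db, "chr2", 1581L, 230L), "G_E")
})

test_that("5'->3' orientation matches the hand-enumerated 16-configuration table", {
  # columns: gene A strand, gene B strand, aligned A, aligned B, expected.
  # Sense representation (both segments read along their genes) -> AB;
  # antisense representation (both flipped) -> BA; mixed -> discordant.
  cases <- tibble::tribble(
    ~ga,  ~gb,  ~sa,  ~sb,  ~expected,
    "+",  "+",  "+",  "+",  "AB",
    "+",  "+",  "+",  "-",  NA,
    "+",  "+",  "-",  "+",  NA,
    "+",  "+",  "-",  "-",  "BA",
    "+",  "-",  "+",  "+",  NA,
    "+",  "-",  "+",  "-",  "AB",
    "+",  "-",  "-",  "+",  "BA",
    "+",  "-",  "-",  "-",  NA,
    "-",  "+",  "+",  "+",  NA,
    "-",  "+",  "+",  "-",  "BA",
    "-",  "+",  "-",  "+",  "AB",
    "-",  "+",  "-",  "-",  NA,
    "-",  "-",  "+",  "+",  "BA",
    "-",  "-",  "+",  "-",  NA,
    "-",  "-",  "-",  "+",  NA,
    "-",  "-",  "-",  "-",  "AB"
  )
  got <- orient_pair(cases$ga, cases$gb, cases$sa, cases$sb)
  expect_equal(got, cases$expected)
  # unstranded alignment leaves both orderings open -> reject as ambiguous
  expect_true(is.na(orient_pair("+", "+", "*", "+")))
  # global strand-flip symmetry: flipping every strand preserves the call
  flipped <- orient_pair(flip(cases$ga), flip(cases$gb),
                         flip(cases$sa), flip(cases$sb))
  expect_equal(flipped, cases$expected)
})

test_that("read-support tiers are boundary-tight at 5, 10 and 20 chimeric reads", {
  t <- toy(); db <- t$db
  a <- t$genes$A; b <- t$genes$B
  run <- function(n_chimeric, n_split) {
    nrow(detect_sample(ev_fusion("s1", a, b, n_chimeric, n_split), db))
  }
  expect_equal(run(5, 2), 1L)   # 2+ split reads need 5 chimeric
  expect_equal(run(4, 2), 0L)
  expect_equal(run(10, 1), 1L)  # 1 split read needs 10 chimeric
  expect_equal(run(9, 1), 0L)
  expect_equal(run(20, 0), 1L)  # no split read needs 20 chimeric
  expect_equal(run(19, 0), 0L)
})

test_that("split admissibility requires both overhangs at the minimum", {
  t <- toy(); db <- t$db
  a <- t$genes$A; b <- t$genes$B
  base <- ev_fusion("s1", a, b, n_chimeric = 10, n_split = 0)
  ok <- ev_split("s1", "x1", a, b, 420L, 5201L, oh5 = 15L, oh3 = 15L)
  short <- ev_split("s1", "x2", a, b, 420L, 5201L, oh5 = 14L, oh3 = 15L)
  # 15/15 counts as the single split read: 10 chimeric suffice
  cand <- detect_sample(dplyr::bind_rows(base, ok), db)
  expect_equal(cand$n_split, 1L)
  expect_equal(cand$n_chimeric, 10L)
  # 14/15 does not count at all: 0 split + 10 chimeric is below tier
  expect_equal(nrow(detect_sample(dplyr::bind_rows(base, short), db)), 0L)
})

test_that("a read id contributes once per pair, split outranking pair", {
  t <- toy(); db <- t$db
  a <- t$genes$A; b <- t$genes$B
  ev <- dplyr::bind_rows(
    ev_fusion("s1", a, b, n_chimeric = 5, n_split = 2),
    # same fragment seen both ways: counts once, as a split
    ev_split("s1", "dup", a, b, 420L, 5201L),
    ev_pair("s1", "dup", a, b)
  )
  cand <- detect_sample(ev, db)
  expect_equal(cand$n_split, 3L)
  expect_equal(cand$n_chimeric, 5L)
})

test_that("homologous and overlapping-homologous partners are flagged and discarded", {
  t <- toy(); db <- t$db
  cfg <- fusion_filter_config()
  # G's coding sequence is a verbatim copy of E's; F differs by two codons
  expect_true(mark_homologous(db, "G_E", "G_G", cfg))
  expect_true(mark_homologous(db, "G_E", "G_F", cfg))
  expect_false(mark_homologous(db, "G_A", "G_B", cfg))
  # a paralog table alone marks a pair homologous
  par <- tibble::tibble(a = "G_A", b = "G_B")
  expect_true(mark_homologous(db, "G_A", "G_B", cfg, paralogs = par))

  ev <- ev_fusion("s1", t$genes$E, t$genes$G, n_chimeric = 10, n_split = 2)
  kept <- detect_sample(ev, db)
  expect_equal(nrow(kept), 0L)
  flagged <- detect_sample(ev, db, keep_flagged = TRUE)
  expect_match(flagged$flags, "homologous_partners")
  expect_match(flagged$flags, "overlapping_homologs")  # spans intersect
  # E--F: homologous but genomically disjoint
  ev2 <- ev_fusion("s1", t$genes$E, t$genes$F, n_chimeric = 10, n_split = 2)
  f2 <- detect_sample(ev2, db, keep_flagged = TRUE)
  expect_match(f2$flags, "homologous_partners")
  expect_no_match(f2$flags, "overlapping_homologs")
})

test_that("identical sequences share all k-mers and random ones nearly none", {
  withr::with_seed(31, {
    s1 <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  })
  expect_equal(kinfuse:::kmer_share(s1, s1, 24L), 1)
  # brute-force k-mer set intersection on independent sequences
  k1 <- unique(substring(s1, 1:977, 24:1000))
  k2 <- unique(substring(s2, 1:977, 24:1000))
  expect_equal(kinfuse:::kmer_share(s1, s2, 24L),
               max(mean(k1 %in% k2), mean(k2 %in% k1)))
  expect_lt(kinfuse:::kmer_share(s1, s2, 24L), 0.05)
})

test_that("the modal split junction defines the breakpoint, with deterministic ties", {
  t <- toy(); db <- t$db
  a <- t$genes$A; b <- t$genes$B
  bpX <- c(420L, 5201L); bpY <- c(309L, 5201L)
  pairs10 <- ev_fusion("s1", a, b, n_chimeric = 10, n_split = 0)
  mk <- function(read, bp, oh) ev_split("s1", read, a, b, bp[1], bp[2],
                                        oh5 = oh, oh3 = oh)
  # 2 reads at X vs 1 at Y -> modal X
  cand <- detect_sample(dplyr::bind_rows(
    pairs10, mk("s1r", bpX, 20L), mk("s2r", bpX, 20L), mk("s3r", bpY, 20L)), db)
  expect_equal(c(cand$breakpoint5, cand$breakpoint3), bpX)
  # 1 vs 1, Y carries the larger total overhang -> Y
  cand <- detect_sample(dplyr::bind_rows(
    pairs10, mk("s1r", bpX, 20L), mk("s2r", bpY, 30L)), db)
  expect_equal(c(cand$breakpoint5, cand$breakpoint3), bpY)
  # full tie -> smallest genomic coordinate (Y's 309 < X's 420)
  cand <- detect_sample(dplyr::bind_rows(
    pairs10, mk("s1r", bpX, 20L), mk("s2r", bpY, 20L)), db)
  expect_equal(c(cand$breakpoint5, cand$breakpoint3), bpY)
})

test_that("support tallies match an independent brute-force count", {
  t <- toy(); db <- t$db
  gene_pool <- list(t$genes$A, t$genes$B, t$genes$C, t$genes$D)
  withr::with_seed(123, {
    rows <- list(); truth <- list()
    for (i in 1:150) {
      ij <- sample(4L, 2L)
      g5 <- gene_pool[[ij[1]]]; g3 <- gene_pool[[ij[2]]]
      kind <- sample(c("pair", "split"), 1)
      anti <- runif(1) < 0.5
      if (kind == "pair") {
        rows[[i]] <- ev_pair("s1", paste0("r", i), g5, g3, antisense = anti)
        admissible <- TRUE
      } else {
        oh <- sample(12:20, 2, replace = TRUE)
        rows[[i]] <- ev_split("s1", paste0("r", i), g5, g3,
                              toy_donor(g5, 2), toy_acceptor(g3, 2),
                              oh5 = oh[1], oh3 = oh[2], antisense = anti)
        admissible <- all(oh >= 15L)
      }
      truth[[i]] <- tibble::tibble(gene5 = g5$gene_id, gene3 = g3$gene_id,
                                   kind = kind, admissible = admissible)
    }
  })
  got <- detect_sample(dplyr::bind_rows(rows), db, keep_flagged = TRUE)
  expected <- dplyr::bind_rows(truth) |>
    dplyr::filter(.data$kind == "pair" | .data$admissible) |>
    dplyr::count(.data$gene5, .data$gene3, .data$kind) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n",
                       values_fill = 0L)
  for (col in c("pair", "split")) {
    if (!col %in% names(expected)) expected[[col]] <- 0L
  }
  joined <- dplyr::left_join(expected, got, by = c("gene5", "gene3"))
  expect_equal(joined$n_chimeric, joined$pair)
  expect_equal(joined$n_split, joined$split)
})

test_that("adding supporting evidence never drops a retained candidate", {
  t <- toy(); db <- t$db
  a <- t$genes$A; b <- t$genes$B
  base <- ev_fusion("s1", a, b, n_chimeric = 5, n_split = 2)
  expect_equal(nrow(detect_sample(base, db)), 1L)
  for (extra in list(
    ev_pair("s1", "mono1", a, b),
    ev_split("s1", "mono2", a, b, 420L, 5201L),
    ev_fusion("s1", a, b, 3, 2, prefix = "mono3"))) {
    expect_equal(nrow(detect_sample(dplyr::bind_rows(base, extra), db)), 1L)
  }
})

test_that("evidence from mixed samples is refused", {
  t <- toy()
  ev <- dplyr::bind_rows(ev_pair("s1", "r1", t$genes$A, t$genes$B),
                         ev_pair("s2", "r2", t$genes$A, t$genes$B))
  expect_error(detect_sample(ev, t$db), class = "kinfuse_input_error")
})

test_that("strand-discordant observations are dropped and counted", {
  t <- toy(); db <- t$db
  ev <- ev_pair("s1", "r1", t$genes$A, t$genes$B)
  ev$strandA <- "-"  # sense on B, antisense on A: no consistent ordering
  cand <- detect_sample(ev, db, keep_flagged = TRUE)
  expect_equal(nrow(cand), 0L)
  expect_equal(attr(cand, "dropped")[["strand_discordant"]], 1L)
})
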
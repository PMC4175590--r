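# Breakpoint landmarks on the toy genes (transcription-orientation
# boundaries): A exon2 donor = 420 (+), exon1 donor = 200; B exon2
# acceptor = 5201, exon3 acceptor = 5701; C (minus strand) exon2
# acceptor = genomic end 8900.

test_that("junctions classify as exon-exon, exon-cryptic or unresolved", {
  t <- toy(); db <- t$db
  expect_equal(classify_junction(db, "G_A", "G_B", 420L, 5201L, 3L),
               "exon_exon")
  # 5' breakpoint mid-exon, 3' at a boundary
  expect_equal(classify_junction(db, "G_A", "G_B", 410L, 5201L, 3L),
               "exon_cryptic")
  # 5' breakpoint mid-intron also counts as cryptic on that side
  expect_equal(classify_junction(db, "G_A", "G_B", 450L, 5201L, 3L),
               "exon_cryptic")
  # no split support -> no base-resolution junction
  expect_equal(classify_junction(db, "G_A", "G_B", NA_integer_, NA_integer_, 0L),
               "unresolved")
  # neither side at a boundary
  expect_equal(classify_junction(db, "G_A", "G_B", 410L, 5210L, 3L),
               "unresolved")
  # minus-strand acceptor boundary is the genomic end of the exon
  expect_equal(classify_junction(db, "G_A", "G_C", 420L, 8900L, 2L),
               "exon_exon")
})

test_that("fusion transcripts concatenate exonic sequence across strands", {
  t <- toy(); db <- t$db
  ft <- build_fusion_transcript(db, "G_A", "G_B", 420L, 5201L)
  s5 <- oracle_tx_seq(t, "A"); s3 <- oracle_tx_seq(t, "B")
  expect_equal(ft$seq, paste0(substr(s5, 1, 220), substring(s3, 101)))
  expect_equal(ft$retained5_cds, 120L)
  expect_equal(ft$cds3_before, 0L)
  # minus-strand 3' partner: spliced, reverse-complemented sequence
  ftc <- build_fusion_transcript(db, "G_A", "G_C", 420L, 8900L)
  sC <- oracle_tx_seq(t, "C")
  expect_equal(ftc$seq, paste0(substr(s5, 1, 220), substring(sC, 101)))
  # breakpoint in an intron of the canonical transcript aborts construction
  expect_warning(ft_bad <- build_fusion_transcript(db, "G_A", "G_B", 450L, 5201L),
                 "outside")
  expect_null(ft_bad)
})

test_that("frame prediction reproduces the canonical configurations", {
  t <- toy(); db <- t$db
  frame_of <- function(g5, g3, bp5, bp3) {
    predict_frame(build_fusion_transcript(db, g5, g3, bp5, bp3))
  }
  # whole-codon junction: 120 retained coding nt join CDS phase 0
  f <- frame_of("G_A", "G_B", 420L, 5201L)
  expect_equal(f$frame_status, "in_frame")
  expect_equal(f$partner_contrib_aa, 40L)
  # partner contributing 9 coding nt -> in frame, 3 aa
  f9 <- frame_of("G_A", "G_B", 309L, 5201L)
  expect_equal(f9$frame_status, "in_frame")
  expect_equal(f9$partner_contrib_aa, 3L)
  # 10 coding nt -> frameshift
  expect_equal(frame_of("G_A", "G_B", 310L, 5201L)$frame_status, "out_of_frame")
  # 5'UTR-only partner with the complete downstream CDS -> promoter fusion
  fp <- frame_of("G_A", "G_B", 200L, 5201L)
  expect_equal(fp$frame_status, "promoter_fusion")
  expect_equal(fp$partner_contrib_aa, 0L)
  # 5'UTR-only partner but truncated downstream CDS -> not a promoter fusion
  expect_equal(frame_of("G_A", "G_B", 200L, 5701L)$frame_status, "out_of_frame")
  # junction in both 5'UTRs -> still a promoter fusion (full CDS intact)
  expect_equal(frame_of("G_A", "G_B", 200L, 5050L)$frame_status,
               "promoter_fusion")
  # 5' breakpoint in the 3'UTR: the 5' gene's own stop intervenes
  expect_equal(frame_of("G_A", "G_B", 700L, 5201L)$frame_status, "out_of_frame")
  # neither side coding
  expect_equal(frame_of("G_A", "G_B", 200L, 5990L)$frame_status, "no_cds")
})

test_that("frame prediction agrees with direct translation on a breakpoint grid", {
  t <- toy(); db <- t$db
  # every combination of 5' breakpoints on A and 3' breakpoints on B/C,
  # mixing boundaries, in-exon offsets and UTR positions
  bp5s <- c(200L, 301L:312L, 420L, 601L, 650L, 700L)
  cases <- rbind(
    expand.grid(g3 = "G_B", bp3 = c(5050L, 5201L, 5202L, 5203L, 5250L, 5701L,
                                    5800L, 5990L), stringsAsFactors = FALSE),
    expand.grid(g3 = "G_C", bp3 = c(9050L, 8900L, 8899L, 8898L, 8700L, 8400L,
                                    8300L), stringsAsFactors = FALSE)
  )
  n_checked <- 0L
  for (bp5 in bp5s) {
    for (k in seq_len(nrow(cases))) {
      g3 <- cases$g3[k]; bp3 <- cases$bp3[k]
      ft <- build_fusion_transcript(db, "G_A", g3, bp5, bp3)
      got <- predict_frame(ft)$frame_status
      name3 <- sub("G_", "", g3)
      expected <- oracle_frame(t, "A", name3, bp5, bp3)
      expect_equal(got, expected,
                   info = sprintf("A:%d -> %s:%d", bp5, g3, bp3))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("kinase-domain conservation follows the breakpoint position", {
  t <- toy(); db <- t$db
  # B: 180 aa, domain 20-120. Acceptor at CDS start -> whole domain kept
  ft <- build_fusion_transcript(db, "G_A", "G_B", 420L, 5201L)
  expect_equal(check_kinase_domain(ft, 20L, 120L, "3"), "complete")
  # acceptor at exon 3 (first retained native residue 101) -> truncated
  ft2 <- build_fusion_transcript(db, "G_A", "G_B", 420L, 5701L)
  expect_equal(check_kinase_domain(ft2, 20L, 120L, "3"), "truncated")
  # same junction but a domain ending before residue 101 -> absent
  expect_equal(check_kinase_domain(ft2, 20L, 90L, "3"), "absent")
  # kinase as the 5' partner retaining 100 residues of 180
  ft3 <- build_fusion_transcript(db, "G_B", "G_A", 5500L, 301L)
  expect_equal(check_kinase_domain(ft3, 20L, 120L, "5"), "truncated")
  expect_equal(check_kinase_domain(ft3, 20L, 100L, "5"), "complete")
  # kinase as 5' partner contributing only its 5'UTR -> domain absent
  ft4 <- build_fusion_transcript(db, "G_B", "G_A", 5100L, 301L)
  expect_equal(check_kinase_domain(ft4, 20L, 120L, "5"), "absent")
  # missing registry coordinates degrade to absent with a warning
  expect_warning(st <- check_kinase_domain(ft, NA_integer_, NA_integer_, "3"))
  expect_equal(st, "absent")
})

test_that("moving the 3' breakpoint upstream never degrades domain status", {
  t <- toy(); db <- t$db
  rank_of <- c(absent = 0L, truncated = 1L, complete = 2L)
  # acceptor positions from deep in the gene towards the CDS start
  bps <- c(8300L, 8400L, 8700L, 8898L, 8899L, 8900L, 9050L)
  status <- vapply(bps, function(bp3) {
    ft <- build_fusion_transcript(db, "G_A", "G_C", 420L, bp3)
    check_kinase_domain(ft, 10L, 100L, "3")
  }, character(1))
  expect_true(all(diff(rank_of[status]) >= 0L))
  expect_equal(status[[length(status)]], "complete")
})
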
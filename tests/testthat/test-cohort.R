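cand <- function(sample, g5, g3, flags = "", cohort = "co") {
  tibble::tibble(sample_id = sample, gene5 = g5, gene3 = g3,
                 n_chimeric = 10L, n_split = 2L,
                 breakpoint5 = NA_integer_, breakpoint3 = NA_integer_,
                 flags = flags, cohort = cohort)
}

many <- function(n, g5, g3, from = 1L) {
  dplyr::bind_rows(lapply(seq_len(n), function(i)
    cand(sprintf("s%03d", from + i - 1L), g5, g3)))
}

test_that("the >95% prevalence clause flags with a strict inequality", {
  flagged96 <- flag_improbable(many(96, "P1", "P2"), n_samples = 100)
  expect_true(all(grepl("improbable_frequency", flagged96$flags)))
  flagged95 <- flag_improbable(many(95, "P1", "P2"), n_samples = 100)
  expect_false(any(grepl("improbable_frequency", flagged95$flags)))
})

test_that("the dual-partner promiscuity clause flags at >25% of samples", {
  build <- function(n_carrier) dplyr::bind_rows(
    many(n_carrier, "P1", "P2"),
    cand("s001", "P1", "X"),   # second distinct pair for P1
    cand("s001", "P2", "Y")    # second distinct pair for P2
  )
  f26 <- flag_improbable(build(26), n_samples = 100)
  expect_true(all(grepl("promiscuous_partners",
                        f26$flags[f26$gene5 == "P1" & f26$gene3 == "P2"])))
  f25 <- flag_improbable(build(25), n_samples = 100)
  expect_false(any(grepl("promiscuous_partners", f25$flags)))
  # a partner with a single pair is never promiscuous, however prevalent
  solo <- flag_improbable(many(40, "P1", "P2"), n_samples = 100)
  expect_false(any(grepl("promiscuous_partners", solo$flags)))
})

test_that("a single-sample cohort flags its only fusion (1/1 > 0.95)", {
  f <- flag_improbable(cand("s1", "A", "B"), n_samples = 1)
  expect_match(f$flags, "improbable_frequency")
})

test_that("the normals panel excludes at 5 carrying normals and keeps at 4", {
  calls <- dplyr::bind_rows(cand("s1", "A", "K1"), cand("s1", "B", "K2"),
                            cand("s2", "C", "K3"))
  panel <- tibble::tibble(gene5 = c("A", "B"), gene3 = c("K1", "K2"),
                          n_normal_samples = c(5L, 4L))
  out <- apply_normals_panel(calls, panel)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_setequal(paste(out$gene5, out$gene3), c("B K2", "C K3"))
  # empty panel leaves the callset unchanged
  empty <- tibble::tibble(gene5 = character(0), gene3 = character(0),
                          n_normal_samples = integer(0))
  expect_equal(nrow(apply_normals_panel(calls, empty)), 3L)
})

test_that("a panel is built from normal evidence by the same procedure", {
  t <- toy(); db <- t$db
  dir <- withr::local_tempdir()
  paths <- vapply(1:3, function(i) {
    p <- file.path(dir, sprintf("n%d.tsv", i))
    ev <- ev_fusion(sprintf("n%d", i), t$genes$A, t$genes$B, 8, 3)
    if (i < 3) ev <- dplyr::bind_rows(
      ev, ev_fusion(sprintf("n%d", i), t$genes$D, t$genes$C, 2, 0,
                    prefix = "weak"))  # below tier: never detected
    write_evidence(ev, p)
    p
  }, character(1))
  panel <- build_normals_panel(paths, db)
  expect_equal(nrow(panel), 1L)
  expect_equal(panel$n_normal_samples, 3L)
  expect_equal(c(panel$gene5, panel$gene3), c("G_A", "G_B"))
})

test_that("recurrence pools across cohorts and respects the counting mode", {
  t <- toy(); db <- t$db  # kinases: G_B, G_C
  calls <- dplyr::bind_rows(
    cand("s1", "G_A", "G_B", cohort = "coA"),   # same pair, two cohorts
    cand("s2", "G_A", "G_B", cohort = "coB"),
    cand("s3", "G_D", "G_C", cohort = "coA"),   # kinase pair, singleton
    cand("s4", "G_A", "G_D", cohort = "coA"),   # non-kinase pair
    cand("s5", "G_A", "G_D", cohort = "coB")
  )
  rec <- select_recurrent_kinase(calls, db)
  expect_setequal(unique(paste(rec$gene5, rec$gene3)), "G_A G_B")
  expect_equal(unique(rec$recurrence_n), 2L)

  # kinase mode aggregates one kinase's fusions across partners
  calls2 <- dplyr::bind_rows(cand("s1", "G_A", "G_B"),
                             cand("s2", "G_D", "G_B"))
  expect_equal(nrow(select_recurrent_kinase(calls2, db, mode = "kinase")), 2L)
  expect_equal(nrow(select_recurrent_kinase(calls2, db, mode = "pair")), 0L)

  # flagged candidates neither count nor pass through
  calls3 <- dplyr::bind_rows(cand("s1", "G_A", "G_B"),
                             cand("s2", "G_A", "G_B",
                                  flags = "improbable_frequency"))
  expect_equal(nrow(select_recurrent_kinase(calls3, db)), 0L)
})

test_that("raising the recurrence threshold never adds fusions", {
  t <- toy(); db <- t$db
  withr::with_seed(11, {
    calls <- dplyr::bind_rows(lapply(1:40, function(i) {
      cand(sprintf("s%02d", sample(12, 1)), "G_A",
           sample(c("G_B", "G_C"), 1))
    }))
  })
  prev <- Inf
  for (k in 1:6) {
    n <- nrow(select_recurrent_kinase(
      calls, db, fusion_filter_config(recurrence_min = k)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("normals removal and improbable flagging commute", {
  calls <- dplyr::bind_rows(
    many(97, "A", "K1"),          # improbable-frequency pair
    many(10, "B", "K2"),          # normals-panel pair
    many(3, "C", "K3")            # clean pair
  )
  panel <- tibble::tibble(gene5 = "B", gene3 = "K2", n_normal_samples = 7L)
  ab <- apply_normals_panel(flag_improbable(calls, 100), panel)
  ba <- flag_improbable(apply_normals_panel(calls, panel), 100)
  expect_equal(dplyr::arrange(as.data.frame(ab), sample_id, gene5),
               dplyr::arrange(as.data.frame(ba), sample_id, gene5),
               ignore_attr = TRUE)
})

test_that("cohort summaries report burden and recurrence percentages exactly", {
  t <- toy(); db <- t$db
  sheet <- tibble::tibble(sample_id = sprintf("s%03d", 1:10), cohort = "co")
  calls <- dplyr::bind_rows(cand("s001", "G_A", "G_B"),
                            cand("s002", "G_A", "G_B"),
                            cand("s003", "G_D", "G_C"))
  s <- cohort_summary(calls, sheet, recurrent = NULL, db)
  expect_equal(s$n_kinase_fusions, 3L)
  expect_equal(s$fusions_per_sample, 0.3)

  # planted recurrent fusions in 13 of 100 samples -> exactly 13%
  sheet100 <- tibble::tibble(sample_id = sprintf("s%03d", 1:100), cohort = "co")
  rec <- many(13, "G_A", "G_B")
  rec$kinase_gene <- "G_B"; rec$recurrence_n <- 13L
  s100 <- cohort_summary(rec, sheet100, recurrent = rec, db)
  expect_equal(s100$pct_samples_recurrent, 13)

  # empty cohort: zeros, no division error
  s0 <- cohort_summary(cand("x", "a", "b")[0, ], sheet, NULL, db)
  expect_equal(s0$n_kinase_fusions, 0L)
  expect_equal(s0$fusions_per_sample, 0)
  expect_equal(s0$pct_samples_recurrent, 0)
})
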
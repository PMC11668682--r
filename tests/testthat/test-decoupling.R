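# helper: trajectories table for hand-set enrichments
traj_row <- function(variant, sel, ref_rank, sel_rank, e, ref_f = 0.01,
                     sel_f = 0.01, missing = FALSE) {
  data.frame(variant = variant, reference = "R3_DEX_CD3",
             selected = sel, ref_rank = ref_rank, ref_frequency = ref_f,
             sel_rank = sel_rank, sel_frequency = sel_f,
             missing = missing, delta_rank = sel_rank - ref_rank,
             log2_enrichment = e, stringsAsFactors = FALSE)
}

test_that("D is the enrichment difference and ordering is
          deterministic", {
  tr <- rbind(
    traj_row("FAQAT", "R3_PEP_GFPhigh", 10, 300, -3),
    traj_row("FAQAT", "R3_BLINA_GFPhigh", 10, 9, 0),
    traj_row("FSQST", "R3_PEP_GFPhigh", 5, 6, -0.5),
    traj_row("FSQST", "R3_BLINA_GFPhigh", 5, 5, -0.5))
  s <- score_decoupling(tr)
  expect_equal(s$D[s$variant == "FAQAT"], 3)
  expect_equal(s$D[s$variant == "FSQST"], 0)
  expect_equal(s$variant, c("FAQAT", "FSQST"))  # sorted by D desc
})

test_that("candidate rules: peptide enrichment or blinatumomab
          de-enrichment disqualify", {
  tr <- rbind(
    # enriched under peptide: excluded regardless of BLINA behaviour
    traj_row("FAQAT", "R3_PEP_GFPhigh", 50, 10, +2),
    traj_row("FAQAT", "R3_BLINA_GFPhigh", 50, 10, +2),
    # de-enriched in both: 'absence of de-enrichment' violated
    traj_row("FCQCT", "R3_PEP_GFPhigh", 40, 300, -4),
    traj_row("FCQCT", "R3_BLINA_GFPhigh", 40, 350, -4),
    # textbook decoupled variant
    traj_row("FDQDT", "R3_PEP_GFPhigh", 30, 290, -4),
    traj_row("FDQDT", "R3_BLINA_GFPhigh", 30, 25, 0.1))
  called <- call_candidates(score_decoupling(tr),
                            selection_thresholds(),
                            library_size = 400)
  expect_equal(called$variant, "FDQDT")
  expect_equal(called$final_rank, 1L)
  # rank improvement in BLINA does not disqualify
  tr2 <- rbind(tr,
               traj_row("FHQHT", "R3_PEP_GFPhigh", 60, 400, -4),
               traj_row("FHQHT", "R3_BLINA_GFPhigh", 60, 2, 0.2))
  called2 <- call_candidates(score_decoupling(tr2),
                             selection_thresholds(), library_size = 400)
  expect_true("FHQHT" %in% called2$variant)
  # the backbone is excluded by default
  tr3 <- rbind(tr,
               traj_row("FEQWT", "R3_PEP_GFPhigh", 1, 200, -5,
                        ref_f = 0.4),
               traj_row("FEQWT", "R3_BLINA_GFPhigh", 1, 1, 0,
                        ref_f = 0.4))
  called3 <- call_candidates(score_decoupling(tr3),
                             selection_thresholds(), library_size = 400)
  expect_false("FEQWT" %in% called3$variant)
  expect_true("FEQWT" %in%
                call_candidates(score_decoupling(tr3),
                                selection_thresholds(),
                                library_size = 400,
                                exclude_variants = character(0))$variant)
})

test_that("monotonicity: raising a variant's BLINA frequency never
          lowers its D or its candidate rank", {
  base <- c(FAQAT = 500L, FSQST = 300L, FTQTT = 150L, FGQGT = 50L)
  mk <- function(blina_faqat) {
    counts <- cbind(R3_DEX_CD3 = base,
                    R3_PEP_GFPhigh = c(5L, 250L, 120L, 40L),
                    R3_BLINA_GFPhigh = c(blina_faqat, 280L, 140L, 45L))
    score_decoupling(build_trajectories(
      rank_table_from_counts(counts), "R3_DEX_CD3",
      c("R3_PEP_GFPhigh", "R3_BLINA_GFPhigh")))
  }
  lo <- mk(100L); hi <- mk(600L)
  expect_gt(hi$D[hi$variant == "FAQAT"], lo$D[lo$variant == "FAQAT"])
  expect_lte(which(hi$variant == "FAQAT"), which(lo$variant == "FAQAT"))
})

test_that("scoring is invariant to trajectory row order", {
  cfg <- small_screen_config()
  res <- run_screen_pipeline(cfg, seed = 6, dir = NULL, via_reads = FALSE)
  tr <- res$trajectories
  shuffled <- tr[withr::with_seed(1, sample(nrow(tr))), ]
  expect_equal(score_decoupling(shuffled), res$scored)
})

test_that("rank improvement report normalises by the improvement
          ceiling", {
  counts <- cbind(R1_DEX_CD3 = c(FAQAT = 900L, FSQST = 500L, FTQTT = 100L),
                  R3_PEP_GFPhigh = c(FAQAT = 900L, FSQST = 500L,
                                     FTQTT = 950L))
  rt <- rank_table_from_counts(counts)
  rep <- rank_improvement_report(rt, c("R1_DEX_CD3", "R3_PEP_GFPhigh"))
  expect_equal(rep$improvement_R3_PEP_GFPhigh[rep$start_rank == 1], 0)
  r3 <- rep[rep$variant == "FTQTT", ]
  expect_equal(r3$start_rank, 3L)
  expect_equal(r3$improvement_R3_PEP_GFPhigh, 1)  # rank 3 -> rank 1
  # range property over a simulated screen
  res <- run_screen_pipeline(small_screen_config(), seed = 9,
                             dir = NULL, via_reads = FALSE)
  cols <- grep("^R3_", unique(res$rank_table$column), value = TRUE)
  rep2 <- rank_improvement_report(res$rank_table, cols)
  imp <- unlist(rep2[grep("^improvement_", names(rep2))])
  expect_true(all(imp >= -1 & imp <= 1))
})

test_that("planted variants out-score ordinary variants in >=95% of 20
          seeds", {
  cfg <- screen_config()
  wins <- vapply(1:20, function(seed) {
    res <- run_screen_pipeline(cfg, seed = seed, dir = NULL,
                               via_reads = FALSE)
    s <- res$scored
    pl <- s$variant %in% res$planted
    ord <- !pl & s$variant != cfg$backbone
    mean(s$D[pl]) > mean(s$D[ord])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
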
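tpl <- default_amplicon_template()

# build a read carrying the given motif-region nucleotides (and optional
# flank edits) from the template
mutate_read <- function(motif_nt = NULL, edit = NULL) {
  r <- tpl$template
  if (!is.null(motif_nt)) {
    substr(r, tpl$motif_span[1] + 1, tpl$motif_span[2]) <- motif_nt
  }
  if (!is.null(edit)) for (e in edit) substr(r, e[[1]], e[[1]]) <- e[[2]]
  r
}

test_that("error-free reads parse to their variant; the backbone read
          gives FEQWT", {
  calls <- parse_reads(c(r1 = tpl$template))
  expect_true(calls$pass)
  expect_equal(calls$motif, "FEQWT")
  expect_equal(calls$aa_1, "E")
  expect_equal(calls$aa_3, "W")
  # a GGG/GGT double substitution reads back as FGQGT
  r <- mutate_read("TTTGGGCAGGGTACC")
  calls2 <- parse_reads(c(x = r))
  expect_equal(calls2$motif, "FGQGT")
})

test_that("the cleaning rule assigns exactly one primary failure reason
          in fixed order", {
  s <- tpl$motif_span[1]
  reads <- c(
    anchor2 = mutate_read(edit = list(list(s - 1L, "N"),
                                      list(s - 3L, "N"))),
    offtarget = mutate_read("TTAGAACAGTGGACC"),       # codon 0 TTT->TTA
    stopc = mutate_read("TTTTAGCAGTGGACC"),           # codon 1 -> TAG
    ambig = mutate_read("TTTGANCAGTGGACC"),           # N in codon 1
    # anchor failure dominates an off-target mutation
    both = mutate_read("TTAGAACAGTGGACC",
                       edit = list(list(s - 1L, "G"), list(s - 3L, "T"),
                                   list(s - 5L, "T"))))
  calls <- parse_reads(reads, max_anchor_mismatches = 1)
  expect_false(any(calls$pass))
  expect_equal(calls$reason[calls$read_id == "anchor2"],
               "anchor_mismatch")
  expect_equal(calls$reason[calls$read_id == "offtarget"],
               "off_target_mutation")
  expect_equal(calls$reason[calls$read_id == "stopc"], "stop_codon")
  expect_equal(calls$reason[calls$read_id == "ambig"], "ambiguous_base")
  expect_equal(calls$reason[calls$read_id == "both"], "anchor_mismatch")
  # a single anchor mismatch is tolerated at the default setting
  one <- parse_reads(c(a1 = mutate_read(edit = list(list(s - 1L, "N")))))
  expect_true(one$pass)
})

test_that("every read is pass or carries exactly one reason (parsed
          simulator output with errors)", {
  cts <- matrix(as.integer(rep(200, 5)), ncol = 1,
                dimnames = list(c("FEQWT", "FGQGT", "FAQCT", "FWQWT",
                                  "FKQST"), "R1_DEX_CD3"))
  sets <- emit_reads(cts, dir = NULL, error_rate = 0.02, seed = 3)
  calls <- parse_reads(sets[[1]])
  expect_equal(nrow(calls), 1000L)
  expect_true(all(xor(calls$pass, !is.na(calls$reason))))
  expect_true(all(stats::na.omit(calls$reason) %in%
                    aedscreen:::FAIL_REASONS))
})

test_that("counting, frequency and deterministic tie-ranked ordering", {
  calls <- make_calls(c(rep("FAQAT", 5), rep("FSQST", 3), rep("FCQCT", 2)))
  rt <- count_and_rank(calls, column = "R1_DEX_CD3")
  expect_equal(rt$frequency, c(0.5, 0.3, 0.2))
  expect_equal(rt$rank, 1:3)
  expect_equal(rt$variant[1], "FAQAT")
  # ties break lexicographically
  calls2 <- make_calls(c(rep("FYQYT", 4), rep("FAQAT", 4), rep("FMQMT", 2)))
  rt2 <- count_and_rank(calls2, column = "R2_PEP_GFPhigh")
  expect_equal(rt2$variant[rt2$rank <= 2], c("FAQAT", "FYQYT"))
  expect_equal(rt2$population[1], "PEP_GFPhigh")
  expect_equal(rt2$round[1], 2L)
  # column with zero passing calls is flagged empty
  bad <- make_calls("FAQAT"); bad$pass <- FALSE
  rt3 <- count_and_rank(list(R1_A = calls, R1_B = bad))
  expect_equal(attr(rt3, "empty_columns"), "R1_B")
})

test_that("zero-error simulator output reproduces sorted-cell
          frequencies exactly", {
  cfg <- screen_config(n_cells = 1e4, error_rate = 0, read_depth = 1e5)
  res <- run_screen_pipeline(cfg, seed = 8, dir = NULL)
  for (col in unique(res$rank_table$column)) {
    rt <- res$rank_table[res$rank_table$column == col, ]
    cells <- res$screen$counts[, col]
    cells <- cells[cells > 0]
    expect_setequal(rt$variant, names(cells))
    expect_equal(rt$count, unname(cells[rt$variant]))
    expect_equal(sum(rt$frequency), 1, tolerance = 1e-9)
    expect_equal(sort(rt$rank), seq_len(nrow(rt)))  # valid permutation
  }
})

test_that("trajectories: deltas, enrichment, and the missing-variant
          closed form", {
  counts <- matrix(c(500L, 300L, 200L,
                     500L, 300L, 0L), ncol = 2,
                   dimnames = list(c("FAQAT", "FSQST", "FTQTT"),
                                   c("R3_DEX_CD3", "R3_PEP_GFPhigh")))
  rt <- rank_table_from_counts(counts)
  tr <- build_trajectories(rt, "R3_DEX_CD3", "R3_PEP_GFPhigh")
  a <- tr[tr$variant == "FAQAT", ]
  expect_equal(a$delta_rank, 0L)
  # f_ref = f_sel = 500/1000 vs 500/800: not equal; check the equal case
  expect_equal(tr$log2_enrichment[tr$variant == "FAQAT"],
               log2((500 / 800 + 1 / 1600) / (0.5 + 1 / 1600)))
  t3 <- tr[tr$variant == "FTQTT", ]
  expect_true(t3$missing)
  eps <- 1 / (2 * 800)
  expect_equal(t3$log2_enrichment, log2(eps / (0.2 + eps)))
  expect_equal(t3$delta_rank, (2L + 1L) - 3L)  # effective bottom rank
  # identical columns give all-zero deltas and enrichments
  c2 <- counts[, c(1, 1)]
  colnames(c2) <- c("R3_DEX_CD3", "R3_BLINA_GFPhigh")
  tr2 <- build_trajectories(rank_table_from_counts(c2), "R3_DEX_CD3",
                            "R3_BLINA_GFPhigh")
  expect_true(all(tr2$delta_rank == 0))
  expect_true(all(tr2$log2_enrichment == 0))
  expect_error(build_trajectories(rt, "R9_NOPE", "R3_PEP_GFPhigh"),
               "reference")
})
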
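design400 <- design_library("FGQGT", c(1, 3), "NNK")

test_that("phenotype assignment is deterministic and plants the stated
          number of decoupled variants", {
  cfg <- screen_config()
  a <- assign_phenotypes(design400, cfg, seed = 11)
  b <- assign_phenotypes(design400, cfg, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, assign_phenotypes(design400, cfg, seed = 12)))
  expect_equal(sum(a$planted), 5L)
  expect_true(all(a$is_decoupled[a$planted]))
  expect_true(a$is_backbone[a$variant == "FEQWT"])
  expect_false(any(a$planted & a$is_backbone))
  expect_true(all(a$expression >= 0 & a$expression <= 1))
  expect_error(assign_phenotypes(design400,
                                 screen_config(n_planted = 500)),
               "planted")
})

test_that("ordinary-variant response correlation tracks the configured
          copula value", {
  cfg <- screen_config()
  cors <- vapply(1:20, function(seed) {
    ph <- assign_phenotypes(design400, cfg, seed)
    ord <- !ph$planted & !ph$is_backbone
    stats::cor(ph$peptide_response[ord], ph$blina_response[ord])
  }, numeric(1))
  expect_true(all(abs(cors - cfg$response_cor) <= 0.15))
})

test_that("sorting conserves cells and respects degenerate
          probabilities", {
  cfg <- screen_config()
  ph <- assign_phenotypes(design400, cfg, seed = 3)
  input <- stats::setNames(rep(1000L, nrow(ph)), ph$variant)
  for (g in c("DEX_CD3", "PEP_GFPhigh", "BLINA_GFPlow")) {
    for (seed in c(1, 99)) {
      s <- simulate_sort(input, gate_spec(g, round = 1), ph, cfg, seed)
      expect_true(all(s$pass + s$fail == input))
      expect_true(all(s$pass >= 0 & s$fail >= 0))
    }
  }
  # expression 0 passes nothing through any expression-dependent gate
  ph0 <- ph; ph0$expression[] <- 0
  for (g in c("DEX_CD3", "PEP_GFPhigh", "BLINA_GFPhigh")) {
    s <- simulate_sort(input, gate_spec(g, round = 1), ph0, cfg, 1)
    expect_true(all(s$pass == 0L))
  }
  # pi = 1 passes everything
  ph1 <- ph; ph1$expression[] <- 1; ph1$dextramer_binding[] <- 1
  s1 <- simulate_sort(input, gate_spec("DEX_CD3", round = 1), ph1, cfg, 1)
  expect_true(all(s1$pass == input))
  expect_error(gate_spec("NOT_A_GATE"), "arg")
})

test_that("binomial sorting stays within 3 sd of its expectation", {
  cfg <- screen_config()
  ph <- assign_phenotypes(design400, cfg, seed = 1)[1, , drop = FALSE]
  ph$expression <- 0.3; ph$dextramer_binding <- 1
  input <- stats::setNames(10000L, ph$variant)
  bound <- 3 * sqrt(10000 * 0.3 * 0.7)
  hits <- vapply(1:200, function(seed) {
    s <- simulate_sort(input, gate_spec("DEX_CD3", round = 1), ph, cfg,
                       seed)
    abs(s$pass - 3000) <= bound
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("run_screen records 3 rounds x 5 populations and conserves
          cells within rounds", {
  cfg <- screen_config(n_cells = 5e4)
  ph <- assign_phenotypes(design400, cfg, seed = 4)
  sc <- run_screen(design400, ph, cfg, seed = 4)
  expect_equal(nrow(sc$lineage), 15L)
  expect_equal(ncol(sc$counts), 15L)
  expect_setequal(unique(sc$meta$population), aedscreen:::SCREEN_POPULATIONS)
  for (r in 1:3) {
    dex <- sum(sc$counts[, sprintf("R%d_DEX_CD3", r)])
    split <- sum(sc$counts[, sprintf("R%d_%s", r,
                                     c("PEP_GFPhigh", "PEP_GFPlow",
                                       "BLINA_GFPhigh",
                                       "BLINA_GFPlow"))])
    expect_equal(split, dex)  # aliquots partition the sorted cells
  }
  # frequencies normalise to 1
  f <- count_frequencies(sc)
  expect_true(all(abs(colSums(f) - 1) < 1e-9))
  expect_error(run_screen(design400, ph, screen_config(rounds = 0)),
               "rounds")
})

test_that("all-pass gates reproduce the input distribution", {
  cfg <- screen_config(rounds = 1, n_cells = 1e5, abundance_sigma = 0,
                       backbone = NA)
  ph <- assign_phenotypes(design400, cfg, seed = 2)
  ph$expression[] <- 1; ph$dextramer_binding[] <- 1
  sc <- run_screen(design400, ph, cfg, seed = 2)
  expect_true(all(sc$counts[, "R1_DEX_CD3"] ==
                    sc$counts[, "R1_DEX_CD3"]))
  dex <- sc$counts[, "R1_DEX_CD3"]
  expect_equal(sum(dex), 1e5)
  # uniform abundance: every variant within 5 sd of 1e5/400
  expect_true(all(abs(dex - 250) <= 5 * sqrt(250)))
})

test_that("planted variants are progressively enriched in the carried
          population (>=90% of trajectories over 50 seeds)", {
  cfg <- screen_config()
  mono <- logical(0)
  for (seed in 1:50) {
    ph <- assign_phenotypes(design400, cfg, seed)
    sc <- run_screen(design400, ph, cfg, seed)
    f <- count_frequencies(sc)
    pl <- ph$variant[ph$planted]
    fr <- vapply(1:3, function(r) f[pl, sprintf("R%d_PEP_GFPlow", r)],
                 numeric(length(pl)))
    mono <- c(mono, apply(fr, 1, function(x) all(diff(x) >= 0)))
  }
  expect_gte(mean(mono), 0.9)
})

test_that("read emission round-trips at error 0 and matches the error
          model at error 0.001", {
  tpl <- default_amplicon_template()
  cts <- matrix(c(5L, 3L, 2L), ncol = 1,
                dimnames = list(c("FEQWT", "FGQGT", "FAQCT"),
                                "R1_DEX_CD3"))
  sets <- emit_reads(cts, dir = NULL, error_rate = 0, seed = 1)
  calls <- parse_reads(sets[[1]])
  expect_true(all(calls$pass))
  expect_equal(sort(table(calls$motif)),
               sort(c(FEQWT = 5L, FGQGT = 3L, FAQCT = 2L)),
               ignore_attr = TRUE)
  # empty column -> empty FASTQ
  cts0 <- matrix(0L, 3, 1, dimnames = dimnames(cts))
  d <- withr::local_tempdir()
  files <- emit_reads(cts0, dir = d, error_rate = 0, seed = 1)
  expect_true(file.exists(files[[1]]))
  expect_equal(length(Biostrings::readDNAStringSet(files[[1]],
                                                   format = "fastq")),
               0L)
  # error-rate check: fraction of reads with >= 1 substitution
  n <- 1e5
  cts1 <- matrix(as.integer(n), 1, 1,
                 dimnames = list("FEQWT", "R1_DEX_CD3"))
  sets1 <- emit_reads(cts1, dir = NULL, error_rate = 0.001, seed = 7)
  clean <- aedscreen:::.variant_read("FEQWT", tpl)
  frac <- mean(as.character(sets1[[1]]) != clean)
  L <- nchar(clean)
  p <- 1 - (1 - 0.001)^L
  expect_lte(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the simulation chain is fully deterministic under a fixed
          seed", {
  cfg <- small_screen_config()
  a <- run_screen_pipeline(cfg, seed = 5, dir = NULL)
  b <- run_screen_pipeline(cfg, seed = 5, dir = NULL)
  expect_identical(a$screen$counts, b$screen$counts)
  expect_identical(a$rank_table, b$rank_table)
  expect_identical(a$candidates, b$candidates)
})
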
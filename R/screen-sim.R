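# Synthetic three-round FACS sort-seq screen.
#
# Each library variant carries a latent phenotype (surface expression,
# dextramer binding, peptide response, bispecific-antibody response). A
# round consists of an expression sort (dextramer+/CD3+), then separate
# peptide and bispecific challenges whose GFP-high gates are passed
# binomially; the peptide GFP-low output seeds the next round. Reads are
# emitted as single-end synthetic amplicons with substitution error.

SCREEN_POPULATIONS <- c("DEX_CD3", "PEP_GFPhigh", "PEP_GFPlow",
                        "BLINA_GFPhigh", "BLINA_GFPlow")

#' Default screen simulation configuration
#'
#' The defaults state the simulated world: a 400-variant NNK library
#' integrated into 10^6 cells, three selection rounds, peptide challenge
#' at 0.1 ug/ml and blinatumomab at 12 ng/ml, 10^5 reads per sequenced
#' population at substitution error 0.001, five planted decoupled
#' variants, and a quarter of variants failing to express.
#'
#' @param n_cells Cells entering each round (round 1: library
#'   transfection scale; later rounds: expansion of the carried-forward
#'   population).
#' @param rounds Number of selection rounds.
#' @param read_depth Reads sequenced per population.
#' @param error_rate Per-base substitution error of read emission.
#' @param n_planted Number of planted decoupled variants.
#' @param nonexpressor_frac Fraction of non-planted variants with
#'   ablated surface expression.
#' @param response_cor Latent (Gaussian-copula) correlation between
#'   peptide and blinatumomab responses of ordinary variants.
#' @param abundance_sigma Log-normal sigma of the initial library skew.
#' @param backbone Motif string of the cloning-backbone variant, included
#'   at elevated initial abundance; `NA` to disable.
#' @param backbone_weight Initial abundance multiplier of the backbone.
#' @param peptide_conc,pep_ec50 Peptide challenge concentration and
#'   half-maximal concentration (ug/ml) of the gate dose term.
#' @param blina_conc,blina_ec50 Blinatumomab concentration and EC50
#'   (ng/ml).
#' @param p_low,b_high,e_min Phenotype thresholds defining ground-truth
#'   decoupling: peptide response <= `p_low`, blinatumomab response >=
#'   `b_high`, expression >= `e_min`.
#' @return Named list of class `screen_config`.
#' @export
screen_config <- function(n_cells = 1e6, rounds = 3, read_depth = 1e5,
                          error_rate = 0.001, n_planted = 5,
                          nonexpressor_frac = 0.25, response_cor = 0.7,
                          abundance_sigma = 0.5, backbone = "FEQWT",
                          backbone_weight = 40, peptide_conc = 0.1,
                          pep_ec50 = 0.03, blina_conc = 12,
                          blina_ec50 = 2, p_low = 0.15, b_high = 0.6,
                          e_min = 0.5) {
  structure(as.list(environment()), class = "screen_config")
}

.split_seed <- function(seed, k) (as.integer(seed) + k * 10007L) %% .Machine$integer.max

#' Assign latent phenotypes to library variants
#'
#' Deterministic given `seed`. A configured number of planted decoupled
#' variants get low peptide response, high blinatumomab response and high
#' expression; a configured fraction are non-expressors; the backbone
#' variant (on which the library was cloned) behaves like a planted
#' decoupled variant; all remaining variants draw Beta-distributed
#' responses with a positive Gaussian-copula correlation between peptide
#' and blinatumomab response.
#'
#' @param design A [design_library()] result.
#' @param config A [screen_config()].
#' @param seed Integer seed.
#' @return data.frame of class `variant_phenotypes`: `variant`,
#'   `expression`, `dextramer_binding`, `peptide_response`,
#'   `blina_response`, `is_backbone`, `planted`, `is_decoupled`.
#' @export
assign_phenotypes <- function(design, config = screen_config(), seed = 1) {
  variants <- design$protein_variants$motif
  n <- length(variants)
  if (n == 0L) stop("empty library", call. = FALSE)
  if (config$n_planted > n) stop("more planted decoupled variants than ",
                                 "library members", call. = FALSE)
  withr::with_seed(.split_seed(seed, 1L), {
    is_backbone <- !is.na(config$backbone) & variants == config$backbone
    eligible <- which(!is_backbone)
    planted <- rep(FALSE, n)
    planted[sample(eligible, config$n_planted)] <- TRUE
    rest <- which(!planted & !is_backbone)
    nonexp <- rep(FALSE, n)
    nonexp[sample(rest, round(config$nonexpressor_frac * length(rest)))] <- TRUE

    expression <- rbeta(n, 4, 2)
    dex <- rbeta(n, 6, 2)
    z1 <- rnorm(n)
    z2 <- config$response_cor * z1 +
      sqrt(1 - config$response_cor^2) * rnorm(n)
    pep <- qbeta(pnorm(z1), 2, 2)
    blina <- qbeta(pnorm(z2), 2, 2)

    special <- planted | is_backbone
    expression[special] <- runif(sum(special), 0.8, 1)
    dex[special] <- runif(sum(special), 0.7, 1)
    pep[special] <- runif(sum(special), 0, 0.05)
    blina[special] <- runif(sum(special), 0.85, 1)
    expression[nonexp] <- rbeta(sum(nonexp), 1, 30)
  })
  out <- data.frame(variant = variants, expression = expression,
                    dextramer_binding = dex, peptide_response = pep,
                    blina_response = blina, is_backbone = is_backbone,
                    planted = planted, stringsAsFactors = FALSE)
  out$is_decoupled <- out$peptide_response <= config$p_low &
    out$blina_response >= config$b_high & out$expression >= config$e_min
  class(out) <- c("variant_phenotypes", "data.frame")
  out
}

#' FACS gate specification
#' @param name Gate name, one of
#'   `r paste(SCREEN_POPULATIONS, collapse = ", ")`.
#' @param stimulus Stimulus level (peptide ug/ml or blinatumomab ng/ml);
#'   `NA` for the expression gate.
#' @param round Selection round index (>= 1).
#' @return List of class `gate_spec`.
#' @export
gate_spec <- function(name, stimulus = NA_real_, round = 1L) {
  name <- match.arg(name, SCREEN_POPULATIONS)
  if (round < 1L) stop("round must be >= 1", call. = FALSE)
  structure(list(name = name, stimulus = stimulus, round = as.integer(round)),
            class = "gate_spec")
}

# Emax dose term: stimulus / (stimulus + EC50).
.dose <- function(conc, ec50) conc / (conc + ec50)

#' Per-variant gate passage probability
#'
#' Multiplicative model: the expression sort passes with probability
#' `expression x dextramer_binding`; GFP-high gates pass with
#' `expression x dose x response`, where `dose` is an Emax term in the
#' stimulus concentration; GFP-low gates are the complements.
#'
#' @param gate A [gate_spec()].
#' @param phenotypes A [assign_phenotypes()] table.
#' @param config A [screen_config()].
#' @return Numeric vector of probabilities, one per variant.
#' @export
gate_probability <- function(gate, phenotypes, config = screen_config()) {
  e <- phenotypes$expression
  p <- switch(gate$name,
    DEX_CD3 = e * phenotypes$dextramer_binding,
    PEP_GFPhigh = e * .dose(if (is.na(gate$stimulus)) config$peptide_conc
                            else gate$stimulus, config$pep_ec50) *
      phenotypes$peptide_response,
    PEP_GFPlow = 1 - gate_probability(gate_spec("PEP_GFPhigh",
                                                gate$stimulus, gate$round),
                                      phenotypes, config),
    BLINA_GFPhigh = e * .dose(if (is.na(gate$stimulus)) config$blina_conc
                              else gate$stimulus, config$blina_ec50) *
      phenotypes$blina_response,
    BLINA_GFPlow = 1 - gate_probability(gate_spec("BLINA_GFPhigh",
                                                  gate$stimulus,
                                                  gate$round),
                                        phenotypes, config),
    stop("unknown gate: ", gate$name, call. = FALSE))
  pmin(pmax(p, 0), 1)
}

#' Simulate one FACS sort
#'
#' Per variant, `pass ~ Binomial(input, pi)` with `pi` from
#' [gate_probability()]; `fail = input - pass`, so cells are conserved
#' exactly.
#'
#' @param input_counts Named integer vector of cells per variant.
#' @param gate A [gate_spec()].
#' @param phenotypes A [assign_phenotypes()] table (same variant order).
#' @param config A [screen_config()].
#' @param seed Integer seed.
#' @return List with integer vectors `pass` and `fail`.
#' @export
simulate_sort <- function(input_counts, gate, phenotypes,
                          config = screen_config(), seed = 1) {
  stopifnot(all(input_counts >= 0))
  pi <- gate_probability(gate, phenotypes, config)
  stopifnot(length(pi) == length(input_counts))
  pass <- withr::with_seed(.split_seed(seed, 2L + gate$round),
                           rbinom(length(input_counts), input_counts, pi))
  list(pass = stats::setNames(as.integer(pass), names(input_counts)),
       fail = stats::setNames(as.integer(input_counts - pass),
                              names(input_counts)))
}

#' Run the multi-round sort-seq screen
#'
#' Round 1 starts from the full library at log-normally skewed abundance
#' (backbone elevated). Each round: expression sort (DEX_CD3), then the
#' sorted cells are split into two aliquots challenged with peptide and
#' with blinatumomab; GFP-high/-low fractions are recorded; the peptide
#' GFP-low fraction is expanded to `n_cells` and seeds the next round.
#'
#' @param design A [design_library()] result.
#' @param phenotypes A [assign_phenotypes()] table.
#' @param config A [screen_config()].
#' @param seed Integer seed.
#' @return A `screen_counts` object: integer matrix `counts` (variants x
#'   populations, columns named `R<round>_<population>`), `meta`
#'   data.frame (column, population, round), `lineage` data.frame, and
#'   the config as an attribute.
#' @export
run_screen <- function(design, phenotypes, config = screen_config(),
                       seed = 1) {
  if (config$rounds < 1L) stop("rounds must be >= 1", call. = FALSE)
  variants <- phenotypes$variant
  n <- length(variants)
  counts <- matrix(0L, n, 0L)
  meta <- data.frame(column = character(), population = character(),
                     round = integer(), stringsAsFactors = FALSE)
  lineage <- data.frame(round = integer(), population = character(),
                        parent = character(), n_cells = integer(),
                        stringsAsFactors = FALSE)

  input <- withr::with_seed(.split_seed(seed, 10L), {
    w <- rlnorm(n, 0, config$abundance_sigma)
    w[phenotypes$is_backbone] <- w[phenotypes$is_backbone] *
      config$backbone_weight
    as.integer(rmultinom(1L, config$n_cells, w))
  })
  names(input) <- variants

  add_col <- function(cts, pop, r, parent) {
    counts <<- cbind(counts, cts)
    colnames(counts)[ncol(counts)] <<- sprintf("R%d_%s", r, pop)
    meta <<- rbind(meta, data.frame(column = sprintf("R%d_%s", r, pop),
                                    population = pop, round = r,
                                    stringsAsFactors = FALSE))
    lineage <<- rbind(lineage,
                      data.frame(round = r, population = pop,
                                 parent = parent,
                                 n_cells = sum(cts),
                                 stringsAsFactors = FALSE))
  }

  for (r in seq_len(config$rounds)) {
    rs <- .split_seed(seed, 100L * r)
    dex <- simulate_sort(input, gate_spec("DEX_CD3", round = r),
                         phenotypes, config, seed = rs)
    add_col(dex$pass, "DEX_CD3", r, if (r == 1L) "library" else
      sprintf("R%d_PEP_GFPlow", r - 1L))
    # split sorted cells into two challenge aliquots
    pep_aliquot <- withr::with_seed(.split_seed(rs, 1L),
                                    rbinom(n, dex$pass, 0.5))
    blina_aliquot <- dex$pass - pep_aliquot
    pep <- simulate_sort(stats::setNames(pep_aliquot, variants),
                         gate_spec("PEP_GFPhigh", config$peptide_conc, r),
                         phenotypes, config, seed = .split_seed(rs, 2L))
    add_col(pep$pass, "PEP_GFPhigh", r, sprintf("R%d_DEX_CD3", r))
    add_col(pep$fail, "PEP_GFPlow", r, sprintf("R%d_DEX_CD3", r))
    blina <- simulate_sort(stats::setNames(blina_aliquot, variants),
                           gate_spec("BLINA_GFPhigh", config$blina_conc,
                                     r),
                           phenotypes, config, seed = .split_seed(rs, 3L))
    add_col(blina$pass, "BLINA_GFPhigh", r, sprintf("R%d_DEX_CD3", r))
    add_col(blina$fail, "BLINA_GFPlow", r, sprintf("R%d_DEX_CD3", r))
    if (r < config$rounds) {
      low <- pep$fail
      if (sum(low) == 0L) stop("peptide GFP-low population extinct in ",
                               "round ", r, call. = FALSE)
      input <- withr::with_seed(.split_seed(rs, 4L),
                                as.integer(rmultinom(1L, config$n_cells,
                                                     low)))
      names(input) <- variants
    }
  }
  rownames(counts) <- variants
  structure(list(counts = counts, meta = meta, lineage = lineage),
            class = "screen_counts", config = config)
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("<screen_counts> %d variants x %d populations (%d rounds)\n",
              nrow(x$counts), ncol(x$counts), max(x$meta$round)))
  invisible(x)
}

#' Column-wise variant frequencies of a count matrix
#' @param counts Integer matrix (variants x populations) or a
#'   `screen_counts`.
#' @return Matrix of frequencies; each column sums to 1.
#' @export
count_frequencies <- function(counts) {
  if (inherits(counts, "screen_counts")) counts <- counts$counts
  sweep(counts, 2L, colSums(counts), "/")
}

#' Downsample sorted-cell counts to sequencing reads
#'
#' Read count per population is `min(depth, column total)`: when the
#' column total does not exceed the depth every sorted cell yields one
#' read (frequencies are preserved exactly); otherwise reads are drawn
#' multinomially from the cell frequencies.
#'
#' @param screen A `screen_counts` object or a counts matrix.
#' @param depth Reads per population.
#' @param seed Integer seed.
#' @param columns Optional subset of column names.
#' @return Integer matrix of read counts per variant and population.
#' @export
sample_reads <- function(screen, depth = 1e5, seed = 1, columns = NULL) {
  counts <- if (inherits(screen, "screen_counts")) screen$counts else screen
  if (!is.null(columns)) counts <- counts[, columns, drop = FALSE]
  out <- counts
  withr::with_seed(.split_seed(seed, 20L), {
    for (j in seq_len(ncol(counts))) {
      tot <- sum(counts[, j])
      if (tot > depth) {
        out[, j] <- as.integer(rmultinom(1L, depth, counts[, j]))
      }
    }
  })
  out
}
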
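# Decoupling-candidate calling: variants de-enriched in the
# peptide-positive fraction yet maintained in the blinatumomab-positive
# fraction, relative to the dextramer/CD3 expression sort.

#' Selection thresholds for candidate calling
#'
#' The screen's published rule is qualitative (rank decrease and
#' frequency de-enrichment under peptide; rank maintenance and no
#' de-enrichment under blinatumomab); these knobs quantify it and must be
#' reported alongside any result.
#'
#' @param min_rank_drop_pep Minimum rank worsening in the peptide-positive
#'   column (`delta_rank_pep >=` this).
#' @param max_abs_rank_change_blina Maximum rank *worsening* in the
#'   blinatumomab-positive column ("maintenance"; rank improvement is
#'   unbounded, since improved blinatumomab ranking is itself the
#'   selection signal).
#' @param max_log2_enrich_pep Maximum log2 enrichment in the
#'   peptide-positive column (must be <= 0: de-enrichment).
#' @param min_log2_enrich_blina Minimum log2 enrichment in the
#'   blinatumomab-positive column (absence of de-enrichment).
#' @param min_reference_frequency Minimum frequency in the reference
#'   column; `NULL` defaults to `1 / (4 * library_size)` at call time.
#' @return List of class `selection_thresholds`.
#' @export
selection_thresholds <- function(min_rank_drop_pep = 20,
                                 max_abs_rank_change_blina = 20,
                                 max_log2_enrich_pep = -1,
                                 min_log2_enrich_blina = -0.5,
                                 min_reference_frequency = NULL) {
  stopifnot(min_rank_drop_pep >= 0)
  if (!is.null(min_reference_frequency)) {
    stopifnot(min_reference_frequency >= 0, min_reference_frequency < 1)
  }
  structure(as.list(environment()), class = "selection_thresholds")
}

#' Score variants for decoupling
#'
#' Joins the peptide-positive and blinatumomab-positive trajectories of
#' each variant (relative to the same reference column) and computes the
#' decoupling score `D = log2_enrich_blina - log2_enrich_pep`. Output is
#' sorted by `D` descending, ties by peptide rank drop descending, then
#' lexicographically by variant.
#'
#' @param trajectories A `rank_trajectories` table from
#'   [build_trajectories()] containing both columns.
#' @param pep_column,blina_column Selected column names; defaults pick
#'   the unique `*_PEP_GFPhigh` / `*_BLINA_GFPhigh` columns present.
#' @return data.frame of class `candidate_calls`.
#' @export
score_decoupling <- function(trajectories, pep_column = NULL,
                             blina_column = NULL) {
  tr <- as.data.frame(trajectories)
  pick <- function(given, pat) {
    if (!is.null(given)) return(given)
    hit <- unique(grep(pat, tr$selected, value = TRUE))
    if (length(hit) != 1L) {
      stop("cannot identify a unique column matching ", pat, call. = FALSE)
    }
    hit
  }
  pep_column <- pick(pep_column, "PEP_GFPhigh$")
  blina_column <- pick(blina_column, "BLINA_GFPhigh$")
  pep <- tr[tr$selected == pep_column, , drop = FALSE]
  bl <- tr[tr$selected == blina_column, , drop = FALSE]
  if (!identical(unique(pep$reference), unique(bl$reference))) {
    stop("peptide and blinatumomab trajectories use different reference ",
         "columns", call. = FALSE)
  }
  i <- match(pep$variant, bl$variant)
  stopifnot(!anyNA(i))
  out <- data.frame(
    variant = pep$variant,
    ref_rank = pep$ref_rank, ref_frequency = pep$ref_frequency,
    rank_pep = pep$sel_rank, delta_rank_pep = pep$delta_rank,
    log2_enrich_pep = pep$log2_enrichment, missing_pep = pep$missing,
    rank_blina = bl$sel_rank[i], delta_rank_blina = bl$delta_rank[i],
    log2_enrich_blina = bl$log2_enrichment[i],
    missing_blina = bl$missing[i],
    stringsAsFactors = FALSE)
  out$D <- out$log2_enrich_blina - out$log2_enrich_pep
  out <- out[order(-out$D, -out$delta_rank_pep, out$variant), ,
             drop = FALSE]
  row.names(out) <- NULL
  class(out) <- c("candidate_calls", "data.frame")
  out
}

#' Call decoupling candidates
#'
#' Retains variants satisfying all of: peptide rank drop at least
#' `min_rank_drop_pep`; peptide log2 enrichment at most
#' `max_log2_enrich_pep`; absolute blinatumomab rank change at most
#' `max_abs_rank_change_blina`; blinatumomab log2 enrichment at least
#' `min_log2_enrich_blina`; reference frequency at least
#' `min_reference_frequency`. The cloning backbone variant is excluded by
#' default (it dominates the library by construction).
#'
#' @param scored A `candidate_calls` table from [score_decoupling()].
#' @param thresholds A [selection_thresholds()] object.
#' @param library_size Library size used for the default reference
#'   frequency floor.
#' @param exclude_variants Variant ids never called (default: the
#'   backbone motif FEQWT); use `character(0)` to include everything.
#' @return The candidates (possibly zero rows), sorted as in
#'   [score_decoupling()], with a `final_rank` column and per-criterion
#'   flag columns.
#' @export
call_candidates <- function(scored, thresholds = selection_thresholds(),
                            library_size = 400,
                            exclude_variants = "FEQWT") {
  if (nrow(scored) == 0L) stop("empty scored table", call. = FALSE)
  minf <- thresholds$min_reference_frequency
  if (is.null(minf)) minf <- 1 / (4 * library_size)
  s <- scored
  s$crit_rank_drop_pep <- s$delta_rank_pep >= thresholds$min_rank_drop_pep
  s$crit_deenrich_pep <- s$log2_enrich_pep <= thresholds$max_log2_enrich_pep
  # "maintenance" bounds rank *worsening* only: improved ranking in the
  # blinatumomab-positive fraction is the selection signal and never
  # disqualifies.
  s$crit_rank_maint_blina <-
    s$delta_rank_blina <= thresholds$max_abs_rank_change_blina
  s$crit_no_deenrich_blina <-
    s$log2_enrich_blina >= thresholds$min_log2_enrich_blina
  s$crit_ref_frequency <- s$ref_frequency >= minf
  keep <- s$crit_rank_drop_pep & s$crit_deenrich_pep &
    s$crit_rank_maint_blina & s$crit_no_deenrich_blina &
    s$crit_ref_frequency & !(s$variant %in% exclude_variants)
  out <- s[keep, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  row.names(out) <- NULL
  class(out) <- c("candidate_calls", "data.frame")
  out
}

#' Rank-improvement report with ceiling normalisation
#'
#' Highly ranked variants in the reference sort have less room for rank
#' improvement; this report normalises each variant's rank change by its
#' maximum possible improvement (`start_rank - 1`). A variant starting at
#' rank 1 has improvement capacity 0; values are clipped to [-1, 1].
#'
#' @param table A `rank_table`.
#' @param reference_order Column names, first one being the starting
#'   (reference) column.
#' @return data.frame with per-column ranks and normalised improvements.
#' @export
rank_improvement_report <- function(table, reference_order) {
  tab <- as.data.frame(table)
  miss <- setdiff(reference_order, unique(tab$column))
  if (length(miss)) stop("column(s) absent: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  start <- tab[tab$column == reference_order[1L], , drop = FALSE]
  out <- data.frame(variant = start$variant, start_rank = start$rank,
                    stringsAsFactors = FALSE)
  for (col in reference_order[-1L]) {
    st <- tab[tab$column == col, , drop = FALSE]
    i <- match(out$variant, st$variant)
    r <- st$rank[i]
    eff <- ifelse(is.na(r), nrow(st) + 1L, r)
    impr <- ifelse(out$start_rank > 1L,
                   (out$start_rank - eff) / (out$start_rank - 1L), 0)
    out[[paste0("rank_", col)]] <- r
    out[[paste0("improvement_", col)]] <- pmin(pmax(impr, -1), 1)
  }
  out
}

#' Recovery metrics against planted ground truth
#'
#' @param called A `candidate_calls` table (from [call_candidates()] or
#'   [score_decoupling()]).
#' @param planted Character vector of planted decoupled variant ids.
#' @param top_n Top-N window for the hit count.
#' @return List with `hits_top_n`, `precision`, `recall` (precision and
#'   recall over all called candidates).
#' @export
recovery_metrics <- function(called, planted, top_n = 10) {
  top <- utils::head(called$variant, top_n)
  tp <- sum(called$variant %in% planted)
  list(hits_top_n = sum(top %in% planted),
       precision = if (nrow(called)) tp / nrow(called) else NA_real_,
       recall = tp / length(planted))
}

#' Export candidate calls as TSV
#' @param called A `candidate_calls` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(called, path) {
  utils::write.table(as.data.frame(called), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
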
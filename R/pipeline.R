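# Pipeline orchestration: validated config, per-stage commands, run
# manifests, and the command-line entry point.

.CONFIG_SCHEMA <- list(
  top = c("seed", "out_dir", "log_level", "motif", "screen", "rings"),
  motif = c("fasta", "annotations", "region", "species", "k",
            "min_conservation", "max_wildcards", "max_gap_fraction",
            "gap_open", "gap_extend"),
  screen = c("parent_motif", "mutated_positions", "scheme", "n_cells",
             "rounds", "read_depth", "error_rate", "n_planted",
             "nonexpressor_frac", "response_cor", "abundance_sigma",
             "backbone", "backbone_weight", "peptide_conc", "pep_ec50",
             "blina_conc", "blina_ec50", "p_low", "b_high", "e_min",
             "thresholds", "anchor_length", "max_anchor_mismatches",
             "min_base_quality"),
  rings = c("amplitudes", "group_labels", "clusters_per_group",
            "cluster_radius_um", "ring_offset_um", "ring_width_um",
            "background", "noise_sd", "size_px", "pixel_size_um",
            "sigma_um", "bin_width_um", "image_paths", "write_images"),
  thresholds = c("min_rank_drop_pep", "max_abs_rank_change_blina",
                 "max_log2_enrich_pep", "min_log2_enrich_blina",
                 "min_reference_frequency"))

#' Read and validate a pipeline configuration
#'
#' YAML file with optional blocks `motif`, `screen`, `rings` plus
#' top-level `seed`, `out_dir`, `log_level`. Unknown keys anywhere are
#' rejected before any stage runs.
#'
#' @param path YAML file path, or a list (validated in place).
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  check <- function(block, allowed, where) {
    unknown <- setdiff(names(block), allowed)
    if (length(unknown)) {
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  check(cfg, .CONFIG_SCHEMA$top, "top level")
  for (b in c("motif", "screen", "rings")) {
    if (!is.null(cfg[[b]])) check(cfg[[b]], .CONFIG_SCHEMA[[b]], b)
  }
  if (!is.null(cfg$screen$thresholds)) {
    check(cfg$screen$thresholds, .CONFIG_SCHEMA$thresholds,
          "screen$thresholds")
  }
  if (!is.null(cfg$screen$rounds) && cfg$screen$rounds < 1) {
    stop("screen$rounds must be >= 1", call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) cfg$out_dir <- "aedscreen_out"
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.log <- function(...) message("[aedscreen] ", sprintf(...))

.write_manifest <- function(out_dir, stage, cfg, seed) {
  manifest <- list(
    stage = stage,
    seed = seed,
    config_hash = digest::digest(cfg, algo = "md5"),
    package_version = as.character(utils::packageVersion("aedscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

.stage_defaults <- function(block, fn_defaults) {
  for (nm in names(block)) fn_defaults[[nm]] <- block[[nm]]
  fn_defaults
}

#' Run the motif-discovery stage
#'
#' Aligns the germline FASTA, writes the aligned FASTA, the conservation
#' profile TSV and motif reports (before and after CDR/aCPM exclusion
#' filtering).
#'
#' @param config A [read_pipeline_config()] result (needs a `motif`
#'   block with at least `fasta`).
#' @param out_dir Output directory override.
#' @param seed Seed override (the stage is deterministic; recorded in
#'   the manifest).
#' @return Invisibly, a list with the alignment, profile and motifs.
#' @export
cmd_motif <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- read_pipeline_config(config)
  m <- cfg$motif
  if (is.null(m$fasta)) stop("motif$fasta not set", call. = FALSE)
  out <- if (is.null(out_dir)) cfg$out_dir else out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(seed)) cfg$seed else seed
  p <- .stage_defaults(m, list(region = "TRAJ", species = "unknown",
                               k = 5, min_conservation = 0.85,
                               max_wildcards = 1, max_gap_fraction = 0.5,
                               gap_open = 10, gap_extend = 1))
  genes <- read_germline_fasta(m$fasta, region = p$region,
                               species = p$species)
  if (!is.null(m$annotations)) {
    genes <- attach_annotations(genes, read_annotations_tsv(m$annotations))
  }
  .log("aligning %d germline sequences", length(genes))
  aln <- align_sequences(genes, gap_open = p$gap_open,
                         gap_extend = p$gap_extend)
  write_aligned_fasta(aln, file.path(out, "alignment.fasta"))
  prof <- conservation_profile(aln)
  write_conservation_tsv(prof, file.path(out, "conservation.tsv"))
  motifs <- find_conserved_motifs(prof, k = p$k,
                                  min_conservation = p$min_conservation,
                                  max_wildcards = p$max_wildcards,
                                  max_gap_fraction = p$max_gap_fraction)
  utils::write.table(motif_report(motifs),
                     file.path(out, "motifs_all.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  filtered <- motifs
  if (!is.null(m$annotations)) {
    filtered <- filter_candidate_motifs(motifs, aln)
  }
  utils::write.table(motif_report(filtered),
                     file.path(out, "motifs_filtered.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .log("found %d motif(s), %d after exclusion filtering",
       length(motifs), length(filtered))
  .write_manifest(out, "motif", cfg, seed)
  invisible(list(alignment = aln, profile = prof, motifs = motifs,
                 filtered = filtered))
}

#' Run the full synthetic screen chain in memory
#'
#' Library design, phenotype assignment, multi-round sorting, read
#' sampling/emission for the final-round reference and selected
#' populations, parsing, ranking, trajectory building, decoupling
#' scoring, and candidate calling.
#'
#' @param config A [screen_config()].
#' @param seed Integer seed.
#' @param thresholds A [selection_thresholds()].
#' @param design Optional pre-built [design_library()].
#' @param dir FASTQ output directory (`NULL` keeps reads in memory).
#' @param via_reads When `FALSE`, skips read emission/parsing and ranks
#'   the sampled read counts directly (fast path; identical at error
#'   rate 0).
#' @return List: `design`, `phenotypes`, `screen`, `rank_table`,
#'   `trajectories`, `scored`, `candidates`, `planted`, `files`.
#' @export
run_screen_pipeline <- function(config = screen_config(), seed = 1,
                                thresholds = selection_thresholds(),
                                design = NULL, dir = NULL,
                                via_reads = TRUE) {
  if (is.null(design)) design <- design_library("FGQGT", c(1, 3), "NNK")
  phen <- assign_phenotypes(design, config, seed)
  screen <- run_screen(design, phen, config, seed)
  r <- config$rounds
  cols <- sprintf("R%d_%s", r, c("DEX_CD3", "PEP_GFPhigh",
                                 "BLINA_GFPhigh"))
  reads <- sample_reads(screen, depth = config$read_depth, seed = seed,
                        columns = cols)
  files <- NULL
  if (via_reads) {
    emitted <- emit_reads(reads, dir = dir,
                          error_rate = config$error_rate, seed = seed)
    calls <- lapply(emitted, parse_reads)
    names(calls) <- cols
    rt <- count_and_rank(calls)
    if (!is.null(dir)) files <- unlist(emitted)
  } else {
    rt <- rank_table_from_counts(reads)
  }
  traj <- build_trajectories(rt, reference_column = cols[1],
                             selected_columns = cols[2:3])
  scored <- score_decoupling(traj, pep_column = cols[2],
                             blina_column = cols[3])
  cand <- call_candidates(scored, thresholds,
                          library_size = design$theoretical_protein_diversity,
                          exclude_variants = if (is.na(config$backbone))
                            character(0) else config$backbone)
  list(design = design, phenotypes = phen, screen = screen,
       rank_table = rt, trajectories = traj, scored = scored,
       candidates = cand, planted = phen$variant[phen$planted],
       files = files)
}

#' Run the screen stage of the pipeline
#'
#' Drives [run_screen_pipeline()] from a config file and writes the
#' ground truth, library table, FASTQ files, rank table, trajectories,
#' scored table and candidate report.
#'
#' @inheritParams cmd_motif
#' @return Invisibly, the [run_screen_pipeline()] result.
#' @export
cmd_screen <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- read_pipeline_config(config)
  s <- cfg$screen
  out <- if (is.null(out_dir)) cfg$out_dir else out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(seed)) cfg$seed else seed
  sc_args <- s[setdiff(names(s), c("parent_motif", "mutated_positions",
                                   "scheme", "thresholds",
                                   "anchor_length",
                                   "max_anchor_mismatches",
                                   "min_base_quality"))]
  sc <- do.call(screen_config, sc_args)
  thr <- do.call(selection_thresholds,
                 if (is.null(s$thresholds)) list() else s$thresholds)
  design <- design_library(
    if (is.null(s$parent_motif)) "FGQGT" else s$parent_motif,
    if (is.null(s$mutated_positions)) c(1, 3) else
      unlist(s$mutated_positions),
    if (is.null(s$scheme)) "NNK" else s$scheme)
  .log("library: %d protein variants", design$theoretical_protein_diversity)
  res <- run_screen_pipeline(sc, seed = seed, thresholds = thr,
                             design = design,
                             dir = file.path(out, "reads"))
  write_library_tsv(design, file.path(out, "library.tsv"))
  utils::write.table(as.data.frame(res$phenotypes),
                     file.path(out, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_rank_tsv(res$rank_table, file.path(out, "rank_table.tsv"))
  utils::write.table(as.data.frame(res$trajectories),
                     file.path(out, "trajectories.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_candidates_tsv(res$scored, file.path(out, "scored.tsv"))
  write_candidates_tsv(res$candidates, file.path(out, "candidates.tsv"))
  rec <- recovery_metrics(res$candidates, res$planted)
  .log("candidates called: %d (top-10 planted hits %d, precision %.2f, recall %.2f)",
       nrow(res$candidates), rec$hits_top_n, rec$precision, rec$recall)
  .write_manifest(out, "screen", cfg, seed)
  invisible(res)
}

#' Run the ring-quantification stage
#'
#' Either loads PNG image pairs listed in the config or generates the
#' synthetic three-group demo (with-ring / intermediate / without-ring,
#' 12 clusters per group), computes per-cluster ring statistics and the
#' one-way ANOVA report.
#'
#' @inheritParams cmd_motif
#' @return Invisibly, a list with the per-cluster statistics table and
#'   the `anova_report`.
#' @export
cmd_rings <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- read_pipeline_config(config)
  rg <- if (is.null(cfg$rings)) list() else cfg$rings
  out <- if (is.null(out_dir)) cfg$out_dir else out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(seed)) cfg$seed else seed
  p <- .stage_defaults(rg, list(
    amplitudes = c(0.6, 0.3, 0), group_labels = NULL,
    clusters_per_group = 12, cluster_radius_um = 40, ring_offset_um = 5,
    ring_width_um = 15, background = 0.05, noise_sd = 0.02,
    size_px = 256, pixel_size_um = 1.3, sigma_um = 14.4,
    bin_width_um = NULL, write_images = FALSE))
  rows <- list(); stats_by_group <- list()
  if (!is.null(rg$image_paths)) {
    groups <- names(rg$image_paths)
    for (g in groups) {
      vals <- numeric(0)
      for (i in seq_along(rg$image_paths[[g]])) {
        pr <- rg$image_paths[[g]][[i]]
        pair <- structure(list(bright_field = read_image_png(pr$bf),
                               fluorescence = read_image_png(pr$fl),
                               pixel_size_um = p$pixel_size_um,
                               group = g, replicate = i),
                          class = "image_pair")
        cp <- cluster_profile(pair, sigma_um = p$sigma_um,
                              bin_width_um = p$bin_width_um)
        vals <- c(vals, cp$max_intensity_difference)
        rows[[length(rows) + 1L]] <- .cluster_row(cp)
      }
      stats_by_group[[g]] <- vals
    }
  } else {
    amps <- unlist(p$amplitudes)
    labels <- if (is.null(p$group_labels)) {
      sprintf("amp_%.2f", amps)
    } else unlist(p$group_labels)
    for (gi in seq_along(amps)) {
      vals <- numeric(0)
      for (i in seq_len(p$clusters_per_group)) {
        pair <- generate_cluster_image(
          cluster_radius_um = p$cluster_radius_um,
          ring_offset_um = p$ring_offset_um,
          ring_width_um = p$ring_width_um, ring_amplitude = amps[gi],
          background = p$background, noise_sd = p$noise_sd,
          size_px = p$size_px, pixel_size_um = p$pixel_size_um,
          seed = .split_seed(seed, 1000L * gi + i),
          group = labels[gi], replicate = i)
        if (isTRUE(p$write_images)) {
          write_image_png(pair$bright_field,
                          file.path(out, sprintf("%s_%02d_bf.png",
                                                 labels[gi], i)))
          write_image_png(pair$fluorescence,
                          file.path(out, sprintf("%s_%02d_fl.png",
                                                 labels[gi], i)))
        }
        cp <- cluster_profile(pair, sigma_um = p$sigma_um,
                              bin_width_um = p$bin_width_um)
        vals <- c(vals, cp$max_intensity_difference)
        rows[[length(rows) + 1L]] <- .cluster_row(cp)
      }
      stats_by_group[[labels[gi]]] <- vals
    }
  }
  stat_tab <- do.call(rbind, rows)
  utils::write.table(stat_tab, file.path(out, "cluster_statistics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- compare_groups(stats_by_group)
  an <- data.frame(F = rep$F, p = rep$p, df_between = rep$df_between,
                   df_within = rep$df_within)
  utils::write.table(an, file.path(out, "anova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rep$pairwise, file.path(out, "tukey.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log("ANOVA F(%d, %d) = %.3f, p = %.3g", rep$df_between,
       rep$df_within, rep$F, rep$p)
  .write_manifest(out, "rings", cfg, seed)
  invisible(list(statistics = stat_tab, anova = rep))
}

.cluster_row <- function(cp) {
  data.frame(group = cp$group, replicate = cp$replicate,
             centre_row = cp$centre[1], centre_col = cp$centre[2],
             max_intensity_difference = cp$max_intensity_difference,
             r_argmax_um = cp$r_argmax_um, degenerate = cp$degenerate,
             stringsAsFactors = FALSE)
}

#' Command-line entry point
#'
#' Usage: `aedscreen motif|screen|rings --config <file> [--out DIR]
#' [--seed N]`. Logs go to stderr, data to files under the output
#' directory. Returns (and the shell wrapper exits with) a non-zero
#' status on error, and for `screen` also when zero candidates are
#' called.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status.
#' @export
aedscreen_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: aedscreen motif|screen|rings --config <file> [--out DIR] [--seed N]"
  if (length(argv) < 1L) { message(usage); return(2L) }
  cmd <- argv[1L]
  opts <- list(config = NULL, out = NULL, seed = NULL)
  i <- 2L
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[i])
    if (!key %in% names(opts) || i == length(argv)) {
      message(usage); return(2L)
    }
    opts[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  if (is.null(opts$config)) { message(usage); return(2L) }
  seed <- if (is.null(opts$seed)) NULL else as.integer(opts$seed)
  res <- tryCatch({
    switch(cmd,
      motif = { cmd_motif(opts$config, opts$out, seed); 0L },
      screen = {
        r <- cmd_screen(opts$config, opts$out, seed)
        if (nrow(r$candidates) == 0L) {
          message("[aedscreen] zero candidates called")
          1L
        } else 0L
      },
      rings = { cmd_rings(opts$config, opts$out, seed); 0L },
      { message("unknown subcommand: ", cmd); 2L })
  }, error = function(e) {
    message("[aedscreen] error: ", conditionMessage(e))
    1L
  })
  res
}
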
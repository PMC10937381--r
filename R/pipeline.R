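#' Pipeline configuration
#'
#' Bundles the fixed numeric settings of the analysis (bin resolutions 20/40/
#' 80 bp, insulation windows 400/640/800 bp, 3,000 bp pile-up and insulation
#' composite windows, 2,001/3,001 bp profile composite windows), the input
#' paths or the synthetic-generation switch, and the seeds.
#'
#' @param generator a [generator_config()] to synthesize inputs, or NULL to
#'   read `pairs_path` / `fragments_path`.
#' @param pairs_path,fragments_path input files (pairs-text, BED3), used when
#'   `generator` is NULL.
#' @param anchors anchor set (TF sites); defaults to the generator's.
#' @param resolutions_bp contact-matrix resolutions.
#' @param insulation_windows_bp diamond window sizes.
#' @param insulation_resolution_bp resolution used for insulation, default 80.
#' @param pileup_window_bp pile-up window, default 3000.
#' @param composite_window_bp nucleosome composite window, default 3001.
#' @param run_structure also build and anneal the 3D model (slower).
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL,
                            pairs_path = NULL, fragments_path = NULL,
                            anchors = NULL,
                            resolutions_bp = c(20L, 40L, 80L),
                            insulation_windows_bp = c(400L, 640L, 800L),
                            insulation_resolution_bp = 80L,
                            pileup_window_bp = 3000L,
                            composite_window_bp = 3001L,
                            run_structure = FALSE,
                            seed = 42L) {
  if (is.null(generator) && (is.null(pairs_path) || is.null(fragments_path))) {
    stop("either a generator config or pairs_path + fragments_path required")
  }
  structure(list(generator = generator, pairs_path = pairs_path,
                 fragments_path = fragments_path, anchors = anchors,
                 resolutions_bp = resolutions_bp,
                 insulation_windows_bp = insulation_windows_bp,
                 insulation_resolution_bp = insulation_resolution_bp,
                 pileup_window_bp = pileup_window_bp,
                 composite_window_bp = composite_window_bp,
                 run_structure = isTRUE(run_structure),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Bundled demonstration configuration
#'
#' A small synthetic plasmid-scale setup (one 30 kbp linear contig, five TF
#' sites, INO80 preset) sized to run the full pipeline in well under a minute.
#'
#' @param seed master seed.
#' @param n_pairs,n_fragments sampling depths.
#' @return a [pipeline_config()].
#' @export
demo_config <- function(seed = 42L, n_pairs = 2e5, n_fragments = 2e5) {
  contigs <- contig_table("chrS", 30000L)
  sites <- anchor_set("chrS", c(5000L, 10000L, 15000L, 20000L, 25000L), "+")
  gen <- generator_config(contigs, sites, preset = remodeler_preset("ino80"),
                          n_pairs = n_pairs, n_fragments = n_fragments,
                          seed = seed)
  pipeline_config(generator = gen, seed = seed)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes synthesis (optional), pair processing (classify, shift, filter),
#' contact matrices, insulation and boundary calling, nucleosome profiles and
#' metrics, and optionally the 3D reconstruction; writes all artifacts plus a
#' JSON run report with versions, seeds, per-stage conservation counts, and a
#' parameter-recovery summary when ground truth is present. Re-running with
#' the same config and seed reproduces byte-identical numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return the run report, invisibly (list).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(version = as.character(packageVersion("nucfold")),
                 seed = config$seed, stages = list())
  cfg_file <- file.path(outdir, "config.yaml")
  yaml::write_yaml(.config_as_list(config), cfg_file)
  config_hash <- unname(tools::md5sum(cfg_file))
  report$config_md5 <- config_hash
  prov <- .provenance_header(config$seed, config_hash)

  gt <- NULL
  anchors <- config$anchors
  if (!is.null(config$generator)) {
    gen <- config$generator
    gt <- .stage("synth", make_ground_truth(gen))
    fragments <- .stage("synth", simulate_mnase_fragments(gt))
    raw_pairs <- .stage("synth", simulate_ligation_pairs(gt))
    contigs <- gen$contigs
    if (is.null(anchors)) anchors <- gen$tf_sites
    write_pairs(raw_pairs, file.path(outdir, "pairs_raw.txt"))
    write_fragments_bed(fragments, file.path(outdir, "fragments.bed"))
    yaml::write_yaml(list(preset = unclass(gt$preset),
                          dyads = lapply(gt$dyads, as.integer),
                          nfr_centers = lapply(gt$nfr, function(x) x$center)),
                     file.path(outdir, "ground_truth.yaml"))
  } else {
    if (!file.exists(config$pairs_path)) {
      stop("pairs file not found: ", config$pairs_path)
    }
    if (!file.exists(config$fragments_path)) {
      stop("fragments file not found: ", config$fragments_path)
    }
    raw_pairs <- .stage("pairs", read_pairs(config$pairs_path))
    fragments <- .stage("pairs", read_fragments_bed(config$fragments_path))
    cts <- unique(c(raw_pairs$contig1, raw_pairs$contig2, fragments$contig))
    contigs <- contig_table(cts, vapply(cts, function(cn) {
      max(raw_pairs$pos2[raw_pairs$contig2 == cn],
          raw_pairs$pos1[raw_pairs$contig1 == cn],
          fragments$end[fragments$contig == cn], 0L) + 200L
    }, 1))
  }
  if (is.null(anchors)) stop("no anchors available for composite analyses")

  # pairs: classify -> shift -> filter
  fcfg <- pair_filter_config()
  pairs <- .stage("pairs", classify_orientation(raw_pairs))
  pairs <- .stage("pairs", shift_to_dyad(pairs, fcfg))
  flt <- .stage("pairs", filter_pairs(pairs, fcfg))
  write_pairs(flt$kept, file.path(outdir, "pairs_filtered.txt"))
  report$stages$pairs <- c(flt$stats[c("n_input", "n_interchromosomal",
                                       "n_close", "n_kept")],
                           list(n_dropped_negative =
                                  attr(pairs, "n_dropped_negative")))

  # matrices
  mats <- .stage("matrix", lapply(config$resolutions_bp, function(r) {
    bin_pairs(flt$kept, r, contigs)
  }))
  names(mats) <- paste0("res", config$resolutions_bp)
  for (nm in names(mats)) {
    write_matrix_triplets(mats[[nm]], file.path(outdir, paste0("matrix_", nm, ".txt")))
  }
  report$stages$matrix <- list(
    totals = vapply(mats, function(m) sum(m$counts), 1),
    conserved = all(vapply(mats, function(m) sum(m$counts), 1) == flt$stats$n_kept))

  # insulation + boundaries on the configured resolution
  ins_mat <- mats[[paste0("res", config$insulation_resolution_bp)]]
  if (is.null(ins_mat)) {
    ins_mat <- bin_pairs(flt$kept, config$insulation_resolution_bp, contigs)
  }
  profs <- .stage("insulation", lapply(config$insulation_windows_bp, function(w) {
    insulation_score(ins_mat, w)
  }))
  names(profs) <- paste0("w", config$insulation_windows_bp)
  for (nm in names(profs)) {
    write_insulation(profs[[nm]], file.path(outdir, paste0("insulation_", nm, ".bedGraph")))
  }
  bounds <- .stage("insulation",
                   call_boundaries(profs[[length(profs)]]))
  write_boundaries_bed(bounds, file.path(outdir, "boundaries.bed"))
  report$stages$insulation <- list(n_boundaries = nrow(bounds),
                                   n_strong = sum(bounds$strong),
                                   li_threshold = attr(bounds, "li_threshold"))

  # nucleosome profiles and metrics
  track <- .stage("profiles", dyad_coverage(fragments, contigs))
  write_bedgraph(track, file.path(outdir, "dyad_coverage.bedGraph"),
                 name = "dyad_coverage")
  comp <- .stage("profiles",
                 composite_profile(track, anchors, config$composite_window_bp))
  peaks <- .stage("profiles", call_profile_peaks(comp))
  metrics <- .stage("profiles", nucleosome_metrics(peaks))
  utils::write.table(
    data.frame(offset = comp$offset, signal = comp$signal),
    file.path(outdir, "composite.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  report$stages$profiles <- list(
    n_fragments_kept = attr(track, "n_kept"),
    n_fragments_excluded = attr(track, "n_excluded"),
    linker_mean = metrics$linker_mean,
    nfr_width = metrics$nfr_width)
  if (!is.null(gt)) {
    report$recovery <- list(
      planted_linker = gt$preset$linker_bp,
      recovered_linker = metrics$linker_mean,
      planted_nfr = gt$preset$nfr_bp,
      recovered_nfr = metrics$nfr_width)
  }

  # optional 3D structure
  if (config$run_structure) {
    loci <- if (!is.null(gt)) gt$dyads[[1]] else {
      stop("structure stage needs nucleosome loci (synthetic run)")
    }
    nm <- .stage("structure",
                 bin_to_nucleosomes(flt$kept,
                                    stats::setNames(list(loci), contigs$name[1]),
                                    contigs))
    model <- .stage("structure",
                    build_topology(loci, contig = contigs$name[1],
                                   seed = config$seed))
    rs <- restraints_from_matrix(nm)
    ann <- .stage("structure",
                  anneal(model, rs, anneal_schedule(seed = config$seed)))
    write_structure(model, ann$coords, file.path(outdir, "structure.xyz"))
    utils::write.table(
      data.frame(sweep = seq_along(ann$energy_trace),
                 energy = ann$energy_trace),
      file.path(outdir, "energy_trace.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    report$stages$structure <- list(initial_energy = ann$initial_energy,
                                    final_energy = ann$final_energy,
                                    acceptance = ann$acceptance)
  }

  report$provenance <- prov
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$generator)) {
    g <- unclass(out$generator)
    g$beta_fun <- NULL
    g$preset <- unclass(g$preset)
    g$contigs <- as.list(g$contigs)
    if (!is.null(g$tf_sites)) g$tf_sites <- as.list(g$tf_sites)
    g$orientation_mix <- as.list(g$orientation_mix)
    out$generator <- g
  }
  if (!is.null(out$anchors)) out$anchors <- as.list(out$anchors)
  out
}
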
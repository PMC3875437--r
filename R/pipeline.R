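#' Pipeline run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. With no
#' input paths the pipeline simulates its inputs from [sim_config()] /
#' [sim_msa_config()] under `seed`. Unknown keys are rejected (a YAML file
#' with a misspelled key errors rather than being silently ignored).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed used for every stochastic stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("classify", "entropy", "enhancement", "crosstab", "screen")`.
#' @param variants,contexts Optional paths to variant/context tables; when
#'   `NULL` the inputs are simulated.
#' @param alignment Optional path to an aligned FASTA; when `NULL` a family
#'   alignment is simulated.
#' @param reference_id,reference_offset Reference sequence naming for a
#'   supplied alignment.
#' @param motif Motif constraints for the two-tier entropy analysis.
#' @param toggle_cut,rheostat_cut Entropy cuts for [tier_separation()].
#' @param behavior Named list of [behavior_config()] overrides.
#' @param sim Named list of [sim_config()] overrides.
#' @param msa_sim Named list of [sim_msa_config()] overrides.
#' @param overwrite Allow overwriting existing stage outputs.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            stages = c("classify", "entropy",
                                       "enhancement", "crosstab",
                                       "screen"),
                            variants = NULL, contexts = NULL,
                            alignment = NULL, reference_id = NULL,
                            reference_offset = 1L,
                            motif = ypal_motif(),
                            toggle_cut = 0.1, rheostat_cut = 0.6,
                            behavior = list(), sim = list(),
                            msa_sim = list(), overwrite = FALSE) {
  known <- c("classify", "entropy", "enhancement", "crosstab", "screen")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), stages = stages,
      variants = variants, contexts = contexts, alignment = alignment,
      reference_id = reference_id,
      reference_offset = as.integer(reference_offset), motif = motif,
      toggle_cut = toggle_cut, rheostat_cut = rheostat_cut,
      behavior = behavior, sim = sim, msa_sim = msa_sim,
      overwrite = isTRUE(overwrite)
    ),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [pipeline_config()]
#'   arguments; unknown keys are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(pipeline_config)), "")
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(vals$motif)) vals$motif <- unlist(vals$motif)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages over real or simulated inputs and writes the
#' report tables into `cfg$out_dir`: `behavior.tsv` (one behavior call per
#' homolog and position), `entropy.tsv` (per-position entropies of the
#' family, the motif subset and, when simulated, the subfamily, with tier
#' labels), `enhancement.tsv`, `codes.tsv` (outcome codes versus MSA
#' frequency), `screen.tsv` (physico-chemical scale screen), plus simulated
#' inputs (`vars.csv`, `contexts.csv`, `truth.csv`, `family.fasta`,
#' `truth_msa.csv`) when no inputs were supplied, and `run_manifest.json`
#' recording the effective configuration and the MD5 checksum of every
#' file. Reruns with the same seed and configuration produce byte-identical
#' outputs.
#'
#' @param cfg A [pipeline_config()], or a path to a YAML file for
#'   [read_pipeline_config()].
#' @return Invisibly, a named list of the stage result tables plus
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  results <- list()
  emit <- function(tbl, file) {
    path <- file.path(cfg$out_dir, file)
    if (file.exists(path) && !cfg$overwrite) {
      abort(sprintf("Output '%s' already exists (write-once run directory; set overwrite = TRUE)",
                    file))
    }
    write_report(tbl, path)
    outputs <<- c(outputs, path)
    path
  }

  # ---- inputs: load or simulate -------------------------------------
  simulated <- is.null(cfg$variants)
  if (simulated) {
    sim <- simulate_dataset(do.call(sim_config, c(list(seed = cfg$seed),
                                                  cfg$sim)))
    measurements <- sim$measurements
    contexts <- sim$contexts
    emit(measurements, "vars.csv")
    emit(contexts, "contexts.csv")
    emit(sim$truth, "truth.csv")
  } else {
    loaded <- read_variant_table(cfg$variants, contexts = cfg$contexts)
    measurements <- loaded$measurements
    contexts <- loaded$contexts
    if (is.null(contexts)) abort("A context table is required")
  }
  if (is.null(cfg$alignment)) {
    msa <- simulate_msa(do.call(sim_msa_config,
                                c(list(seed = cfg$seed + 1L),
                                  cfg$msa_sim)))
    aln <- msa$alignment
    msa_truth <- msa$truth
    aln_path <- file.path(cfg$out_dir, "family.fasta")
    if (file.exists(aln_path) && !cfg$overwrite) {
      abort("Output 'family.fasta' already exists")
    }
    write_alignment(aln, aln_path)
    outputs <- c(outputs, aln_path)
    emit(msa_truth, "truth_msa.csv")
  } else {
    if (is.null(cfg$reference_id)) {
      abort("reference_id is required with a supplied alignment")
    }
    aln <- read_alignment(cfg$alignment, cfg$reference_id,
                          cfg$reference_offset)
    msa_truth <- NULL
  }
  motif_aln <- subset_by_motif(aln, cfg$motif)

  # ---- stages --------------------------------------------------------
  bcfg <- do.call(behavior_config, cfg$behavior)
  if ("classify" %in% cfg$stages) {
    results$behavior <- classify_behavior(measurements, contexts, bcfg)
    emit(results$behavior, "behavior.tsv")
  }
  if ("entropy" %in% cfg$stages) {
    ent_all <- entropy_table(aln, set_name = "all_seqs")
    ent_motif <- entropy_table(motif_aln, set_name = "motif_seqs")
    ent <- dplyr::full_join(
      dplyr::select(ent_all, "position", H_all = "entropy"),
      dplyr::select(ent_motif, "position", H_motif = "entropy"),
      by = "position"
    )
    if (!is.null(msa_truth) && any(msa_truth$in_subfamily)) {
      sub_aln <- aln
      sub_aln$sequences <-
        aln$sequences[aln$sequences$id %in%
                        msa_truth$id[msa_truth$in_subfamily], ,
                      drop = FALSE]
      ent_sub <- entropy_table(sub_aln, set_name = "subfamily")
      ent <- dplyr::full_join(
        ent,
        dplyr::select(ent_sub, "position", H_subfamily = "entropy"),
        by = "position"
      )
    }
    results$entropy <- ent %>%
      dplyr::mutate(entropy = .data$H_motif) %>%
      tier_separation(cfg$toggle_cut, cfg$rheostat_cut) %>%
      dplyr::select(-"entropy")
    emit(results$entropy, "entropy.tsv")
  }
  if ("enhancement" %in% cfg$stages) {
    results$enhancement <- enhancement_table(measurements, contexts)
    emit(results$enhancement, "enhancement.tsv")
  }
  if ("crosstab" %in% cfg$stages) {
    freqs <- column_frequencies(motif_aln,
                                unique(measurements$position))
    results$codes <- assign_outcome_codes(measurements, contexts, freqs)
    emit(results$codes, "codes.tsv")
  }
  if ("screen" %in% cfg$stages) {
    results$screen <- scale_screen(measurements, contexts)
    emit(results$screen, "screen.tsv")
  }

  # ---- manifest ------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("rheoscan")),
    seed = cfg$seed,
    stages = cfg$stages,
    simulated_inputs = simulated,
    config = list(
      toggle_cut = cfg$toggle_cut, rheostat_cut = cfg$rheostat_cut,
      motif = as.list(cfg$motif), behavior = bcfg,
      sim = cfg$sim, msa_sim = cfg$msa_sim
    ),
    files = lapply(stats::setNames(outputs, basename(outputs)),
                   function(p) unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(cfg$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
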
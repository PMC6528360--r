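# One-call reproduction of the full analysis graph on synthetic or user
# data, with fixed-seed determinism and per-step output tables.

#' Pipeline configuration
#'
#' Exactly one of `input` (paths to TPS, classifier, slider and partition
#' files) or `simulate` (an [ontogeny_sim_config()]) must be given.
#'
#' @param input Named list with paths `tps`, `classifiers` and optionally
#'   `sliders`, `partition`.
#' @param simulate An `ontogeny_sim_config`.
#' @param n_permutations Permutations for every test (default 10000).
#' @param seed Global seed; each analysis step derives an independent
#'   child seed from it and the step name, so toggling one step never
#'   perturbs another's permutations.
#' @param out_dir Output directory.
#' @param steps Steps to run, a subset of `c("gpa", "pca", "anova",
#'   "allometry", "trajectory", "disparity", "integration")` or `"all"`.
#'   Steps other than `"gpa"` reuse cached aligned coordinates in
#'   `out_dir` when present.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            n_permutations = 10000L, seed = 1L,
                            out_dir = "ontomorph_out", steps = "all") {
  if (is.null(input) == is.null(simulate))
    stop("exactly one of 'input' and 'simulate' must be given")
  all_steps <- c("gpa", "pca", "anova", "allometry", "trajectory",
                 "disparity", "integration")
  if (identical(steps, "all")) steps <- all_steps
  bad <- setdiff(steps, all_steps)
  if (length(bad)) stop("unknown step(s): ", paste(bad, collapse = ", "))
  structure(list(input = input, simulate = simulate,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), out_dir = out_dir, steps = steps),
            class = "pipeline_config")
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

load_pipeline_input <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- generate_dataset(config$simulate)
    list(configs = sim$configs, metadata = sim$metadata,
         partition = sim$partition)
  } else {
    inp <- config$input
    configs <- read_tps(inp$tps)
    if (!is.null(inp$sliders)) {
      sliders <- read_sliders(inp$sliders)
      configs <- lapply(configs, function(cfg)
        landmark_config(cfg$specimen_id, cfg$coords, cfg$scale, sliders))
    }
    metadata <- read_classifiers(inp$classifiers)
    partition <- if (!is.null(inp$partition))
      read_partition(inp$partition, k = nrow(configs[[1L]]$coords)) else NULL
    list(configs = configs, metadata = metadata, partition = partition)
  }
}

read_aligned_cache <- function(out_dir) {
  coord_path <- file.path(out_dir, "aligned_coordinates.csv")
  meta_path <- file.path(out_dir, "aligned_metadata.csv")
  cons_path <- file.path(out_dir, "consensus.csv")
  if (!all(file.exists(coord_path, meta_path, cons_path))) return(NULL)
  tab <- utils::read.csv(coord_path, check.names = FALSE)
  ids <- tab[[1L]]
  Y <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(Y) <- ids
  md <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  aligned <- structure(list(shapes = matrix_to_arr(Y),
                            consensus = as.matrix(utils::read.csv(cons_path)),
                            centroid_sizes = stats::setNames(md$centroid_size,
                                                             ids),
                            sliders = matrix(integer(0), ncol = 3L),
                            metadata = md, iterations = NA_integer_,
                            converged = TRUE),
                       class = "aligned_dataset")
  aligned
}

write_aligned_cache <- function(aligned, out_dir) {
  Y <- arr_to_matrix(aligned$shapes)
  k <- dim(aligned$shapes)[1]
  cn <- as.vector(rbind(paste0("x", seq_len(k)), paste0("y", seq_len(k))))
  df <- data.frame(specimen_id = rownames(Y), Y, check.names = FALSE)
  names(df) <- c("specimen_id", cn)
  write_table(df, file.path(out_dir, "aligned_coordinates.csv"))
  cons <- as.data.frame(aligned$consensus)
  names(cons) <- c("x", "y")
  write_table(cons, file.path(out_dir, "consensus.csv"))
  write_table(aligned$metadata, file.path(out_dir, "aligned_metadata.csv"))
}

#' Run the full ontogenetic shape-analysis pipeline
#'
#' Executes GPA (with semilandmark sliding), shape PCA, Procrustes ANOVA
#' of species and life-stage effects, the allometry models (size-by-species
#' interaction and pairwise slope angles), phenotypic trajectory analysis
#' across ontogenetic stages, stage-wise disparity, and per-cell CR and GI
#' profiles, writing one CSV per result plus a run manifest
#' (`manifest.json` with seed and config hash). Identical config and seed
#' give identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list with every computed result object and
#'   the output file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  np <- config$n_permutations
  step_active <- function(s) s %in% config$steps

  run_step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline step '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dat <- run_step("input", load_pipeline_input(config))
  aligned <- NULL
  if (step_active("gpa")) {
    aligned <- run_step("gpa",
      gpa_align(dat$configs, slide = TRUE, metadata = dat$metadata))
    if (is.null(aligned$metadata$ontogenetic_stage) ||
        anyNA(aligned$metadata$ontogenetic_stage))
      aligned$metadata <- assign_ontogenetic_stage(aligned$metadata)
    write_aligned_cache(aligned, config$out_dir)
  } else {
    aligned <- read_aligned_cache(config$out_dir)
    if (is.null(aligned))
      stop("pipeline step 'gpa' is disabled but no cached alignment was ",
           "found in ", config$out_dir)
  }
  results$aligned <- aligned

  if (step_active("pca")) {
    pca <- run_step("pca", shape_pca(aligned))
    results$pca <- pca
    write_table(data.frame(specimen_id = rownames(pca$scores),
                           pca$scores, check.names = FALSE),
                file.path(config$out_dir, "pca_scores.csv"))
    write_table(data.frame(component = seq_along(pca$percent),
                           eigenvalue = pca$eigenvalues,
                           percent = pca$percent),
                file.path(config$out_dir, "pca_variance.csv"))
  }

  if (step_active("anova")) {
    an <- run_step("anova",
      procrustes_anova(aligned, ~ species * life_stage, n_perm = np,
                       seed = derive_seed(config$seed, "anova")))
    results$anova <- an
    write_anova_csv(an, file.path(config$out_dir, "anova_species_stage.csv"))
  }

  if (step_active("allometry")) {
    an_allo <- run_step("allometry",
      procrustes_anova(aligned, ~ log_csize * species, n_perm = np,
                       seed = derive_seed(config$seed, "allometry_anova")))
    slopes <- run_step("allometry",
      compare_allometric_slopes(aligned, "species", n_perm = np,
                                seed = derive_seed(config$seed, "allometry")))
    results$allometry_anova <- an_allo
    results$slopes <- slopes
    write_anova_csv(an_allo, file.path(config$out_dir, "anova_allometry.csv"))
    lv <- rownames(slopes$angle)
    rows <- do.call(rbind, lapply(seq_along(lv), function(a)
      do.call(rbind, lapply(seq_along(lv), function(b) if (a < b)
        data.frame(pair = paste(lv[a], lv[b], sep = " - "),
                   angle = slopes$angle[a, b], Z = slopes$Z[a, b],
                   p = slopes$p[a, b])))))
    write_table(rows, file.path(config$out_dir, "slope_angles.csv"))
  }

  if (step_active("trajectory")) {
    traj <- run_step("trajectory", build_trajectories(aligned))
    cmp <- run_step("trajectory",
      compare_trajectories(traj, n_perm = np,
                           seed = derive_seed(config$seed, "trajectory")))
    results$trajectories <- traj
    results$trajectory_comparison <- cmp
    write_table(trajectory_comparison_table(cmp),
                file.path(config$out_dir, "trajectory_comparison.csv"))
  }

  if (step_active("disparity")) {
    disp <- run_step("disparity",
      disparity_test(aligned, c("species", "ontogenetic_stage"),
                     n_perm = np,
                     seed = derive_seed(config$seed, "disparity")))
    prof <- run_step("disparity", stage_disparity(aligned))
    results$disparity <- disp
    results$stage_disparity <- prof
    write_table(data.frame(group = names(disp$variances),
                           procrustes_variance = disp$variances),
                file.path(config$out_dir, "disparity_groups.csv"))
    write_table(prof, file.path(config$out_dir, "disparity_stages.csv"))
  }

  if (step_active("integration")) {
    if (is.null(dat$partition))
      stop("pipeline step 'integration' needs a module partition")
    prof <- run_step("integration",
      integration_profiles(aligned, dat$partition, n_perm = min(np, 999L),
                           seed = derive_seed(config$seed, "integration")))
    results$integration <- prof
    write_table(prof[, c("group", "stage", "n", "CR", "p_CR")],
                file.path(config$out_dir, "cr_by_species_stage.csv"))
    write_table(prof[, c("group", "stage", "n", "GI_slope", "GI_class")],
                file.path(config$out_dir, "gi_by_species_stage.csv"))
  }

  manifest <- list(seed = config$seed, n_permutations = np,
                   steps = config$steps,
                   n_specimens = dim(aligned$shapes)[3],
                   k_landmarks = dim(aligned$shapes)[1],
                   package_version = as.character(utils::packageVersion("ontomorph")),
                   config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$out_dir <- config$out_dir
  invisible(results)
}

# Small deterministic hash of the serialized config (djb2 over the
# deparsed object; provenance only, not cryptographic).
config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  h <- 5381
  for (code in utf8ToInt(txt)) h <- (h * 33 + code) %% 2^31
  sprintf("%08x", h)
}
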
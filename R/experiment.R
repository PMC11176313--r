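#' Objective set of a numbered experimental condition
#'
#' The seven objective-function combinations compared in the experiment:
#' 1 baseline (TE up, coupling cost down); 2 TE up only; 3 coupling cost
#' down only; 4 density down only; 5 all three; 6 TE up and density down;
#' 7 coupling cost down and density down.
#'
#' @param condition_id Integer 1..7.
#' @return Character vector of canonical objective names.
#' @export
condition_objectives <- function(condition_id) {
  sets <- list(
    c("maximize_te", "minimize_cost"),
    "maximize_te",
    "minimize_cost",
    "minimize_density",
    c("maximize_te", "minimize_cost", "minimize_density"),
    c("maximize_te", "minimize_density"),
    c("minimize_cost", "minimize_density")
  )
  if (!condition_id %in% 1:7) stop("'condition_id' must be 1..7")
  sets[[condition_id]]
}

#' Size presets for experiment runs
#'
#' Bundles the run dimensions: `"paper"` is the full published scale
#' (100 generations, P = Q = 250, a 20,000-step series from 5 landscapes);
#' `"desk"` is the reduced scale used throughout the test-suite-sized
#' experiments (10 generations, P = Q = 25, a 2,000-step series); `"smoke"`
#' is minimal.
#'
#' @param scale `"paper"`, `"desk"` or `"smoke"`.
#' @return List with `generations`, `p_survivors`, `q_offspring`,
#'   `n_landscapes`, `n_scenes`, `n_clips`.
#' @export
scale_preset <- function(scale = c("desk", "smoke", "paper")) {
  scale <- match.arg(scale)
  switch(scale,
         paper = list(generations = 100L, p_survivors = 250L,
                      q_offspring = 250L, n_landscapes = 5L,
                      n_scenes = 100L, n_clips = 40L),
         desk = list(generations = 10L, p_survivors = 25L,
                     q_offspring = 25L, n_landscapes = 2L,
                     n_scenes = 25L, n_clips = 40L),
         smoke = list(generations = 2L, p_survivors = 6L,
                      q_offspring = 6L, n_landscapes = 1L,
                      n_scenes = 5L, n_clips = 10L))
}

#' Build the training saccade series for a preset
#'
#' @param preset A [scale_preset()] list.
#' @param seed Integer seed.
#' @return A training `"stimulus_series"`.
#' @export
preset_training_series <- function(preset, seed = 1L) {
  landscapes <- lapply(seq_len(preset$n_landscapes), function(i) {
    generate_surrogate_landscape(derive_seed(seed, 100L + i))
  })
  make_saccade_series(landscapes, n_scenes = preset$n_scenes,
                      n_clips = preset$n_clips,
                      seed = derive_seed(seed, 200L))
}

#' Consensus connectivity across a set of patterns
#'
#' For each matrix entry, the signed agreement rate
#' `(#patterns with w > 0 - #patterns with w < 0) / #patterns`, mapping
#' unanimous excitatory connections to +1 and unanimous inhibitory ones to
#' -1.
#'
#' @param patterns Nonempty list of `"wiring_pattern"` objects (or plain
#'   matrices) with identical dimensions.
#' @return Matrix with entries in `[-1, 1]`.
#' @export
consensus_connectivity <- function(patterns) {
  if (length(patterns) < 1) stop("need at least one pattern")
  mats <- lapply(patterns, function(p) if (is.list(p)) p$W else p)
  pos <- Reduce(`+`, lapply(mats, function(W) (W > 0) * 1))
  neg <- Reduce(`+`, lapply(mats, function(W) (W < 0) * 1))
  (pos - neg) / length(mats)
}

#' Run one full experimental condition
#'
#' Orchestrates an experiment end-to-end: builds the training saccade
#' series, evolves wiring patterns under the condition's objective set,
#' extracts the top and bottom transfer-entropy sets, characterizes three
#' representative entities (a fresh random pattern, the top pattern, the
#' bottom pattern) under the eight-stimulus probe protocol, and assembles a
#' manifest of summary tables.
#'
#' @param condition_id Condition 1..7 (see [condition_objectives()]).
#' @param scale Size preset name (see [scale_preset()]).
#' @param seed Master integer seed.
#' @param params,hebb,info Model parameter objects.
#' @param out_dir Optional directory; when given, the per-generation summary
#'   and per-pattern metrics are written there as CSV.
#' @param verbose Passed to [evolve_wiring()].
#' @return An object of class `"run_manifest"`: list with `condition`,
#'   `objectives`, `scale`, `seed`, `fit` (the `"wiring_evolution"`),
#'   `top`, `bottom` (archive index vectors), `characterization` (named
#'   list for `rand`, `top`, `bot` entities: `fd`, `separation_nmi`,
#'   normalized `volume`, `cumulative_contribution`), `consensus` (list
#'   with `top` and `bottom` consensus-connectivity matrices) and
#'   `files` (paths written, if any).
#' @export
run_condition <- function(condition_id = 1L, scale = "desk", seed = 1L,
                          params = reservoir_params(), hebb = hebb_params(),
                          info = info_config(), out_dir = NULL,
                          verbose = FALSE) {
  objectives <- condition_objectives(condition_id)
  preset <- scale_preset(scale)
  series <- preset_training_series(preset, seed)
  config <- evolution_config(generations = preset$generations,
                             p_survivors = preset$p_survivors,
                             q_offspring = preset$q_offspring,
                             objectives = objectives)
  fit <- evolve_wiring(series, config, params, hebb, info,
                       seed = seed, verbose = verbose)
  tb <- top_bottom_patterns(fit, fraction = 0.1, from = "all")

  probe <- make_probe_series(seed = derive_seed(seed, 300L))
  rand_pat <- init_pattern(params, seed = derive_seed(seed, 301L),
                           layout = fit$layout, id = "rand")
  entities <- list(rand = rand_pat,
                   top = fit$archive[[tb$top[1]]]$pattern,
                   bot = fit$archive[[tb$bottom[1]]]$pattern)
  characterization <- lapply(entities, function(p) {
    characterize_pattern(p, probe = probe, params = params, info = info,
                         seed = derive_seed(seed, 302L))
  })
  # volumes are compared on a shared voxel grid across the entities
  edges <- vapply(characterization, function(ch) {
    p <- ch$embedded$points
    max(apply(p, 2, max) - apply(p, 2, min))
  }, 0)
  vox <- max(edges) / 50
  vols <- normalize_volumes(vapply(characterization, function(ch) {
    trajectory_volume(ch$embedded$points, voxel_size = vox)
  }, 0))
  for (nm in names(characterization)) {
    characterization[[nm]]$volume <- vols[[nm]]
  }

  consensus <- list(
    top = consensus_connectivity(lapply(fit$archive[tb$top],
                                        function(r) r$pattern)),
    bottom = consensus_connectivity(lapply(fit$archive[tb$bottom],
                                           function(r) r$pattern)))

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "generation_summary.csv")
    write.csv(fit$summary, f1, row.names = FALSE)
    metrics <- do.call(rbind, lapply(fit$archive, function(r) {
      data.frame(id = r$pattern$id, gen = r$gen, te = r$te, cost = r$cost,
                 density = r$density, modularity = r$modularity,
                 clustering = r$clustering, avg_path = r$avg_path)
    }))
    f2 <- file.path(out_dir, "pattern_metrics.csv")
    write.csv(metrics, f2, row.names = FALSE)
    files <- c(f1, f2)
  }

  structure(list(condition = condition_id, objectives = objectives,
                 scale = scale, seed = seed, fit = fit,
                 top = tb$top, bottom = tb$bottom,
                 characterization = characterization,
                 consensus = consensus, files = files),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Experiment manifest: condition", x$condition,
      "| objectives:", paste(x$objectives, collapse = ", "),
      "| scale:", x$scale, "| seed:", x$seed, "\n")
  ch <- x$characterization
  for (nm in names(ch)) {
    cat(sprintf("  %-4s FD %.3f  NMI %.3f  volume %.3f\n", nm,
                ch[[nm]]$fd, ch[[nm]]$separation_nmi, ch[[nm]]$volume))
  }
  invisible(x)
}
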
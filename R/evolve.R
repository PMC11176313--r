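#' Evolution configuration
#'
#' Settings of the NSGA-II loop over wiring patterns.  Objectives are any
#' nonempty subset of `"maximize_te"`, `"minimize_cost"`,
#' `"minimize_density"` (shorthand `"te"`, `"cost"`, `"density"` accepted);
#' internally all objectives are minimized, transfer entropy entering
#' negated.
#'
#' @param generations Number of NSGA-II cycles.
#' @param p_survivors Patterns preserved per generation (P).
#' @param q_offspring Patterns newly generated per generation (Q); the
#'   working population holds `P + Q` patterns.
#' @param objectives Character vector of objective names.
#' @param block_size Side of the square structural regions used by crossover
#'   and mutation (default 2).
#' @param p_mutation Fraction of offspring subjected to mutation
#'   (default 0.8).
#' @param p_delete Probability a mutation deletes rather than adds
#'   (default 0.5).
#' @param parent_selection `"tournament"` (binary tournament on rank then
#'   crowding, the default) or `"uniform"` (parents drawn uniformly from the
#'   survivors).
#' @param n_mut_regions Regions mutated per mutation event (default 1).
#' @return A list of class `"evolution_config"`.
#' @export
evolution_config <- function(generations = 10L, p_survivors = 25L,
                             q_offspring = 25L,
                             objectives = c("maximize_te", "minimize_cost"),
                             block_size = 2L, p_mutation = 0.8,
                             p_delete = 0.5,
                             parent_selection = c("tournament", "uniform"),
                             n_mut_regions = 1L) {
  objectives <- canonical_objectives(objectives)
  stopifnot(generations >= 1, p_survivors >= 1, q_offspring >= 1,
            p_mutation >= 0, p_mutation <= 1,
            p_delete >= 0, p_delete <= 1, block_size >= 1)
  structure(list(generations = as.integer(generations),
                 p_survivors = as.integer(p_survivors),
                 q_offspring = as.integer(q_offspring),
                 objectives = objectives,
                 block_size = as.integer(block_size),
                 p_mutation = p_mutation, p_delete = p_delete,
                 parent_selection = match.arg(parent_selection),
                 n_mut_regions = as.integer(n_mut_regions)),
            class = "evolution_config")
}

canonical_objectives <- function(objectives) {
  map <- c(te = "maximize_te", maximize_te = "maximize_te",
           cost = "minimize_cost", minimize_cost = "minimize_cost",
           density = "minimize_density", minimize_density = "minimize_density")
  if (length(objectives) == 0 || !all(objectives %in% names(map))) {
    stop("'objectives' must be a nonempty subset of maximize_te, ",
         "minimize_cost, minimize_density")
  }
  unname(unique(map[objectives]))
}

# Objective vector (minimization convention) from an evaluation record.
objective_vector <- function(rec, objectives) {
  vapply(objectives, function(o) {
    switch(o,
           maximize_te = -rec$te,
           minimize_cost = rec$cost,
           minimize_density = rec$density)
  }, 0)
}

# Full per-pattern evaluation pipeline: spectral normalization is already
# guaranteed by init/crossover/mutation; here the pattern is Hebbian-tuned
# under spontaneous activity, its readout is Hebbian-trained while the
# reservoir is driven by the training series (a single pass: readout weights
# do not feed back into the reservoir), and all metrics are measured from
# that run.
evaluate_pattern <- function(pattern, series, params, hebb, info, layout,
                             seed) {
  pattern <- tune_reservoir(pattern, params, hebb,
                            seed = derive_seed(seed, 1L))
  W_out <- init_readout(params, seed = derive_seed(seed, 2L))
  res <- run_core(pattern, W_out, series, params,
                  seed = derive_seed(seed, 3L),
                  hebb = hebb, learn_readout = TRUE)
  te_m <- te_matrix(series$vectors,
                    res$trajectory$r[, subtype_index(pattern, "rc_readout"),
                                     drop = FALSE],
                    info)
  sr <- structure_record(pattern, layout)
  list(pattern = pattern, te = sum(te_m), cost = sr$cost,
       density = sr$density, modularity = sr$modularity,
       clustering = sr$clustering, avg_path = sr$avg_path)
}

summary_row <- function(gen, recs) {
  g <- function(f, x) f(vapply(recs, `[[`, 0, x))
  data.frame(gen = gen, n = length(recs),
             te_max = g(max, "te"), te_min = g(min, "te"),
             te_mean = g(mean, "te"),
             cost_max = g(max, "cost"), cost_min = g(min, "cost"),
             cost_mean = g(mean, "cost"),
             density_max = g(max, "density"), density_min = g(min, "density"),
             density_mean = g(mean, "density"),
             modularity_max = g(max, "modularity"),
             modularity_min = g(min, "modularity"),
             modularity_mean = g(mean, "modularity"),
             clustering_mean = g(mean, "clustering"),
             path_mean = g(mean, "avg_path"))
}

# Rank + crowding over a set of records; returns list(rank, crowding).
rank_and_crowding <- function(recs, objectives) {
  pts <- t(vapply(recs, objective_vector, numeric(length(objectives)),
                  objectives = objectives))
  if (length(objectives) == 1) pts <- matrix(pts, ncol = 1)
  fronts <- non_dominated_sort(pts)
  rank <- integer(length(recs))
  crowd <- numeric(length(recs))
  for (f in seq_along(fronts)) {
    idx <- fronts[[f]]
    rank[idx] <- f
    crowd[idx] <- crowding_distance(pts[idx, , drop = FALSE])
  }
  list(rank = rank, crowding = crowd, fronts = fronts, points = pts)
}

# NSGA-II survivor selection: fill by front, crowding-truncate the last.
select_survivors <- function(recs, objectives, p) {
  rc <- rank_and_crowding(recs, objectives)
  chosen <- integer(0)
  for (f in rc$fronts) {
    if (length(chosen) + length(f) <= p) {
      chosen <- c(chosen, f)
    } else {
      need <- p - length(chosen)
      ord <- f[order(rc$crowding[f], decreasing = TRUE)]
      chosen <- c(chosen, ord[seq_len(need)])
      break
    }
  }
  chosen
}

tournament_pick <- function(rank, crowding) {
  a <- sample.int(length(rank), 1L)
  b <- sample.int(length(rank), 1L)
  if (rank[a] < rank[b]) return(a)
  if (rank[b] < rank[a]) return(b)
  if (crowding[a] >= crowding[b]) a else b
}

#' Evolve reservoir wiring patterns with NSGA-II
#'
#' The central fitting routine.  An initial population of `P + Q` random
#' patterns is spectral-radius normalized, Hebbian-tuned under spontaneous
#' activity, readout-trained on the supplied stimulus series and scored on
#' the configured objectives (transfer entropy, coupling cost, density).
#' Each generation, `P` survivors are kept by non-dominated rank and
#' crowding distance, and `Q` offspring are produced by block crossover of
#' tournament-selected parents followed (with probability `p_mutation`) by
#' block mutation; offspring are evaluated through the same pipeline.  The
#' run is fully reproducible from `seed`.
#'
#' @param series Training `"stimulus_series"` (saccade clips).
#' @param config An [evolution_config()] object.
#' @param params A [reservoir_params()] object.
#' @param hebb A [hebb_params()] object.
#' @param info An [info_config()] object.
#' @param layout A [build_layout()] object (default: 3-layer 4x4 grid).
#' @param seed Master integer seed for every random choice in the run.
#' @param verbose Print one progress line per generation.
#' @return An object of class `"wiring_evolution"`: list with `summary`
#'   (per-generation statistics, `generations + 1` rows: the initial
#'   population then each generation's survivors), `archive` (every
#'   evaluated pattern with its metrics and birth generation),
#'   `survivors` (archive indices of the final surviving P patterns),
#'   `population` (archive indices of the final P + Q population), plus the
#'   configuration objects and seed.
#' @seealso [run_condition()] for the full experiment including
#'   characterization; [top_bottom_patterns()] to extract extreme entities.
#' @export
evolve_wiring <- function(series, config = evolution_config(),
                          params = reservoir_params(),
                          hebb = hebb_params(), info = info_config(),
                          layout = NULL, seed = 1L, verbose = FALSE) {
  if (is.null(layout)) layout <- default_layout(params)
  P <- config$p_survivors
  Q <- config$q_offspring
  archive <- vector("list", P + config$generations * Q)
  n_arch <- 0L
  summary_rows <- vector("list", config$generations + 1L)

  with_seed(seed, {
    eval_seed <- function() sample.int(2147483646L, 1L)
    new_id <- function(gen, k) sprintf("g%02d-%03d", gen, k)

    # initial population of P + Q patterns
    pop <- vector("list", P + Q)
    for (i in seq_len(P + Q)) {
      pat <- init_pattern(params, seed = eval_seed(), layout = layout,
                          id = new_id(0L, i))
      rec <- evaluate_pattern(pat, series, params, hebb, info, layout,
                              seed = eval_seed())
      rec$gen <- 0L
      n_arch <- n_arch + 1L
      rec$archive_index <- n_arch
      archive[[n_arch]] <- rec
      pop[[i]] <- rec
    }
    summary_rows[[1L]] <- summary_row(0L, pop)

    # the initial population counts as the first cycle; each further cycle
    # preserves P survivors and adds Q offspring, so a run touches
    # generations * Q + P patterns in total
    for (gen in seq_len(config$generations - 1L)) {
      surv_idx <- select_survivors(pop, config$objectives, P)
      survivors <- pop[surv_idx]
      summary_rows[[gen + 1L]] <- summary_row(gen, survivors)
      rc <- rank_and_crowding(survivors, config$objectives)

      offspring <- vector("list", Q)
      for (k in seq_len(Q)) {
        if (config$parent_selection == "tournament") {
          ia <- tournament_pick(rc$rank, rc$crowding)
          ib <- tournament_pick(rc$rank, rc$crowding)
        } else {
          ia <- sample.int(length(survivors), 1L)
          ib <- sample.int(length(survivors), 1L)
        }
        child <- crossover(survivors[[ia]]$pattern, survivors[[ib]]$pattern,
                           config$block_size, id = new_id(gen, k))
        if (runif(1) < config$p_mutation) {
          child <- mutate_pattern(child, config$block_size, config$p_delete,
                                  params$sparsity, config$n_mut_regions)
        }
        rec <- evaluate_pattern(child, series, params, hebb, info, layout,
                                seed = eval_seed())
        rec$gen <- gen
        n_arch <- n_arch + 1L
        rec$archive_index <- n_arch
        archive[[n_arch]] <- rec
        offspring[[k]] <- rec
      }
      pop <- c(survivors, offspring)
      if (verbose) {
        s <- summary_rows[[gen + 1L]]
        message(sprintf(
          "gen %3d | TE max %.3f mean %.3f | cost mean %.1f | dens %.3f",
          gen, s$te_max, s$te_mean, s$cost_mean, s$density_mean))
      }
    }

    # final survivor selection closes the run
    final_idx <- select_survivors(pop, config$objectives, P)
    summary_rows[[config$generations + 1L]] <-
      summary_row(config$generations, pop[final_idx])

    structure(list(
      summary = do.call(rbind, summary_rows),
      archive = archive[seq_len(n_arch)],
      survivors = vapply(pop[final_idx], `[[`, 0L, "archive_index"),
      population = vapply(pop, `[[`, 0L, "archive_index"),
      config = config, params = params, hebb = hebb, info = info,
      layout = layout, seed = seed),
      class = "wiring_evolution")
  })
}

#' Extract top/bottom transfer-entropy patterns from an evolution run
#'
#' Ranks evaluated patterns by transfer entropy and returns the indices of
#' the highest and lowest sets — the analogue of the top-100/bottom-100
#' split at full scale, taken as a fraction of the evaluated patterns at
#' reduced scale.
#'
#' @param fit A `"wiring_evolution"` object.
#' @param fraction Fraction of patterns per set (default 0.1).
#' @param from `"all"` evaluated patterns (default) or the `"final"`
#'   population.
#' @return List with `top` and `bottom` (archive indices, best/worst first).
#' @export
top_bottom_patterns <- function(fit, fraction = 0.1,
                                from = c("all", "final")) {
  from <- match.arg(from)
  idx <- if (from == "all") seq_along(fit$archive) else fit$population
  te <- vapply(fit$archive[idx], `[[`, 0, "te")
  k <- max(1L, round(fraction * length(idx)))
  ord <- order(te, decreasing = TRUE)
  list(top = idx[ord[seq_len(k)]],
       bottom = idx[rev(ord)[seq_len(k)]])
}

#' Expected number of patterns touched by a run
#'
#' The accounting identity for a full NSGA-II run: the initial population
#' (`P + Q`, counting as the first cycle) plus `Q` fresh offspring in each
#' of the remaining `generations - 1` cycles, i.e.
#' `generations * Q + P` patterns in total.
#'
#' @param generations,p_survivors,q_offspring Run dimensions.
#' @return Total number of evaluated patterns.
#' @examples
#' pattern_count(100, 250, 250)  # 25250
#' @export
pattern_count <- function(generations, p_survivors, q_offspring) {
  generations * q_offspring + p_survivors
}

#' @export
print.wiring_evolution <- function(x, ...) {
  s <- x$summary
  last <- s[nrow(s), ]
  cat("Wiring-pattern evolution (NSGA-II)\n")
  cat("  objectives :", paste(x$config$objectives, collapse = ", "), "\n")
  cat(sprintf("  generations: %d   P = %d, Q = %d   evaluated: %d\n",
              x$config$generations, x$config$p_survivors,
              x$config$q_offspring, length(x$archive)))
  cat(sprintf("  TE    mean : %.3f -> %.3f (bits)\n",
              s$te_mean[1], last$te_mean))
  cat(sprintf("  cost  mean : %.1f -> %.1f\n",
              s$cost_mean[1], last$cost_mean))
  cat(sprintf("  dens. mean : %.3f -> %.3f\n",
              s$density_mean[1], last$density_mean))
  invisible(x)
}

#' @export
summary.wiring_evolution <- function(object, ...) {
  structure(list(summary = object$summary,
                 objectives = object$config$objectives),
            class = "summary.wiring_evolution")
}

#' @export
print.summary.wiring_evolution <- function(x, ...) {
  cat("Per-generation statistics (row 0 = initial population):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot metric trajectories of an evolution run
#'
#' Draws the per-generation maximum, minimum and mean of transfer entropy,
#' coupling cost, density and modularity across survivors.
#'
#' @param x A `"wiring_evolution"` object.
#' @param ... Unused.
#' @export
plot.wiring_evolution <- function(x, ...) {
  s <- x$summary
  old <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  panel <- function(stem, label) {
    cols <- paste0(stem, c("_max", "_min", "_mean"))
    matplot(s$gen, s[, cols], type = "l", lty = c(2, 2, 1),
            col = c("red", "blue", "black"), xlab = "generation",
            ylab = label, main = label)
  }
  panel("te", "transfer entropy (bits)")
  panel("cost", "coupling cost")
  panel("density", "density")
  panel("modularity", "modularity Q")
  invisible(x)
}
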
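#' Simulation configuration
#'
#' Collects every tunable of the recurrent-selection scheme with the study's
#' standard values as defaults: 50 couples x 20 offspring give a breeding
#' population of 1000; two generations of single-seed descent; a training
#' panel updated with 150 records per cycle; 100 geometric-effect QTL;
#' entry-mean heritability 0.5 over 3 environments with environmental
#' variance 8x the genetic variance.
#'
#' @param method one of `"baseline"`, `"scoping"`, `"population_merit"`,
#'   `"mvt"`.
#' @param SR scoping rate (scoping method only).
#' @param c population-merit penalty weight.
#' @param n_cycles breeding cycles per replicate.
#' @param n_reps number of independent replicates.
#' @param n_couples couples per crossing block (parents = `2 * n_couples`).
#' @param offspring_per_couple F1 per couple.
#' @param ssd_generations single-seed-descent generations.
#' @param tp_update_n training-panel records exchanged per cycle.
#' @param maf_threshold MAF filter threshold.
#' @param L number of QTL.
#' @param h2 target entry-mean heritability.
#' @param env_ratio environmental-to-genetic variance ratio.
#' @param n_env environments per phenotyping event.
#' @param mvt_pre_n pre-selection size of the MVT method.
#' @param master_seed integer master seed; replicate sub-seeds derive from it.
#' @param founders founder source: a list from [synth_founders()] (fields
#'   `panel_a`, `panel_b`) or a specification list
#'   `list(type = "synthetic", n_lines_per_panel = ..., n_loci = ..., ...)`
#'   forwarded to [synth_founders()].
#' @return A validated list of class `gs_config`.
#' @export
sim_config <- function(method = c("baseline", "scoping", "population_merit",
                                  "mvt"),
                       SR = 0.3, c = 20, n_cycles = 50, n_reps = 250,
                       n_couples = 50, offspring_per_couple = 20,
                       ssd_generations = 2, tp_update_n = 150,
                       maf_threshold = 0.03, L = 100, h2 = 0.5,
                       env_ratio = 8, n_env = 3, mvt_pre_n = 300,
                       master_seed = 1, founders = list(type = "synthetic")) {
  method <- match.arg(method)
  stopifnot(SR >= 0.1, SR <= 1, n_cycles >= 1, n_reps >= 1,
            n_couples >= 1, offspring_per_couple >= 1,
            ssd_generations >= 1, tp_update_n %% 2 == 0)
  cfg <- list(method = method, SR = SR, c = c, n_cycles = n_cycles,
              n_reps = n_reps, n_couples = n_couples,
              n_parents = 2L * n_couples,
              offspring_per_couple = offspring_per_couple,
              pop_size = n_couples * offspring_per_couple,
              ssd_generations = ssd_generations, tp_update_n = tp_update_n,
              maf_threshold = maf_threshold, L = L, h2 = h2,
              env_ratio = env_ratio, n_env = n_env, mvt_pre_n = mvt_pre_n,
              master_seed = as.integer(master_seed), founders = founders)
  if (cfg$pop_size < cfg$n_parents)
    stop("breeding population smaller than the number of parents",
         call. = FALSE)
  structure(cfg, class = "gs_config")
}

#' @export
print.gs_config <- function(x, ...) {
  cat(sprintf(
    "<gs_config> method = %s, %d cycles x %d reps, pop = %d, parents = %d\n",
    x$method, x$n_cycles, x$n_reps, x$pop_size, x$n_parents))
  invisible(x)
}

resolve_founders <- function(founders) {
  if (!is.null(founders$panel_a)) return(founders)
  if (identical(founders$type, "synthetic")) {
    args <- founders[setdiff(names(founders), "type")]
    return(do.call(synth_founders, args))
  }
  if (identical(founders$type, "files")) {
    return(list(
      panel_a = read_founders(founders$genotype_a, founders$map, panel = "A"),
      panel_b = read_founders(founders$genotype_b, founders$map, panel = "B")))
  }
  stop("unrecognized founder specification", call. = FALSE)
}

#' Initial crossing block (cycle 0)
#'
#' Regardless of the selection method, cycle 0 couples the `n_per_panel`
#' phenotypically best lines of each founder panel, each couple pairing one
#' line from each panel by random cross-panel matching. This gives every
#' method the same starting breeding population under a shared seed.
#'
#' @param panel_a,panel_b founder `gs_pop` panels.
#' @param pheno_a,pheno_b phenotype tibbles (`id`, `value`) for the panels.
#' @param n_per_panel lines selected per panel.
#' @return A tibble `couple`, `p1`, `p2` (`p1` from panel A, `p2` from B).
#' @export
initial_crossing_block <- function(panel_a, panel_b, pheno_a, pheno_b,
                                   n_per_panel = 50) {
  if (n_ind(panel_a) < n_per_panel || n_ind(panel_b) < n_per_panel)
    stop("founder panel smaller than the requested selection", call. = FALSE)
  top <- function(ph) ph$id[order(ph$value, decreasing = TRUE)][seq_len(n_per_panel)]
  tibble::tibble(couple = seq_len(n_per_panel),
                 p1 = sample(top(pheno_a)), p2 = sample(top(pheno_b)))
}

select_couples <- function(cfg, gebvs, pop, q) {
  switch(cfg$method,
    baseline = random_mating(truncation_select(gebvs, cfg$n_parents)),
    scoping = scoping_select(gebvs, pop, q, SR = cfg$SR,
                             n_couples = cfg$n_couples),
    population_merit = pm_select(gebvs, pop, q, c = cfg$c,
                                 n = cfg$n_parents),
    mvt = mvt_select(gebvs, pop, q, pre_n = cfg$mvt_pre_n,
                     n = cfg$n_parents))
}

#' Run one breeding cycle
#'
#' One turn of the recurrent-selection loop: (1) fit RR-BLUP on the training
#' panel (MAF-filtered), (2) predict GEBVs on the breeding population,
#' (3) select parents and couples by the configured method, (4) update the
#' training panel by the tails rule (phenotyping the selected records),
#' (5) cross the couples into F1, (6) advance by single-seed descent to the
#' next breeding population, (7) record the cycle's metrics (for the
#' population the model was fit against, with its prediction accuracy).
#'
#' @param state list with elements `pop` (breeding `gs_pop`), `tp` (`gs_tp`),
#'   `q` (`gs_qtl`), `vs` (`gs_varsettings`), `cycle` (completed cycles).
#' @param cfg a `gs_config`.
#' @return The updated state; `state$metrics` accumulates one row per cycle.
#' @export
run_cycle <- function(state, cfg) {
  cyc <- state$cycle + 1L
  model <- fit_rrblup(state$tp, maf_threshold = cfg$maf_threshold)
  gebvs <- predict_gebv(state$pop, model)
  couples <- select_couples(cfg, gebvs, state$pop, state$q)
  state$tp <- tails_update(state$tp, state$pop, gebvs, state$q, state$vs,
                           n_new = cfg$tp_update_n, cycle = cyc)
  f1 <- cross(state$pop, couples, n_offspring = cfg$offspring_per_couple,
              cycle = cyc)
  nxt <- single_seed_descent(f1, generations = cfg$ssd_generations)
  state$metrics <- dplyr::bind_rows(
    state$metrics, summarize_cycle(state$pop, state$q, gebvs,
                                   cycle = state$cycle))
  state$pop <- nxt
  state$cycle <- cyc
  state
}

# one full replicate under its own seed; returns the per-cycle metrics tibble
run_one_rep <- function(cfg, founders, seed) {
  set.seed(seed)
  base <- bind_pops(founders$panel_a, founders$panel_b)
  q <- sample_qtl(base$map, L = cfg$L)
  vs <- calibrate_variances(base, q, h2 = cfg$h2, env_ratio = cfg$env_ratio,
                            n_env = cfg$n_env)
  pheno <- simulate_phenotypes(base, q, vs, cycle = 0L)
  tp <- training_panel(base, pheno, q)
  block <- initial_crossing_block(
    founders$panel_a, founders$panel_b,
    pheno[match(founders$panel_a$id, pheno$id), ],
    pheno[match(founders$panel_b$id, pheno$id), ],
    n_per_panel = cfg$n_couples)
  f1 <- cross(base, block, n_offspring = cfg$offspring_per_couple, cycle = 0L)
  pop <- single_seed_descent(f1, generations = cfg$ssd_generations)

  state <- list(pop = pop, tp = tp, q = q, vs = vs, cycle = 0L,
                metrics = NULL)
  for (i in seq_len(cfg$n_cycles)) state <- run_cycle(state, cfg)
  # final population: one extra fit so its accuracy is defined
  model <- fit_rrblup(state$tp, maf_threshold = cfg$maf_threshold)
  gebvs <- predict_gebv(state$pop, model)
  dplyr::bind_rows(state$metrics,
                   summarize_cycle(state$pop, state$q, gebvs,
                                   cycle = state$cycle))
}

#' Run replicated breeding simulations
#'
#' Runs `n_reps` independent replicates of the configured breeding scheme.
#' The founder panels are resolved once; each replicate draws its own
#' sub-seed from the master seed and re-samples the QTL model, founder
#' phenotype noise and every stochastic stage. Two calls with the same
#' configuration (and founders) give identical trajectories, and different
#' methods run with the same `master_seed` share founders, per-replicate QTL
#' models and cycle-0 crossing blocks, so method comparisons are paired.
#'
#' @param cfg a `gs_config`.
#' @param founders optional resolved founder list (`panel_a`, `panel_b`);
#'   by default resolved from `cfg$founders`.
#' @param progress print a line per replicate.
#' @return An object of class `gs_trajectory`: list with `per_rep` (tibble:
#'   `rep`, `method`, per-cycle metrics) and `aggregate` (per-cycle means
#'   across replicates), plus the configuration.
#' @export
run_replicates <- function(cfg, founders = NULL, progress = FALSE) {
  if (is.null(founders)) {
    set.seed(cfg$master_seed)
    founders <- resolve_founders(cfg$founders)
  }
  set.seed(cfg$master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_reps)
  reps <- vector("list", cfg$n_reps)
  for (r in seq_len(cfg$n_reps)) {
    t0 <- Sys.time()
    reps[[r]] <- dplyr::mutate(run_one_rep(cfg, founders, seeds[r]),
                               rep = r, method = cfg$method,
                               .before = 1)
    if (progress)
      message(sprintf("rep %d/%d (%s) done in %.1fs", r, cfg$n_reps,
                      cfg$method,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  per_rep <- dplyr::bind_rows(reps)
  agg <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$method, .data$cycle),
    dplyr::across(c("mean_gv", "top10_gv", "fixed_gv", "max_reachable_gv",
                    "pct_qtl_fixed", "genetic_variance", "accuracy"),
                  ~ mean(.x, na.rm = TRUE)),
    .groups = "drop")
  structure(list(per_rep = per_rep, aggregate = agg, config = cfg),
            class = "gs_trajectory")
}

#' @export
print.gs_trajectory <- function(x, ...) {
  cat(sprintf("<gs_trajectory> %s: %d reps x %d cycles\n",
              x$config$method, x$config$n_reps, x$config$n_cycles))
  print(utils::tail(x$aggregate, 3))
  invisible(x)
}

#' @export
tidy.gs_trajectory <- function(x, ...) x$per_rep

#' @export
glance.gs_trajectory <- function(x, ...) {
  last <- dplyr::filter(x$aggregate, .data$cycle == max(.data$cycle))
  dplyr::mutate(last, n_reps = x$config$n_reps, .before = 1)
}

#' Plot a simulation trajectory
#'
#' Per-cycle aggregate means of the main metrics (mean and top-10 genetic
#' value, maximum reachable value, QTL fixation), faceted by metric.
#'
#' @param object a `gs_trajectory` (or a list of them, to overlay methods).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.gs_trajectory <- function(object, ...) {
  agg <- if (inherits(object, "gs_trajectory")) object$aggregate
         else dplyr::bind_rows(lapply(object, function(t) t$aggregate))
  long <- tidyr::pivot_longer(
    agg, c("mean_gv", "top10_gv", "max_reachable_gv", "pct_qtl_fixed"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "breeding cycle", y = NULL, colour = "method") +
    ggplot2::theme_minimal()
}

#' Write a trajectory as long-format TSV
#' @param x a `gs_trajectory`.
#' @param file output path.
#' @return `x`, invisibly.
#' @export
write_trajectory <- function(x, file) {
  long <- tidyr::pivot_longer(x$per_rep, -c("rep", "method", "cycle"),
                              names_to = "metric", values_to = "value")
  readr::write_tsv(long, file)
  invisible(x)
}
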
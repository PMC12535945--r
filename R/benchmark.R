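#' Benchmark active against random experiment selection
#'
#' Generates `n_gems` seeded synthetic gems, assembles each learning
#' problem once (the prediction matrix is shared across repeats), and
#' runs both strategies `repeats` times per gem with distinct seeds.
#' Per run it records the number of experiments and cumulative reagent
#' cost needed to first reach 100% held-out accuracy, plus totals at the
#' stopping point. Aggregate sample-complexity ratio curves are computed
#' from the step-wise mean accuracy of each strategy (runs shorter than
#' the longest carry their final accuracy forward), with the
#' discriminativeness floor `phi` taken as the minimum minimal reduction
#' ratio over every active selection.
#'
#' @param n_gems number of synthetic gems.
#' @param repeats repeats per gem per strategy.
#' @param params a [gem_params()] list.
#' @param mode `"digenic"` or `"monogenic"` target annotation.
#' @param budget per-run budget (default unlimited).
#' @param base_seed seed from which gem and run seeds are derived.
#' @param max_deletions,nutrient_subsets_up_to experiment-grid bounds.
#' @return list with `runs` (one row per run: gem, repeat, strategy,
#'   steps_to_full_accuracy, cost_to_full_accuracy, total_steps,
#'   total_cost, converged, recovered), `summary` (per-strategy
#'   medians), `ratios` (aggregate [sample_complexity_ratios()] table)
#'   and `phi`.
#' @export
simulate_benchmark <- function(n_gems = 20L, repeats = 10L,
                               params = gem_params(), mode = "digenic",
                               budget = Inf, base_seed = 1L,
                               max_deletions = 2L,
                               nutrient_subsets_up_to = 1L) {
  runs <- list()
  acc_curves <- list(active = list(), random = list())
  phi <- Inf

  for (g in seq_len(n_gems)) {
    gem_seed <- as.integer(base_seed) + 1000L * g
    gem <- generate_gem(params, seed = gem_seed, mode = mode)
    prob <- gem_learning_problem(gem, max_deletions, nutrient_subsets_up_to)
    for (r in seq_len(repeats)) {
      run_seed <- gem_seed + r
      for (strategy in c("active", "random")) {
        res <- if (strategy == "active") {
          run_active_learning(prob$task, prob$labels, budget, run_seed)
        } else {
          run_random_baseline(prob$task, prob$labels, budget, run_seed)
        }
        tr <- res$trace
        full <- tr$step[tr$heldout_accuracy >= 1 - 1e-12]
        s_full <- if (length(full) > 0L) min(full) else NA_integer_
        c_full <- if (is.na(s_full)) NA_real_ else tr$cumulative_cost[tr$step == s_full]
        runs[[length(runs) + 1L]] <- data.frame(
          gem = g, gem_seed = gem_seed, rep = r, strategy = strategy,
          steps_to_full_accuracy = s_full,
          cost_to_full_accuracy = c_full,
          total_steps = nrow(tr), total_cost = res$total_cost,
          converged = res$converged,
          recovered = identical(res$final_id, prob$hstar$id),
          stringsAsFactors = FALSE)
        acc_curves[[strategy]][[length(acc_curves[[strategy]]) + 1L]] <-
          tr$heldout_accuracy
        if (strategy == "active" && nrow(tr) > 0L) {
          phi <- min(phi, min(tr$min_reduction_ratio))
        }
      }
    }
  }
  runs <- do.call(rbind, runs)

  mean_curve <- function(curves) {
    len <- max(vapply(curves, length, integer(1L)))
    padded <- vapply(curves, function(a) {
      if (length(a) < len) a <- c(a, rep(a[length(a)], len - length(a)))
      a
    }, numeric(len))
    if (len == 1L) padded <- matrix(padded, nrow = 1L)
    data.frame(step = seq_len(len), heldout_accuracy = rowMeans(padded))
  }
  agg_active <- mean_curve(acc_curves$active)
  agg_random <- mean_curve(acc_curves$random)
  if (!is.finite(phi)) phi <- 0
  ratios <- sample_complexity_ratios(agg_active, agg_random, phi = phi)

  med <- function(strategy, col) {
    stats::median(runs[[col]][runs$strategy == strategy], na.rm = TRUE)
  }
  summary <- data.frame(
    strategy = c("active", "random"),
    median_steps_to_full_accuracy = c(med("active", "steps_to_full_accuracy"),
                                      med("random", "steps_to_full_accuracy")),
    median_cost_to_full_accuracy = c(med("active", "cost_to_full_accuracy"),
                                     med("random", "cost_to_full_accuracy")),
    median_total_steps = c(med("active", "total_steps"),
                           med("random", "total_steps")),
    median_total_cost = c(med("active", "total_cost"),
                          med("random", "total_cost")),
    recovery_rate = c(mean(runs$recovered[runs$strategy == "active"]),
                      mean(runs$recovered[runs$strategy == "random"])),
    stringsAsFactors = FALSE)

  list(runs = runs, summary = summary, ratios = ratios, phi = phi,
       mean_accuracy = list(active = agg_active, random = agg_random))
}
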
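#' Candidate experiments
#'
#' An experiment deletes a set of genes and optionally adds nutrients
#' (extra source metabolites) to the base medium; its cost is the summed
#' per-gram reagent cost of the added nutrients, normalised so the
#' cheapest nutrient costs 1. No-deletion controls (empty `deleted`) are
#' legal and cheap but carry little information.
#'
#' @param id experiment identifier.
#' @param deleted character vector of deleted gene ids (may be empty).
#' @param nutrients character vector of added nutrient metabolite ids.
#' @param cost non-negative experiment cost.
#' @return an object of class `experiment`.
#' @export
experiment <- function(id, deleted = character(), nutrients = character(),
                       cost = 0) {
  stopifnot(is.numeric(cost), length(cost) == 1L, cost >= 0)
  structure(list(id = as.character(id),
                 deleted = sort(unique(as.character(deleted))),
                 nutrients = sort(unique(as.character(nutrients))),
                 cost = as.numeric(cost)),
            class = "experiment")
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf("<experiment %s> delete {%s}, add {%s}, cost %.3g\n", x$id,
              paste(x$deleted, collapse = ","),
              paste(x$nutrients, collapse = ","), x$cost))
  invisible(x)
}

experiment_costs <- function(experiments) {
  vapply(experiments, `[[`, numeric(1L), "cost")
}

experiment_ids <- function(experiments) {
  vapply(experiments, `[[`, character(1L), "id")
}

#' Hypothesis-by-experiment Boolean prediction matrix
#'
#' Entry (i, j) is 1 (phenotypic effect predicted) iff, with hypothesis
#' `h_i` added to the background network, the mutant of experiment `t_j`
#' (genes deleted, nutrients added to the base medium) fails to produce
#' at least one essential metabolite *while the undeleted strain under
#' the same hypothesis and medium produces them all*. Wild-type controls
#' are therefore always predicted negative. All phenotypes are computed
#' with [bmlp_ie()]; fixpoints are memoised on the (mask, medium) pair,
#' so hypotheses inducing identical reaction masks share columns at no
#' extra cost.
#'
#' @param bk background [metabolic_network()] (possibly with masked
#'   rules).
#' @param H list of [hypothesis()] objects.
#' @param experiments list of [experiment()] objects.
#' @param base_medium character vector of base-medium metabolite ids.
#' @param essential character vector of essential metabolite ids.
#' @return 0/1 matrix of shape `|H| x |T|` with hypothesis ids as row
#'   names and experiment ids as column names.
#' @export
prediction_matrix <- function(bk, H, experiments, base_medium, essential) {
  stopifnot(inherits(bk, "metabolic_network"), length(H) > 0L,
            length(experiments) > 0L)
  enc <- encode_matrices(bk)
  ess_idx <- match(essential, bk$metabolites)
  if (anyNA(ess_idx)) stop("essential metabolite not in network", call. = FALSE)
  rxn_ids <- reaction_ids(bk)

  # a hypothesis only adds activations on the reactions its facts name, so
  # a (deletion set, extra-activation set, medium) triple determines the
  # fixpoint; memoise on that triple instead of on full masks
  h_genes <- lapply(H, function(h) h$facts$gene)
  h_rxn <- lapply(H, function(h) {
    idx <- match(h$facts$reaction, rxn_ids)
    if (anyNA(idx)) stop("hypothesis names unknown reaction", call. = FALSE)
    idx
  })
  wt_key <- vapply(seq_along(H), function(i) {
    paste(sort(unique(h_rxn[[i]])), collapse = ",")
  }, character(1L))

  mask_cache <- new.env(parent = emptyenv())
  base_mask <- function(del_key, deleted) {
    if (is.null(mask_cache[[del_key]])) {
      mask_cache[[del_key]] <- reaction_mask(bk, NULL, deleted)
    }
    mask_cache[[del_key]]
  }
  fp_cache <- new.env(parent = emptyenv())
  produces_all <- function(key, vmed, m0, extra_idx) {
    ok <- fp_cache[[key]]
    if (is.null(ok)) {
      mask <- m0
      if (length(extra_idx) > 0L) mask[extra_idx] <- 1L
      ok <- all(bmlp_ie(vmed, enc$R1, enc$R2, mask)$vstar[ess_idx] == 1L)
      fp_cache[[key]] <- ok
    }
    ok
  }

  nH <- length(H)
  pred <- matrix(0L, nH, length(experiments),
                 dimnames = list(vapply(H, `[[`, character(1L), "id"),
                                 experiment_ids(experiments)))
  m0_wt <- base_mask("d:", character())

  # process experiments grouped by deletion set: within a group every
  # hypothesis induces the same extra activations, so hypotheses collapse
  # into a handful of equivalence classes evaluated once per medium
  exp_del_key <- vapply(experiments, function(t) {
    paste0("d:", paste(t$deleted, collapse = ","))
  }, character(1L))
  for (grp in split(seq_along(experiments), exp_del_key)) {
    deleted <- experiments[[grp[[1L]]]]$deleted
    del_key <- exp_del_key[[grp[[1L]]]]
    m0 <- base_mask(del_key, deleted)
    ext <- lapply(seq_len(nH), function(i) {
      sort(unique(h_rxn[[i]][!(h_genes[[i]] %in% deleted)]))
    })
    ext_key <- vapply(ext, paste, character(1L), collapse = ",")
    classes <- split(seq_len(nH), ext_key)
    for (j in grp) {
      t_j <- experiments[[j]]
      vmed <- medium_vector(bk, union(base_medium, t_j$nutrients))
      med_key <- paste(t_j$nutrients, collapse = ",")
      for (members in classes) {
        lead <- members[[1L]]
        mut_ok <- produces_all(
          paste0(med_key, "|", del_key, "|", ext_key[[lead]]),
          vmed, m0, ext[[lead]])
        if (mut_ok) next  # mutants grow: no effect whatever the control
        for (wk in unique(wt_key[members])) {
          sub <- members[wt_key[members] == wk]
          wt_ok <- produces_all(paste0(med_key, "|d:|", wk),
                                vmed, m0_wt, h_rxn[[sub[[1L]]]])
          if (wt_ok) pred[sub, j] <- 1L
        }
      }
    }
  }
  pred
}

#' Probability of a positive experiment outcome
#'
#' Sum of the posterior weights of the alive hypotheses that predict a
#' phenotypic effect for the experiment.
#'
#' @param col 0/1 prediction column over the alive hypotheses.
#' @param posteriors posterior weights aligned with `col`.
#' @return a probability.
#' @export
outcome_probability <- function(col, posteriors) {
  if (length(col) != length(posteriors)) {
    stop("prediction column and posteriors misaligned", call. = FALSE)
  }
  sum(posteriors[col == 1L])
}

#' Expected-cost heuristic for one candidate experiment
#'
#' `EC(t) = C_t + p(t) * mbar * J_pos + (1 - p(t)) * mbar * J_neg`,
#' where `mbar` is the mean cost of the other remaining experiments
#' (0 when `t` is the last one), `p(t)` the positive-outcome probability
#' and `J_pos`/`J_neg` the (un-renormalised) posterior entropies of the
#' hypothesis subsets consistent with a positive/negative outcome. Lower
#' is better: a cheap experiment whose answer leaves little entropy
#' behind wins.
#'
#' @param cost cost of the candidate experiment.
#' @param other_costs costs of the remaining unlabelled experiments
#'   excluding the candidate (may be empty).
#' @param p_t positive-outcome probability (see
#'   [outcome_probability()]).
#' @param J_pos,J_neg entropy (bits) of the consistent /
#'   inconsistent-on-positive hypothesis subsets (see [entropy_term()]).
#' @return the expected cost (real).
#' @export
expected_cost <- function(cost, other_costs, p_t, J_pos, J_neg) {
  stopifnot(cost >= 0, p_t >= 0, p_t <= 1 + 1e-9)
  mbar <- if (length(other_costs) == 0L) 0 else mean(other_costs)
  cost + p_t * mbar * J_pos + (1 - p_t) * mbar * J_neg
}

#' Minimal reduction ratio of a candidate experiment
#'
#' The minority fraction of the current version space under the
#' experiment's predicted outcome: `min(#predict-1, #predict-0) /
#' #alive`, in \[0, 1/2\]. An experiment with ratio near 1/2 halves the
#' version space whichever way its label falls; a unanimous column has
#' ratio 0 and teaches nothing.
#'
#' @param col 0/1 prediction column over the alive hypotheses.
#' @return a real in \[0, 0.5\].
#' @export
minimal_reduction_ratio <- function(col) {
  if (length(col) == 0L) {
    stop("minimal reduction ratio undefined on an empty version space",
         call. = FALSE)
  }
  min(sum(col == 1L), sum(col == 0L)) / length(col)
}

#' Prune a version space with a labelled outcome
#'
#' Keeps exactly the alive hypotheses whose prediction for the labelled
#' experiment equals the observed label; ordering is preserved and the
#' operation is idempotent.
#'
#' @param alive logical vector over the full hypothesis list.
#' @param col 0/1 prediction column over the *full* hypothesis list.
#' @param label observed label, 0 or 1.
#' @return updated logical alive vector.
#' @export
prune_version_space <- function(alive, col, label) {
  stopifnot(length(alive) == length(col), label %in% c(0L, 1L))
  alive & (col == label)
}

#' Select the next experiment by minimum expected cost
#'
#' Among unlabelled experiments whose cost fits the remaining budget,
#' returns the index minimising the [expected_cost()] heuristic computed
#' from the current alive posteriors. Ties (within 1e-12) are broken by
#' the caller-supplied shuffle order. With uniform costs the rule reduces
#' to minimising the expected residual entropy
#' `p J_pos + (1 - p) J_neg`.
#'
#' @param pred full 0/1 prediction matrix (`|H| x |T|`).
#' @param alive logical vector over hypotheses (the version space).
#' @param posteriors posterior weights over the alive hypotheses (in
#'   alive order, summing to 1).
#' @param costs per-experiment cost vector.
#' @param labels integer vector over experiments, `NA` where unlabelled.
#' @param budget_remaining unspent budget.
#' @param tie_pos integer ranks used to break exact ties (e.g. a seeded
#'   shuffle); defaults to input order.
#' @return the selected experiment index, or `NA` if none is affordable.
#' @export
select_experiment <- function(pred, alive, posteriors, costs, labels,
                              budget_remaining = Inf,
                              tie_pos = seq_len(ncol(pred))) {
  stopifnot(nrow(pred) == length(alive), ncol(pred) == length(costs),
            ncol(pred) == length(labels), sum(alive) == length(posteriors))
  unlab <- which(is.na(labels))
  if (length(unlab) == 0L) return(NA_integer_)
  affordable <- unlab[costs[unlab] <= budget_remaining + 1e-12]
  if (length(affordable) == 0L) return(NA_integer_)

  w <- ifelse(posteriors > 0, -posteriors * log2(posteriors), 0)
  Ra <- pred[alive, unlab, drop = FALSE]
  p_t <- as.vector(posteriors %*% Ra)
  J_pos <- as.vector(w %*% Ra)
  J_neg <- sum(w) - J_pos
  n_un <- length(unlab)
  mbar <- if (n_un == 1L) {
    rep(0, 1L)
  } else {
    (sum(costs[unlab]) - costs[unlab]) / (n_un - 1L)
  }
  ec <- costs[unlab] + p_t * mbar * J_pos + (1 - p_t) * mbar * J_neg
  keep <- unlab %in% affordable
  cand <- unlab[keep]
  ec_aff <- ec[keep]
  tied <- cand[ec_aff <= min(ec_aff) + 1e-12]
  tied[which.min(tie_pos[tied])]
}

best_alive_hypothesis <- function(H, alive, comp) {
  idx <- which(alive)
  if (length(idx) == 0L) return(NA_integer_)
  sizes <- vapply(H[idx], hypothesis_size, integer(1L))
  # argmax compression; ties -> smaller size -> earlier input order
  ord <- order(-comp[idx], sizes, idx)
  idx[ord[1L]]
}

#' Bundle a learning problem
#'
#' Packages the background network, hypothesis space, candidate
#' experiments, base medium and essential set, computing (or accepting a
#' precomputed) prediction matrix. A task can be reused across repeats
#' and strategies so the expensive phenotype predictions are made once.
#'
#' @inheritParams prediction_matrix
#' @param pred optional precomputed [prediction_matrix()].
#' @return an object of class `learning_task`.
#' @export
learning_task <- function(bk, H, experiments, base_medium, essential,
                          pred = NULL) {
  if (is.null(pred)) {
    pred <- prediction_matrix(bk, H, experiments, base_medium, essential)
  }
  stopifnot(nrow(pred) == length(H), ncol(pred) == length(experiments))
  structure(list(bk = bk, H = H, experiments = experiments,
                 base_medium = base_medium, essential = essential,
                 pred = pred),
            class = "learning_task")
}

resolve_oracle_labels <- function(task, oracle) {
  if (is.function(oracle)) {
    labs <- vapply(task$experiments, function(t) as.integer(oracle(t)),
                   integer(1L))
  } else {
    labs <- as.integer(oracle)
  }
  if (length(labs) != length(task$experiments) || anyNA(labs) ||
      !all(labs %in% c(0L, 1L))) {
    stop("oracle must yield one 0/1 label per candidate experiment",
         call. = FALSE)
  }
  names(labs) <- experiment_ids(task$experiments)
  labs
}

run_learning_loop <- function(task, oracle, budget, seed, strategy,
                              fixed_init = FALSE) {
  stopifnot(inherits(task, "learning_task"))
  H <- task$H
  pred <- task$pred
  costs <- experiment_costs(task$experiments)
  ids <- experiment_ids(task$experiments)
  nT <- length(costs)
  nH <- length(H)
  sizes <- vapply(H, hypothesis_size, integer(1L))
  pc_all <- rowSums(pred)  # generality over the full instance pool; fixed

  oracle_labels <- resolve_oracle_labels(task, oracle)

  withr::with_seed(as.integer(seed), {
    shuffle <- sample.int(nT)           # tie-break order for selections
    tie_pos <- integer(nT)
    tie_pos[shuffle] <- seq_len(nT)

    labels <- rep(NA_integer_, nT)
    alive <- rep(TRUE, nH)
    spend <- 0
    rows <- list()
    step <- 0L
    first_pick <- TRUE

    score_now <- function() {
      labelled <- which(!is.na(labels))
      n_pos <- sum(labels[labelled] == 1L)
      neg <- labelled[labels[labelled] == 0L]
      fp <- if (length(neg) > 0L) {
        rowSums(pred[, neg, drop = FALSE])
      } else {
        integer(nH)
      }
      comp <- vapply(seq_len(nH), function(i) {
        compression(sizes[[i]], n_pos, pc_all[[i]], fp[[i]])
      }, numeric(1L))
      comp
    }

    repeat {
      if (sum(alive) <= 1L) break
      unlab <- which(is.na(labels))
      if (length(unlab) == 0L) break
      affordable <- unlab[costs[unlab] <= budget - spend + 1e-12]
      if (length(affordable) == 0L) break

      comp <- score_now()
      post_alive <- posterior(comp[alive])

      if (strategy == "random") {
        j <- affordable[sample.int(length(affordable), 1L)]
      } else if (fixed_init && first_pick) {
        # fixed initialisation: cheapest discriminative affordable experiment
        ratios <- vapply(affordable, function(t) {
          minimal_reduction_ratio(pred[alive, t])
        }, numeric(1L))
        pool <- affordable[ratios > 0]
        if (length(pool) == 0L) pool <- affordable
        ord <- order(costs[pool], tie_pos[pool])
        j <- pool[ord[1L]]
      } else {
        j <- select_experiment(pred, alive, post_alive, costs, labels,
                               budget_remaining = budget - spend,
                               tie_pos = tie_pos)
      }
      first_pick <- FALSE

      mrr <- minimal_reduction_ratio(pred[alive, j])
      label <- oracle_labels[[j]]
      labels[j] <- label
      spend <- spend + costs[[j]]
      alive <- prune_version_space(alive, pred[, j], label)
      step <- step + 1L

      comp <- score_now()
      best <- best_alive_hypothesis(H, alive, comp)
      acc <- if (is.na(best)) NA_real_ else mean(pred[best, ] == oracle_labels)
      rows[[step]] <- data.frame(
        step = step, strategy = strategy, experiment_id = ids[[j]],
        cost = costs[[j]], label = label,
        version_space_size = sum(alive), min_reduction_ratio = mrr,
        best_hypothesis_id = if (is.na(best)) NA_character_ else H[[best]]$id,
        best_compression = if (is.na(best)) NA_real_ else comp[[best]],
        cumulative_cost = spend, heldout_accuracy = acc,
        stringsAsFactors = FALSE
      )
      if (sum(alive) == 0L) {
        warning("version space emptied: the true hypothesis is not in H")
        break
      }
    }

    comp <- score_now()
    best <- best_alive_hypothesis(H, alive, comp)
    trace <- if (length(rows) > 0L) {
      do.call(rbind, rows)
    } else {
      data.frame(step = integer(), strategy = character(),
                 experiment_id = character(), cost = numeric(),
                 label = integer(), version_space_size = integer(),
                 min_reduction_ratio = numeric(),
                 best_hypothesis_id = character(),
                 best_compression = numeric(), cumulative_cost = numeric(),
                 heldout_accuracy = numeric(), stringsAsFactors = FALSE)
    }
    structure(list(
      trace = trace,
      final = if (is.na(best)) NULL else H[[best]],
      final_id = if (is.na(best)) NA_character_ else H[[best]]$id,
      converged = sum(alive) <= 1L,
      n_alive = sum(alive),
      total_cost = spend,
      strategy = strategy,
      seed = as.integer(seed)
    ), class = "learning_trace")
  })
}

#' Run the cost-aware active-learning loop
#'
#' Iterates: score the alive hypotheses (compression and posterior),
#' select the affordable unlabelled experiment with minimum
#' [expected_cost()] (ties broken by a seeded shuffle fixed at start),
#' query the oracle, prune the version space, and record the step. Stops
#' when at most one hypothesis survives, no affordable unlabelled
#' experiment remains, or everything is labelled. The returned final
#' hypothesis is the alive compression maximiser (ties: smaller size,
#' then input order).
#'
#' @param task a [learning_task()].
#' @param oracle either a function `experiment -> 0/1` or an integer
#'   label vector over all candidate experiments (used both to answer
#'   queries and as the fixed held-out test set for per-step accuracy).
#' @param budget total cost budget (`Inf` for unlimited); an experiment
#'   is affordable iff its cost fits in the unspent budget.
#' @param seed integer seed controlling the tie-break shuffle (and, for
#'   the random baseline, the draws).
#' @param fixed_init select the cheapest discriminative experiment first
#'   instead of the expected-cost minimiser.
#' @return a `learning_trace`: list with `trace` (one data.frame row per
#'   step: step, strategy, experiment_id, cost, label,
#'   version_space_size, min_reduction_ratio, best_hypothesis_id,
#'   best_compression, cumulative_cost, heldout_accuracy), `final`
#'   (the selected [hypothesis()]), `converged`, `total_cost`, `seed`.
#' @export
run_active_learning <- function(task, oracle, budget = Inf, seed = 1L,
                                fixed_init = FALSE) {
  run_learning_loop(task, oracle, budget, seed, "active", fixed_init)
}

#' Run the random-selection baseline
#'
#' Identical loop to [run_active_learning()] except the next experiment
#' is drawn uniformly at random from the affordable unlabelled pool.
#' Pruning, scoring and the final-hypothesis rule are unchanged.
#'
#' @inheritParams run_active_learning
#' @return a `learning_trace` (see [run_active_learning()]).
#' @export
run_random_baseline <- function(task, oracle, budget = Inf, seed = 1L) {
  run_learning_loop(task, oracle, budget, seed, "random")
}

#' @export
print.learning_trace <- function(x, ...) {
  cat(sprintf(
    "<learning_trace %s> %d steps, cost %.3g, %s, final: %s\n",
    x$strategy, nrow(x$trace), x$total_cost,
    if (x$converged) "converged" else "not converged",
    if (is.null(x$final)) "none" else x$final_id))
  invisible(x)
}

trace_frame <- function(x) {
  if (inherits(x, "learning_trace")) x$trace else as.data.frame(x)
}

#' Sample-complexity ratio curves for active vs random selection
#'
#' For each error level `eps` reached by either trace, let `s(eps)` be
#' the first step at which the trace's held-out error drops to `eps` or
#' below. The active curve plots `eps / s_active(eps)` and the passive
#' (random) curve `(eps + phi) / s_passive(eps)`, where `phi` is the
#' smallest minimal reduction ratio among the active learner's selected
#' experiments. The sample-complexity bound for version-space active
#' learning predicts the active curve to lie above the passive one for
#' every `eps > 0`.
#'
#' @param active,passive `learning_trace` objects (or data.frames with
#'   `step` and `heldout_accuracy` columns).
#' @param phi discriminativeness floor; defaults to the minimum recorded
#'   minimal reduction ratio in the active trace.
#' @return data.frame with columns `epsilon`, `s_active`, `s_passive`,
#'   `ratio_active`, `ratio_passive`, one row per error level reached by
#'   both traces.
#' @export
sample_complexity_ratios <- function(active, passive, phi = NULL) {
  ta <- trace_frame(active)
  tp <- trace_frame(passive)
  for (tr in list(ta, tp)) {
    if (!all(c("step", "heldout_accuracy") %in% names(tr))) {
      stop("trace lacks step/accuracy records", call. = FALSE)
    }
  }
  if (is.null(phi)) {
    if (!("min_reduction_ratio" %in% names(ta)) || nrow(ta) == 0L) {
      stop("phi not supplied and not recoverable from the active trace",
           call. = FALSE)
    }
    phi <- min(ta$min_reduction_ratio)
  }
  stopifnot(phi >= 0, phi <= 0.5)

  first_step_at <- function(tr, eps) {
    hit <- tr$step[(1 - tr$heldout_accuracy) <= eps + 1e-12]
    if (length(hit) == 0L) NA_integer_ else min(hit)
  }
  eps_levels <- sort(unique(round(c(1 - ta$heldout_accuracy,
                                    1 - tp$heldout_accuracy), 12)))
  rows <- lapply(eps_levels, function(eps) {
    sa <- first_step_at(ta, eps)
    sp <- first_step_at(tp, eps)
    if (is.na(sa) || is.na(sp)) return(NULL)
    data.frame(epsilon = eps, s_active = sa, s_passive = sp,
               ratio_active = eps / sa, ratio_passive = (eps + phi) / sp)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(epsilon = numeric(), s_active = integer(),
                      s_passive = integer(), ratio_active = numeric(),
                      ratio_passive = numeric()))
  }
  do.call(rbind, rows)
}
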
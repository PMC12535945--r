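#' Parameters for the synthetic GEM generator
#'
#' Defaults describe a small but structured world: a layered network of
#' 3 internal layers x 6 metabolites fed by a 6-metabolite base medium,
#' ~40 gene-associated reactions over 15 genes with a 30% isoenzyme
#' (OR-rule) fraction, 3 purchasable nutrients with log-uniform per-gram
#' costs in \[1, 100\] (normalised so the cheapest costs 1), and 3
#' essential end-point metabolites. With double deletions and single-
#' nutrient additions this yields an experiment grid of 484 candidates
#' and a digenic hypothesis space of 121 — the scale of the benchmark
#' tasks.
#'
#' @param n_layers number of internal layers.
#' @param metabolites_per_layer metabolites per layer (base medium uses
#'   the same width).
#' @param n_reactions total metabolic reactions (spanning + distractor;
#'   nutrient-uptake reactions are added on top).
#' @param max_reactants maximum reactant-set size.
#' @param n_genes size of the gene pool.
#' @param isoenzyme_fraction probability that a gene-associated reaction
#'   gets an OR rule over two genes.
#' @param n_optional_nutrients number of purchasable nutrients.
#' @param n_essential number of essential metabolites.
#' @return a named list of parameters.
#' @export
gem_params <- function(n_layers = 3L, metabolites_per_layer = 6L,
                       n_reactions = 40L, max_reactants = 2L,
                       n_genes = 15L, isoenzyme_fraction = 0.3,
                       n_optional_nutrients = 3L, n_essential = 3L) {
  p <- list(n_layers = as.integer(n_layers),
            metabolites_per_layer = as.integer(metabolites_per_layer),
            n_reactions = as.integer(n_reactions),
            max_reactants = as.integer(max_reactants),
            n_genes = as.integer(n_genes),
            isoenzyme_fraction = as.numeric(isoenzyme_fraction),
            n_optional_nutrients = as.integer(n_optional_nutrients),
            n_essential = as.integer(n_essential))
  stopifnot(p$n_layers >= 1L, p$metabolites_per_layer >= 1L,
            p$n_reactions >= 2L, p$max_reactants >= 1L, p$n_genes >= 3L,
            p$isoenzyme_fraction >= 0, p$isoenzyme_fraction <= 1,
            p$n_optional_nutrients >= 0L, p$n_essential >= 1L)
  p
}

#' Generate a ground-truth synthetic GEM
#'
#' Builds a layered reaction network in which every internal metabolite
#' is producible from the base medium (each gets a spanning reaction
#' whose reactants come from strictly earlier layers), then adds random
#' distractor reactions up to the reaction budget. One designated target
#' pathway is wired in explicitly: a source metabolite feeds a private
#' intermediate, which feeds a private essential end point. The target
#' reaction carries an isoenzyme pair `OR(gA, gB)` in digenic mode or a
#' single gene in monogenic mode, and its gene(s) appear nowhere else,
#' so in digenic mode either single deletion is silent while the double
#' deletion is lethal. Nutrients are extra source metabolites with
#' spontaneous uptake reactions; the first rescues the target
#' intermediate and the second (if present) the target end point,
#' making auxotrophy rescue experiments available.
#'
#' The wild type on the base medium alone is validated to produce every
#' essential metabolite via [bmlp_ie()] at construction.
#'
#' @param params a [gem_params()] list.
#' @param seed integer seed; all structure is deterministic given
#'   (params, seed, mode).
#' @param mode `"digenic"` (isoenzyme-pair target) or `"monogenic"`.
#' @return an object of class `synthetic_gem`: list with `network`
#'   (ground truth [metabolic_network()]), `base_medium`, `nutrients`
#'   (named normalised cost vector), `essential`, `target` (list:
#'   `reaction`, `genes`, `mode`), `seed`, `params`.
#' @export
generate_gem <- function(params = gem_params(), seed = 1L,
                         mode = c("digenic", "monogenic")) {
  mode <- match.arg(mode)
  p <- do.call(gem_params, params)  # validate/normalise

  withr::with_seed(as.integer(seed), {
    base_mets <- sprintf("b%d", seq_len(p$metabolites_per_layer))
    layers <- list(base_mets)
    for (l in seq_len(p$n_layers)) {
      layers[[l + 1L]] <- sprintf("m%d_%d", l, seq_len(p$metabolites_per_layer))
    }
    internal <- unlist(layers[-1L])
    genes <- sprintf("g%d", seq_len(p$n_genes))

    n_target_genes <- if (mode == "digenic") 2L else 1L
    target_genes <- sort(sample(genes, n_target_genes))
    chain_gene <- sample(setdiff(genes, target_genes), 1L)
    other_genes <- setdiff(genes, target_genes)

    tgt_mid <- "m_tgt"   # private intermediate of the target pathway
    tgt_end <- "e_tgt"   # private essential end point
    tgt_src <- sample(base_mets, 1L)

    random_rule <- function() {
      u <- stats::runif(1L)
      if (u < 0.1) return(gpr_spontaneous())
      pairs_ok <- length(other_genes) >= 2L
      if (pairs_ok && stats::runif(1L) < p$isoenzyme_fraction) {
        gs <- sample(other_genes, 2L)
        return(gpr_or(gpr_gene(gs[[1L]]), gpr_gene(gs[[2L]])))
      }
      if (!pairs_ok || stats::runif(1L) < 0.5) {
        gpr_gene(sample(other_genes, 1L))
      } else {
        gs <- sample(other_genes, 2L)
        gpr_and(gpr_gene(gs[[1L]]), gpr_gene(gs[[2L]]))
      }
    }

    reactions <- list(
      list(id = "R_tgt", reactants = tgt_src, products = tgt_mid,
           rule = if (mode == "digenic") {
             gpr_or(gpr_gene(target_genes[[1L]]), gpr_gene(target_genes[[2L]]))
           } else {
             gpr_gene(target_genes[[1L]])
           }),
      list(id = "R_tgt_chain", reactants = tgt_mid, products = tgt_end,
           rule = gpr_gene(chain_gene))
    )

    rid <- 0L
    next_id <- function() {
      rid <<- rid + 1L
      sprintf("R%03d", rid)
    }
    # spanning reactions: every internal metabolite gets one producer fed
    # from strictly earlier layers, so the base medium reaches everything
    for (l in seq_len(p$n_layers)) {
      pool <- unlist(layers[seq_len(l)])
      for (m in layers[[l + 1L]]) {
        k <- sample.int(p$max_reactants, 1L)
        reactions[[length(reactions) + 1L]] <- list(
          id = next_id(),
          reactants = sample(pool, min(k, length(pool))),
          products = m,
          rule = random_rule())
      }
    }
    # distractor reactions up to the budget (cycles allowed: reachability
    # is monotone, so they never break feasibility)
    all_plain <- c(base_mets, internal)
    while (length(reactions) < p$n_reactions + 2L) {
      k <- sample.int(p$max_reactants, 1L)
      reactions[[length(reactions) + 1L]] <- list(
        id = next_id(),
        reactants = sample(all_plain, k),
        products = sample(internal, 1L),
        rule = random_rule())
    }

    # purchasable nutrients: spontaneous uptake into rescue points
    nutrients <- numeric(0L)
    if (p$n_optional_nutrients > 0L) {
      nut_ids <- sprintf("n%d", seq_len(p$n_optional_nutrients))
      rescue <- character(p$n_optional_nutrients)
      rescue[1L] <- tgt_mid
      if (p$n_optional_nutrients >= 2L) rescue[2L] <- tgt_end
      if (p$n_optional_nutrients >= 3L) {
        rescue[3:p$n_optional_nutrients] <-
          sample(internal, p$n_optional_nutrients - 2L, replace = TRUE)
      }
      for (k in seq_along(nut_ids)) {
        reactions[[length(reactions) + 1L]] <- list(
          id = paste0("R_up_", nut_ids[[k]]),
          reactants = nut_ids[[k]], products = rescue[[k]],
          rule = gpr_spontaneous())
      }
      raw_cost <- exp(stats::runif(p$n_optional_nutrients, log(1), log(100)))
      nutrients <- raw_cost / min(raw_cost)
      names(nutrients) <- nut_ids
    }

    mets_order <- c(base_mets, tgt_mid, internal, tgt_end, names(nutrients))
    net <- metabolic_network(reactions, metabolites = mets_order,
                             genes = genes)

    essential <- tgt_end
    if (p$n_essential > 1L) {
      last_layer <- layers[[p$n_layers + 1L]]
      extra <- sample(last_layer, min(p$n_essential - 1L, length(last_layer)))
      essential <- c(essential, extra)
    }

    # constructor invariant: wild type on the base medium produces all
    # essential metabolites
    wt <- producible_metabolites(net, base_mets)
    if (!all(essential %in% wt)) {
      stop("gem generation error: essential metabolite unreachable from ",
           "the base medium", call. = FALSE)
    }

    structure(list(
      network = net,
      base_medium = base_mets,
      nutrients = nutrients,
      essential = essential,
      target = list(reaction = "R_tgt", genes = target_genes, mode = mode),
      seed = as.integer(seed),
      params = p
    ), class = "synthetic_gem")
  })
}

#' @export
print.synthetic_gem <- function(x, ...) {
  cat(sprintf(
    "<synthetic_gem seed %d> %d metabolites, %d genes, %d reactions; %s target %s (%s)\n",
    x$seed, length(x$network$metabolites), length(x$network$genes),
    length(x$network$reactions), x$target$mode, x$target$reaction,
    paste(x$target$genes, collapse = ",")))
  invisible(x)
}

#' Mask annotations: background knowledge and true hypothesis
#'
#' Replaces the rule of each target reaction by the `unknown` marker (the
#' learner's background knowledge no longer states what catalyses it)
#' and returns the true hypothesis h* whose facts restore exactly the
#' masked gene associations: one fact for a monogenic target, two
#' (the isoenzyme pair) for a digenic one.
#'
#' @param gem a [generate_gem()] result.
#' @param targets reaction ids to mask; defaults to the gem's designated
#'   target reaction.
#' @return list with `bk` (the masked [metabolic_network()]) and `hstar`
#'   (a [hypothesis()]).
#' @export
mask_annotations <- function(gem, targets = NULL) {
  stopifnot(inherits(gem, "synthetic_gem"))
  if (is.null(targets)) targets <- gem$target$reaction
  net <- gem$network
  ids <- reaction_ids(net)
  genes <- character()
  rxns <- character()
  for (tg in targets) {
    idx <- match(tg, ids)
    if (is.na(idx)) stop("unknown target reaction: ", tg, call. = FALSE)
    rule <- net$reactions[[idx]]$rule
    if (rule$op == "spontaneous") {
      stop("cannot mask a spontaneous reaction: ", tg, call. = FALSE)
    }
    gs <- gpr_genes(rule)
    genes <- c(genes, gs)
    rxns <- c(rxns, rep(tg, length(gs)))
    net$reactions[[idx]]$rule <- gpr_unknown()
  }
  list(bk = net, hstar = hypothesis(genes, rxns))
}

#' Enumerate the candidate hypothesis space
#'
#' Monogenic mode: the empty hypothesis plus one singleton per
#' (candidate gene, masked reaction) pair. Digenic mode: additionally one
#' pair hypothesis per unordered gene pair per masked reaction. Order is
#' deterministic (empty, then singletons, then pairs); the true
#' hypothesis is a member whenever its genes are among the candidates.
#'
#' @param masked character vector of masked reaction ids.
#' @param candidate_genes character vector of candidate gene ids.
#' @param mode `"monogenic"` or `"digenic"`.
#' @return list of [hypothesis()] objects.
#' @export
enumerate_hypotheses <- function(masked, candidate_genes,
                                 mode = c("digenic", "monogenic")) {
  mode <- match.arg(mode)
  stopifnot(length(candidate_genes) > 0L)
  out <- list(hypothesis())
  for (r in masked) {
    for (g in candidate_genes) {
      out[[length(out) + 1L]] <- hypothesis(g, r)
    }
  }
  if (mode == "digenic") {
    for (r in masked) {
      pairs <- utils::combn(candidate_genes, 2L)
      for (k in seq_len(ncol(pairs))) {
        out[[length(out) + 1L]] <- hypothesis(pairs[, k], c(r, r))
      }
    }
  }
  out
}

#' Enumerate the candidate experiment grid
#'
#' Cartesian grid of gene-deletion sets (sizes 0..`max_deletions`, so the
#' no-deletion control is included) and optional-nutrient subsets (sizes
#' 0..`nutrient_subsets_up_to`). Experiment cost is the sum of the
#' normalised per-gram costs of the added nutrients. Deterministic order:
#' deletion sets by size then lexicographic combination order, nutrient
#' subsets likewise within each deletion set.
#'
#' @param gem a [generate_gem()] result.
#' @param max_deletions maximum deletion-set size (1 or 2).
#' @param nutrient_subsets_up_to maximum nutrient-subset size.
#' @return list of [experiment()] objects.
#' @export
enumerate_experiments <- function(gem, max_deletions = 2L,
                                  nutrient_subsets_up_to = 1L) {
  stopifnot(inherits(gem, "synthetic_gem"), max_deletions >= 0L,
            nutrient_subsets_up_to >= 0L)
  genes <- gem$network$genes
  del_sets <- list(character())
  for (k in seq_len(min(max_deletions, length(genes)))) {
    cmb <- utils::combn(genes, k)
    for (i in seq_len(ncol(cmb))) del_sets[[length(del_sets) + 1L]] <- cmb[, i]
  }
  nut_ids <- names(gem$nutrients)
  nut_sets <- list(character())
  for (k in seq_len(min(nutrient_subsets_up_to, length(nut_ids)))) {
    cmb <- utils::combn(nut_ids, k)
    for (i in seq_len(ncol(cmb))) nut_sets[[length(nut_sets) + 1L]] <- cmb[, i]
  }
  out <- vector("list", length(del_sets) * length(nut_sets))
  pos <- 0L
  for (d in del_sets) {
    for (o in nut_sets) {
      pos <- pos + 1L
      out[[pos]] <- experiment(
        id = paste0("del[", paste(d, collapse = "+"), "]add[",
                    paste(o, collapse = "+"), "]"),
        deleted = d, nutrients = o,
        cost = if (length(o) == 0L) 0 else sum(gem$nutrients[o]))
    }
  }
  out
}

#' Ground-truth oracle label for one experiment
#'
#' Runs [bmlp_ie()] on the *full* ground-truth network with the
#' experiment's deletions and medium; the label is 1 (phenotypic effect)
#' iff some essential metabolite is unproduced.
#'
#' @param gem a [generate_gem()] result.
#' @param t an [experiment()].
#' @return integer 0 or 1.
#' @export
oracle_label <- function(gem, t) {
  stopifnot(inherits(gem, "synthetic_gem"), inherits(t, "experiment"))
  prod <- producible_metabolites(gem$network, union(gem$base_medium, t$nutrients),
                                 deleted = t$deleted)
  as.integer(!all(gem$essential %in% prod))
}

#' Ground-truth oracle labels for an experiment list
#'
#' Vectorised [oracle_label()] sharing one network encoding.
#'
#' @param gem a [generate_gem()] result.
#' @param experiments list of [experiment()] objects.
#' @return named integer 0/1 vector.
#' @export
oracle_labels <- function(gem, experiments) {
  enc <- encode_matrices(gem$network)
  ess_idx <- match(gem$essential, gem$network$metabolites)
  labs <- vapply(experiments, function(t) {
    v0 <- medium_vector(gem$network, union(gem$base_medium, t$nutrients))
    mask <- reaction_mask(gem$network, NULL, t$deleted)
    fp <- bmlp_ie(v0, enc$R1, enc$R2, mask)
    as.integer(!all(fp$vstar[ess_idx] == 1L))
  }, integer(1L))
  names(labs) <- experiment_ids(experiments)
  labs
}

#' Assemble a full learning task from a synthetic gem
#'
#' Masks the designated target annotation, enumerates the hypothesis
#' space and experiment grid, computes oracle labels and the prediction
#' matrix, and returns everything needed to run the learning strategies.
#'
#' @param gem a [generate_gem()] result.
#' @param max_deletions,nutrient_subsets_up_to grid bounds, see
#'   [enumerate_experiments()].
#' @return list with `task` (a [learning_task()]), `hstar`, `labels`
#'   (oracle labels over the grid), `bk`, `experiments`, `H`.
#' @export
gem_learning_problem <- function(gem, max_deletions = 2L,
                                 nutrient_subsets_up_to = 1L) {
  masked <- mask_annotations(gem)
  H <- enumerate_hypotheses(gem$target$reaction, gem$network$genes,
                            mode = gem$target$mode)
  experiments <- enumerate_experiments(gem, max_deletions,
                                       nutrient_subsets_up_to)
  labels <- oracle_labels(gem, experiments)
  task <- learning_task(masked$bk, H, experiments, gem$base_medium,
                        gem$essential)
  list(task = task, hstar = masked$hstar, labels = labels,
       bk = masked$bk, experiments = experiments, H = H)
}
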
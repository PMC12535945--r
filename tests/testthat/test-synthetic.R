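test_that("minimal parameters force a lethal single-gene target", {
  p <- gem_params(n_layers = 1L, metabolites_per_layer = 1L, n_reactions = 2L,
                  max_reactants = 1L, n_genes = 3L, isoenzyme_fraction = 0,
                  n_optional_nutrients = 0L, n_essential = 1L)
  gem <- generate_gem(p, seed = 1L, mode = "monogenic")
  expect_equal(gem$essential[[1L]], "e_tgt")
  # deleting the target gene severs the only route to the essential target
  lethal <- experiment("t", deleted = gem$target$genes)
  expect_equal(oracle_label(gem, lethal), 1L)
  expect_equal(oracle_label(gem, experiment("ctrl")), 0L)
})

test_that("every generated gem passes the wild-type viability check", {
  for (seed in c(2L, 13L, 77L)) {
    gem <- generate_gem(small_params(), seed = seed, mode = "digenic")
    wt <- producible_metabolites(gem$network, gem$base_medium)
    expect_true(all(gem$essential %in% wt))
    # with all nutrients added the producible set only grows
    wt_plus <- producible_metabolites(
      gem$network, c(gem$base_medium, names(gem$nutrients)))
    expect_true(all(wt %in% wt_plus))
    # nutrient costs are normalised by the cheapest
    expect_equal(min(gem$nutrients), 1)
  }
})

test_that("generation is byte-stable under a fixed seed", {
  g1 <- generate_gem(gem_params(), seed = 7L, mode = "digenic")
  g2 <- generate_gem(gem_params(), seed = 7L, mode = "digenic")
  expect_identical(format_network_tsv(g1$network),
                   format_network_tsv(g2$network))
  expect_identical(g1$nutrients, g2$nutrients)
  expect_identical(g1$essential, g2$essential)
  # a different seed changes the draw
  g3 <- generate_gem(gem_params(), seed = 8L, mode = "digenic")
  expect_false(identical(format_network_tsv(g1$network),
                         format_network_tsv(g3$network)))
})

test_that("masking hides the rule and h* restores it exactly", {
  gem_m <- generate_gem(small_params(), seed = 3L, mode = "monogenic")
  mm <- mask_annotations(gem_m)
  expect_equal(hypothesis_size(mm$hstar), 1L)

  gem_d <- generate_gem(small_params(), seed = 3L, mode = "digenic")
  md <- mask_annotations(gem_d)
  expect_equal(hypothesis_size(md$hstar), 2L)
  idx <- match(gem_d$target$reaction, vapply(md$bk$reactions, `[[`,
                                             character(1L), "id"))
  expect_equal(md$bk$reactions[[idx]]$rule$op, "unknown")

  # masking a spontaneous reaction is refused
  spont <- vapply(gem_d$network$reactions, function(r) {
    r$rule$op == "spontaneous"
  }, logical(1L))
  expect_error(mask_annotations(gem_d, vapply(gem_d$network$reactions,
                                              `[[`, character(1L),
                                              "id")[which(spont)[1L]]),
               "spontaneous")

  # BK + h* reproduces the ground-truth reaction mask on random deletions
  set.seed(101)
  genes <- gem_d$network$genes
  for (i in 1:100) {
    d <- sample(genes, sample(0:3, 1L))
    expect_identical(reaction_mask(md$bk, md$hstar, d),
                     reaction_mask(gem_d$network, NULL, d))
  }
})

test_that("hypothesis enumeration has the combinatorial counts", {
  genes <- paste0("g", 1:4)
  mono <- enumerate_hypotheses("R1", genes, mode = "monogenic")
  expect_length(mono, 5L)  # empty + 4 singletons
  dig <- enumerate_hypotheses("R1", genes, mode = "digenic")
  expect_length(dig, 11L)  # empty + 4 singletons + C(4,2) pairs
  expect_equal(sum(vapply(dig, hypothesis_size, integer(1L)) == 2L), 6L)
  # h* membership for a generated gem
  gem <- generate_gem(small_params(), seed = 5L, mode = "digenic")
  m <- mask_annotations(gem)
  H <- enumerate_hypotheses(gem$target$reaction, gem$network$genes, "digenic")
  expect_true(m$hstar$id %in% vapply(H, `[[`, character(1L), "id"))
})

test_that("experiment grids enumerate deletions x nutrient subsets", {
  gem <- generate_gem(gem_params(n_genes = 3L, n_optional_nutrients = 0L),
                      seed = 2L)
  T1 <- enumerate_experiments(gem, max_deletions = 1L)
  expect_length(T1, 4L)  # control + 3 single deletions
  expect_true(all(experiment_costs <- vapply(T1, `[[`, numeric(1L),
                                             "cost") == 0))

  gem2 <- generate_gem(gem_params(n_genes = 3L, n_optional_nutrients = 2L),
                       seed = 2L)
  T2 <- enumerate_experiments(gem2, max_deletions = 0L,
                              nutrient_subsets_up_to = 1L)
  costs <- sort(vapply(T2, `[[`, numeric(1L), "cost"))
  expect_equal(costs[1L], 0)
  expect_equal(costs[2L], 1)  # cheapest nutrient is normalised to 1
  expect_equal(length(T2), 3L)

  gem3 <- generate_gem(gem_params(n_genes = 15L, n_optional_nutrients = 3L),
                       seed = 2L)
  T3 <- enumerate_experiments(gem3, max_deletions = 2L,
                              nutrient_subsets_up_to = 1L)
  expect_length(T3, (1L + 15L + choose(15L, 2L)) * 4L)  # 484
})

test_that("oracle labels realise lethality and nutrient rescue", {
  gem <- generate_gem(small_params(), seed = 9L, mode = "digenic")
  ga <- gem$target$genes[[1L]]
  gb <- gem$target$genes[[2L]]
  expect_equal(oracle_label(gem, experiment("ctrl")), 0L)
  # digenic discriminability: singles silent, double lethal
  expect_equal(oracle_label(gem, experiment("a", deleted = ga)), 0L)
  expect_equal(oracle_label(gem, experiment("b", deleted = gb)), 0L)
  expect_equal(oracle_label(gem, experiment("ab", deleted = c(ga, gb))), 1L)
  # supplying the downstream intermediate rescues the double deletion
  expect_equal(oracle_label(gem, experiment("ab_resc", deleted = c(ga, gb),
                                            nutrients = "n1",
                                            cost = gem$nutrients[["n1"]])),
               0L)
})

test_that("keystone consistency: h* prediction row equals the oracle labels", {
  for (seed in c(4L, 21L)) {
    for (mode in c("monogenic", "digenic")) {
      gem <- generate_gem(small_params(), seed = seed, mode = mode)
      prob <- gem_learning_problem(gem)
      i <- match(prob$hstar$id, rownames(prob$task$pred))
      expect_false(is.na(i))
      expect_equal(unname(prob$task$pred[i, ]), unname(prob$labels))
    }
  }
})

test_that("gem bundles round-trip through plain-text serialization", {
  gem <- generate_gem(small_params(), seed = 12L, mode = "digenic")
  dir <- withr::local_tempdir()
  write_gem_bundle(gem, dir)
  expect_true(all(file.exists(file.path(dir, c("network.tsv", "medium.txt",
                                               "costs.tsv",
                                               "manifest.json")))))
  back <- read_gem_bundle(dir)
  expect_identical(format_network_tsv(back$network),
                   format_network_tsv(gem$network))
  expect_identical(back$network$metabolites, gem$network$metabolites)
  expect_identical(back$network$genes, gem$network$genes)
  expect_equal(back$nutrients, gem$nutrients)
  expect_identical(back$essential, gem$essential)
  expect_identical(back$target, gem$target)
})
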
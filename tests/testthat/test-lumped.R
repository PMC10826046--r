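# Lumped-model analytics: per-species optimization, max-min community
# growth, pathway summaries, KL divergence and flux-sum.

test_that("iterative biomass optimization reproduces per-organism optima", {
  a <- simple_microbe("A", "glc", yield = 1)
  p1 <- apply_diet(pool_models(list(a)), make_diet("sugar", FALSE))
  it <- iterative_biomass_optimization(p1)
  expect_length(it, 1)
  expect_equal(it[[1]]$objective_value, solve_fba(p1)$objective_value)
  # growth-capped organisms keep their individual ceilings in the pool
  a4 <- make_toy_microbe(microbe_spec("A", "glc", aerobic_yield = 1,
                                      anaerobic_yield = 1, max_growth = 10))
  b4 <- make_toy_microbe(microbe_spec("B", "fru", aerobic_yield = 1,
                                      anaerobic_yield = 1, max_growth = 4))
  pool <- apply_diet(pool_models(list(a4, b4)), make_diet("sugar", FALSE))
  it2 <- iterative_biomass_optimization(pool)
  expect_equal(unname(vapply(it2, `[[`, 0, "objective_value")), c(10, 4),
               tolerance = 1e-8)
  # an organism with no route to biomass records optimum 0
  dead <- make_toy_microbe(microbe_spec("D", "glc", requires = "vit",
                                        aerobic_yield = 1, anaerobic_yield = 1))
  pd <- apply_diet(pool_models(list(a, dead)), make_diet("sugar", FALSE))
  itd <- iterative_biomass_optimization(pd)
  expect_equal(itd[[2]]$objective_value, 0)
})

test_that("optimal community growth is the max-min and constrains the model", {
  # independent ceilings 10 and 4 -> g* = 4
  a4 <- make_toy_microbe(microbe_spec("A", "glc", aerobic_yield = 1,
                                      anaerobic_yield = 1, max_growth = 10))
  b4 <- make_toy_microbe(microbe_spec("B", "fru", aerobic_yield = 1,
                                      anaerobic_yield = 1, max_growth = 4))
  pool <- apply_diet(pool_models(list(a4, b4)), make_diet("sugar", FALSE))
  oc <- optimal_community_growth(pool)
  expect_equal(oc$g_star, 4, tolerance = 1e-8)
  cm <- as_metabolic_model(oc$constrained_model)
  expect_true(all(cm$reactions$lb[match(cm$biomass_ids, cm$reactions$id)] >=
                  oc$g_star - 1e-9))
  # two clones sharing one 10-unit substrate at yield 1 -> g* = 5
  c1 <- simple_microbe("C", "glc", yield = 1)
  poolC <- apply_diet(pool_models(list(c1, c1)), diet_spec("g", c(glc = 10), FALSE))
  expect_equal(optimal_community_growth(poolC)$g_star, 5, tolerance = 1e-8)
  # an organism unable to grow pins g* at zero
  dead <- make_toy_microbe(microbe_spec("D", "glc", requires = "vit",
                                        aerobic_yield = 1, anaerobic_yield = 1))
  poolD <- apply_diet(pool_models(list(c1, dead)), make_diet("sugar", FALSE))
  expect_equal(optimal_community_growth(poolD)$g_star, 0)
  # g* never exceeds any per-organism optimum (max-min property)
  for (seed in 1:2) {
    models <- make_community(3, 0.4, seed = seed)
    pl <- apply_diet(pool_models(models), make_diet("sugar", FALSE))
    g <- optimal_community_growth(pl)$g_star
    opts <- vapply(iterative_biomass_optimization(pl), `[[`, 0, "objective_value")
    expect_lte(g, min(opts) + 1e-8)
  }
})

test_that("sampling the g*-constrained model keeps every biomass above g*", {
  c1 <- simple_microbe("C", "glc", yield = 1)
  c2 <- simple_microbe("D", "fru", yield = 1)
  pool <- apply_diet(pool_models(list(c1, c2)), make_diet("sugar", FALSE))
  oc <- optimal_community_growth(pool)
  ss <- sample_fluxes(oc$constrained_model, fast_sampler(n = 100, thin = 20))
  bio <- as_metabolic_model(oc$constrained_model)$biomass_ids
  for (b in bio) expect_gte(min(ss$samples[, b]), oc$g_star - 1e-9)
})

test_that("pathway summary normalizes per reaction across both conditions", {
  # 1-dof toy: sampled flux uniform on [0,10] (median 5), FBA flux 10;
  # max-normalization maps the pair to about (0.5, 1.0)
  cyc <- cycle_model()
  ss <- sample_fluxes(cyc, sampler_settings(1000, 100, seed = 2))
  opt <- structure(list(values = c(r1 = 10, r2 = 10), objective_value = 10,
                        objective_id = "r1"), class = "flux_vector")
  tab <- pathway_flux_summary(ss, opt, cyc)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$median_optimization, 1.0, tolerance = 1e-9)
  expect_equal(tab$median_sampling, 0.5, tolerance = 0.1)
  # all-zero fluxes give zero medians
  zero <- ss; zero$samples[] <- 0
  tab0 <- pathway_flux_summary(zero, structure(list(values = c(r1 = 0, r2 = 0)),
                                               class = "flux_vector"), cyc)
  expect_equal(tab0$median_sampling, 0)
  expect_equal(tab0$median_optimization, 0)
})

test_that("biomass optimization hides side-pathway flux that sampling reveals", {
  # the conversion route carries nothing at the growth optimum, but the
  # polytope allows it; sampling reports a positive median
  w <- make_toy_microbe(microbe_spec("W", "glc",
                                     converts = list(c(from = "glc", to = "bx")),
                                     aerobic_yield = 1, anaerobic_yield = 1,
                                     mass_overrides = c(bx = 1)))
  wd <- apply_diet(w, c(glc = 10))
  opt <- solve_fba(wd)
  expect_equal(unname(opt$values["CONV_glc_bx"]), 0, tolerance = 1e-9)
  ss <- sample_fluxes(wd, fast_sampler(n = 300, thin = 40, seed = 8))
  expect_gt(median(ss$samples[, "CONV_glc_bx"]), 0.1)
})

test_that("KL divergence: zero on identical inputs, calibrated on Gaussians, monotone", {
  set.seed(31)
  X <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("ra", "rb")))
  same <- reaction_divergence(X, X)
  expect_equal(same$kl_sum, c(0, 0), tolerance = 1e-12)
  expect_true(all(same$class == "low"))
  # N(0,1) vs N(1,1): analytic symmetrized KL = 1.0
  P <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "r"))
  Q <- matrix(rnorm(5000, mean = 1), ncol = 1, dimnames = list(NULL, "r"))
  d <- reaction_divergence(P, Q)
  expect_gte(d$kl_sum, 0.8)
  expect_lte(d$kl_sum, 1.2)
  expect_equal(d$median_difference, -1, tolerance = 0.15)
  # divergence grows with separation
  seps <- c(0.5, 1, 2)
  kls <- vapply(seps, function(s) {
    Q2 <- matrix(rnorm(5000, mean = s), ncol = 1, dimnames = list(NULL, "r"))
    reaction_divergence(P, Q2)$kl_sum
  }, 0)
  expect_true(all(diff(kls) > 0))
  expect_true(all(kls >= 0))
  # degenerate distributions compare as point masses, no division by zero
  Z1 <- matrix(1, 10, 1, dimnames = list(NULL, "r"))
  expect_equal(reaction_divergence(Z1, Z1)$kl_sum, 0)
})

test_that("flux-sum equals throughput on a chain and is homogeneous", {
  ch <- chain_model(f = 3)
  v <- solve_fba(ch, objective = "r1")
  fs <- flux_sum(v, ch)
  expect_equal(fs$median_flux_sum[fs$metabolite == "B"], 3)
  expect_equal(fs$median_flux_sum[fs$metabolite == "A"], 3)
  # doubling all fluxes doubles every flux-sum
  V <- rbind(v$values, v$values)
  colnames(V) <- names(v$values)
  fs1 <- flux_sum(V, ch)
  fs2 <- flux_sum(2 * V, ch)
  expect_equal(fs2$median_flux_sum, 2 * fs1$median_flux_sum)
  expect_true(all(fs1$median_flux_sum >= 0))
  # a metabolite in no reaction scores zero
  ch2 <- ch
  ch2$metabolites <- rbind(ch2$metabolites,
                           data.frame(id = "orphan", compartment = "c", name = "orphan"))
  ch2$stoich <- rbind(ch2$stoich, 0)
  rownames(ch2$stoich)[4] <- "orphan"
  fs3 <- flux_sum(v, ch2)
  expect_equal(fs3$median_flux_sum[fs3$metabolite == "orphan"], 0)
})
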
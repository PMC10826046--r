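# The costless-secretion loop: media initialization, secretion thresholds,
# convergence, growth rescue and interaction labels.

test_that("minimal media initialization opens exactly the stated uptakes", {
  fx <- make_costless_pair("commensal")
  init <- init_minimal_media(fx$models, fx$media, fx$carbon_sources,
                             aerobic = FALSE)
  expect_equal(sort(init$media_state$metabolite), c("glc", "o2"))
  expect_equal(init$media_state$cap[init$media_state$metabolite == "glc"], 10)
  expect_equal(init$media_state$cap[init$media_state$metabolite == "o2"], 0)
  a <- init$models[[1]]
  expect_equal(a$reactions$lb[match("EX_glc", a$reactions$id)], -10)
  open <- a$exchange_ids[a$reactions$lb[match(a$exchange_ids, a$reactions$id)] < 0]
  expect_equal(open, "EX_glc")
  expect_error(init_minimal_media(fx$models, fx$media, "unobtainium", FALSE),
               "unobtainium")
})

test_that("secretion thresholds follow the all/most/any fraction semantics", {
  m2 <- make_toy_microbe(microbe_spec("A", "glc", secretes = c(ac = "ferment"),
                                      aerobic_yield = 1, anaerobic_yield = 1))
  fake <- function(frac, n = 1000) {
    # synthetic sample set: metabolite ac secreted in frac*n of n samples
    V <- matrix(0, n, n_reactions(m2), dimnames = list(NULL, m2$reactions$id))
    V[seq_len(frac * n), "EX_ac"] <- 1
    structure(list(samples = V, reaction_ids = colnames(V)),
              class = "flux_sample_set")
  }
  # 200/1000: only "any"; 750/1000: "any" and "most"; 1000/1000: all three
  expect_equal(detect_secretions(fake200 <- fake(0.2), m2, "any"), "ac")
  expect_length(detect_secretions(fake200, m2, "most"), 0)
  expect_length(detect_secretions(fake200, m2, "all"), 0)
  f750 <- fake(0.75)
  expect_equal(detect_secretions(f750, m2, "any"), "ac")
  expect_equal(detect_secretions(f750, m2, "most"), "ac")
  expect_length(detect_secretions(f750, m2, "all"), 0)
  f1000 <- fake(1)
  for (mode in c("any", "most", "all")) {
    expect_equal(detect_secretions(f1000, m2, mode), "ac", label = mode)
  }
  # exactly half the samples does not satisfy "most"
  expect_length(detect_secretions(fake(0.5), m2, "most"), 0)
  # FBA single solution
  fv <- solve_fba(apply_diet(m2, c(glc = 10)))
  expect_equal(detect_secretions(fv, m2, "fba"), "ac")
})

test_that("FBA-mode loop rescues the cross-fed organism and labels the motifs", {
  for (kind in c("commensal", "mutualistic", "independent")) {
    fx <- make_costless_pair(kind)
    rec <- run_costless(fx$models, fx$media, fx$carbon_sources,
                        aerobic = FALSE, mode = "fba")
    expect_true(rec$converged, label = kind)
    expect_equal(label_costless_interaction(rec), fx$expected_label,
                 label = kind)
    # termination bound: at most one iteration per extracellular metabolite
    n_extracellular <- length(unique(unlist(lapply(fx$models, function(m)
      m$metabolites$id[m$metabolites$compartment == "e"]))))
    expect_lte(rec$converged_at, n_extracellular)
    # media grows monotonically and every added metabolite has provenance
    expect_true(!is.unsorted(rec$media_state$added_iteration))
    added <- rec$media_state[rec$media_state$added_iteration > 0, ]
    expect_true(all(nzchar(added$secreted_by)))
  }
  fx <- make_costless_pair("commensal")
  rec <- run_costless(fx$models, fx$media, fx$carbon_sources, FALSE, "fba")
  # growth rescue: B grows 0 before acetate appears, > 0 after
  expect_equal(rec$iterations[[1]]$growth$B, 0)
  expect_gt(rec$iterations[[2]]$growth$B, 0)
  expect_equal(rec$media_state$added_iteration[rec$media_state$metabolite == "ac"], 1L)
  expect_equal(rec$media_state$secreted_by[rec$media_state$metabolite == "ac"], "A")
  expect_equal(rec$converged_at, 2L)
})

test_that("a pair with nothing to secrete converges immediately", {
  models <- list(simple_microbe("A"), simple_microbe("B", "fru"))
  rec <- run_costless(models, c(fru = 10), "glc", aerobic = FALSE, mode = "fba")
  expect_true(rec$converged)
  expect_equal(rec$converged_at, 1L)
  expect_equal(sum(rec$media_state$added_iteration > 0), 0)
})

test_that("no-growth pairs fall into the distinguished seventh category", {
  models <- list(simple_microbe("A"), simple_microbe("B", "fru"))
  rec <- run_costless(models, numeric(0), "glc", aerobic = FALSE, mode = "fba")
  expect_equal(label_costless_interaction(rec), "NG")  # B never grows
})

test_that("competition suffix marks shared consumption of a capped metabolite", {
  models <- list(simple_microbe("A"), simple_microbe("B"))  # both on glc
  rec <- run_costless(models, numeric(0), "glc", aerobic = FALSE, mode = "fba")
  expect_equal(label_costless_interaction(rec), "N1b")
})

test_that("sampling-mode media sets are nested all within most within any", {
  fx <- make_costless_pair("commensal")
  st <- fast_sampler(n = 200, thin = 40, seed = 17)
  recs <- lapply(c("all", "most", "any"), function(mode)
    run_costless(fx$models, fx$media, fx$carbon_sources, FALSE, mode,
                 sampler_settings = st))
  names(recs) <- c("all", "most", "any")
  media_at <- function(rec, it) {
    ms <- rec$media_state
    ms$metabolite[ms$added_iteration < it]
  }
  max_it <- max(vapply(recs, function(r) length(r$iterations), 0L))
  for (it in seq_len(max_it + 1)) {
    expect_true(all(media_at(recs$all, it) %in% media_at(recs$most, it)),
                label = paste("all within most, iteration", it))
    expect_true(all(media_at(recs$most, it) %in% media_at(recs$any, it)),
                label = paste("most within any, iteration", it))
  }
  expect_lte(recs$all$converged_at, recs$any$converged_at)
  # sampling rescues B through the acetate route under the loosest cutoff
  expect_gt(max(recs$any$iterations[[length(recs$any$iterations)]]$growth$B), 0)
})

test_that("the costless design grid enumerates pairs x oxygen x fuels", {
  d <- costless_design(3, carbon_sources = c("glc", "fru"))
  expect_equal(nrow(d), 3 * 2 * 2)  # 3 pairs, 2 aerobic states, 2 fuels
  expect_equal(nrow(unique(d)), nrow(d))
})
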
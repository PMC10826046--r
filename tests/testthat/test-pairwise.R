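# Interaction classification and the pairwise protocol in both modes.

# Straight-line reimplementation of the classification prose, used as an
# independent cross-check of classify_interaction.
naive_classify <- function(ga0, gb0, ga1, gb1, delta = 0.1) {
  lab <- function(m, co) {
    if (m == 0) return(if (co > 1e-6) "faster" else "unchanged")
    if (co > (1 + delta) * m) "faster"
    else if (co < (1 - delta) * m) "slower"
    else "unchanged"
  }
  a <- lab(ga0, ga1); b <- lab(gb0, gb1)
  if (a == "faster" && b == "faster") return("mutualism")
  if (a == "slower" && b == "slower") return("competition")
  if (a == "unchanged" && b == "unchanged") return("neutralism")
  if ((a == "faster" && b == "slower") || (a == "slower" && b == "faster")) return("parasitism")
  if (a == "faster" || b == "faster") return("commensalism")
  "amensalism"
}

test_that("the 3x3 label grid maps to six types with multiplicities 1,1,1,2,2,2", {
  # growths engineered to hit each label: mono 1, co in {1.5, 1.0, 0.5}
  co_for <- c(faster = 1.5, unchanged = 1.0, slower = 0.5)
  labels <- names(co_for)
  types <- character(0)
  for (la in labels) for (lb in labels) {
    call <- classify_interaction(1, 1, co_for[[la]], co_for[[lb]], delta = 0.1)
    expect_equal(call$label_a, la)
    expect_equal(call$label_b, lb)
    types <- c(types, call$type)
  }
  counts <- table(types)
  expect_equal(sort(as.integer(counts)), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(as.integer(counts[c("mutualism", "competition", "neutralism")]),
               c(1L, 1L, 1L))
  expect_equal(as.integer(counts[c("parasitism", "commensalism", "amensalism")]),
               c(2L, 2L, 2L))
})

test_that("classification is total and matches an independent reimplementation", {
  grid <- c(0, 0.05, 0.5, 0.89, 0.91, 1, 1.09, 1.11, 2, 10)
  set.seed(1)
  for (i in 1:200) {
    g <- c(sample(grid, 2, replace = TRUE), sample(grid, 2, replace = TRUE))
    call <- classify_interaction(g[1], g[2], g[3], g[4])
    expect_true(call$type %in% c("mutualism", "commensalism", "neutralism",
                                 "amensalism", "parasitism", "competition"))
    expect_equal(call$type, naive_classify(g[1], g[2], g[3], g[4]),
                 label = paste(g, collapse = ","))
  }
  expect_error(classify_interaction(-1, 1, 1, 1), "nonnegative")
  # threshold semantics: within +-10 percent is unchanged
  expect_equal(classify_interaction(1, 1, 1.05, 0.95)$type, "neutralism")
  expect_equal(classify_interaction(1, 1, 1.2, 1.2)$type, "mutualism")
})

test_that("FBA-mode protocol recovers every engineered motif", {
  for (motif in c("neutralism", "competition", "commensalism", "mutualism",
                  "amensalism", "parasitism")) {
    p <- make_crossfeeding_pair(motif)
    call <- pairwise_protocol_fba(p$a, p$b, p$diet)
    expect_equal(call$type, p$expected, label = motif)
  }
  # quantitative spot checks from the fixture designs
  pc <- make_crossfeeding_pair("competition")
  call <- pairwise_protocol_fba(pc$a, pc$b, pc$diet)
  expect_lt(call$growth_a_co, 0.9 * call$growth_a_mono)
  expect_lt(call$growth_b_co, 0.9 * call$growth_b_mono)
  pm <- make_crossfeeding_pair("mutualism")
  call <- pairwise_protocol_fba(pm$a, pm$b, pm$diet)
  expect_gt(call$growth_a_co, 1.1 * call$growth_a_mono)
  expect_gt(call$growth_b_co, 1.1 * call$growth_b_mono)
})

test_that("the separate two-LP reading cannot register growth reductions", {
  # with each organism optimized alone, the partner's open network is a
  # superset of the shut-off one, so co-culture optima dominate mono optima
  p <- make_crossfeeding_pair("competition")
  call <- pairwise_protocol_fba(p$a, p$b, p$diet, co_mode = "separate")
  expect_gte(call$growth_a_co, call$growth_a_mono - 1e-8)
  expect_gte(call$growth_b_co, call$growth_b_mono - 1e-8)
  expect_equal(call$type, "neutralism")
  p2 <- make_crossfeeding_pair("commensalism")
  expect_equal(pairwise_protocol_fba(p2$a, p2$b, p2$diet,
                                     co_mode = "separate")$type, "commensalism")
})

test_that("sampling-mode protocol: basal bounds hold and modal calls recover motifs", {
  st <- fast_sampler(n = 300, thin = 60, seed = 11)
  for (motif in c("neutralism", "competition", "mutualism")) {
    p <- make_crossfeeding_pair(motif)
    res <- pairwise_protocol_sampling(p$a, p$b, p$diet, st)
    expect_equal(res$modal_call, motif, label = motif)
    # sampled biomass bounded by basal below and FBA optimum above
    for (k in 1:2) {
      g <- res$co$samples[, res$biomass_ids[k]]
      basal <- 0.1 * c(res$growth_a_mono_fba, res$growth_b_mono_fba)[k]
      expect_gte(min(g), basal - 1e-9)
    }
    expect_equal(sum(res$distribution), 1, tolerance = 1e-12)
  }
})

test_that("regime maps bin by quantiles with modal calls and conserved support", {
  # hand-built sample array whose calls switch at the growth medians
  calls <- data.frame(
    g_a = c(1, 2, 1.1, 2.2, 8, 9, 8.5, 9.5),
    g_b = c(1, 1.5, 8, 9, 1.2, 1.8, 8.2, 9.8),
    type = c("competition", "competition", "amensalism", "amensalism",
             "parasitism", "parasitism", "mutualism", "mutualism"),
    stringsAsFactors = FALSE)
  rm2 <- build_regime_map(calls, n_bins = 2)
  expect_equal(nrow(rm2), 4)
  expect_equal(sum(rm2$support), nrow(calls))
  get <- function(a, b) rm2$type[rm2$bin_a == a & rm2$bin_b == b]
  expect_equal(get(1, 1), "competition")
  expect_equal(get(1, 2), "amensalism")
  expect_equal(get(2, 1), "parasitism")
  expect_equal(get(2, 2), "mutualism")
  # a constant call field gives a constant map
  calls$type <- "neutralism"
  expect_true(all(build_regime_map(calls, 2)$type == "neutralism"))
  expect_error(build_regime_map(calls, 0), "n_bins")
  # modal ties break by the fixed type order
  tied <- data.frame(g_a = c(1, 1), g_b = c(1, 1),
                     type = c("competition", "mutualism"))
  expect_equal(build_regime_map(tied, 1)$type, "mutualism")
})

test_that("interaction frequency tables close to 100% with correct aggregates", {
  types <- c("mutualism", "commensalism", "neutralism", "amensalism",
             "parasitism", "competition")
  tab <- summarize_interaction_frequencies(types)
  expect_equal(sum(tab$percent), 100)
  expect_true(all(abs(tab$percent - 100 / 6) < 1e-9))
  agg <- attr(tab, "aggregates")
  expect_equal(agg$antagonistic + agg$cooperative, 100)
  expect_equal(agg$symmetrical, 50)
  one <- summarize_interaction_frequencies("mutualism")
  expect_equal(one$percent[one$type == "mutualism"], 100)
  # grouped input
  df <- data.frame(type = c("mutualism", "competition", "competition"),
                   diet = c("sugar", "sugar", "fiber"))
  g <- summarize_interaction_frequencies(df, grouping = "diet")
  expect_equal(g$percent[g$condition == "fiber" & g$type == "competition"], 100)
})

test_that("pair enumeration counts unique unordered pairs", {
  expect_equal(nrow(pair_design(4)), 6)
  d <- pair_design(c("x", "y", "z"))
  expect_equal(nrow(d), 3)
  expect_true(all(d$a != d$b))
})
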
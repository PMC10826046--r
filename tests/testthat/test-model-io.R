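# Model container invariants and serialization round trips.

test_that("model validation catches structural violations", {
  mets <- data.frame(id = c("m1", "m2"), compartment = "c", name = c("m1", "m2"),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("r1", "r2"), lb = c(0, 5), ub = c(10, 1),
                     subsystem = "", organism = "x", stringsAsFactors = FALSE)
  S <- rbind(c(-1, 1), c(1, -1)); dimnames(S) <- list(mets$id, rxns$id)
  expect_error(metabolic_model(mets, rxns, S, character(0), character(0)),
               "r2")   # lb > ub names the offending reaction
  rxns$ub <- 10
  expect_error(metabolic_model(mets, rxns, S, biomass_ids = "nope",
                               exchange_ids = character(0)),
               "unknown biomass")
  expect_error(metabolic_model(mets, rxns, S, character(0),
                               exchange_ids = "r1"),
               "exactly one metabolite")  # r1 touches two metabolites
})

test_that("JSON write/read is the identity and preserves unknown fields", {
  m <- make_toy_microbe(microbe_spec("A", "glc", secretes = c(ac = "ferment"),
                                     aerobic_yield = 2, anaerobic_yield = 1))
  m$annotations <- list(source = "unit test", curation_round = 3)
  tf <- tempfile(fileext = ".json")
  write_model(m, tf)
  m2 <- read_model(tf)
  expect_identical(m2$metabolites, m$metabolites)
  expect_identical(m2$reactions, m$reactions)
  expect_equal(as.matrix(m2$stoich), as.matrix(m$stoich))
  expect_identical(m2$biomass_ids, m$biomass_ids)
  expect_identical(m2$exchange_ids, m$exchange_ids)
  expect_equal(m2$masses, m$masses)
  expect_equal(m2$annotations$source, "unit test")
  expect_equal(m2$annotations$curation_round, 3)
})

test_that("SBML L3/fbc write/read is the identity on all container fields", {
  m <- make_toy_microbe(microbe_spec("A", "glc", secretes = c(ac = "ferment"),
                                     requires = "vit",
                                     aerobic_yield = 2, anaerobic_yield = 1))
  tf <- tempfile(fileext = ".xml")
  write_model(m, tf)
  m2 <- read_model(tf)
  expect_identical(m2$metabolites, m$metabolites)
  expect_identical(m2$reactions, m$reactions)
  expect_equal(as.matrix(m2$stoich), as.matrix(m$stoich))
  expect_setequal(m2$exchange_ids, m$exchange_ids)
  expect_identical(m2$biomass_ids, m$biomass_ids)
  expect_equal(m2$masses, m$masses)
})

tempfile_model <- function() {
  ts <- tempfile(fileext = ".xml")
  write_model(simple_microbe(), ts)
  ts
}

test_that("malformed and invalid files raise informative errors", {
  tf <- tempfile(fileext = ".json")
  writeLines("{ not json", tf)
  expect_error(read_model(tf), "malformed JSON")
  # SBML whose flux bounds are inverted must name the reaction
  m <- simple_microbe()
  ts <- tempfile(fileext = ".xml")
  write_model(m, ts)
  txt <- readLines(ts)
  txt <- sub('fbc:lowerFluxBound="bnd_1" fbc:upperFluxBound="bnd_3"',
             'fbc:lowerFluxBound="bnd_3" fbc:upperFluxBound="bnd_1"', txt)
  writeLines(txt, ts)
  expect_error(read_model(ts), "lower bound exceeds upper bound")
  # missing biomass objective -> warning, empty biomass_ids
  txt2 <- readLines(tempfile_model())
  sel <- !grepl("fbc:listOfObjectives|fbc:objective|fbc:fluxObjective", txt2)
  ts2 <- tempfile(fileext = ".xml")
  writeLines(txt2[sel], ts2)
  expect_warning(m3 <- read_model(ts2), "no fbc objective")
  expect_length(m3$biomass_ids, 0)
})

test_that("diet application follows the export-positive convention", {
  m <- simple_microbe(yield = 1)
  d <- apply_diet(m, c(glc = 10))
  j <- match("EX_glc", d$reactions$id)
  expect_equal(d$reactions$lb[j], -10)      # uptake capacity c -> lb = -c
  expect_equal(d$reactions$ub[j], 1000)     # secretion left open
  # unlisted exchange metabolites are closed for uptake
  expect_true(all(d$reactions$lb[match(setdiff(d$exchange_ids, "EX_glc"),
                                       d$reactions$id)] == 0))
  # idempotent, and the input model is untouched
  expect_identical(apply_diet(d, c(glc = 10))$reactions, d$reactions)
  expect_equal(m$reactions$lb[j], 0)
  # empty diet: no uptake anywhere, growth 0
  closed <- apply_diet(m, numeric(0))
  expect_equal(solve_fba(closed)$objective_value, 0)
  # unknown metabolites error under strict matching
  expect_error(apply_diet(m, c(nothing = 5), strict = TRUE), "nothing")
})
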
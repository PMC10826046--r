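# Small hand-checkable networks used across the suite.

# Two-reaction cycle A<->B with one degree of freedom; the free flux is
# uniform on [0, ub] under uniform polytope sampling.
cycle_model <- function(lb = 0, ub = 10) {
  mets <- data.frame(id = c("Am", "Bm"), compartment = "c",
                     name = c("Am", "Bm"), stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("r1", "r2"), lb = lb, ub = ub,
                     subsystem = "cycle", organism = "x",
                     stringsAsFactors = FALSE)
  S <- rbind(c(-1, 1), c(1, -1))
  dimnames(S) <- list(mets$id, rxns$id)
  metabolic_model(mets, rxns, S, biomass_ids = character(0),
                  exchange_ids = character(0), name = "cycle")
}

# Linear chain with fixed throughput f: uptake -> A -> B -> C -> export.
chain_model <- function(f = 3) {
  mets <- data.frame(id = c("A", "B", "C"), compartment = "c",
                     name = c("A", "B", "C"), stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_A", "r1", "r2", "EX_C"),
                     lb = c(-f, f, f, f), ub = c(-f, f, f, f),
                     subsystem = "chain", organism = "x",
                     stringsAsFactors = FALSE)
  S <- rbind(c(-1, -1, 0, 0),
             c(0, 1, -1, 0),
             c(0, 0, 1, -1))
  dimnames(S) <- list(mets$id, rxns$id)
  metabolic_model(mets, rxns, S, biomass_ids = character(0),
                  exchange_ids = c("EX_A", "EX_C"), name = "chain")
}

# Anaerobic single-substrate microbe: growth = anaerobic_yield * cap.
simple_microbe <- function(name = "A", source = "glc", yield = 1, ...) {
  make_toy_microbe(microbe_spec(name, source, aerobic_yield = yield,
                                anaerobic_yield = yield, ...))
}

fast_sampler <- function(n = 300, thin = 50, seed = 1) {
  sampler_settings(n_samples = n, steps_per_point = thin, seed = seed)
}
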
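# Small designs and a cached desk-scale pipeline run shared across test files.

tinyDesign <- function() ExperimentDesign(trialsPerCondition = 8L)

oneTrialEvents <- function(condition = "congruent", category = "old") {
  data.frame(run = 1L, onset = 0, duration = 10, condition = condition,
             category = category, trial_index = 1L,
             stringsAsFactors = FALSE)
}

.fixtureCache <- new.env(parent = emptyenv())

# one desk-scale synthetic subject with its full analysis, computed once
deskRun <- function() {
  if (is.null(.fixtureCache$res)) {
    p <- deskScaleProtocol(seed = 11)
    ds <- generateSubject(p$config, p$design)
    .fixtureCache$proto <- p
    .fixtureCache$ds <- ds
    .fixtureCache$res <- runSubject(ds, p$params, seed = 11)
  }
  list(proto = .fixtureCache$proto, ds = .fixtureCache$ds,
       res = .fixtureCache$res)
}
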
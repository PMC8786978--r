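## Shared scenario runs for the trend/acceptance tests.  The reduced-scale
## comparisons reuse one control run; results are cached per session.

.run_cache <- new.env(parent = emptyenv())

## two miniature cycles (protrusive 6 s, retractile 3 s, severing 1.5 s)
trend_run <- function(tag, seed = 1, protrusive = 6, retractile = 3,
                      severing = 1.5, cycles = 2, ...) {
  if (!is.null(.run_cache[[tag]])) return(.run_cache[[tag]])
  cfg <- make_fixture("tiny", seed = seed, protrusive = protrusive,
                      retractile = retractile, severing = severing, ...)
  cfg$total_time <- cycles * (protrusive + retractile + severing)
  res <- run_scenario(cfg)
  tr <- res$trajectory
  out <- list(
    trajectory = tr,
    tip_advance = utils::tail(tr$tip_z, 1) - tr$tip_z[1],
    degraded = sum(!res$state$ecm$seg$intact),
    counts = res$counts,
    state = res$state)
  .run_cache[[tag]] <- out
  out
}
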
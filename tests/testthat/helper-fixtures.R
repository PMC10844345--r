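# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

fx_study <- function() fx("study", default_study)

fx_subject <- function() fx("subject", function() {
  st <- fx_study()
  list(bold = simulate_subject_bold(st$mesh, st$atlas, st$config,
                                    n_volumes = 180, tr_s = 2, seed = 11),
       motion = simulate_motion(180, severity = 1, seed = 12))
})

# a small cohort for pipeline-level tests (4 per group, light permutations)
fx_small_cohort <- function() fx("small_cohort", function() {
  st <- fx_study()
  simulate_cohort(4, st$mesh, st$atlas, st$config, st$truth, seed = 77)
})

fx_small_config <- function() run_config(n_perm = 120, seed = 5)

cfg_with <- function(cfg, ...) {
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

# single equilateral unit triangle as a minimal mesh
fx_triangle <- function() surface_mesh(
  rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
  rbind(c(1L, 2L, 3L)))
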
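# Shared fixtures. The full synthetic landscape is expensive to build, so
# the noise-free generate + pipeline run is computed once and reused across
# test files.

.sf_cache <- new.env(parent = emptyenv())

noisefree_run <- function() {
  if (is.null(.sf_cache$nf)) {
    gen <- generate_landscape(seed = 42, noise_level = 0)
    .sf_cache$nf <- list(gen = gen, res = run_pipeline(gen$bundle))
  }
  .sf_cache$nf
}

# small valid budget table built from components
make_budget <- function(stand_id = "s1", year = 2017, anpp_t = 150, l = 40,
                        bnpp_t_cr = 30, bnpp_t_fr = 60, anpp_u = 40,
                        bnpp_u = 20, rh_s = 210, rh_dw = 8) {
  compose_budget(stand_id, year, anpp_t, l, bnpp_t_cr, bnpp_t_fr,
                 anpp_u, bnpp_u, rh_s, rh_dw)
}
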
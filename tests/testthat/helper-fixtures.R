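## Shared small fixtures, built once per test session.

fix_cells <- local({
  cache <- list()
  function(g) {
    key <- as.character(g)
    if (is.null(cache[[key]])) cache[[key]] <<- build_cell(g)
    cache[[key]]
  }
})

## unit-edge reference radii from explicit coordinates (independent oracle,
## frozen values computed from centroid-to-face / edge / vertex distances)
ref_radii <- list(
  tetra = c(r_in = 0.2041241452, r_mid = 0.3535533906, r_out = 0.6123724357),
  cube  = c(r_in = 0.5, r_mid = 0.7071067812, r_out = 0.8660254038)
)

## synthetic telegraph trajectory with known jump times (ground truth for
## event detection)
make_telegraph <- function(jump_times, period = 1, t_total = 100, dt = 0.1) {
  t <- seq(dt, t_total, by = dt)
  lev <- findInterval(t, jump_times)       # cumulative jump count
  traj <- list(t = t, z = lev * period, v = rep(0, length(t)),
               config = nle_config(dt = dt, t_total = t_total,
                                   out_stride = 1L))
  class(traj) <- "nle_trajectory"
  traj
}
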
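# Shared fixtures, built once per test run. The coarse phantom (32^3 at
# 5 mm) is enough for geometric/contract tests; finer grids are created
# locally where a test needs them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, make) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- make()
  .fixture_env[[key]]
}

coarse_spec <- function(...) phantom_spec(size = c(32, 32, 32),
                                          spacing = c(5, 5, 5), ...)

get_phantom32 <- function() memo("ph32", function() make_4dct(coarse_spec()))

get_phantom48 <- function() memo("ph48", function()
  make_4dct(phantom_spec(size = c(48, 48, 48), spacing = c(3, 3, 3))))

get_phantom64 <- function() memo("ph64", function() make_4dct(phantom_spec()))

# small ramp grid: value = x coordinate (mm)
ramp_grid <- function(n = 8, spacing = 2) {
  g <- grid_geometry(c(0, 0, 0), rep(spacing, 3), rep(n, 3))
  pts <- voxel_centers(g)
  scalar_grid(array(pts[, 1], g$size), g$origin, g$spacing)
}

# brute-force trilinear DVH oracle: full sort, explicit loop
oracle_dq <- function(doses, q) {
  s <- sort(doses, decreasing = TRUE)
  n <- length(s)
  xs <- seq_len(n) / n
  if (q / 100 <= xs[1]) return(s[1])
  if (q / 100 >= xs[n]) return(s[n])
  i <- max(which(xs <= q / 100))
  s[i] + (s[i + 1] - s[i]) * (q / 100 - xs[i]) / (xs[i + 1] - xs[i])
}
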
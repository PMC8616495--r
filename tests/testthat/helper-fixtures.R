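# Shared fixtures, built in code.

disk_mask <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad + 1
  cy <- r + pad + 1
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - cy)^2 + (j - cy)^2 <= (r + 0.5)^2)
}

square_mask <- function(s, pad = 10) {
  m <- matrix(FALSE, s + 2 * pad, s + 2 * pad)
  m[pad + seq_len(s), pad + seq_len(s)] <- TRUE
  m
}

ellipse_mask <- function(a, b, pad = 10) {
  n1 <- 2 * a + 2 * pad + 1; n2 <- 2 * b + 2 * pad + 1
  outer(seq_len(n1), seq_len(n2),
        function(i, j) ((i - a - pad - 1) / a)^2 + ((j - b - pad - 1) / b)^2 <= 1)
}

# Ramanujan's approximation of the ellipse perimeter (closed-form oracle)
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Small rendered movie shared across test files (built once per run)
.movie_cache <- new.env(parent = emptyenv())
small_movie <- function() {
  if (is.null(.movie_cache$mv)) {
    geom <- acquisition_geometry(duration = 1, image_shape = c(192L, 192L))
    .movie_cache$mv <- render_movie(kinetics_model(0.5, 1.5), geom,
                                    n_cells = 60, seed = 42)
  }
  .movie_cache$mv
}

# standard segmentation settings for synthetic movies: opening radius above
# the aggregate scale (documented precondition), permissive area filter
synth_seg_config <- function(image_side = 192L)
  segmentation_config(min_area_px = 100,
                      opening_radius = as.integer(0.43 * image_side))

# exhaustive two-sided Mann-Whitney p-value by enumeration of all
# choose(m + n, m) group assignments of the pooled ranks (independent oracle)
mw_exact_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  combs <- utils::combn(m + n, m)
  us <- apply(combs, 2, u_of)
  mu <- m * n / 2
  sum(abs(us - mu) >= abs(u_obs - mu) - 1e-9) / ncol(combs)
}
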
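# Fixture builders and independent oracles used across the suite.

# A weekly profile sampled on a regular grid from the canonical sine model.
make_profile <- function(A = 10, phi = 9.5, b = 70, noise_sd = 0,
                         step = 5, n_bins = 2016, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, by = step, length.out = n_bins)
  y <- sine_predict(A, phi, b, t)
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  tibble::tibble(bin_start = t, mean_hr = y, n_samples = 1L)
}

# Independent sine-fit oracle: exhaustive 1-min grid over the phase with
# closed-form (A, b) at each candidate, then golden-section refinement of
# the residual sum of squares in phi. Never touches the linear-basis path.
grid_fit_oracle <- function(t, y) {
  sse_at <- function(phi_min) {
    s <- sin(pi / 720 * (t - phi_min))
    fit <- stats::lsfit(s, y)
    sum(fit$residuals^2)
  }
  grid <- seq(0, 1439, by = 1)
  sse <- vapply(grid, sse_at, numeric(1))
  best <- grid[which.min(sse)]
  opt <- stats::optimize(sse_at, interval = c(best - 2, best + 2), tol = 1e-10)
  phi_min <- opt$minimum
  s <- sin(pi / 720 * (t - phi_min))
  cf <- stats::lsfit(s, y)$coefficients
  A <- unname(cf[2]); b <- unname(cf[1])
  if (A < 0) { # canonicalise: negative amplitude is a half-period shift
    A <- -A
    phi_min <- phi_min + 720
  }
  list(A = A, phi = (phi_min %% 1440) / 60, b = b)
}

# Breadth-first-search closure oracle over a parent->child edge list.
bfs_closure_oracle <- function(edges, concept, max_depth = Inf) {
  frontier <- concept
  seen <- concept
  depth <- 0
  while (length(frontier) > 0 && depth < max_depth) {
    nxt <- unique(edges$child_id[edges$parent_id %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
    depth <- depth + 1
  }
  sort(seen)
}

# Random rooted tree on n nodes: each node's parent drawn among earlier
# nodes, bounded depth via branching over levels.
random_tree <- function(n_nodes, seed) {
  set.seed(seed)
  parent <- vapply(2:n_nodes, function(i) sample.int(i - 1, 1), integer(1))
  tibble::tibble(parent_id = as.numeric(parent), child_id = as.numeric(2:n_nodes))
}

# Minimal cohort covariate frame for regression tests (no simulator).
make_covars <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    age = runif(n, 30, 75),
    y_chromosome = runif(n) < 0.33,
    pc1 = rnorm(n), pc2 = rnorm(n), pc3 = rnorm(n),
    pc4 = rnorm(n), pc5 = rnorm(n),
    weekly_steps = pmax(rnorm(n, 5.4, 2.5), 0.1)
  )
}
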
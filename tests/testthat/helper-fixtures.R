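# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no data files.

b15_schedule <- c(0, 5, 10, 20, 30, 40, 60, 80, 120, 160, 200, 300,
                  500, 750, 1000)

# A desk-size spec for fast unit tests (full-size defaults are exercised in
# the acceptance suite).
tiny_spec <- function(...) {
  phantom_spec(grid_shape = c(10L, 10L, 6L), n_per_group = 3L,
               n_directions = 2L, ...)
}

# Independent connected-component oracle: union-find over the supra-threshold
# voxel list, written without reference to the package's labelling code.
oracle_components <- function(mask, connectivity) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  coord <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  maxman <- c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)]
  offs <- offs[man > 0 & man <= maxman, , drop = FALSE]
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_along(idx)) {
    for (k in seq_len(nrow(offs))) {
      nb <- coord[i, ] + offs[k, ]
      if (any(nb < 1) || any(nb > d)) next
      flat <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
      j <- match(flat, idx)
      if (!is.na(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  comps <- split(idx, roots)
  # canonical form: components sorted by first voxel, members sorted
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, min, numeric(1)))])
}

# Canonical form of form_clusters output for comparison with the oracle.
canonical_clusters <- function(clusters) {
  comps <- lapply(clusters, function(cl) sort(cl$indices))
  unname(comps[order(vapply(comps, min, numeric(1)))])
}

# Wrap a plain statistic array as a tmap for cluster-formation tests.
as_tmap <- function(arr, df = 20) {
  structure(list(t = arr, df = df, mask = array(TRUE, dim = dim(arr)),
                 n_A = (df + 2) / 2, n_B = (df + 2) / 2), class = "tmap")
}

# Brute-force IVIM oracle: coarse grid search over (v_bw, D, D*) followed by
# local grid refinement; independent of the package's fitting path.
oracle_ivim_fit <- function(signal, b, n_grid = 16, n_refine = 12) {
  rss_at <- function(v, D, S) {
    r <- (1 - v) * exp(-b * D) + v * exp(-b * (D + S)) - signal
    sum(r^2)
  }
  vs <- seq(0, 0.3, length.out = n_grid)
  Ds <- seq(1e-5, 3e-3, length.out = n_grid)
  Ss <- exp(seq(log(5e-4), log(0.1), length.out = n_grid))
  best <- c(NA, NA, NA); best_rss <- Inf
  for (v in vs) for (D in Ds) for (S in Ss[Ss >= D]) {
    rss <- rss_at(v, D, S)
    if (rss < best_rss) { best_rss <- rss; best <- c(v, D, S) }
  }
  span <- c(0.3, 3e-3, 0.1) / (n_grid - 1)
  for (round in seq_len(n_refine)) {
    vs <- seq(max(0, best[1] - span[1]), min(0.3, best[1] + span[1]),
              length.out = 13)
    Ds <- seq(max(0, best[2] - span[2]), min(3e-3, best[2] + span[2]),
              length.out = 13)
    Ss <- seq(max(1e-5, best[3] - span[3]), min(0.1, best[3] + span[3]),
              length.out = 13)
    for (v in vs) for (D in Ds) for (S in Ss[Ss >= D]) {
      rss <- rss_at(v, D, S)
      if (rss < best_rss) { best_rss <- rss; best <- c(v, D, S) }
    }
    span <- span / 2
  }
  list(v_bw = best[1], D = best[2], D_star = best[3], rss = best_rss)
}
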
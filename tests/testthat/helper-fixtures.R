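# Fixtures and independent oracles, built in code at test time.

# Solid axis-aligned cuboid of one label centered in background.
cuboid_volume <- function(edges, grid = edges + 4L, label = 1L) {
  v <- array(0L, grid)
  lo <- (grid - edges) %/% 2L + 1L
  hi <- lo + edges - 1L
  v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- label
  label_volume(v)
}

# Seeded random label volume (labels 0..n_labels).
random_label_volume <- function(dims, n_labels, seed) {
  set.seed(seed)
  label_volume(array(sample(0:n_labels, prod(dims), replace = TRUE), dims))
}

# Literal triple-loop 6-neighbor surface-voxel count: the independent oracle
# for the vectorized implementation.
oracle_surface_count <- function(vox, region) {
  d <- dim(vox)
  cnt <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (vox[i, j, k] != region) next
    nbs <- rbind(c(i - 1L, j, k), c(i + 1L, j, k), c(i, j - 1L, k),
                 c(i, j + 1L, k), c(i, j, k - 1L), c(i, j, k + 1L))
    for (b in seq_len(6L)) {
      p <- nbs[b, ]
      lab <- if (any(p < 1L) || any(p > d)) 0L else vox[p[1], p[2], p[3]]
      if (lab != region) { cnt <- cnt + 1L; break }
    }
  }
  cnt
}

# Small feature table with hand-chosen columns.
toy_feature_table <- function(ages = c(30, 34, 38, 42),
                              extra = list()) {
  vals <- cbind(`SVR:signal` = ages,
                `RV:noise` = c(0.2, 0.8, 0.4, 0.6))
  for (nm in names(extra)) {
    vals <- cbind(vals, extra[[nm]])
    colnames(vals)[ncol(vals)] <- nm
  }
  feature_table(sprintf("s%d", seq_along(ages)),
                rep("ses-1", length(ages)), ages, vals)
}

# Quick single-session manifest of n subjects.
toy_manifest <- function(n, seed = 1) {
  set.seed(seed)
  cohort_manifest(sprintf("sub-%04d", seq_len(n)),
                  rep("ses-1", n),
                  runif(n, 29, 45))
}
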
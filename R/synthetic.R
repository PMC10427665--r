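# Synthetic data: voxel-level label phantoms with age-dependent regional
# volume shares and surface complexity, and a tabular cohort simulator with
# a planted linear age signal.
#
# The phantoms are deliberately geometric, not anatomical: an ellipsoidal
# "brain" partitioned into regions by weighted nearest-centroid assignment.
# What they reproduce is the statistical structure the pipeline consumes --
# region volume fractions that drift with age (softmax share model, so
# RV sums to 1 by construction) and boundary complexity that grows with age
# for designated "cortical" regions (a radial sinusoidal perturbation whose
# amplitude rises with age, raising the surface-voxel count).

default_growth_coefs <- function(n_regions, n_informative = 10L) {
  g <- rep(0, n_regions)
  k <- min(n_informative, n_regions)
  g[seq_len(k)] <- rep(c(0.05, -0.05, 0.04, -0.04, 0.035, -0.035,
                         0.03, -0.03, 0.025, -0.025), length.out = k)
  g
}

# Fold ("cortical") regions are disjoint from the growth regions so that the
# two planted trends can be verified independently: a fold region's voxel
# share stays flat while its boundary corrugation grows with age.
default_fold_coefs <- function(n_regions, n_cortical = 5L) {
  f <- rep(0, n_regions)
  lo <- min(11L, n_regions)
  hi <- min(lo + n_cortical - 1L, n_regions)
  f[lo:hi] <- 0.02
  f
}

#' Specification of a label-volume phantom
#'
#' @param grid_shape integer length-3 voxel grid (default 64^3).
#' @param n_regions number of regions (default 87, so a full phantom yields
#'   the standard 174-feature table).
#' @param age_weeks PMA of the simulated subject, weeks.
#' @param growth_coefs per-region relative volume growth per week; a
#'   region's target share scales as softmax(growth * (age - 37)).
#' @param fold_coefs per-region surface-perturbation amplitude growth per
#'   week; amplitude = fold_coef * (age - 29), so folding is absent at 29
#'   weeks and rises with age, as cortical gyrification does.
#' @param noise_sd fraction of between-structure boundary voxels flipped to
#'   a random differing face-neighbor label.
#' @param seed per-subject seed (boundary noise).
#' @param layout_seed seed for the shared region geometry (centroids); keep
#'   it fixed across a cohort so regions mean the same thing in every
#'   subject.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), n_regions = 87L,
                         age_weeks = 40, growth_coefs = NULL,
                         fold_coefs = NULL, noise_sd = 0, seed = 0L,
                         layout_seed = 1000L) {
  if (n_regions < 2L) stopf("n_regions must be >= 2")
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    stopf("grid_shape must be 3 dimensions, each >= 8")
  }
  growth_coefs <- growth_coefs %||% default_growth_coefs(n_regions)
  fold_coefs <- fold_coefs %||% default_fold_coefs(n_regions)
  if (length(growth_coefs) != n_regions || length(fold_coefs) != n_regions) {
    stopf("growth_coefs and fold_coefs must have length n_regions")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 n_regions = as.integer(n_regions),
                 age_weeks = age_weeks,
                 growth_coefs = growth_coefs,
                 fold_coefs = fold_coefs,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 layout_seed = as.integer(layout_seed)),
            class = "phantom_spec")
}

#' Generate a label-volume phantom
#'
#' Builds an ellipsoidal mask, places `n_regions` seeded centroids, and
#' assigns every mask voxel to the nearest centroid under per-region distance
#' scales. The scales are iterated so realized region shares track the
#' softmax volume-share targets; regions with positive `fold_coefs` get a
#' sinusoidal distance perturbation that corrugates their boundary with
#' age-growing amplitude. Optional boundary label noise then flips a
#' fraction of between-structure surface voxels.
#'
#' @param spec a [phantom_spec()].
#' @return a [label_volume]; errors if any expected region came out empty
#'   (grid too small for `n_regions`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  n_r <- spec$n_regions

  ax <- (d - 1) / 2
  semi <- 0.46 * (d - 1)
  gx <- seq_len(d[1]) - 1; gy <- seq_len(d[2]) - 1; gz <- seq_len(d[3]) - 1
  coord <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  inside <- ((coord[, 1] - ax[1]) / semi[1])^2 +
            ((coord[, 2] - ax[2]) / semi[2])^2 +
            ((coord[, 3] - ax[3]) / semi[3])^2 <= 1
  mask_idx <- which(inside)
  pts <- coord[mask_idx, , drop = FALSE]
  if (nrow(pts) < 4L * n_r) {
    stopf("grid too small: %d mask voxels cannot host %d regions",
          nrow(pts), n_r)
  }

  centroids <- with_seed(spec$layout_seed, {
    pts[sample.int(nrow(pts), n_r), , drop = FALSE]
  })

  n_vox <- nrow(pts)

  # Squared distances voxel x centroid; boundary corrugation multiplies the
  # fold regions' distances before the capacity iteration.
  d2 <- outer(pts[, 1], centroids[, 1], "-")^2 +
        outer(pts[, 2], centroids[, 2], "-")^2 +
        outer(pts[, 3], centroids[, 3], "-")^2

  amp <- pmin(pmax(spec$fold_coefs * (spec$age_weeks - 29), 0), 0.85)
  wavelength <- 4
  wfield <- sin(2 * pi * pts[, 1] / wavelength) *
            sin(2 * pi * pts[, 2] / wavelength) *
            sin(2 * pi * pts[, 3] / wavelength)
  for (j in which(amp > 0)) {
    d2[, j] <- d2[, j] * (1 + amp[j] * wfield)^2
  }

  target <- softmax(spec$growth_coefs * (spec$age_weeks - 37))

  # Capacity-constrained power diagram: assign to argmin(d^2 - w_i) and move
  # each weight by ~ (cell radius)^2 * log(target/realized) until realized
  # shares track the softmax targets. Damped (0.6, then 0.3 after 20 steps)
  # to avoid the oscillation the undamped fixed point exhibits; the best
  # iterate by worst-region log error is kept.
  r2_cell <- (3 * (n_vox * target) / (4 * pi))^(2 / 3)
  w <- (2 / 3) * r2_cell * log(target * n_r)
  assign <- integer(n_vox)
  best_err <- Inf
  for (it in 1:60) {
    a <- pd_assign(d2, w)
    realized <- tabulate(a, n_r) / n_vox
    err <- log(target / pmax(realized, 0.1 / n_vox))
    if (max(abs(err)) < best_err) {
      best_err <- max(abs(err))
      assign <- a
    }
    if (best_err < 0.02) break
    damp <- if (it <= 20L) 0.6 else 0.3
    w <- w + damp * (2 / 3) * r2_cell * pmin(pmax(err, -1), 1)
  }

  vox <- array(0L, d)
  vox[mask_idx] <- assign
  vol <- label_volume(vox)

  if (spec$noise_sd > 0) {
    vol <- flip_boundary_voxels(vol, spec$noise_sd, spec$seed)
  }

  present <- tabulate(vol$voxels[vol$voxels > 0L], n_r)
  if (any(present == 0L)) {
    stopf("grid too small: region(s) %s empty",
          paste(utils::head(which(present == 0L), 5), collapse = ", "))
  }
  vol
}

softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

# Flip a fraction of between-structure boundary voxels to the label of a
# randomly chosen differing face neighbor.
flip_boundary_voxels <- function(vol, fraction, seed) {
  v <- vol$voxels
  d <- dim(v)
  sm <- surface_mask(v, 6)
  cand <- which(sm)
  n_flip <- floor(fraction * length(cand))
  if (n_flip == 0L) return(vol)
  offs <- connectivity_offsets(6)
  with_seed(seed, {
    chosen <- sample(cand, n_flip)
    ai <- arrayInd(chosen, d)
    pick <- sample.int(6L, n_flip, replace = TRUE)
    for (i in seq_len(n_flip)) {
      nb <- ai[i, ] + offs[pick[i], ]
      if (any(nb < 1L) || any(nb > d)) next
      lab <- v[nb[1], nb[2], nb[3]]
      if (lab != v[ai[i, 1], ai[i, 2], ai[i, 3]] && lab > 0L) {
        v[ai[i, 1], ai[i, 2], ai[i, 3]] <- lab
      }
    }
  })
  label_volume(v, vol$spacing)
}

#' Generate a phantom cohort on disk
#'
#' Draws `n` ages uniformly over `age_range`, generates one phantom per
#' subject from the template spec (same layout seed, per-subject noise
#' seeds), writes NIfTI volumes and a manifest TSV into `dir`, and returns
#' the manifest plus ground truth.
#'
#' @param n number of subjects.
#' @param age_range (lo, hi) PMA window in weeks; default the 29-45 week
#'   neonatal scan range.
#' @param template a [phantom_spec()] supplying everything but age and seed.
#' @param seed cohort seed.
#' @param dir output directory (created if needed).
#' @return object of class `synthetic_cohort`: `manifest`
#'   (a [cohort_manifest()]) and `truth` (ages, growth/fold coefficients,
#'   informative region ids).
#' @export
generate_cohort <- function(n, age_range = c(29, 45),
                            template = phantom_spec(), seed = 0L,
                            dir = tempfile("cohort")) {
  if (n < 1L) stopf("n must be >= 1")
  if (age_range[1] >= age_range[2]) stopf("age_range must satisfy lo < hi")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ages <- with_seed(seed, stats::runif(n, age_range[1], age_range[2]))
  paths <- character(n)
  for (i in seq_len(n)) {
    sp <- template
    sp$age_weeks <- ages[i]
    sp$seed <- derive_seed(seed, i)
    vol <- generate_phantom(sp)
    paths[i] <- file.path(dir, sprintf("sub-%03d_ses-1.nii.gz", i))
    write_label_volume(vol, paths[i])
  }
  manifest <- cohort_manifest(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    session_id = "ses-1",
    pma_weeks = ages,
    volume_path = paths)
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  structure(
    list(manifest = manifest,
         truth = list(ages = ages,
                      growth_coefs = template$growth_coefs,
                      fold_coefs = template$fold_coefs,
                      informative_regions =
                        which(template$growth_coefs != 0 |
                              template$fold_coefs != 0))),
    class = "synthetic_cohort")
}

#' Simulate a tabular feature cohort with planted age signal
#'
#' A fast stand-in for phantom extraction used to test regression and PFI.
#' Ages are uniform over `age_range`. RV columns are Dirichlet-distributed
#' (so each row sums to 1) with concentrations that drift with age for the
#' informative regions, in alternating directions. SVR columns of
#' informative regions follow `s0 + beta * (age + e)`, with feature noise
#' `e ~ N(0, noise_sd^2)` expressed on the age scale (weeks): inverting a
#' single informative feature therefore predicts age with error sd
#' `noise_sd`, i.e. an oracle univariate regression attains
#' MAE = noise_sd * sqrt(2 / pi). Non-informative SVR columns are pure noise
#' of comparable magnitude.
#'
#' @param n number of subjects.
#' @param n_regions regions per family (default 87, giving 174 features).
#' @param informative integer region indices carrying signal (default 1:10).
#' @param beta SVR slope per week for informative regions.
#' @param noise_sd feature noise on the age scale, weeks; the default 0.5
#'   puts the univariate-oracle MAE floor at 0.5 * sqrt(2/pi) ~ 0.40 weeks.
#' @param age_range PMA window, weeks.
#' @param seed integer seed.
#' @param rv_growth concentration log-slope per week for informative RV
#'   regions.
#' @return list: `table` (a [feature_table()]) and `truth` (informative set,
#'   slopes, `noise_floor_mae = noise_sd * sqrt(2/pi)`).
#' @export
simulate_feature_table <- function(n, n_regions = 87L,
                                   informative = seq_len(min(10L, n_regions)),
                                   beta = 0.012, noise_sd = 0.5,
                                   age_range = c(29, 45), seed = 0L,
                                   rv_growth = 0.03) {
  if (length(informative) && (min(informative) < 1 ||
                              max(informative) > n_regions)) {
    stopf("informative regions must lie in 1..n_regions")
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")

  rnames <- region_names(seq_len(n_regions))
  out <- with_seed(seed, {
    ages <- stats::runif(n, age_range[1], age_range[2])

    g <- rep(0, n_regions)
    g[informative] <- rv_growth * rep_len(c(1, -1), length(informative))
    conc <- 50 * exp(outer(ages - 37, g))          # n x regions
    gam <- matrix(stats::rgamma(n * n_regions, shape = conc, rate = 1),
                  n, n_regions)
    rv <- gam / rowSums(gam)

    s0 <- 0.15 + 0.005 * (seq_len(n_regions) %% 20)
    svr <- matrix(rep(s0, each = n), n, n_regions)
    for (j in informative) {
      svr[, j] <- s0[j] + beta * (ages + stats::rnorm(n, 0, noise_sd))
    }
    noise_cols <- setdiff(seq_len(n_regions), informative)
    svr[, noise_cols] <- svr[, noise_cols] +
      matrix(stats::rnorm(n * length(noise_cols), 0, beta * noise_sd),
             n, length(noise_cols))
    list(ages = ages, rv = rv, svr = svr, g = g)
  })

  values <- cbind(out$rv, out$svr)
  colnames(values) <- c(paste0("RV:", rnames), paste0("SVR:", rnames))
  tab <- feature_table(sprintf("sim-%04d", seq_len(n)),
                       rep("ses-1", n), out$ages, values)
  list(table = tab,
       truth = list(informative = informative,
                    beta = beta,
                    rv_growth = out$g,
                    noise_sd = noise_sd,
                    noise_floor_mae = noise_sd * sqrt(2 / pi)))
}
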
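# Per-region morphometry from label volumes: voxel counts, surface-voxel
# counts, relational volume (RV) and surface-to-volume ratio (SVR), plus the
# Dice coefficient for segmentation QC.
#
# RV is a region's voxel count divided by the total voxel count of all
# nonzero structures: a head-size-invariant volume fraction. SVR counts the
# region's surface voxels (voxels with at least one differing-label neighbor)
# and divides by the region's voxel count: a cheap proxy for how folded the
# structure is, which rises sharply with gyrification in the third trimester.
# Both features use raw voxel counts; spacing metadata never enters.

connectivity_offsets <- function(connectivity = 6) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6"  = d == 1,
                 "18" = d >= 1 & d <= 2,
                 "26" = d >= 1,
                 stopf("connectivity must be 6, 18 or 26"))
  as.matrix(g[keep, , drop = FALSE])
}

# Logical mask of nonzero voxels having >= 1 neighbor with a different label.
# Out-of-bounds neighbors count as background, so voxels on the volume border
# are surface voxels.
surface_mask <- function(voxels, connectivity = 6) {
  d <- dim(voxels)
  pad <- array(0L, d + 2L)
  core <- list(2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L))
  pad[core[[1]], core[[2]], core[[3]]] <- voxels
  differs <- array(FALSE, d)
  offs <- connectivity_offsets(connectivity)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    nb <- pad[core[[1]] + o[1], core[[2]] + o[2], core[[3]] + o[3]]
    differs <- differs | (nb != voxels)
  }
  differs & (voxels > 0L)
}

#' Per-region voxel counts
#'
#' @param vol a [label_volume].
#' @return named integer vector mapping region id to voxel count, covering
#'   every nonzero label present; empty for an all-background volume.
#' @export
region_volumes <- function(vol) {
  assert_label_volume(vol)
  v <- vol$voxels[vol$voxels > 0L]
  if (length(v) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(v)
  setNames(as.integer(tab), names(tab))
}

#' Count surface voxels of one region
#'
#' A voxel of the region is a surface voxel when at least one of its
#' neighbors (6-, 18- or 26-connectivity; default 6, i.e. face-adjacent)
#' carries a different label. Any differing label counts, including other
#' structures, not only background. Out-of-bounds neighbors are background.
#'
#' @param vol a [label_volume].
#' @param region_id positive integer label.
#' @param connectivity 6 (default), 18 or 26.
#' @return integer surface voxel count.
#' @export
surface_voxel_count <- function(vol, region_id, connectivity = 6) {
  assert_label_volume(vol)
  if (length(region_id) != 1L || region_id <= 0L) {
    stopf("region_id must be a single positive integer (background 0 rejected)")
  }
  sm <- surface_mask(vol$voxels, connectivity)
  sum(sm & (vol$voxels == as.integer(region_id)))
}

# All regions at once: one surface-mask pass, then a tally of surface labels.
surface_voxel_counts <- function(vol, connectivity = 6) {
  sm <- surface_mask(vol$voxels, connectivity)
  v <- vol$voxels[sm]
  if (length(v) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(v)
  setNames(as.integer(tab), names(tab))
}

#' Relational volume of a region
#'
#' Voxel count of the region divided by the summed voxel count of all
#' nonzero structures (background excluded from the denominator).
#'
#' @param volumes named vector as returned by [region_volumes()].
#' @param region_id region label; a region absent from `volumes` has RV 0.
#' @return RV in \[0, 1\].
#' @export
relational_volume <- function(volumes, region_id) {
  total <- sum(volumes)
  if (total <= 0) stopf("no structures present (all-background volume)")
  cnt <- volumes[as.character(region_id)]
  if (is.na(cnt)) cnt <- 0L
  as.numeric(cnt) / as.numeric(total)
}

#' Surface-to-volume ratio
#'
#' @param surface surface voxel count.
#' @param voxel_count region voxel count; 0 yields SVR 0 (absent region).
#' @return SVR in \[0, 1\].
#' @export
surface_to_volume_ratio <- function(surface, voxel_count) {
  if (voxel_count < 0) stopf("voxel_count must be >= 0")
  if (surface > voxel_count) {
    stopf("surface count (%d) exceeds voxel count (%d)", surface, voxel_count)
  }
  if (voxel_count == 0) return(0)
  surface / voxel_count
}

#' Extract per-region morphometry from a label volume
#'
#' Computes, for every expected region in scheme order, the voxel count,
#' surface voxel count, RV and SVR. Regions absent from the volume get
#' zero counts, RV 0 and SVR 0, and are flagged `absent`. The RV denominator
#' uses only regions actually present (all nonzero labels in the volume).
#'
#' @param vol a [label_volume].
#' @param expected_regions integer region ids defining the output rows;
#'   default the 87-region scheme.
#' @param connectivity neighborhood for surface counting (6, 18, 26).
#' @param scheme naming scheme for `region_name`.
#' @return data.frame with columns `region_id`, `region_name`, `voxel_count`,
#'   `surface_voxel_count`, `rv`, `svr`, `absent`.
#' @export
extract_features <- function(vol, expected_regions = region_scheme()$id,
                             connectivity = 6, scheme = "draw-em-87") {
  assert_label_volume(vol)
  if (length(expected_regions) == 0L) stopf("expected_regions must be non-empty")
  expected_regions <- as.integer(expected_regions)
  vols <- region_volumes(vol)
  surf <- surface_voxel_counts(vol, connectivity)
  total <- sum(vols)
  key <- as.character(expected_regions)
  vc <- vols[key]; vc[is.na(vc)] <- 0L
  sc <- surf[key]; sc[is.na(sc)] <- 0L
  rv <- if (total > 0) as.numeric(vc) / as.numeric(total) else rep(0, length(vc))
  svr <- ifelse(vc > 0, as.numeric(sc) / as.numeric(vc), 0)
  data.frame(
    region_id = expected_regions,
    region_name = region_names(expected_regions, scheme),
    voxel_count = as.integer(vc),
    surface_voxel_count = as.integer(sc),
    rv = rv,
    svr = svr,
    absent = vc == 0L,
    row.names = NULL,
    stringsAsFactors = FALSE)
}

#' Dice similarity coefficient for one region
#'
#' DSC = 2 |A n B| / (|A| + |B|) between the binary masks of `region_id` in
#' predicted and ground-truth label volumes; defined as 1 when both masks are
#' empty.
#'
#' @param pred,truth [label_volume]s on identical grids.
#' @param region_id positive region label.
#' @return DSC in \[0, 1\].
#' @export
dice_coefficient <- function(pred, truth, region_id) {
  assert_label_volume(pred); assert_label_volume(truth)
  if (!identical(dim(pred$voxels), dim(truth$voxels))) {
    stopf("shape mismatch between prediction and ground truth")
  }
  a <- pred$voxels == as.integer(region_id)
  b <- truth$voxels == as.integer(region_id)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Mean Dice over a region list
#'
#' @param pred,truth [label_volume]s on identical grids.
#' @param regions integer region ids to average over.
#' @return mean per-region DSC.
#' @export
mean_dice <- function(pred, truth, regions) {
  mean(vapply(regions, function(r) dice_coefficient(pred, truth, r), numeric(1)))
}
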
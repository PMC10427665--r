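# Region label schemes.
#
# The default scheme mirrors the layout of the DRAW-EM 87-region neonatal
# parcellation (paired cortical GM/WM subdivisions, deep grey structures,
# cerebellum, brainstem, ventricles, CSF). Names are a convenience for
# reporting; all computation keys on the integer ids. Unknown ids fall back
# to "region_<id>".

cortical_pairs_anterior <- c(
  "Anterior temporal lobe, medial part",
  "Anterior temporal lobe, lateral part",
  "Gyri parahippocampalis et ambiens, anterior part",
  "Superior temporal gyrus, middle part",
  "Medial and inferior temporal gyri, anterior part",
  "Lateral occipitotemporal gyrus, anterior part")

cortical_pairs_posterior <- c(
  "Insula",
  "Occipital lobe",
  "Gyri parahippocampalis et ambiens, posterior part",
  "Lateral occipitotemporal gyrus, posterior part",
  "Medial and inferior temporal gyri, posterior part",
  "Superior temporal gyrus, posterior part",
  "Cingulate gyrus, anterior part",
  "Cingulate gyrus, posterior part",
  "Frontal lobe",
  "Parietal lobe")

build_scheme_87 <- function() {
  lr <- function(base, tissue, order = c("left", "right")) {
    sprintf("%s %s %s", base, order, tissue)
  }
  nm <- character(87)
  nm[1:2] <- c("Hippocampus left", "Hippocampus right")
  nm[3:4] <- c("Amygdala left", "Amygdala right")
  i <- 5L
  for (b in cortical_pairs_anterior) {
    nm[i:(i + 1L)] <- lr(b, "GM"); i <- i + 2L
  }
  nm[17:19] <- c("Cerebellum left", "Cerebellum right", "Brainstem")
  i <- 20L
  for (b in cortical_pairs_posterior) {
    nm[i:(i + 1L)] <- lr(b, "GM", order = c("right", "left")); i <- i + 2L
  }
  nm[40:41] <- c("Caudate nucleus right", "Caudate nucleus left")
  nm[42:43] <- c("Thalamus right", "Thalamus left")
  nm[44:45] <- c("Subthalamic nucleus right", "Subthalamic nucleus left")
  nm[46:47] <- c("Lentiform nucleus right", "Lentiform nucleus left")
  nm[48] <- "Corpus callosum"
  nm[49:50] <- c("Lateral ventricle left", "Lateral ventricle right")
  i <- 51L
  for (b in cortical_pairs_anterior) {
    nm[i:(i + 1L)] <- lr(b, "WM"); i <- i + 2L
  }
  for (b in cortical_pairs_posterior) {
    nm[i:(i + 1L)] <- lr(b, "WM", order = c("right", "left")); i <- i + 2L
  }
  nm[83] <- "CSF"
  nm[84] <- "Extra-cranial CSF"
  nm[85:86] <- c("Internal capsule right", "Internal capsule left")
  nm[87] <- "Optic chiasm"
  data.frame(id = 1:87, name = nm, stringsAsFactors = FALSE)
}

scheme_cache <- new.env(parent = emptyenv())

#' Region labelling schemes
#'
#' @param scheme scheme identifier; `"draw-em-87"` (the default 87-region
#'   neonatal parcellation layout) is packaged.
#' @return data.frame with columns `id` and `name`.
#' @export
region_scheme <- function(scheme = "draw-em-87") {
  if (!identical(scheme, "draw-em-87")) {
    stopf("unknown region scheme '%s'", scheme)
  }
  if (is.null(scheme_cache$draw_em_87)) {
    scheme_cache$draw_em_87 <- build_scheme_87()
  }
  scheme_cache$draw_em_87
}

#' Map region ids to names
#'
#' Ids absent from the scheme are named `region_<id>`.
#'
#' @param ids integer region ids.
#' @param scheme scheme identifier passed to [region_scheme()].
#' @return character vector of names, same length as `ids`.
#' @export
region_names <- function(ids, scheme = "draw-em-87") {
  tab <- region_scheme(scheme)
  idx <- match(ids, tab$id)
  out <- tab$name[idx]
  out[is.na(idx)] <- sprintf("region_%d", ids[is.na(idx)])
  out
}
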
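#' Post-processing parameters for DVF-based segmentation
#'
#' The predicted displacement field is converted to a distance map; voxels
#' with distance above `t_seed` form seed cores, voxels above `t_fg` form the
#' foreground, and a marker-controlled watershed on the negated distance map
#' grows each seed into an instance.  Defaults suit nuclei of roughly 2--6
#' voxel radius.
#'
#' @param t_seed Distance threshold (voxels) for seed cores.
#' @param t_fg Foreground distance threshold (voxels); `t_seed >= t_fg >= 0`.
#' @param min_size Minimum seed component size in voxels.
#' @param connectivity Neighbourhood, `6` or `26`.
#' @return A `postprocess_params` object.
#' @export
postprocess_params <- function(t_seed = 2, t_fg = 0.5, min_size = 9L,
                               connectivity = 26L) {
  if (t_fg < 0 || t_seed < t_fg) abort("need t_seed >= t_fg >= 0")
  if (!connectivity %in% c(6L, 26L)) abort("connectivity must be 6 or 26")
  structure(list(t_seed = t_seed, t_fg = t_fg, min_size = as.integer(min_size),
                 connectivity = as.integer(connectivity)),
            class = "postprocess_params")
}

#' Extract watershed seeds from a distance map
#'
#' Connected components of `dist > t_seed`, with components smaller than
#' `min_size` removed.  Components are labelled `1..K` in order of their
#' minimum linear array index, so the labelling is deterministic.
#'
#' @param dist A non-negative 3D distance array.
#' @param p A [postprocess_params()].
#' @return An instance mask of seed labels (possibly empty).
#' @export
extract_seeds <- function(dist, p = postprocess_params()) {
  dist <- as_volume(dist)
  d <- dim(dist)
  lab <- cpp_label_components(as.vector(dist > p$t_seed), d[1], d[2], d[3],
                              p$connectivity)
  if (p$min_size > 0 && any(lab > 0)) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= p$min_size)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  as_instance_mask(array(lab, d))
}

#' Marker-controlled watershed on a distance map
#'
#' Grows the labelled seeds over the foreground `dist > t_fg` by flooding the
#' negated distance map (highest distances claimed first), so the boundary
#' between two cells falls on the distance-map ridge.  Every foreground voxel
#' reachable from a seed receives exactly one seed label.
#'
#' @param dist A non-negative 3D distance array.
#' @param seeds An instance mask of seed labels.
#' @param p A [postprocess_params()].
#' @return An instance mask; its labels are a subset of the seed labels.
#' @export
watershed_segment <- function(dist, seeds, p = postprocess_params()) {
  dist <- as_volume(dist)
  seeds <- as_instance_mask(seeds)
  check_same_dims(dist, seeds, "distance map and seeds")
  if (all(seeds == 0)) {
    warn("no seeds; returning an all-background segmentation")
    return(as_instance_mask(array(0L, dim(dist))))
  }
  d <- dim(dist)
  lab <- cpp_watershed(as.vector(dist), as.vector(seeds),
                       as.vector(dist > p$t_fg | seeds > 0),
                       d[1], d[2], d[3], p$connectivity)
  as_instance_mask(array(lab, d))
}

#' Instance segmentation from a displacement vector field
#'
#' Composition of [dvf_to_distance()], [extract_seeds()] and
#' [watershed_segment()]: the standard inference path after [predict_dvf()].
#'
#' @param field A `dvf_field`.
#' @param p A [postprocess_params()].
#' @return An instance mask.
#' @export
segment_from_dvf <- function(field, p = postprocess_params()) {
  dist <- dvf_to_distance(field)
  seeds <- extract_seeds(dist, p)
  if (all(seeds == 0)) {
    return(as_instance_mask(array(0L, dim(dist))))
  }
  watershed_segment(dist, seeds, p)
}
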
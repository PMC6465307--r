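# Regional extraction: ROI means over the atlas, averaging of paired
# structures, and normalization to the frontal-horn CSF reference.
# "Normalization" is subtraction of the reference mean: dipole-inverted
# susceptibility is defined only up to an additive constant (D(0) = 0), so
# an additive reference is the physically meaningful choice.

#' Per-label mean susceptibility
#'
#' Arithmetic mean of the map over the in-mask voxels of each atlas label.
#' ROI means are restricted to the map's valid mask; a label with no valid
#' voxels is an error naming the region.
#'
#' @param chi_map a `susceptibility_map` (or list with `values` and
#'   `valid_mask`).
#' @param atlas atlas list with `labels`, `name_map`, `reference_label`
#'   (see [build_phantom()]).
#' @return Named numeric vector of means (ppm), names = label ids.
#' @export
roi_means <- function(chi_map, atlas) {
  values <- chi_map$values
  valid <- if (!is.null(chi_map$valid_mask)) chi_map$valid_mask
  else array(TRUE, dim(values))
  if (!identical(dim(values), dim(atlas$labels)))
    stop("map and atlas shapes differ")
  labs <- sort(unique(atlas$labels[atlas$labels > 0L]))
  out <- vapply(labs, function(l) {
    sel <- atlas$labels == l & valid
    if (!any(sel)) {
      nm <- atlas$name_map$region[atlas$name_map$label == l]
      stop(sprintf("label %d (%s) has no voxels inside the valid mask", l,
                   if (length(nm)) nm else "?"))
    }
    mean(values[sel])
  }, numeric(1))
  names(out) <- labs
  out
}

#' Average paired structures
#'
#' Unweighted mean of the left and right ROI means for each paired region;
#' unpaired regions (e.g. the CSF reference) pass through.
#'
#' @param label_means named vector from [roi_means()].
#' @param atlas atlas list with `name_map`.
#' @return Named numeric vector, one value per region name.
#' @export
average_pairs <- function(label_means, atlas) {
  nm <- atlas$name_map
  regions <- unique(nm$region)
  out <- vapply(regions, function(r) {
    rows <- nm[nm$region == r, , drop = FALSE]
    if (any(c("left", "right") %in% rows$side)) {
      if (!all(c("left", "right") %in% rows$side))
        stop("region ", r, " is missing one side")
    }
    m <- label_means[as.character(rows$label)]
    if (any(is.na(m))) stop("region ", r, " has labels absent from the means")
    mean(m)
  }, numeric(1))
  names(out) <- regions
  out
}

#' Normalize regional values to the CSF reference
#'
#' Subtracts the CSF reference mean from every regional value, making the
#' result invariant to any global additive offset of the map.
#'
#' @param region_values named numeric vector of regional means (ppm).
#' @param csf_mean scalar CSF reference mean (ppm).
#' @return Referenced values (ppm relative to CSF).
#' @export
reference_normalize <- function(region_values, csf_mean) {
  if (!is.finite(csf_mean)) stop("csf_mean must be finite")
  region_values - csf_mean
}

#' Build a per-subject record of referenced regional susceptibilities
#'
#' Composes [roi_means()], [average_pairs()] and [reference_normalize()] and
#' attaches demographics. Requires all five deep nuclei plus the reference
#' region to be represented in the atlas.
#'
#' @param chi_map a `susceptibility_map`.
#' @param atlas atlas list (with `reference_label`).
#' @param demographics list or one-row data frame with at least
#'   `subject_id` and `group`; optional `age_years`, `gender`,
#'   `disease_duration_years`, `updrs_iii`, `hoehn_yahr`.
#' @return One-row data frame: subject_id, group, age, gender, duration,
#'   updrs_iii, hoehn_yahr, gp, put, sn, rn, dn (referenced ppm).
#' @export
build_subject_record <- function(chi_map, atlas, demographics) {
  lm_ <- roi_means(chi_map, atlas)
  rm_ <- average_pairs(lm_, atlas)
  ref_region <- atlas$name_map$region[atlas$name_map$label == atlas$reference_label]
  if (!length(ref_region)) stop("reference label absent from the atlas")
  missing <- setdiff(QSM_REGIONS, names(rm_))
  if (length(missing))
    stop("atlas is missing regions: ", paste(missing, collapse = ", "))
  refd <- reference_normalize(rm_[QSM_REGIONS], rm_[[ref_region]])
  g <- function(f, default = NA) if (!is.null(demographics[[f]])) demographics[[f]] else default
  out <- data.frame(subject_id = g("subject_id", "subject"),
                    group = g("group", NA_character_),
                    age = g("age_years"), gender = g("gender", NA_character_),
                    duration = g("disease_duration_years"),
                    updrs_iii = g("updrs_iii"), hoehn_yahr = g("hoehn_yahr"),
                    stringsAsFactors = FALSE)
  for (r in QSM_REGIONS) out[[QSM_REGION_CODES[[r]]]] <- unname(refd[[r]])
  out
}
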
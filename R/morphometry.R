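# Measurement formulas and dendrite-level summaries from reconstruction
# tables and serial-section contour stacks.

#' Serial-section contour stack
#'
#' Per-section measurements of one reconstructed spine head: plasma-membrane
#' cross-sectional areas and, for cross-sectioned synapses, PSD trace
#' lengths, together with the section thickness. Synapses cut en face carry
#' a single-section PSD area instead of trace lengths.
#'
#' @param areas Per-section cross-sectional areas, um^2 (>= 0).
#' @param thickness Section thickness, um (> 0; study value 0.04 um).
#' @param psd_trace_lengths Optional per-section PSD trace lengths, um.
#' @param en_face_area Optional single-section PSD area, um^2, for en face
#'   synapses. At most one of `psd_trace_lengths` / `en_face_area` may be
#'   given.
#' @return An object of class `contour_stack`.
#' @export
contour_stack <- function(areas, thickness, psd_trace_lengths = NULL,
                          en_face_area = NULL) {
  if (length(areas) < 1L) stop("contour stack needs >= 1 section", call. = FALSE)
  if (!is.numeric(areas) || any(areas < 0))
    stop("section areas must be non-negative", call. = FALSE)
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0)
    stop("thickness must be a single value > 0", call. = FALSE)
  if (!is.null(psd_trace_lengths) &&
      (!is.numeric(psd_trace_lengths) || any(psd_trace_lengths < 0)))
    stop("PSD trace lengths must be non-negative", call. = FALSE)
  if (!is.null(en_face_area) &&
      (!is.numeric(en_face_area) || length(en_face_area) != 1L ||
       en_face_area < 0))
    stop("en_face_area must be a single non-negative value", call. = FALSE)
  structure(list(areas = as.numeric(areas), thickness = thickness,
                 psd_trace_lengths = psd_trace_lengths,
                 en_face_area = en_face_area),
            class = "contour_stack")
}

#' Spine head volume from a contour stack
#'
#' The head volume is the total cross-sectional area of the plasma-membrane
#' contours multiplied by the section thickness.
#'
#' @param stack A [contour_stack()].
#' @return Head volume, um^3.
#' @examples
#' head_volume(contour_stack(c(0.5, 0.5), 0.04))  # 0.04
#' @export
head_volume <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  sum(stack$areas) * stack$thickness
}

#' PSD area from a contour stack
#'
#' For a cross-sectioned synapse the PSD area is the summed PSD trace length
#' over consecutive sections multiplied by the section thickness; for a
#' synapse cut en face it is the single-section area, taken verbatim. A
#' stack carrying both representations is ambiguous and rejected.
#'
#' @param stack A [contour_stack()].
#' @return PSD area, um^2.
#' @examples
#' psd_area(contour_stack(1, 0.04, psd_trace_lengths = c(0.2, 0.3)))  # 0.02
#' @export
psd_area <- function(stack) {
  stopifnot(inherits(stack, "contour_stack"))
  has_trace <- !is.null(stack$psd_trace_lengths)
  has_face <- !is.null(stack$en_face_area)
  if (has_trace && has_face)
    stop("ambiguous PSD representation: both trace lengths and en face area",
         call. = FALSE)
  if (!has_trace && !has_face)
    stop("stack carries no PSD representation", call. = FALSE)
  if (has_trace) sum(stack$psd_trace_lengths) * stack$thickness
  else stack$en_face_area
}

#' Dendritic diameter from per-section widths
#'
#' The diameter of an ovoid dendritic profile is the mean of the widths
#' measured across the widest transect of the narrowest dimension.
#'
#' @param section_widths Per-section widths, um (>= 1 value).
#' @return Mean diameter, um.
#' @export
dendrite_diameter <- function(section_widths) {
  if (length(section_widths) < 1L)
    stop("need at least one section width", call. = FALSE)
  if (!is.numeric(section_widths) || any(section_widths <= 0))
    stop("section widths must be positive", call. = FALSE)
  mean(section_widths)
}

# Accept either a dendrite record (list with length_um and spines) or an
# explicit (spines, length) pair; returns list(spines, length).
as_dendrite <- function(dendrite, length_um = NULL) {
  if (is.list(dendrite) && !is.data.frame(dendrite) &&
      all(c("spines", "length_um") %in% names(dendrite)))
    return(list(spines = dendrite$spines, length_um = dendrite$length_um))
  if (is.data.frame(dendrite) && !is.null(length_um))
    return(list(spines = dendrite, length_um = length_um))
  stop("pass a dendrite record (list with spines, length_um) or a spine ",
       "table plus length_um", call. = FALSE)
}

flag_col <- function(spines, col) {
  if (col %in% names(spines)) as.logical(spines[[col]]) else
    rep(FALSE, nrow(spines))
}

#' Dendrite-level density measures
#'
#' `spine_density()` divides the number of spines (filopodia excluded: they
#' lack synaptic contacts) by the dendrite length. `psd_area_density()`
#' divides the summed PSD area of the dendrite's spines by its length;
#' spines with missing PSD (neck left the field of view) are excluded and
#' counted in the `qc_excluded` attribute. `neck_length_density()` does the
#' same with summed neck lengths.
#'
#' @param dendrite A dendrite record (list with `spines` data frame and
#'   `length_um`), or a spine data frame if `length_um` is given.
#' @param length_um Dendrite length, um (> 0), when `dendrite` is a plain
#'   spine table.
#' @return Density in spines/um, um^2/um or um/um. For the PSD measure the
#'   number of QC-excluded spines is attached as attribute `qc_excluded`.
#' @examples
#' sp <- data.frame(psd_area_um2 = c(0.05, 0.15), neck_length_um = c(0.4, 0.5))
#' psd_area_density(sp, length_um = 2)  # 0.10
#' @export
spine_density <- function(dendrite, length_um = NULL) {
  d <- as_dendrite(dendrite, length_um)
  if (d$length_um <= 0) stop("dendrite length must be > 0", call. = FALSE)
  sp <- d$spines
  n <- if (is.null(sp) || nrow(sp) == 0L) 0L
  else sum(!flag_col(sp, "filopodium"))
  n / d$length_um
}

#' @rdname spine_density
#' @export
psd_area_density <- function(dendrite, length_um = NULL) {
  d <- as_dendrite(dendrite, length_um)
  if (d$length_um <= 0) stop("dendrite length must be > 0", call. = FALSE)
  sp <- d$spines
  if (is.null(sp) || nrow(sp) == 0L)
    return(structure(0, qc_excluded = 0L))
  psd <- sp$psd_area_um2
  missing <- is.na(psd)
  structure(sum(psd[!missing]) / d$length_um, qc_excluded = sum(missing))
}

#' @rdname spine_density
#' @export
neck_length_density <- function(dendrite, length_um = NULL) {
  d <- as_dendrite(dendrite, length_um)
  if (d$length_um <= 0) stop("dendrite length must be > 0", call. = FALSE)
  sp <- d$spines
  if (is.null(sp) || nrow(sp) == 0L) return(0)
  nl <- sp$neck_length_um
  sum(nl[!is.na(nl)]) / d$length_um
}

#' PSD-area to neck-length ratio
#'
#' `psd_neck_ratio()` is the per-spine ratio of PSD area to neck length, an
#' anatomical index of synaptic strength. `dendrite_psd_neck_ratio()` is the
#' dendrite-level total: summed PSD area over summed neck length — not the
#' mean of per-spine ratios. Spines without a measurable neck (stubby) are
#' excluded with a warning at the spine level and dropped from both sums at
#' the dendrite level.
#'
#' @param psd_area PSD area(s), um^2.
#' @param neck_length Neck length(s), um.
#' @return Ratio(s), um. Zero-neck spines yield `NA` with a warning.
#' @examples
#' psd_neck_ratio(0.08, 0.4)  # 0.2
#' @export
psd_neck_ratio <- function(psd_area, neck_length) {
  stopifnot(length(psd_area) == length(neck_length))
  out <- rep(NA_real_, length(psd_area))
  ok <- !is.na(neck_length) & neck_length > 0 & !is.na(psd_area)
  if (any(!ok & !is.na(neck_length)))
    warning("excluding ", sum(!ok & !is.na(neck_length)),
            " spine(s) with zero neck length (stubby)", call. = FALSE)
  out[ok] <- psd_area[ok] / neck_length[ok]
  out
}

#' @rdname psd_neck_ratio
#' @param dendrite,length_um As in [spine_density()].
#' @export
dendrite_psd_neck_ratio <- function(dendrite, length_um = NULL) {
  d <- as_dendrite(dendrite, length_um)
  sp <- d$spines
  if (is.null(sp) || nrow(sp) == 0L) return(NA_real_)
  ok <- !is.na(sp$neck_length_um) & sp$neck_length_um > 0 &
    !is.na(sp$psd_area_um2)
  if (!any(ok) || sum(sp$neck_length_um[ok]) <= 0)
    stop("total neck length must be > 0", call. = FALSE)
  sum(sp$psd_area_um2[ok]) / sum(sp$neck_length_um[ok])
}

#' Fold range and coefficient of variation
#'
#' `fold_range()` is the ratio of the largest to the smallest value (the
#' fold difference between the largest and smallest spine); `cv()` is the
#' SD over the mean.
#'
#' @param values Positive values, n >= 2.
#' @return A single ratio / dimensionless CV.
#' @examples
#' fold_range(c(0.01, 1.24))  # 124
#' @export
fold_range <- function(values) {
  if (length(values) < 2L) stop("need at least two values", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be positive", call. = FALSE)
  max(values) / min(values)
}

#' @rdname fold_range
#' @export
cv <- function(values) {
  if (length(values) < 2L) stop("need at least two values", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be positive", call. = FALSE)
  stats::sd(values) / mean(values)
}

#' Fraction of axon-coupled spines
#'
#' Axon-coupled spines reside in the same dendritic segment and receive
#' synaptic input from the same axon. A spine is coupled when its
#' (dendrite, axon) pair occurs at least twice in the table.
#'
#' @param spines Data frame with `dendrite_id` and `axon_id` columns; rows
#'   with missing axon IDs (e.g. filopodia) are ignored.
#' @return The coupled fraction, with attribute `multiplicity_range` — the
#'   range of the number of same-dendrite spines contacted by one axon
#'   among coupled groups (`c(NA, NA)` when there are none).
#' @examples
#' sp <- data.frame(dendrite_id = "d1", axon_id = c("a", "a", "b", "c", "d"))
#' axon_coupled_fraction(sp)  # 0.4, range 2 2
#' @export
axon_coupled_fraction <- function(spines) {
  if (is.null(spines) || nrow(spines) == 0L)
    return(structure(0, multiplicity_range = c(NA_integer_, NA_integer_)))
  ok <- !is.na(spines$axon_id)
  key <- paste(spines$dendrite_id[ok], spines$axon_id[ok], sep = "\r")
  if (length(key) == 0L)
    return(structure(0, multiplicity_range = c(NA_integer_, NA_integer_)))
  mult <- table(key)
  coupled <- mult[mult >= 2L]
  frac <- sum(coupled) / length(key)
  rng <- if (length(coupled)) range(as.integer(coupled))
  else c(NA_integer_, NA_integer_)
  structure(frac, multiplicity_range = rng)
}

#' Fraction of ER-containing spines with an ER-containing neighbour
#'
#' Among ER+ spines of a dendrite (ordered by position), the fraction whose
#' immediate positional neighbour (previous or next spine) is also ER+ —
#' the degree to which ER-containing spines cluster into hotspots.
#' Adjacency is ordinal (the next spine in order), not a distance
#' threshold.
#'
#' @param dendrite,length_um As in [spine_density()]; the spine table needs
#'   `er` and `position_um` columns.
#' @return Fraction in [0, 1]; `NA` with fewer than 2 spines or no ER+
#'   spine.
#' @examples
#' sp <- data.frame(position_um = 1:5, er = c(TRUE, TRUE, FALSE, FALSE, TRUE))
#' er_hotspot_fraction(sp, length_um = 10)  # 2/3
#' @export
er_hotspot_fraction <- function(dendrite, length_um = NULL) {
  d <- as_dendrite(dendrite, if (is.null(length_um)) 1 else length_um)
  sp <- d$spines
  if (is.null(sp) || nrow(sp) < 2L) return(NA_real_)
  ord <- order(sp$position_um)
  er <- as.logical(sp$er)[ord]
  idx <- which(er)
  if (length(idx) == 0L) return(NA_real_)
  n <- length(er)
  has_nb <- vapply(idx, function(i) {
    (i > 1L && er[i - 1L]) || (i < n && er[i + 1L])
  }, logical(1))
  mean(has_nb)
}

#' Surface-area fractions of spine compartments
#'
#' Converts the surface areas occupied by spine head, PSD, spine neck and
#' dendritic shaft into fractions of the total.
#'
#' @param head_sa,psd_sa,neck_sa,shaft_sa Surface areas, um^2 (>= 0, not
#'   all zero).
#' @return Named numeric vector of four fractions summing to 1.
#' @export
surface_area_fractions <- function(head_sa, psd_sa, neck_sa, shaft_sa) {
  x <- c(head = head_sa, psd = psd_sa, neck = neck_sa, shaft = shaft_sa)
  if (any(!is.finite(x)) || any(x < 0))
    stop("surface areas must be non-negative", call. = FALSE)
  if (sum(x) == 0) stop("at least one surface area must be > 0", call. = FALSE)
  x / sum(x)
}

#' Per-dendrite and per-region morphometry summaries
#'
#' Computes, for every dendrite of a dataset, the diameter, spine density,
#' PSD-area density, neck-length density and the total PSD/neck ratio, and
#' aggregates region-level summary statistics (means, SDs, fold ranges,
#' CVs, axon-coupled fraction, ER statistics) in the layout of the study's
#' summary tables.
#'
#' @param dataset A `spine_dataset` (or any list with `spines` and
#'   `dendrites` data frames in the same schema).
#' @return List with `per_dendrite` and `per_region` data frames.
#' @export
morphometry_summary <- function(dataset) {
  spines <- dataset$spines
  dend <- dataset$dendrites
  per_dendrite <- do.call(rbind, lapply(seq_len(nrow(dend)), function(i) {
    sp <- spines[spines$dendrite_id == dend$dendrite_id[i], , drop = FALSE]
    rec <- list(spines = sp, length_um = dend$length_um[i])
    ratio <- tryCatch(dendrite_psd_neck_ratio(rec), error = function(e) NA_real_)
    data.frame(
      dendrite_id = dend$dendrite_id[i],
      region = dend$region[i],
      diameter_um = dend$diameter_um[i],
      length_um = dend$length_um[i],
      spine_density = spine_density(rec),
      psd_area_density = as.numeric(psd_area_density(rec)),
      neck_length_density = neck_length_density(rec),
      total_ratio = ratio,
      stringsAsFactors = FALSE
    )
  }))
  synaptic <- spines[!flag_col(spines, "filopodium"), , drop = FALSE]
  nz_neck <- synaptic$neck_length_um[!is.na(synaptic$neck_length_um) &
                                       synaptic$neck_length_um > 0]
  region <- data.frame(
    region = dend$region[1],
    n_spines = nrow(synaptic),
    n_dendrites = nrow(dend),
    spine_density_mean = mean(per_dendrite$spine_density),
    spine_density_sd = stats::sd(per_dendrite$spine_density),
    head_volume_mean = mean(synaptic$head_volume_um3),
    head_volume_sd = stats::sd(synaptic$head_volume_um3),
    head_volume_fold = fold_range(synaptic$head_volume_um3),
    head_volume_cv = cv(synaptic$head_volume_um3),
    neck_length_mean = mean(nz_neck),
    neck_length_sd = stats::sd(nz_neck),
    neck_diameter_mean = mean(synaptic$neck_diameter_um, na.rm = TRUE),
    psd_area_density_mean = mean(per_dendrite$psd_area_density),
    neck_length_density_mean = mean(per_dendrite$neck_length_density),
    total_ratio_mean = mean(per_dendrite$total_ratio, na.rm = TRUE),
    axon_coupled_fraction = as.numeric(axon_coupled_fraction(synaptic)),
    er_fraction = mean(flag_col(synaptic, "er")),
    stringsAsFactors = FALSE
  )
  list(per_dendrite = per_dendrite, per_region = region)
}
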
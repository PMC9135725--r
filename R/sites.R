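#' Site metadata for the six Mediterranean study populations
#'
#' Returns the per-site covariate table used throughout the analysis:
#' region (a three-level proxy of genetic structure: WEST / EAST / SOUTH),
#' the prevalent seabed habitat types (EUNIS-style labels, semicolon
#' separated), a depth category (shallow < 120 m vs deep), the published
#' population-size estimate with its 95% confidence bounds, mean and range
#' of group size, residency pattern and connection with adjacent
#' populations, plus the derived sea-bottom (H1-H3) and demography (P1-P4)
#' cluster factors. These values are consumed as given metadata; the
#' clustering that produced the H and P factors can be recomputed with
#' [cluster_sites()] on the encodings from [encode_sea_bottom()] and
#' [encode_demography()].
#'
#' @return A data frame with one row per site.
#' @export
mediterranean_sites <- function() {
  data.frame(
    site = c("PC", "AL", "FI", "LA", "CL", "GC"),
    region = c("WEST", "WEST", "WEST", "SOUTH", "EAST", "EAST"),
    sea_bottom = c("H1", "H2", "H2", "H1", "H2", "H3"),
    demography = c("P4", "P2", "P4", "P1", "P3", "P2"),
    habitats = c(
      "circalittoral_coarse_sediment;posidonia_bed;infralittoral_sand",
      "circalittoral_coarse_sediment;posidonia_bed;muddy_detritic_bottom",
      "offshore_terrigenous_mud;muddy_detritic_bottom;circalittoral_coarse_sediment",
      "posidonia_bed;infralittoral_sand;circalittoral_coarse_sediment",
      "infralittoral_mud;coastal_terrigenous_mud;circalittoral_coarse_sediment",
      "open_sea_detritic;offshore_terrigenous_mud;bathyal_mud"),
    depth_category = c("shallow", "shallow", "shallow", "shallow",
                       "shallow", "deep"),
    pop_size_mean = c(223, 76, 529, 249, 184, 38),
    pop_size_lo = c(152, 61, 456, 162, 152, 32),
    pop_size_hi = c(385, 118, 614, 449, 250, 46),
    group_size_mean = c(16, 7, 15, 4, 22, 8),
    group_size_min = c(1, 1, 1, 1, 2, 1),
    group_size_max = c(55, 17, 65, 20, 46, 28),
    residency = c("transient", "resident", "transient", "transient",
                  "resident", "resident"),
    connection = c("yes", "yes", "yes", "no", "no", "yes"))
}

#' Encode site covariates for hierarchical clustering
#'
#' `encode_sea_bottom()` turns the habitat list and depth category into a
#' numeric matrix: one 0/1 indicator per habitat type plus a 0/1 deep-water
#' indicator. `encode_demography()` encodes the six demographic variables:
#' population size mean and confidence-interval width, group size mean and
#' range (numeric, standardized to zero mean and unit SD) plus 0/1
#' indicators for a mostly-transient residency pattern and for connection
#' with adjacent populations. Binary indicators are left on the 0/1 scale;
#' mixing standardized numeric and raw binary columns is the declared
#' convention for the Euclidean distances used by [cluster_sites()].
#'
#' @param sites A site table in the schema of [mediterranean_sites()].
#' @return A numeric matrix with one row per site (rownames = site codes).
#' @export
encode_sea_bottom <- function(sites = mediterranean_sites()) {
  habs <- strsplit(sites$habitats, ";", fixed = TRUE)
  types <- sort(unique(unlist(habs)))
  m <- t(vapply(habs, function(h) as.numeric(types %in% h),
                numeric(length(types))))
  colnames(m) <- types
  m <- cbind(m, deep = as.numeric(sites$depth_category == "deep"))
  rownames(m) <- sites$site
  m
}

#' @rdname encode_sea_bottom
#' @export
encode_demography <- function(sites = mediterranean_sites()) {
  num <- cbind(
    pop_size = sites$pop_size_mean,
    pop_size_ci = sites$pop_size_hi - sites$pop_size_lo,
    group_size = sites$group_size_mean,
    group_size_range = sites$group_size_max - sites$group_size_min)
  num <- scale(num)
  m <- cbind(num,
             transient = as.numeric(sites$residency == "transient"),
             connected = as.numeric(sites$connection == "yes"))
  rownames(m) <- sites$site
  m
}
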
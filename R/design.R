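# Sampling designs for the two study systems the generator emulates:
# a mountain transect (WM, 9 stations spanning 400-1,200 m in 100 m steps,
# 2-3 soil replicates each, 24 samples) and a lowland two-watershed design
# (WL, 10 sites spanning 609-657 m, 5 sites per watershed). Elevations, pH,
# temperature and soil organic matter are the reference survey per-sample records;
# coordinates are placed on transects scaled so the mean pairwise geodesic
# distance matches the reference survey design summaries (1,361 m at WM, 353 m at
# WL).

wm_sample_records <- function() {
  df <- data.frame(
    sample_id = c("S01_R01", "S01_R02", "S01_R03", "S02_R01", "S02_R02",
                  "S02_R03", "S03_R02", "S03_R03", "S04_R02", "S04_R03",
                  "S05_R01", "S05_R02", "S05_R03", "S06_R01", "S06_R02",
                  "S06_R03", "S07_R02", "S07_R03", "S08_R01", "S08_R02",
                  "S08_R03", "S09_R01", "S09_R02", "S09_R03"),
    elevation = c(1200, 1200, 1200, 1100, 1100, 1100, 1000, 1000, 900, 900,
                  800, 800, 800, 700, 700, 700, 600, 600, 500, 500, 500,
                  400, 400, 400),
    pH = c(3.93, 4.1, 3.74, 3.86, 3.61, 3.86, 3.67, 4.05, 3.93, 4.69, 4.42,
           4.52, 4.45, 4.96, 4.54, 4.95, 5.09, 4.7, 5.08, 4.81, 4.95, 4.81,
           5.07, 5.11),
    temperature = c(15, 15, 15, 16, 17, 16, 16, 17, 17, 17, 19, 19, 18, 20,
                    19, 18, 20, 19, 20, 20, 20, 19, 19, 19),
    SOM = c(16.6288192, 31.9330525, 29.1874668, 22.1387585, 53.9605634,
            35.9873995, 26.3294986, 27.4130845, 33.735336, 27.6732296,
            15.7430731, 14.0397492, 14.61, 17.9205852, 22.4786858,
            13.2271829, 7.89907312, 8.87326813, 5.65392979, 5.04150015,
            6.75924035, 11.4845938, 28.7365177, 9.08149529),
    group = NA_character_,
    stringsAsFactors = FALSE)
  df$site_id <- substr(df$sample_id, 1L, 3L)
  df
}

wl_sample_records <- function() {
  df <- data.frame(
    sample_id = c("C1A1", "C1B1", "C1C1", "C1D1", "C1E1",
                  "C2A1", "C2B1", "C2C1", "C2D1", "C2E1"),
    elevation = c(610, 615, 657, 620, 638, 609, 622, 630, 643, 643),
    pH = c(4.14, 4.1, 4.28, 4.16, 4.59, 4.45, 4.62, 4.28, 4.21, 4.88),
    temperature = NA_real_,
    SOM = NA_real_,
    stringsAsFactors = FALSE)
  df$group <- substr(df$sample_id, 1L, 2L)
  df$site_id <- df$sample_id
  df
}

# Place sites at planar unit offsets (y along a meridian, x across it) and
# scale so the mean pairwise great-circle distance equals `target_mean_m`.
# Distances are almost exactly linear in the scale at sub-10-km extents, so
# a few fixed-point rescalings converge far below numerical tolerance.
transect_coords <- function(pos_y, target_mean_m, base_lat, base_lon,
                            pos_x = 0) {
  pos_x <- rep_len(pos_x, length(pos_y))
  scale_m <- target_mean_m  # initial guess refined below
  for (it in 1:4) {
    lat <- base_lat + pos_y * scale_m / METERS_PER_DEGREE
    lon <- base_lon + pos_x * scale_m /
      (METERS_PER_DEGREE * cos(base_lat * pi / 180))
    n <- length(lat)
    d <- vapply(seq_len(n), function(i)
      geodesic_distance(lat[i], lon[i], lat, lon), numeric(n))
    scale_m <- scale_m * target_mean_m / mean(d[upper.tri(d)])
  }
  data.frame(latitude = lat, longitude = lon)
}

site_design <- function(samples, target_mean_m, base_lat, base_lon,
                        pos_x = 0) {
  sites <- unique(samples$site_id)
  elev <- samples$elevation[match(sites, samples$site_id)]
  grp <- samples$group[match(sites, samples$site_id)]
  nrep <- as.vector(table(factor(samples$site_id, levels = sites)))
  coords <- transect_coords(seq_along(sites) - 1, target_mean_m,
                            base_lat, base_lon, pos_x = pos_x)
  design <- data.frame(site_id = sites, elevation = elev,
                       n_replicates = nrep,
                       latitude = coords$latitude,
                       longitude = coords$longitude,
                       group = grp, stringsAsFactors = FALSE)
  samples$latitude <- coords$latitude[match(samples$site_id, sites)]
  samples$longitude <- coords$longitude[match(samples$site_id, sites)]
  attr(design, "samples") <-
    samples[, c("sample_id", "site_id", "elevation", "pH", "temperature",
                "SOM", "group", "latitude", "longitude")]
  class(design) <- c("sampling_design", "data.frame")
  design
}

#' Mountain-transect sampling design (24 samples, 9 stations)
#'
#' Nine stations from 1,200 m down to 400 m in 100 m steps with the
#' reference replicate pattern (3, 3, 2, 2, 3, 3, 2, 3, 3), spaced so the
#' mean pairwise geodesic distance between stations is 1,361 m. The design
#' carries the per-sample environmental records (elevation, pH, temperature,
#' soil organic matter) as `attr(design, "samples")`.
#'
#' @return A `data.frame` of class `sampling_design` with one row per site.
#' @export
make_wm_design <- function() {
  # switchbacking descent: lateral offsets keep horizontal distance
  # strongly, but not perfectly, collinear with elevation change
  site_design(wm_sample_records(), target_mean_m = 1361,
              base_lat = 44.3659, base_lon = -73.9026,
              pos_x = c(0, 1.4, 0.2, 1.6, 0.4, 1.8, 0.6, 2.0, 0.8))
}

#' Two-watershed lowland sampling design (10 sites)
#'
#' Ten single-replicate sites at 609-657 m in two watersheds (C1, C2), five
#' sites each, spaced so the mean pairwise geodesic distance is 353 m.
#'
#' @return A `data.frame` of class `sampling_design` with one row per site.
#' @export
make_wl_design <- function() {
  samples <- wl_sample_records()
  # two clustered transects: within-watershed spacing 1 unit, watershed gap 8
  positions <- c(0:4, 8:12)
  sites <- samples$site_id
  coords <- transect_coords(positions, 353, base_lat = 43.52,
                            base_lon = -74.95)
  design <- data.frame(site_id = sites, elevation = samples$elevation,
                       n_replicates = 1L,
                       latitude = coords$latitude,
                       longitude = coords$longitude,
                       group = samples$group, stringsAsFactors = FALSE)
  samples$latitude <- coords$latitude
  samples$longitude <- coords$longitude
  attr(design, "samples") <-
    samples[, c("sample_id", "site_id", "elevation", "pH", "temperature",
                "SOM", "group", "latitude", "longitude")]
  class(design) <- c("sampling_design", "data.frame")
  design
}

#' Per-sample metadata for a sampling design
#'
#' Expands a site-level design into one record per replicate sample.
#'
#' @param design a `sampling_design` from [make_wm_design()],
#'   [make_wl_design()] or built by hand (columns `site_id`, `elevation`,
#'   `n_replicates`, optional coordinates and `group`).
#' @return A metadata `data.frame`, one row per sample.
#' @export
design_samples <- function(design) {
  samples <- attr(design, "samples")
  if (!is.null(samples)) return(samples)
  idx <- rep(seq_len(nrow(design)), design$n_replicates)
  rep_no <- sequence(design$n_replicates)
  out <- design[idx, setdiff(names(design), "n_replicates"), drop = FALSE]
  out$sample_id <- ifelse(design$n_replicates[idx] > 1L,
                          sprintf("%s_R%02d", design$site_id[idx], rep_no),
                          design$site_id[idx])
  rownames(out) <- NULL
  out[, c("sample_id", setdiff(names(out), "sample_id"))]
}

#' Summarize the spatial layout of a sampling design
#'
#' Arithmetic means over all unordered site pairs of the absolute elevation
#' difference and (when coordinates are present) the geodesic distance,
#' plus the maximum elevation difference. Replicates are already collapsed
#' in a site-level design.
#'
#' @param design a site-level `sampling_design` (or any data frame with
#'   `elevation` and optionally `latitude`/`longitude`).
#' @return A list: `n_sites`, `mean_elevation_diff_m`, `max_elevation_diff_m`,
#'   `mean_geodesic_m` (`NA` without coordinates).
#' @export
summarize_design <- function(design) {
  if (nrow(design) < 2L) stop("need at least 2 sites to summarize a design")
  e <- design$elevation
  de <- abs(outer(e, e, "-"))
  de <- de[upper.tri(de)]
  geo <- NA_real_
  if (all(c("latitude", "longitude") %in% names(design)) &&
      all(is.finite(design$latitude)) && all(is.finite(design$longitude))) {
    gd <- as.matrix(geodesic_matrix(
      data.frame(sample_id = design$site_id, latitude = design$latitude,
                 longitude = design$longitude)))
    geo <- mean(gd[upper.tri(gd)])
  }
  list(n_sites = nrow(design),
       mean_elevation_diff_m = mean(de),
       max_elevation_diff_m = max(de),
       mean_geodesic_m = geo)
}
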
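#' Specification of a synthetic membrane-profile image
#'
#' Describes one synthetic 2D cross-section of a synaptic vesicle (SV) /
#' active-zone (AZ) membrane configuration in a given fusion state. All
#' lengths are nm. The intensity convention is membrane-HIGH (bright
#' membranes on a dark cytosolic background); [read_profile()] offers an
#' invert flag for data recorded with the opposite contrast.
#'
#' State labels and the geometry fields they accept:
#' * `"1"` AZ invagination below a tethered spherical SV: `gap_c_nm`
#'   (SV-AZ separation), `invagination_d_nm`.
#' * `"2"` stalk formation: `gap_c_nm`, `invagination_d_nm`,
#'   `droplet_e1_nm`, `droplet_e2_nm` (deviations from the fitted circle at
#'   the top / bottom of the SV).
#' * `"3"` closed fusion pore: `event_width_a_nm` (head diameter),
#'   `neck_height_g_nm`.
#' * `"4"` open fusion pore: `event_width_a_nm`, `event_height_b_nm`,
#'   `pore_width_i_nm`, `neck_angle_j1_deg`.
#' * `"5"` dilating, `"6"` collapsing fusion pore, `"7"` bump:
#'   `event_width_a_nm`, `event_height_b_nm`, `thickening_factor`
#'   (top-membrane thickness relative to the AZ membrane).
#' * `"tethered_sv"` round SV without invagination: `gap_c_nm`.
#' * `"none"` flat AZ membrane only (degenerate control).
#'
#' @param state_label one of `"1"`..`"7"`, `"tethered_sv"`, `"none"`.
#' @param pixel_size_nm pixel size (default 1.228 nm, the 4x-binned
#'   tomogram sampling).
#' @param image_shape integer c(rows, cols), default 200 x 200.
#' @param sv_outer_diameter_nm SV outer-leaflet diameter (default 42.5).
#' @param bilayer_thickness_nm apparent bilayer thickness (default 5.4; the
#'   leaflet ridge width follows from it, giving a ridge sigma of about
#'   0.8 nm, the blur of 4x-binned tomogram slices).
#' @param leaflet_peak_sep_nm leaflet peak-to-peak separation (default 3.5).
#' @param membrane_intensity,background_intensity rendering intensities.
#' @param noise_sigma additive Gaussian noise SD (default 0).
#' @param seed RNG seed for the noise field.
#' @param ... state-specific geometry fields, see above.
#' @return a `profile_spec` object.
#' @export
profile_spec <- function(state_label,
                         pixel_size_nm = 1.228,
                         image_shape = c(200L, 200L),
                         sv_outer_diameter_nm = 42.5,
                         bilayer_thickness_nm = 5.4,
                         leaflet_peak_sep_nm = 3.5,
                         membrane_intensity = 150,
                         background_intensity = 30,
                         noise_sigma = 0,
                         seed = 1L,
                         ...) {
  state_label <- as.character(state_label)
  defaults <- .state_geometry_defaults()
  if (!state_label %in% names(defaults))
    abort(paste0("unknown state_label: ", state_label))
  geom <- defaults[[state_label]]
  extra <- list(...)
  if (length(extra)) {
    bad <- setdiff(names(extra), names(geom))
    if (length(bad))
      abort(paste0(bad[1], " is not a valid field for state ", state_label))
    geom[names(extra)] <- extra
  }
  spec <- c(
    list(state_label = state_label,
         pixel_size_nm = pixel_size_nm,
         image_shape = as.integer(image_shape),
         sv_outer_diameter_nm = sv_outer_diameter_nm,
         bilayer_thickness_nm = bilayer_thickness_nm,
         leaflet_peak_sep_nm = leaflet_peak_sep_nm,
         membrane_intensity = membrane_intensity,
         background_intensity = background_intensity,
         noise_sigma = noise_sigma,
         seed = as.integer(seed)),
    geom)
  lens <- c("pixel_size_nm", "sv_outer_diameter_nm", "bilayer_thickness_nm",
            "leaflet_peak_sep_nm")
  for (f in lens) if (spec[[f]] <= 0) abort(paste0(f, " must be > 0"))
  geolen <- intersect(names(geom),
                      c("gap_c_nm", "event_width_a_nm", "event_height_b_nm",
                        "neck_height_g_nm", "pore_width_i_nm",
                        "thickening_factor"))
  for (f in geolen) if (spec[[f]] <= 0) abort(paste0(f, " must be > 0"))
  if (spec$bilayer_thickness_nm <= spec$leaflet_peak_sep_nm)
    abort("bilayer_thickness_nm must exceed leaflet_peak_sep_nm")
  if (state_label == "4" &&
      spec$event_width_a_nm / 2 <=
        spec$pore_width_i_nm / 2 + spec$leaflet_peak_sep_nm + 1)
    abort("pore_width_i_nm too large for event_width_a_nm (no pore head)")
  structure(spec, class = "profile_spec")
}

.state_geometry_defaults <- function() {
  list(
    "1" = list(gap_c_nm = 6.4, invagination_d_nm = 2.6),
    "2" = list(gap_c_nm = 4, invagination_d_nm = 0,
               droplet_e1_nm = 0.7, droplet_e2_nm = 3),
    "3" = list(event_width_a_nm = 42.5, neck_height_g_nm = 10),
    "4" = list(event_width_a_nm = 30, event_height_b_nm = 35,
               pore_width_i_nm = 8, neck_angle_j1_deg = 90),
    "5" = list(event_width_a_nm = 37.4, event_height_b_nm = 48.4,
               thickening_factor = 1),
    "6" = list(event_width_a_nm = 50.4, event_height_b_nm = 29.6,
               thickening_factor = 1.5),
    "7" = list(event_width_a_nm = 25, event_height_b_nm = 7.7,
               thickening_factor = 1.5),
    tethered_sv = list(gap_c_nm = 10, invagination_d_nm = 0),
    none = list()
  )
}

#' @export
print.profile_spec <- function(x, ...) {
  cat("<profile_spec> state", x$state_label,
      sprintf("(%d x %d px, %.3f nm/px)\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size_nm))
  geo <- setdiff(names(x), c("state_label", "image_shape"))
  for (f in geo) cat("  ", f, "=", format(x[[f]]), "\n")
  invisible(x)
}
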
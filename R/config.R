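#' Read a simulation configuration file
#'
#' YAML configuration with the blocks used by the command-line driver:
#' `phantom` (`semi_axes`, `resolution_mm`), `tumor` (`center`,
#' `outer_diameter_mm`, `core_diameter_mm`, `solid`), `montage` (`pair`,
#' `current_A`, `pitch_mm`, `disc_diameter_mm`), `conductivity` (tissue
#' table overrides, `model`, `fa`, `fiber_pattern`, `fiber_direction`) and
#' `solver` (`tol`, `method`). Missing blocks fall back to package
#' defaults.
#'
#' @param file path to a YAML file.
#' @return nested configuration list merged over the defaults.
#' @export
read_sim_config <- function(file) {
  user <- if (is.null(file)) list() else yaml::read_yaml(file)
  merge_lists(default_sim_config(), user)
}

#' Default simulation configuration
#' @return nested list of the package defaults (see [read_sim_config()]).
#' @export
default_sim_config <- function() {
  list(
    phantom = list(semi_axes = default_head_geometry()$semi_axes,
                   resolution_mm = 6),
    tumor = list(center = c(40, 0, 0), outer_diameter_mm = 20,
                 core_diameter_mm = 14, solid = FALSE),
    montage = list(pair = "both", current_A = 0.9, pitch_mm = c(45, 22),
                   disc_diameter_mm = 20),
    conductivity = c(as.list(default_tissue_table()),
                     list(model = "iso", fa = 0.7,
                          fiber_pattern = "uniform",
                          fiber_direction = c(0, 1, 0))),
    solver = list(tol = 1e-9, method = "pcg"),
    seed = 0L
  )
}

merge_lists <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
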
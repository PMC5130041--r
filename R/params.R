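# Model parameter handling.
#
# All TCP/NTCP model constants live in a versioned YAML file shipped with the
# package (inst/extdata/model_params.yml); nothing is hard-coded in model
# code. Values whose published sources print no exact numbers are marked
# "approximate" in the file itself.

#' Load the radiobiological model parameter set
#'
#' Reads the versioned YAML parameter file shipped with the package (or a
#' user-supplied one with the same layout). The file carries, per model, the
#' constants described in the individual model help pages together with a
#' `source` citation string.
#'
#' @param path Path to a YAML parameter file; `NULL` (default) loads the
#'   packaged file.
#' @return A nested list with components `alpha_beta`, `tcp`, `ntcp`,
#'   `meud` and `pipeline`.
#' @export
radbio_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "model_params.yml", package = "radbio")
  if (!nzchar(path) || !file.exists(path))
    stop("parameter file not found: ", path)
  p <- yaml::read_yaml(path)
  stopifnot(p$alpha_beta$tumor > 0, p$alpha_beta$lung > 0,
            p$alpha_beta$chest_wall > 0)
  p
}

#' Equivalent-sphere diameter of a volume
#'
#' The diameter (cm) of a sphere with the given volume, used as the default
#' tumor-size covariate for covariate-logistic TCP models when only the GTV
#' volume is known.
#'
#' @param volume_cm3 Volume in cm^3.
#' @return Diameter in cm.
#' @export
equivalent_sphere_diameter <- function(volume_cm3) {
  stopifnot(volume_cm3 >= 0)
  2 * (3 * volume_cm3 / (4 * pi))^(1 / 3)
}
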
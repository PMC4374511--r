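#' Genotype preset: generative parameters for one phenotype class
#'
#' A `genotype_preset` bundles everything the synthetic-scene generator needs
#' to emulate one phenotype class of a presynaptic reporter: how densely
#' puncta sit along the cord, how bright and wide they are, how much diffuse
#' axonal signal surrounds them, the camera model, and what fraction of the
#' signal is retained in cell bodies instead of the cord.
#'
#' All intensities are in arbitrary units (AU); lengths in micrometres.
#'
#' @param name Label for the preset (genotype class).
#' @param punctum_density Expected puncta per micrometre of cord (>= 0).
#' @param amplitude_mean,amplitude_sd Punctum peak height above the diffuse
#'   baseline, drawn per punctum from a normal law truncated at 0 (AU).
#' @param punctum_sigma_um Gaussian punctum width (standard deviation, um);
#'   doubles as the effective point-spread blur of a punctum.
#' @param diffuse_level Baseline axonal intensity above the camera offset (AU).
#' @param camera_offset Additive camera constant present everywhere (AU).
#' @param noise_gain Camera gain in AU per photon for the Poisson branch of
#'   the noise model; `0` disables Poisson noise (noiseless photon path).
#' @param read_noise_sd Standard deviation of additive Gaussian read noise (AU).
#' @param soma_fraction Fraction of total above-offset signal placed in
#'   cell-body blobs instead of the cord, in `[0, 1]`.
#' @return An object of class `genotype_preset` (a named list).
#' @seealso [preset_library()], [make_profile()], [make_image()]
#' @export
genotype_preset <- function(name,
                            punctum_density,
                            amplitude_mean,
                            amplitude_sd,
                            punctum_sigma_um,
                            diffuse_level,
                            camera_offset = 10,
                            noise_gain = 1,
                            read_noise_sd = 2,
                            soma_fraction = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (v in list(punctum_density, amplitude_mean, amplitude_sd,
                 punctum_sigma_um, diffuse_level, camera_offset,
                 noise_gain, read_noise_sd, soma_fraction)) {
    if (!num1(v) || v < 0) {
      stop("all preset parameters must be single non-negative numbers",
           call. = FALSE)
    }
  }
  if (soma_fraction > 1) stop("soma_fraction must lie in [0, 1]", call. = FALSE)
  if (punctum_sigma_um <= 0) stop("punctum_sigma_um must be > 0", call. = FALSE)
  structure(
    list(name = name,
         punctum_density = punctum_density,
         amplitude_mean = amplitude_mean,
         amplitude_sd = amplitude_sd,
         punctum_sigma_um = punctum_sigma_um,
         diffuse_level = diffuse_level,
         camera_offset = camera_offset,
         noise_gain = noise_gain,
         read_noise_sd = read_noise_sd,
         soma_fraction = soma_fraction),
    class = "genotype_preset")
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat(sprintf("<genotype_preset> %s\n", x$name))
  flds <- setdiff(names(x), "name")
  for (f in flds) cat(sprintf("  %-18s %g\n", f, x[[f]]))
  invisible(x)
}

#' Built-in library of phenotype-class presets
#'
#' Four presets encode the qualitative phenotype classes the package is
#' designed around:
#'
#' * `wild_type` — punctate cord: well separated bright puncta on a low
#'   diffuse baseline, every punctum passing the ratio-2 calling rule with
#'   margin.
#' * `diffuse_mutant` — loss of punctate localisation: zero punctum density
#'   with the reporter redistributed into an elevated uniform axonal signal
#'   (as in synaptic-vesicle trafficking mutants where puncta become diffuse).
#' * `enlarged_puncta` — fewer but larger and brighter puncta than wild type
#'   (higher amplitude and width at lower density), yielding enhanced
#'   synaptic enrichment. The lower density keeps the wide puncta resolved;
#'   crowding wide puncta contaminates the inter-punctal baseline and makes
#'   the ratio rule unstable.
#' * `soma_retention` — near-total retention of the reporter in cell bodies:
#'   cord signal collapses towards the camera offset while large soma blobs
#'   at the cord ends carry the signal (kinesin-mutant-like).
#'
#' All magnitudes are documented package defaults (the phenotypes fix only
#' the *directions* of the contrasts); every parameter is configurable via
#' [genotype_preset()].
#'
#' @return Named list of [genotype_preset()] objects.
#' @examples
#' names(preset_library())
#' preset_library()$wild_type
#' @export
preset_library <- function() {
  lst <- list(
    genotype_preset("wild_type",
                    punctum_density = 0.3,
                    amplitude_mean = 150, amplitude_sd = 15,
                    punctum_sigma_um = 0.5,
                    diffuse_level = 20),
    genotype_preset("diffuse_mutant",
                    punctum_density = 0,
                    amplitude_mean = 0, amplitude_sd = 0,
                    punctum_sigma_um = 0.5,
                    diffuse_level = 60),
    genotype_preset("enlarged_puncta",
                    punctum_density = 0.2,
                    amplitude_mean = 250, amplitude_sd = 30,
                    punctum_sigma_um = 0.7,
                    diffuse_level = 20),
    genotype_preset("soma_retention",
                    punctum_density = 0.3,
                    amplitude_mean = 100, amplitude_sd = 15,
                    punctum_sigma_um = 0.5,
                    diffuse_level = 20,
                    soma_fraction = 0.95)
  )
  stats::setNames(lst, vapply(lst, `[[`, "", "name"))
}
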
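#' Analysis configuration
#'
#' Returns the full set of tunable thresholds and switches used by the
#' detectors, with shipped defaults. Every value can be overridden either by
#' argument or from a YAML file via [read_config()].
#'
#' @details
#' The defaults encode the detection conventions of the pipeline:
#' * `hbond_threshold`: a hydrogen bond is reported when its energy is
#'   strictly greater than this value (kJ/mol).
#' * `ramp_orientation`: `"increasing"` uses the angular ramp
#'   \eqn{(\alpha-\theta_1)/(\theta_2-\theta_1)}, which is continuous with the
#'   0-below-\eqn{\theta_1} / 1-above-\eqn{\theta_2} plateaus;
#'   `"printed"` is a compatibility mode with the decreasing numerator
#'   \eqn{(\theta_2-\alpha)/(\theta_2-\theta_1)} between the plateaus.
#' * `theta_heavy`, `theta_hydrogen`: the \eqn{(\theta_1,\theta_2)} tables
#'   (degrees) used for heavy-atom and hydrogen angular ramps.
#' * `hax_rule`: how the hydrogen--acceptor--attached-atom factor combines
#'   over several acceptor neighbours (`"max"` keeps the most permissive).
#' * `water_bridge_threshold`: maximum water-H to acceptor leg distance (Å).
#' * `ionic_range`: inclusive adjusted-distance window (Å) for ionic contacts.
#' * `hbond_radii`: per-element radii (Å) subtracted from the raw
#'   centre-to-centre distance of an ionic pair.
#' * `hydrophobic_cutoff`: carbon--carbon distance cutoff (Å).
#' * `cation_species`: residue names counted as bridge-forming cations.
#' * `his_protonated`: treat histidine as a +1 centre (default neutral).
#' * `window_fraction`: leading fraction of the trajectory excluded from all
#'   windowed statistics (equilibration).
#'
#' @param ... name-value pairs overriding individual defaults.
#' @return A named list of class `fp_config`.
#' @examples
#' cfg <- fp_config(hydrophobic_cutoff = 5)
#' cfg$hydrophobic_cutoff
#' @export
fp_config <- function(...) {
  cfg <- list(
    hbond_threshold = 6.25,
    ramp_orientation = "increasing",
    theta_heavy = c(85, 95),
    theta_hydrogen = c(75, 85),
    hax_rule = "max",
    covalent_h_cutoff = 1.2,
    covalent_heavy_cutoff = 1.8,
    water_bridge_threshold = 3.0,
    water_as_acceptor = FALSE,
    ionic_range = c(0, 1.5),
    hbond_radii = c(N = 1.75, O = 1.70, C = 1.80, CL = 1.70,
                    NA. = 1.00, MG = 0.85, CA = 1.10, K = 1.33),
    hydrophobic_cutoff = 4.5,
    cation_species = c("CA", "MG"),
    his_protonated = FALSE,
    window_fraction = 0.4,
    strict_oxygen_map = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    mf_stop("mf_config_error",
            paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  structure(cfg, class = "fp_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys absent from the file keep their [fp_config()] defaults. The key
#' `hbond_radii` may be given as a mapping from element symbol to radius;
#' sodium must be spelled `"NA."` to survive YAML's null literal.
#'
#' @param path path to a YAML file.
#' @return An `fp_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    mf_stop("mf_config_error", paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.null(vals$hbond_radii)) vals$hbond_radii <- unlist(vals$hbond_radii)
  do.call(fp_config, vals)
}

## Radius for an ionic charge centre, keyed by the element of its (nearest)
## real atom; sodium is stored as "NA." because "NA" is not a valid name.
ionic_radius <- function(element, cfg) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  r <- cfg$hbond_radii[key]
  if (anyNA(r))
    mf_stop("mf_config_error",
            paste0("no hydrogen-bond radius configured for element(s): ",
                   paste(unique(element[is.na(r)]), collapse = ", ")))
  unname(r)
}
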
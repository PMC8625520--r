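## Binding-energy decomposition:
##
##   E_bind = E_pot1 + E_pot2 + E_sol1 + E_sol2 - (E_pot_comp + E_sol_comp)
##
## over a pluggable potential/solvation backend. High positive E_bind means
## high ligand-receptor affinity. The shipped reference backend is a simple,
## fully documented desk-scale model (12-6 van der Waals + Coulomb with a
## distance-dependent dielectric + surface-area-proportional solvation); the
## decomposition's value lies in the algebra and its limits, not in
## force-field fidelity.

#' Combine energy components into a binding energy
#'
#' @param components named numeric (or list) with elements `E_pot1`,
#'   `E_pot2`, `E_sol1`, `E_sol2`, `E_pot_comp`, `E_sol_comp`, all kJ/mol.
#' @return Binding energy in kJ/mol; positive values denote affinity.
#' @export
binding_energy <- function(components) {
  cmp <- as.list(components)
  need <- c("E_pot1", "E_pot2", "E_sol1", "E_sol2", "E_pot_comp", "E_sol_comp")
  if (!all(need %in% names(cmp)))
    mf_stop("mf_domain_error",
            paste0("missing components: ",
                   paste(setdiff(need, names(cmp)), collapse = ", ")))
  v <- unlist(cmp[need])
  if (any(!is.finite(v)))
    mf_stop("mf_domain_error", "energy components must be finite")
  unname(v["E_pot1"] + v["E_pot2"] + v["E_sol1"] + v["E_sol2"] -
           (v["E_pot_comp"] + v["E_sol_comp"]))
}

#' Null energy backend
#'
#' Returns zero for every potential and solvation query; useful as the
#' degenerate limit in which the binding energy is exactly zero.
#' @return An `energy_backend` list.
#' @export
null_backend <- function() {
  structure(list(
    potential_energy = function(system, idx, frame) 0,
    solvation_energy = function(system, idx, frame) 0,
    label = "null"
  ), class = "energy_backend")
}

## Default nonbonded parameters of the reference backend. eps in kJ/mol,
## rmin2 = half the pair distance at the van der Waals minimum (Å), sasa_r =
## solvation radius (Å). Documented package constants, not a force field.
REF_NB_PARAMS <- data.frame(
  element = c("H", "C", "N", "O", "S", "NA", "MG", "CA", "CL", "K"),
  eps = c(0.065, 0.36, 0.71, 0.88, 1.05, 0.36, 0.36, 0.45, 0.42, 0.40),
  rmin2 = c(0.60, 1.91, 1.82, 1.66, 2.00, 1.37, 0.79, 1.37, 2.27, 1.76),
  sasa_r = c(1.20, 1.70, 1.55, 1.52, 1.80, 2.27, 1.73, 2.31, 1.75, 2.75),
  stringsAsFactors = FALSE
)

## Shrake-Rupley style solvent-accessible surface area with a deterministic
## golden-spiral point set. Exact for isolated atoms (all points exposed).
sasa_area <- function(xyz, radii, probe = 1.4, n_points = 240L) {
  n <- nrow(xyz)
  if (n == 0L) return(0)
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  sphere <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  R <- radii + probe
  total <- 0
  for (i in seq_len(n)) {
    pts <- sweep(sphere * R[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sum((xyz[i, ] - xyz[j, ])^2)
      if (dij >= (R[i] + R[j])^2) next
      d2 <- colSums((t(pts) - xyz[j, ])^2)
      exposed <- exposed & d2 > R[j]^2
    }
    total <- total + 4 * pi * R[i]^2 * sum(exposed) / n_points
  }
  total
}

#' Reference potential/solvation backend
#'
#' Pairwise 12-6 van der Waals (Lorentz-Berthelot-style combination:
#' geometric-mean well depth, summed half-minima) plus Coulomb interaction
#' of the per-atom formal charges with a distance-dependent dielectric
#' \eqn{\epsilon(r) = 4r}, i.e. \eqn{E_c = 1389.35\, q_i q_j / (4 r^2)}
#' kJ/mol with r in Å. Pairs inside one residue are skipped (they cancel in
#' the binding-energy algebra regardless). Solvation is
#' \eqn{\gamma \cdot SASA} with \eqn{\gamma} in kJ/mol/Å² and the
#' solvent-accessible surface computed on a deterministic spherical point
#' set.
#'
#' @param params nonbonded parameter table (per-element `eps`, `rmin2`,
#'   `sasa_r`); the shipped defaults are package constants.
#' @param gamma solvation surface coefficient, kJ/mol/Å².
#' @param probe solvent probe radius, Å.
#' @param n_points surface sample points per atom.
#' @return An `energy_backend` list with `potential_energy(system, idx,
#'   frame)` and `solvation_energy(system, idx, frame)`.
#' @export
reference_backend <- function(params = REF_NB_PARAMS, gamma = 0.025,
                              probe = 1.4, n_points = 240L) {
  lookup <- function(el) {
    i <- match(toupper(el), params$element)
    if (anyNA(i))
      mf_stop("mf_parameter_error",
              paste0("no nonbonded parameters for element(s): ",
                     paste(unique(el[is.na(i)]), collapse = ", ")))
    params[i, , drop = FALSE]
  }
  potential_energy <- function(system, idx, frame = 1L) {
    if (length(idx) < 2L) return(0)
    a <- system$atoms[idx, , drop = FALSE]
    if (is.null(a$charge)) mf_stop("mf_parameter_error",
                                   "assign_charges() before energy evaluation")
    xyz <- frame_xyz(system, frame)[idx, , drop = FALSE]
    p <- lookup(a$element)
    pr <- utils::combn(length(idx), 2)
    i <- pr[1, ]; j <- pr[2, ]
    same_res <- a$resuid[i] == a$resuid[j]
    i <- i[!same_res]; j <- j[!same_res]
    if (length(i) == 0L) return(0)
    r <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
    eps <- sqrt(p$eps[i] * p$eps[j])
    rmin <- p$rmin2[i] + p$rmin2[j]
    lj <- eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    coul <- 1389.35 * a$charge[i] * a$charge[j] / (4 * r^2)
    sum(lj + coul)
  }
  solvation_energy <- function(system, idx, frame = 1L) {
    if (length(idx) == 0L) return(0)
    a <- system$atoms[idx, , drop = FALSE]
    xyz <- frame_xyz(system, frame)[idx, , drop = FALSE]
    gamma * sasa_area(xyz, lookup(a$element)$sasa_r, probe, n_points)
  }
  structure(list(potential_energy = potential_energy,
                 solvation_energy = solvation_energy,
                 label = "reference", gamma = gamma),
            class = "energy_backend")
}

#' Evaluate the six energy components for one frame
#'
#' Runs the backend on the receptor alone, the ligand alone, and the
#' receptor-ligand complex. Waters and ions enter only through whatever
#' screening/solvation behaviour the backend encodes.
#'
#' @param system a `molsys` object with roles (and, for the reference
#'   backend, charges) assigned.
#' @param frame frame index.
#' @param backend an `energy_backend`.
#' @return Named numeric vector of the six components, kJ/mol.
#' @export
compute_components <- function(system, frame = 1L,
                               backend = reference_backend()) {
  rec <- select_atoms(system, role = "receptor")
  lig <- select_atoms(system, role = "ligand")
  comp <- sort(c(rec, lig))
  out <- tryCatch(c(
    E_pot1 = backend$potential_energy(system, rec, frame),
    E_pot2 = backend$potential_energy(system, lig, frame),
    E_sol1 = backend$solvation_energy(system, rec, frame),
    E_sol2 = backend$solvation_energy(system, lig, frame),
    E_pot_comp = backend$potential_energy(system, comp, frame),
    E_sol_comp = backend$solvation_energy(system, comp, frame)
  ), error = function(e) mf_stop("mf_backend_error",
    paste0("backend failed on frame ", frame, ": ", conditionMessage(e))))
  out
}

#' Per-frame binding-energy trace
#'
#' @param system a multi-frame `molsys` object.
#' @param backend an `energy_backend`.
#' @param frames frames to evaluate (default all).
#' @return Object of class `bind_trace`: data frame of frame, time (ns) and
#'   `E_bind` (kJ/mol) with the window fraction attached.
#' @export
binding_energy_trace <- function(system, backend = reference_backend(),
                                 frames = seq_len(n_frames(system))) {
  eb <- vapply(frames, function(f)
    binding_energy(compute_components(system, f, backend)), numeric(1))
  structure(data.frame(frame = frames, time = system$times[frames],
                       E_bind = eb),
            class = c("bind_trace", "data.frame"))
}

## Frame indices inside the analysis window. The default window drops the
## leading `fraction` of the simulated time span: a frame at time t is kept
## iff t >= t0 + fraction * (t1 - t0), closed on the left.
window_frames <- function(times, window_fraction = 0.4, bounds = NULL) {
  if (length(times) == 0L)
    mf_stop("mf_statistics_error", "empty trace")
  if (!is.null(bounds)) {
    keep <- which(times >= bounds[1] & times <= bounds[2])
  } else {
    t0 <- times[1]; t1 <- times[length(times)]
    keep <- which(times >= t0 + window_fraction * (t1 - t0))
  }
  if (length(keep) == 0L)
    mf_stop("mf_statistics_error", "analysis window contains no frames")
  keep
}

#' Windowed mean and spread of a binding-energy trace
#'
#' By default the first 40% of the simulated time span is treated as
#' equilibration and excluded; the window is closed on the left (a frame
#' exactly at the boundary time is included). The spread is the population
#' standard deviation of the per-frame values, reflecting the fluctuation
#' range rather than an error of the mean.
#'
#' @param trace a `bind_trace` (or any data frame with `time` and `E_bind`).
#' @param window_fraction leading fraction of the time span to exclude.
#' @param bounds optional explicit time window `c(from, to)` overriding the
#'   fraction.
#' @return Named numeric `c(mean, sd, n)`.
#' @export
trace_statistics <- function(trace, window_fraction = 0.4, bounds = NULL) {
  keep <- window_frames(trace$time, window_fraction, bounds)
  x <- trace$E_bind[keep]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  c(mean = m, sd = s, n = length(x))
}

#' @export
print.bind_trace <- function(x, ...) {
  cat("Binding-energy trace:", nrow(x), "frame(s), time",
      sprintf("%.3g..%.3g", min(x$time), max(x$time)), "\n")
  st <- trace_statistics(x)
  cat(sprintf("  windowed mean %.3f kJ/mol (sd %.3f, n %d)\n",
              st["mean"], st["sd"], as.integer(st["n"])))
  invisible(x)
}
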
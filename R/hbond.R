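## Energy-scored hydrogen-bond detection. A hydrogen bond is scored as
##
##   E_HB = 25 * (2.6 - max(d_HA, 2.1)) / 0.5 * s_DHA * s_HAX   [kJ/mol]
##
## where d_HA is the hydrogen-acceptor distance (Å) and the two s factors are
## piecewise-linear angular ramps; a contact is reported when E_HB strictly
## exceeds the detection threshold (default 6.25 kJ/mol).

#' Theta table of an angular ramp
#'
#' @param kind `"heavy"` (85, 95 degrees) or `"hydrogen"` (75, 85 degrees).
#' @return Numeric `c(theta1, theta2)` in degrees.
#' @export
angular_ramp <- function(kind = c("heavy", "hydrogen")) {
  kind <- match.arg(kind)
  if (kind == "heavy") c(85, 95) else c(75, 85)
}

#' Piecewise-linear angular scaling factor
#'
#' Returns 0 for angles at or below `theta1`, 1 above `theta2`, and a linear
#' ramp in between. The default (`orientation = "increasing"`) uses
#' \eqn{(\alpha-\theta_1)/(\theta_2-\theta_1)}, which meets the plateaus
#' continuously; `"printed"` flips the numerator between the plateaus and is
#' kept as a compatibility mode (see the methods vignette).
#'
#' @param alpha angle in degrees, in \[0, 180\]; vectorized.
#' @param ramp `c(theta1, theta2)`, e.g. from [angular_ramp()].
#' @param orientation `"increasing"` or `"printed"`.
#' @return Scaling factor(s) in \[0, 1\].
#' @export
angular_scaling <- function(alpha, ramp = angular_ramp("heavy"),
                            orientation = c("increasing", "printed")) {
  orientation <- match.arg(orientation)
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 180))
    mf_stop("mf_domain_error", "angle must lie in [0, 180] degrees")
  t1 <- ramp[1]; t2 <- ramp[2]
  if (!(0 < t1 && t1 < t2 && t2 <= 180))
    mf_stop("mf_domain_error", "ramp needs 0 < theta1 < theta2 <= 180")
  s <- if (orientation == "increasing") (alpha - t1) / (t2 - t1)
       else (t2 - alpha) / (t2 - t1)
  s[alpha <= t1] <- 0
  s[alpha > t2] <- 1
  pmin(1, pmax(0, s))
}

#' Hydrogen-bond energy
#'
#' Distance-and-angle scored energy in kJ/mol. The distance term plateaus at
#' 25 kJ/mol for distances at or below 2.1 Å, falls linearly to zero at
#' 2.6 Å, and is floored at zero beyond.
#'
#' @param dis_HA hydrogen-acceptor distance in Å; vectorized.
#' @param s_dah donor-hydrogen-acceptor angular factor in \[0, 1\].
#' @param s_hax hydrogen-acceptor-attached-atom angular factor in \[0, 1\].
#' @return Energy in kJ/mol, in \[0, 25\].
#' @export
hbond_energy <- function(dis_HA, s_dah = 1, s_hax = 1) {
  if (any(dis_HA <= 0) || any(s_dah < 0) || any(s_dah > 1) ||
      any(s_hax < 0) || any(s_hax > 1))
    mf_stop("mf_domain_error",
            "need dis_HA > 0 and scaling factors in [0, 1]")
  pmax(0, 25 * (2.6 - pmax(dis_HA, 2.1)) / 0.5) * s_dah * s_hax
}

## Lossless distance prefilter: E > thr requires
## 25*(2.6 - d)/0.5 > thr, i.e. d < 2.6 - 0.5*thr/25.
hbond_prefilter_cutoff <- function(threshold) 2.6 - 0.5 * threshold / 25

## Covalent neighbours (within the same atom group) of given acceptor rows:
## heavy atoms within the heavy cutoff, hydrogens within the H cutoff.
acceptor_neighbors <- function(system, xyz, acceptors, group, config) {
  a <- system$atoms
  out <- vector("list", length(acceptors))
  names(out) <- as.character(acceptors)
  for (k in seq_along(out)) out[[k]] <- integer(0)
  G <- xyz[group, , drop = FALSE]
  gel <- a$element[group]
  cutmax <- max(config$covalent_h_cutoff, config$covalent_heavy_cutoff)
  chunked_cross_dist(xyz[acceptors, , drop = FALSE], G, function(rows, D) {
    w <- which(D <= cutmax, arr.ind = TRUE)
    if (nrow(w) == 0) return()
    acc <- acceptors[rows[w[, 1]]]
    nbg <- w[, 2]
    cut <- ifelse(gel[nbg] == "H", config$covalent_h_cutoff,
                  config$covalent_heavy_cutoff)
    keep <- D[w] <= cut & group[nbg] != acc
    for (i in which(keep)) {
      key <- as.character(acc[i])
      out[[key]] <<- c(out[[key]], group[nbg[i]])
    }
  })
  out
}

#' Detect hydrogen bonds between two atom groups
#'
#' Enumerates donor hydrogens of one group against acceptors (N/O) of the
#' other, in both directions. The donor-hydrogen-acceptor angle is taken at
#' the hydrogen vertex and ramped through the hydrogen theta table; the
#' hydrogen-acceptor-X angle uses, for each covalent neighbour X of the
#' acceptor, the heavy-atom table when X is heavy and the hydrogen table
#' otherwise, combined over neighbours by `config$hax_rule` (default: the
#' maximum, i.e. most permissive). Acceptors without covalent neighbours get
#' a factor of 1. A contact is emitted iff its energy strictly exceeds
#' `config$hbond_threshold`; all qualifying pairs are kept.
#'
#' @param system a `molsys` object with explicit hydrogens.
#' @param groupA,groupB disjoint atom row index vectors (defaults: receptor
#'   and ligand atoms).
#' @param frame frame index.
#' @param config an [fp_config()].
#' @return Data frame of contacts ordered by donor then acceptor serial, with
#'   geometry and energy columns; zero rows when nothing qualifies.
#' @export
detect_hbonds <- function(system,
                          groupA = select_atoms(system, role = "receptor"),
                          groupB = select_atoms(system, role = "ligand"),
                          frame = 1L, config = fp_config()) {
  if (length(intersect(groupA, groupB)) > 0)
    mf_stop("mf_domain_error", "atom groups must be disjoint")
  a <- system$atoms
  if (!any(a$element[c(groupA, groupB)] == "H") &&
      any(a$element[c(groupA, groupB)] %in% c("N", "O")))
    mf_stop("mf_missing_hydrogens",
            "no hydrogens present: donor detection needs explicit hydrogens")
  xyz <- frame_xyz(system, frame)
  cutoff <- hbond_prefilter_cutoff(config$hbond_threshold)
  res <- list()

  scan <- function(gd, ga) {
    da <- find_donors_acceptors_idx(system, gd, frame, config,
                                    require_h = FALSE)
    acc <- ga[a$element[ga] %in% c("N", "O")]
    dh <- da$donor_hydrogens
    if (nrow(dh) == 0L || length(acc) == 0L) return(NULL)
    hits <- list()
    H <- xyz[dh$hydrogen, , drop = FALSE]
    A <- xyz[acc, , drop = FALSE]
    chunked_cross_dist(H, A, function(rows, D) {
      w <- which(D <= cutoff, arr.ind = TRUE)
      if (nrow(w) > 0)
        hits[[length(hits) + 1L]] <<- data.frame(
          pair = rows[w[, 1]], acc = w[, 2], dist = D[w])
    })
    if (length(hits) == 0L) return(NULL)
    hits <- do.call(rbind, hits)
    don_i <- dh$donor[hits$pair]
    hyd_i <- dh$hydrogen[hits$pair]
    acc_i <- acc[hits$acc]
    s_dah <- angular_scaling(
      vec_angle_rows(xyz[don_i, , drop = FALSE], xyz[hyd_i, , drop = FALSE],
                     xyz[acc_i, , drop = FALSE]),
      config$theta_hydrogen, config$ramp_orientation)
    nb <- acceptor_neighbors(system, xyz, unique(acc_i), ga, config)
    s_hax <- numeric(length(acc_i))
    x_pick <- integer(length(acc_i))
    for (k in seq_along(acc_i)) {
      xs <- nb[[as.character(acc_i[k])]]
      if (length(xs) == 0L) { s_hax[k] <- 1; x_pick[k] <- NA_integer_; next }
      sv <- vapply(xs, function(x) {
        ramp <- if (a$element[x] == "H") config$theta_hydrogen
                else config$theta_heavy
        angular_scaling(vec_angle(xyz[hyd_i[k], ], xyz[acc_i[k], ], xyz[x, ]),
                        ramp, config$ramp_orientation)
      }, numeric(1))
      j <- if (config$hax_rule == "min") which.min(sv) else which.max(sv)
      s_hax[k] <- sv[j]
      x_pick[k] <- xs[j]
    }
    e <- hbond_energy(hits$dist, 1, 1) * s_dah * s_hax
    keep <- e > config$hbond_threshold
    if (!any(keep)) return(NULL)
    data.frame(
      donor = don_i[keep], hydrogen = hyd_i[keep], acceptor = acc_i[keep],
      x_atom = x_pick[keep], dist_HA = hits$dist[keep],
      s_dah = s_dah[keep], s_hax = s_hax[keep], energy = e[keep]
    )
  }

  res[[1]] <- scan(groupA, groupB)
  res[[2]] <- scan(groupB, groupA)
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), x_atom = integer(),
                      dist_HA = numeric(), s_dah = numeric(),
                      s_hax = numeric(), energy = numeric())
  out$donor_serial <- a$serial[out$donor]
  out$acceptor_serial <- a$serial[out$acceptor]
  out$donor_resname <- a$resname[out$donor]
  out$donor_resno <- a$resno[out$donor]
  out$donor_role <- a$role[out$donor]
  out$acceptor_resname <- a$resname[out$acceptor]
  out$acceptor_resno <- a$resno[out$acceptor]
  out$acceptor_role <- a$role[out$acceptor]
  out <- out[order(out$donor_serial, out$acceptor_serial), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_contacts", "data.frame")
  out
}
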
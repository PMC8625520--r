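## Geometric contact detectors: water bridges, ionic contacts, cation
## bridges, and hydrophobic contacts.

#' Detect water bridges between receptor and ligand
#'
#' A water bridge is a water molecule donating both of its hydrogens: one
#' hydrogen within the leg threshold (default 3.0 Å, inclusive) of a receptor
#' N/O acceptor and the other, distinct hydrogen within the threshold of a
#' ligand N/O acceptor. Both hydrogen assignments are tried and a
#' (water, receptor atom, ligand atom) triple is counted once; the recorded
#' legs belong to the first valid assignment (hydrogens in atom order).
#'
#' @param system a `molsys` object with explicit water hydrogens.
#' @param frame frame index.
#' @param config an [fp_config()].
#' @return Data frame, one row per bridge, ordered by water serial then
#'   receptor and ligand acceptor serials.
#' @export
detect_water_bridges <- function(system, frame = 1L, config = fp_config()) {
  a <- system$atoms
  xyz <- frame_xyz(system, frame)
  thr <- config$water_bridge_threshold
  wat_uids <- unique(a$resuid[a$role == "water"])
  racc <- which(a$role == "receptor" & a$element %in% c("N", "O"))
  lacc <- which(a$role == "ligand" & a$element %in% c("N", "O"))
  rows <- list()
  for (uid in wat_uids) {
    sel <- which(a$resuid == uid)
    hs <- sel[a$element[sel] == "H"]
    if (length(hs) != 2L)
      mf_stop("mf_missing_hydrogens",
              paste0("water residue lacks explicit hydrogens: ", uid))
    hs <- hs[order(a$serial[hs])]
    if (length(racc) == 0L || length(lacc) == 0L) next
    d1r <- sqrt(colSums((t(xyz[racc, , drop = FALSE]) - xyz[hs[1], ])^2))
    d2r <- sqrt(colSums((t(xyz[racc, , drop = FALSE]) - xyz[hs[2], ])^2))
    d1l <- sqrt(colSums((t(xyz[lacc, , drop = FALSE]) - xyz[hs[1], ])^2))
    d2l <- sqrt(colSums((t(xyz[lacc, , drop = FALSE]) - xyz[hs[2], ])^2))
    for (i in which(pmin(d1r, d2r) <= thr)) {
      for (j in which(pmin(d1l, d2l) <= thr)) {
        ## distinct hydrogens, first valid assignment wins
        if (d1r[i] <= thr && d2l[j] <= thr) {
          legs <- c(d1r[i], d2l[j])
        } else if (d2r[i] <= thr && d1l[j] <= thr) {
          legs <- c(d2r[i], d1l[j])
        } else next
        rows[[length(rows) + 1L]] <- data.frame(
          water_resno = a$resno[sel[1]], water_serial = a$serial[sel[1]],
          receptor_atom = racc[i], ligand_atom = lacc[j],
          receptor_serial = a$serial[racc[i]],
          ligand_serial = a$serial[lacc[j]],
          receptor_resname = a$resname[racc[i]],
          receptor_resno = a$resno[racc[i]],
          ligand_resname = a$resname[lacc[j]],
          ligand_resno = a$resno[lacc[j]],
          leg_receptor = legs[1], leg_ligand = legs[2]
        )
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(water_resno = integer(), water_serial = integer(),
               receptor_atom = integer(), ligand_atom = integer(),
               receptor_serial = integer(), ligand_serial = integer(),
               receptor_resname = character(), receptor_resno = integer(),
               ligand_resname = character(), ligand_resno = integer(),
               leg_receptor = numeric(), leg_ligand = numeric())
  out <- out[order(out$water_serial, out$receptor_serial, out$ligand_serial), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("water_bridges", "data.frame")
  out
}

#' Formal-charge centres of a system
#'
#' Collects the charge centre (see [charge_center()]) of every charged
#' receptor residue, the ligand carboxylates, and every ion.
#'
#' @param system a `molsys` object.
#' @param frame frame index.
#' @param config an [fp_config()].
#' @return Data frame with one row per centre: role, residue identity,
#'   charge, radius element and centre coordinates.
#' @export
charge_centers <- function(system, frame = 1L, config = fp_config()) {
  a <- system$atoms
  xyz <- frame_xyz(system, frame)
  rows <- list()
  charged <- c("LYS", "ARG", "ASP", "GLU", "GCU",
               if (config$his_protonated) "HIS",
               names(ION_CHARGES))
  for (uid in unique(a$resuid)) {
    sel <- which(a$resuid == uid)
    rn <- toupper(a$resname[sel[1]])
    if (!rn %in% charged) next
    if (rn %in% names(ION_CHARGES) && a$role[sel[1]] != "ion") next
    cc <- tryCatch(
      charge_center(rn, a$name[sel], xyz[sel, , drop = FALSE],
                    his_protonated = config$his_protonated),
      mdfinger_error = function(e) NULL)
    if (is.null(cc)) next
    rows[[length(rows) + 1L]] <- data.frame(
      resuid = uid, role = a$role[sel[1]], resname = a$resname[sel[1]],
      chain = a$chain[sel[1]], resno = a$resno[sel[1]],
      charge = cc$charge, element = cc$element,
      x = cc$point[1], y = cc$point[2], z = cc$point[3]
    )
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(resuid = character(), role = character(), resname = character(),
               chain = character(), resno = integer(), charge = numeric(),
               element = character(), x = numeric(), y = numeric(),
               z = numeric())
  rownames(out) <- NULL
  out
}

#' Detect ionic contacts
#'
#' Pairs every positive charge centre with every negative one across the
#' receptor-ligand, ion-receptor and ion-ligand pairings. The raw
#' centre-to-centre distance is reduced by the two hydrogen-bond radii of the
#' centres (per-element table in the config) and a contact is reported iff
#' the adjusted distance lies in the inclusive range `config$ionic_range`
#' (default 0 to 1.5 Å).
#'
#' @param system a `molsys` object.
#' @param frame frame index.
#' @param config an [fp_config()].
#' @param centers optionally precomputed [charge_centers()].
#' @return Data frame, one row per contact, with a `pairing` label.
#' @export
detect_ionic_contacts <- function(system, frame = 1L, config = fp_config(),
                                  centers = NULL) {
  cc <- centers %||% charge_centers(system, frame, config)
  lo <- config$ionic_range[1]; hi <- config$ionic_range[2]
  pos <- which(cc$charge > 0)
  neg <- which(cc$charge < 0)
  rows <- list()
  for (i in pos) {
    for (j in neg) {
      pairing <- paste(sort(c(cc$role[i], cc$role[j])), collapse = "-")
      if (!pairing %in% c("ligand-receptor", "ion-receptor", "ion-ligand"))
        next
      raw <- sqrt(sum((c(cc$x[i], cc$y[i], cc$z[i]) -
                         c(cc$x[j], cc$y[j], cc$z[j]))^2))
      adj <- raw - ionic_radius(cc$element[i], config) -
        ionic_radius(cc$element[j], config)
      if (adj >= lo && adj <= hi) {
        rows[[length(rows) + 1L]] <- data.frame(
          pairing = pairing,
          pos_resuid = cc$resuid[i], pos_resname = cc$resname[i],
          pos_resno = cc$resno[i], pos_charge = cc$charge[i],
          neg_resuid = cc$resuid[j], neg_resname = cc$resname[j],
          neg_resno = cc$resno[j], neg_charge = cc$charge[j],
          raw_dist = raw, adj_dist = adj
        )
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(pairing = character(), pos_resuid = character(),
               pos_resname = character(), pos_resno = integer(),
               pos_charge = numeric(), neg_resuid = character(),
               neg_resname = character(), neg_resno = integer(),
               neg_charge = numeric(), raw_dist = numeric(),
               adj_dist = numeric())
  out <- out[order(out$pairing, out$pos_resuid, out$neg_resuid), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ionic_contacts", "data.frame")
  out
}

#' Detect cation bridges
#'
#' A cation bridge is a cation in simultaneous ionic contact (per
#' [detect_ionic_contacts()]) with at least one receptor anionic centre and
#' at least one ligand anionic centre; all centre pairs are enumerated. The
#' default species filter keeps the divalent cations (Ca, Mg); sodium can be
#' included via `species`.
#'
#' @param system a `molsys` object.
#' @param frame frame index.
#' @param config an [fp_config()].
#' @param species cation residue names to consider.
#' @return Data frame, one row per (cation, receptor centre, ligand centre).
#' @export
detect_cation_bridges <- function(system, frame = 1L, config = fp_config(),
                                  species = config$cation_species) {
  ic <- detect_ionic_contacts(system, frame, config)
  ic <- ic[ic$pairing %in% c("ion-receptor", "ion-ligand") &
             toupper(ic$pos_resname) %in% toupper(species), , drop = FALSE]
  rows <- list()
  for (ion in unique(ic$pos_resuid)) {
    rec <- ic[ic$pos_resuid == ion & ic$pairing == "ion-receptor", ]
    lig <- ic[ic$pos_resuid == ion & ic$pairing == "ion-ligand", ]
    if (nrow(rec) == 0L || nrow(lig) == 0L) next
    for (i in seq_len(nrow(rec))) {
      for (j in seq_len(nrow(lig))) {
        rows[[length(rows) + 1L]] <- data.frame(
          cation_resuid = ion, species = rec$pos_resname[i],
          receptor_resname = rec$neg_resname[i],
          receptor_resno = rec$neg_resno[i],
          ligand_resname = lig$neg_resname[j],
          ligand_resno = lig$neg_resno[j],
          adj_dist_receptor = rec$adj_dist[i],
          adj_dist_ligand = lig$adj_dist[j]
        )
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cation_resuid = character(), species = character(),
               receptor_resname = character(), receptor_resno = integer(),
               ligand_resname = character(), ligand_resno = integer(),
               adj_dist_receptor = numeric(), adj_dist_ligand = numeric())
  out <- out[order(out$cation_resuid, out$receptor_resno, out$ligand_resno), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cation_bridges", "data.frame")
  out
}

#' Detect hydrophobic contacts
#'
#' Pairs receptor and ligand carbons whose hydrophobic class (see
#' [classify_hydrophobic_carbons()]) is not `none` and whose distance is at
#' most the configured cutoff (default 4.5 Å). Alpha carbons are excluded by
#' the class tables for every amino acid except glycine.
#'
#' @param system a `molsys` object.
#' @param frame frame index.
#' @param config an [fp_config()].
#' @param cutoff distance cutoff in Å (default from config).
#' @return Data frame, one row per contact.
#' @export
detect_hydrophobic_contacts <- function(system, frame = 1L,
                                        config = fp_config(),
                                        cutoff = config$hydrophobic_cutoff) {
  a <- system$atoms
  xyz <- frame_xyz(system, frame)
  classify_group <- function(idx) {
    cls <- rep("none", length(idx))
    for (uid in unique(a$resuid[idx])) {
      sel <- idx %in% which(a$resuid == uid)
      cls[sel] <- classify_hydrophobic_carbons(
        a$resname[idx[sel][1]], a$name[idx[sel]])
    }
    cls
  }
  rc <- which(a$role == "receptor" & a$element == "C")
  lc <- which(a$role == "ligand" & a$element == "C")
  rcls <- classify_group(rc)
  lcls <- classify_group(lc)
  rc <- rc[rcls != "none"]; rcls <- rcls[rcls != "none"]
  lc <- lc[lcls != "none"]; lcls <- lcls[lcls != "none"]
  rows <- list()
  if (length(rc) > 0 && length(lc) > 0) {
    chunked_cross_dist(xyz[rc, , drop = FALSE], xyz[lc, , drop = FALSE],
                       function(ridx, D) {
      w <- which(D <= cutoff, arr.ind = TRUE)
      if (nrow(w) > 0)
        rows[[length(rows) + 1L]] <<- data.frame(
          receptor_atom = rc[ridx[w[, 1]]], ligand_atom = lc[w[, 2]],
          receptor_class = rcls[ridx[w[, 1]]], ligand_class = lcls[w[, 2]],
          dist = D[w])
    })
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(receptor_atom = integer(), ligand_atom = integer(),
               receptor_class = character(), ligand_class = character(),
               dist = numeric())
  out$receptor_serial <- a$serial[out$receptor_atom]
  out$ligand_serial <- a$serial[out$ligand_atom]
  out$receptor_resname <- a$resname[out$receptor_atom]
  out$receptor_resno <- a$resno[out$receptor_atom]
  out$ligand_resname <- a$resname[out$ligand_atom]
  out$ligand_resno <- a$resno[out$ligand_atom]
  out <- out[order(out$receptor_serial, out$ligand_serial), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hydrophobic_contacts", "data.frame")
  out
}
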
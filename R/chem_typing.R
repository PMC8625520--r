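## Chemical perception tables: protonation at pH 7.4, donor/acceptor flags,
## hydrophobic carbon classes, formal-charge centres, and the hyaluronate
## oxygen-class map.

## Side-chain / ligand formal charges at pH 7.4. Delocalized carboxylate and
## (protonated) imidazole charges are split over the two equivalent atoms so
## residue totals stay integral; the ionic detector works from midpoints.
CHARGE_TEMPLATES <- list(
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5),
  LYS = c(NZ = 1),
  ARG = c(CZ = 1),
  GCU = c(O6A = -0.5, O6B = -0.5)
)

HIS_PROTONATED_CHARGES <- c(ND1 = 0.5, NE2 = 0.5)

ION_CHARGES <- c("NA" = 1, MG = 2, CA = 2, CL = -1, K = 1)

## Hydrophobic carbon classes per residue template. Three-hydrogen carbons
## are CH3; two-hydrogen carbons and one-hydrogen carbons with three carbon
## neighbours are CH2/CH; hydrogen-carrying aromatic ring carbons are
## aromatic-CH. Alpha carbons are excluded for all amino acids except
## glycine, whose CA carries two hydrogens.
HYDROPHOBIC_CLASSES <- list(
  ALA = c(CB = "CH3"),
  ARG = c(CB = "CH2/CH", CG = "CH2/CH", CD = "CH2/CH"),
  ASN = c(CB = "CH2/CH"),
  ASP = c(CB = "CH2/CH"),
  CYS = c(CB = "CH2/CH"),
  GLN = c(CB = "CH2/CH", CG = "CH2/CH"),
  GLU = c(CB = "CH2/CH", CG = "CH2/CH"),
  GLY = c(CA = "CH2/CH"),
  HIS = c(CB = "CH2/CH", CD2 = "aromatic-CH", CE1 = "aromatic-CH"),
  ILE = c(CB = "CH2/CH", CG1 = "CH2/CH", CG2 = "CH3", CD1 = "CH3"),
  LEU = c(CB = "CH2/CH", CG = "CH2/CH", CD1 = "CH3", CD2 = "CH3"),
  LYS = c(CB = "CH2/CH", CG = "CH2/CH", CD = "CH2/CH", CE = "CH2/CH"),
  MET = c(CB = "CH2/CH", CG = "CH2/CH", CE = "CH3"),
  PHE = c(CB = "CH2/CH", CD1 = "aromatic-CH", CD2 = "aromatic-CH",
          CE1 = "aromatic-CH", CE2 = "aromatic-CH", CZ = "aromatic-CH"),
  PRO = c(CB = "CH2/CH", CG = "CH2/CH", CD = "CH2/CH"),
  SER = c(CB = "CH2/CH"),
  THR = c(CG2 = "CH3"),
  TRP = c(CB = "CH2/CH", CD1 = "aromatic-CH", CE3 = "aromatic-CH",
          CZ2 = "aromatic-CH", CZ3 = "aromatic-CH", CH2 = "aromatic-CH"),
  TYR = c(CB = "CH2/CH", CD1 = "aromatic-CH", CD2 = "aromatic-CH",
          CE1 = "aromatic-CH", CE2 = "aromatic-CH"),
  VAL = c(CB = "CH2/CH", CG1 = "CH3", CG2 = "CH3"),
  NAG = c(C6 = "CH2/CH", C8 = "CH3"),
  GCU = character(0)
)

#' Per-atom formal charges of one residue at a given pH
#'
#' At the default pH 7.4 the aspartate/glutamate and glucuronate carboxylates
#' carry -1 (split -0.5/-0.5 over the two oxygens), lysine +1 on NZ,
#' arginine +1 on CZ, histidine is neutral unless `his_protonated`, waters
#' and N-acetyl-glucosamine are neutral, and monatomic ions carry their
#' nominal charge.
#'
#' @param resname residue name (standard amino acid, GCU, NAG, water or ion).
#' @param atom_names atom names present in the residue.
#' @param pH solution pH (only 7.4-style bulk behaviour is modelled).
#' @param his_protonated logical, treat histidine as a +1 centre.
#' @return Named numeric vector of per-atom charges (one per `atom_names`).
#' @export
assign_protonation <- function(resname, atom_names, pH = 7.4,
                               his_protonated = FALSE) {
  rn <- toupper(resname)
  ch <- stats::setNames(numeric(length(atom_names)), atom_names)
  if (rn %in% names(ION_CHARGES) && length(atom_names) == 1L) {
    ch[] <- ION_CHARGES[[rn]]
  } else if (rn %in% c("HOH", "WAT", "TIP3", "SOL", "NAG")) {
    ## neutral
  } else if (rn == "HIS") {
    if (his_protonated) {
      hit <- atom_names %in% names(HIS_PROTONATED_CHARGES)
      ch[hit] <- HIS_PROTONATED_CHARGES[atom_names[hit]]
    }
  } else if (rn %in% names(CHARGE_TEMPLATES)) {
    tmpl <- CHARGE_TEMPLATES[[rn]]
    hit <- atom_names %in% names(tmpl)
    ch[hit] <- tmpl[atom_names[hit]]
  } else if (!rn %in% STANDARD_AA) {
    mf_stop("mf_typing_error", paste0("unknown residue type: ", resname))
  }
  ch
}

#' Assign formal charges to every atom of a system
#'
#' Applies [assign_protonation()] residue by residue and stores the result in
#' the `charge` column of the atom table.
#'
#' @param system a `molsys` object.
#' @param pH solution pH.
#' @param config an [fp_config()] (supplies the histidine switch).
#' @return The system with `system$atoms$charge` filled in.
#' @export
assign_charges <- function(system, pH = 7.4, config = fp_config()) {
  a <- system$atoms
  a$charge <- 0
  for (uid in unique(a$resuid)) {
    sel <- which(a$resuid == uid)
    a$charge[sel] <- assign_protonation(a$resname[sel[1]], a$name[sel],
                                        pH = pH,
                                        his_protonated = config$his_protonated)
  }
  system$atoms <- a
  system
}

## donor/acceptor perception for a set of atom rows; donors are N/O atoms
## with >= 1 hydrogen of the same residue within the covalent cutoff.
find_donors_acceptors_idx <- function(system, idx, frame = 1L,
                                      config = fp_config(),
                                      require_h = TRUE) {
  a <- system$atoms
  xyz <- frame_xyz(system, frame)
  no <- idx[a$element[idx] %in% c("N", "O")]
  hs <- idx[a$element[idx] == "H"]
  if (require_h && length(hs) == 0L && length(no) > 0L)
    mf_stop("mf_missing_hydrogens",
            "no hydrogens present: donor detection needs explicit hydrogens")
  pairs <- NULL
  if (length(hs) > 0L && length(no) > 0L) {
    cand <- merge(
      data.frame(h = hs, resuid = a$resuid[hs]),
      data.frame(d = no, resuid = a$resuid[no]),
      by = "resuid"
    )
    if (nrow(cand) > 0) {
      dd <- sqrt(rowSums((xyz[cand$h, , drop = FALSE] -
                            xyz[cand$d, , drop = FALSE])^2))
      cand <- cand[dd <= config$covalent_h_cutoff, , drop = FALSE]
    }
    if (nrow(cand) > 0)
      pairs <- data.frame(donor = cand$d, hydrogen = cand$h)
  }
  if (is.null(pairs)) pairs <- data.frame(donor = integer(), hydrogen = integer())
  pairs <- pairs[order(a$serial[pairs$donor], a$serial[pairs$hydrogen]), ,
                 drop = FALSE]
  list(acceptors = no, donors = sort(unique(pairs$donor)),
       donor_hydrogens = pairs)
}

#' Hydrogen-bond donors and acceptors of a system
#'
#' Acceptors are all nitrogen and oxygen atoms; donors are the N/O atoms
#' carrying at least one covalently attached hydrogen (a hydrogen of the same
#' residue within 1.2 Å). Hydroxyl oxygens and amide nitrogens therefore come
#' out flagged as both donor and acceptor.
#'
#' @param system a `molsys` object.
#' @param idx atom rows to scan (default: all atoms).
#' @param frame frame index.
#' @param config an [fp_config()].
#' @return List with `acceptors`, `donors` (atom row indices) and
#'   `donor_hydrogens` (data frame of donor/hydrogen row pairs).
#' @export
find_donors_acceptors <- function(system, idx = seq_len(nrow(system$atoms)),
                                  frame = 1L, config = fp_config()) {
  find_donors_acceptors_idx(system, idx, frame, config, require_h = TRUE)
}

#' Hydrophobic class of each carbon in a residue
#'
#' Template lookup implementing the three contact subcategories: methyl
#' carbons (`CH3`), two-hydrogen or one-hydrogen/three-carbon aliphatic
#' carbons (`CH2/CH`), and hydrogen-carrying aromatic ring carbons
#' (`aromatic-CH`). Alpha carbons are `none` for every amino acid except
#' glycine; atoms outside the template are `none`.
#'
#' @param resname residue name.
#' @param atom_names atom names to classify.
#' @return Named character vector of classes.
#' @export
classify_hydrophobic_carbons <- function(resname, atom_names) {
  tmpl <- HYDROPHOBIC_CLASSES[[toupper(resname)]]
  out <- stats::setNames(rep("none", length(atom_names)), atom_names)
  if (!is.null(tmpl) && length(tmpl) > 0) {
    hit <- atom_names %in% names(tmpl)
    out[hit] <- tmpl[atom_names[hit]]
  }
  out
}

#' Formal-charge centre of a residue
#'
#' The centre of a delocalized charge is the midpoint of its equivalent
#' atoms: carboxylates use the two oxygens, protonated histidine the two ring
#' nitrogens. Lysine's centre is the NZ atom, arginine's the CZ atom, and a
#' monatomic ion is its own centre.
#'
#' @param resname residue name.
#' @param atom_names atom names of the residue.
#' @param coords matrix of residue coordinates (rows follow `atom_names`).
#' @param his_protonated logical, histidine charge switch.
#' @return List with `point` (3-vector), `charge`, and `element` (the element
#'   used for the hydrogen-bond-radius lookup, from the nearest real atom).
#' @export
charge_center <- function(resname, atom_names, coords,
                          his_protonated = FALSE) {
  rn <- toupper(resname)
  mid <- function(n1, n2, el, q) {
    i <- match(n1, atom_names); j <- match(n2, atom_names)
    if (is.na(i) || is.na(j))
      mf_stop("mf_typing_error",
              paste0(rn, " charge centre needs atoms ", n1, " and ", n2))
    list(point = (coords[i, ] + coords[j, ]) / 2, charge = q, element = el)
  }
  single <- function(n, el, q) {
    i <- match(n, atom_names)
    if (is.na(i))
      mf_stop("mf_typing_error", paste0(rn, " charge centre needs atom ", n))
    list(point = coords[i, ], charge = q, element = el)
  }
  switch(rn,
    LYS = single("NZ", "N", 1),
    ARG = single("CZ", "C", 1),
    HIS = if (his_protonated) mid("ND1", "NE2", "N", 1) else
      mf_stop("mf_no_center", "neutral residue has no charge centre"),
    ASP = mid("OD1", "OD2", "O", -1),
    GLU = mid("OE1", "OE2", "O", -1),
    GCU = mid("O6A", "O6B", "O", -1),
    {
      if (rn %in% names(ION_CHARGES) && length(atom_names) == 1L)
        list(point = coords[1, ], charge = unname(ION_CHARGES[[rn]]),
             element = rn)
      else
        mf_stop("mf_no_center", paste0("no charge centre for residue ", rn))
    }
  )
}

OXYGEN_CLASSES <- c(paste0("O", 1:10), "N")

#' Shipped oxygen-class map of the hyaluronate disaccharide
#'
#' Maps every nitrogen/oxygen of the GCU-NAG repeat unit to one of the
#' ligand classes O1..O10 or N. The assignment of individual atoms to class
#' numbers is a documented package convention (carried in outputs as
#' `map_version`): the glucuronate hydroxyls are O1-O3, its carboxylate
#' oxygens share O4, ring and glycosidic oxygens are O5/O6, the
#' N-acetyl-glucosamine ring, hydroxymethyl, carbonyl and remaining hydroxyl
#' oxygens are O7-O10, and the amide nitrogen is class N.
#'
#' @return Data frame with columns `resname`, `atom`, `class` and attribute
#'   `map_version`.
#' @export
default_oxygen_class_map <- function() {
  map <- data.frame(
    resname = c(rep("GCU", 7), rep("NAG", 6)),
    atom = c("O2", "O3", "O4", "O6A", "O6B", "O5", "O1",
             "O5", "O6", "O7", "O4", "O1", "N2"),
    class = c("O1", "O2", "O3", "O4", "O4", "O5", "O6",
              "O7", "O8", "O9", "O10", "O10", "N"),
    stringsAsFactors = FALSE
  )
  attr(map, "map_version") <- "mdfinger-map-1"
  map
}

#' Class labels for the ligand nitrogen/oxygen atoms of a system
#'
#' @param system a `molsys` object.
#' @param map a class map as returned by [default_oxygen_class_map()].
#' @param strict error on ligand N/O atoms missing from the map (otherwise
#'   they are labelled `"unmapped"`).
#' @return Data frame of ligand N/O atoms with their class labels; attribute
#'   `map_version` echoes the map.
#' @export
assign_oxygen_classes <- function(system, map = default_oxygen_class_map(),
                                  strict = FALSE) {
  a <- system$atoms
  idx <- which(a$role == "ligand" & a$element %in% c("N", "O"))
  key <- paste(toupper(a$resname[idx]), a$name[idx])
  mkey <- paste(toupper(map$resname), map$atom)
  cls <- map$class[match(key, mkey)]
  if (anyNA(cls)) {
    if (strict)
      mf_stop("mf_incomplete_map",
              paste0("ligand N/O atoms missing from oxygen-class map: ",
                     paste(unique(key[is.na(cls)]), collapse = ", ")))
    cls[is.na(cls)] <- "unmapped"
  }
  bad <- setdiff(unique(cls), c(OXYGEN_CLASSES, "unmapped"))
  if (length(bad) > 0)
    mf_stop("mf_incomplete_map",
            paste0("class labels outside O1..O10/N: ",
                   paste(bad, collapse = ", ")))
  out <- data.frame(atom = idx, serial = a$serial[idx],
                    resname = a$resname[idx], name = a$name[idx],
                    class = cls, stringsAsFactors = FALSE)
  attr(out, "map_version") <- attr(map, "map_version") %||% "custom"
  out
}
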
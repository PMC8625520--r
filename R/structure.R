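## Molecular system container: a topology table shared by all frames plus a
## coordinate array. Multi-model PDB is the trajectory format.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

ROLES <- c("receptor", "ligand", "water", "ion", "other")

#' Default residue-to-role rules
#'
#' Standard amino acids map to `receptor`, GCU/NAG sugar units to `ligand`,
#' water residue names to `water`, and the monatomic ion residue names to
#' `ion` -- the ion assignment additionally requires the residue to contain a
#' single atom, which disambiguates a calcium ion residue named `CA` from
#' alpha-carbon atoms inside protein residues. Everything else is `other`.
#'
#' @return A named list of character vectors, one per role.
#' @export
default_role_rules <- function() {
  list(
    receptor = STANDARD_AA,
    ligand = c("GCU", "NAG"),
    water = c("HOH", "WAT", "TIP3", "SOL"),
    ion = c("NA", "MG", "CA", "CL", "K")
  )
}

assign_roles <- function(atoms, role_rules) {
  role <- rep("other", nrow(atoms))
  key <- paste(atoms$chain, atoms$resno)
  res_size <- stats::ave(seq_along(key), key, FUN = length)
  rn <- toupper(atoms$resname)
  role[rn %in% role_rules$receptor] <- "receptor"
  role[rn %in% role_rules$ligand] <- "ligand"
  role[rn %in% role_rules$water] <- "water"
  role[rn %in% role_rules$ion & res_size == 1L] <- "ion"
  role
}

## Construct and validate the container.
molecular_system <- function(atoms, xyz, times = NULL) {
  stopifnot(is.data.frame(atoms), is.array(xyz), length(dim(xyz)) == 3)
  if (dim(xyz)[1] != nrow(atoms) || dim(xyz)[2] != 3)
    mf_stop("mf_structure_error", "coordinate array does not match atom table")
  if (any(!is.finite(xyz)))
    mf_stop("mf_structure_error", "non-finite coordinates")
  if (any(atoms$element == "" | is.na(atoms$element)))
    mf_stop("mf_structure_error", "every atom needs a non-empty element")
  if (anyDuplicated(atoms$serial))
    mf_stop("mf_structure_error", "atom serial numbers must be unique")
  if (!all(atoms$role %in% ROLES))
    mf_stop("mf_structure_error",
            paste0("unknown role(s): ",
                   paste(setdiff(unique(atoms$role), ROLES), collapse = ", ")))
  atoms$resuid <- paste(atoms$role, atoms$chain, atoms$resno, atoms$resname,
                        sep = "|")
  ## ion residues are single atoms; waters with hydrogens have 1 O + 2 H
  for (uid in unique(atoms$resuid[atoms$role == "ion"])) {
    if (sum(atoms$resuid == uid) != 1L)
      mf_stop("mf_structure_error",
              paste0("ion residue is not a single atom: ", uid))
  }
  for (uid in unique(atoms$resuid[atoms$role == "water"])) {
    sel <- atoms$resuid == uid
    el <- toupper(atoms$element[sel])
    if (sum(el == "H") > 0 && !(sum(el == "O") == 1L && sum(el == "H") == 2L))
      mf_stop("mf_structure_error",
              paste0("water residue must contain 1 O and 2 H: ", uid))
  }
  if (is.null(times)) times <- seq_len(dim(xyz)[3]) - 1
  structure(list(atoms = atoms, xyz = xyz, times = as.numeric(times)),
            class = "molsys")
}

#' @export
print.molsys <- function(x, ...) {
  tab <- table(factor(x$atoms$role, levels = ROLES))
  cat("Molecular system:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resuid)), "residues,", n_frames(x), "frame(s)\n")
  cat("  atoms per role:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Number of frames in a system
#' @param system a `molsys` object.
#' @return Integer frame count.
#' @export
n_frames <- function(system) dim(system$xyz)[3]

#' Coordinates of one frame
#' @param system a `molsys` object.
#' @param frame 1-based frame index.
#' @return Numeric matrix, atoms x 3, in Å.
#' @export
frame_xyz <- function(system, frame = 1L) {
  if (frame < 1 || frame > n_frames(system))
    mf_stop("mf_structure_error", paste0("no frame ", frame))
  matrix(system$xyz[, , frame], ncol = 3)
}

## Element from a PDB atom name when the element column is blank: strip
## digits/primes, then the leading character (two letters only for ions).
guess_element <- function(name, resname) {
  nm <- toupper(gsub("[0-9']", "", trimws(name)))
  el <- substr(nm, 1, 1)
  two <- nm %in% c("CL", "BR", "MG", "FE", "ZN", "MN") |
    (nm == "CA" & toupper(resname) == "CA") |
    (nm == "NA" & toupper(resname) == "NA") |
    (nm == "K" & toupper(resname) == "K")
  el[two] <- nm[two]
  el
}

#' Read a (multi-model) PDB file into a molecular system
#'
#' Fixed-column ATOM/HETATM records are parsed with MODEL/ENDMDL blocks taken
#' as trajectory frames (a file without MODEL records yields one frame).
#' Residues are assigned to roles (receptor / ligand / water / ion / other)
#' by residue name via `role_rules`; see [default_role_rules()].
#'
#' @param path path to a PDB file.
#' @param role_rules named list of residue-name vectors per role.
#' @param times optional per-frame times in ns.
#' @return A `molsys` object.
#' @export
read_pdb <- function(path, role_rules = default_role_rules(), times = NULL) {
  if (!file.exists(path))
    mf_stop("mf_parse_error", paste0("file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) mf_stop("mf_parse_error",
                                paste0("PDB parse failed for ", path, ": ",
                                       conditionMessage(e)))
  )
  at <- pdb$atom
  el <- trimws(at$elesy %||% "")
  miss <- is.na(el) | el == ""
  el[miss] <- guess_element(at$elety[miss], at$resid[miss])
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    element = toupper(el),
    stringsAsFactors = FALSE
  )
  atoms$role <- assign_roles(atoms, role_rules)
  nat <- nrow(atoms)
  xyzm <- pdb$xyz
  if (is.vector(xyzm)) xyzm <- matrix(xyzm, nrow = 1)
  if (ncol(xyzm) != 3 * nat)
    mf_stop("mf_structure_error",
            "frames with differing atom counts in multi-model file")
  nfr <- nrow(xyzm)
  xyz <- array(NA_real_, c(nat, 3, nfr))
  for (f in seq_len(nfr))
    xyz[, , f] <- matrix(xyzm[f, ], ncol = 3, byrow = TRUE)
  molecular_system(atoms, xyz, times)
}

#' Write a molecular system as a (multi-model) PDB file
#'
#' Round-trips through [read_pdb()]: atom names, residue numbering, roles
#' (via the role rules) and coordinates to PDB precision (3 decimals) are
#' preserved. Multi-frame systems are written as MODEL/ENDMDL blocks.
#'
#' @param system a `molsys` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, path) {
  atoms <- system$atoms
  if (nrow(atoms) == 0) {
    writeLines("END", path)
    return(invisible(path))
  }
  if (any(nchar(atoms$name) > 4))
    mf_stop("mf_format_error", "atom name longer than 4 characters")
  nfr <- n_frames(system)
  xyzm <- matrix(NA_real_, nfr, 3 * nrow(atoms))
  for (f in seq_len(nfr))
    xyzm[f, ] <- as.vector(t(system$xyz[, , f]))
  bio3d::write.pdb(file = path, xyz = xyzm,
                   type = ifelse(atoms$role %in% c("receptor"),
                                 "ATOM", "HETATM"),
                   resno = atoms$resno, resid = atoms$resname,
                   eleno = atoms$serial, elety = atoms$name,
                   chain = atoms$chain, elesy = atoms$element)
  invisible(path)
}

#' Select atoms by role, chain, residue or atom name
#'
#' Conditions are combined with AND; vector-valued conditions match any of
#' their values. The result is ordered by atom serial.
#'
#' @param system a `molsys` object.
#' @param role one or more of receptor, ligand, water, ion, other.
#' @param chain,resname,resno,name,element optional filters.
#' @return Integer vector of atom row indices into `system$atoms`.
#' @export
select_atoms <- function(system, role = NULL, chain = NULL, resname = NULL,
                         resno = NULL, name = NULL, element = NULL) {
  a <- system$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(role)) {
    bad <- setdiff(role, ROLES)
    if (length(bad) > 0)
      mf_stop("mf_selection_error",
              paste0("unknown role(s): ", paste(bad, collapse = ", ")))
    keep <- keep & a$role %in% role
  }
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% toupper(element)
  idx <- which(keep)
  idx[order(a$serial[idx])]
}
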
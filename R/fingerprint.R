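## Trajectory-level aggregation: per-frame contact counts, windowed means,
## amino-acid x oxygen-class matrices, subdomain labels, complex ranking.

#' Run every contact detector on one frame
#'
#' @param system a `molsys` object.
#' @param frame frame index.
#' @param config an [fp_config()].
#' @return List with elements `hbonds`, `water_bridges`, `ionic`,
#'   `cation_bridges`, `hydrophobic`.
#' @export
detect_all_contacts <- function(system, frame = 1L, config = fp_config()) {
  list(
    hbonds = detect_hbonds(system, frame = frame, config = config),
    water_bridges = detect_water_bridges(system, frame, config),
    ionic = detect_ionic_contacts(system, frame, config),
    cation_bridges = detect_cation_bridges(system, frame, config),
    hydrophobic = detect_hydrophobic_contacts(system, frame, config)
  )
}

## ligand-side N/O atom of an h-bond contact row
hbond_ligand_atom <- function(hb) {
  ifelse(hb$acceptor_role == "ligand", hb$acceptor, hb$donor)
}

hbond_receptor_resname <- function(hb) {
  ifelse(hb$acceptor_role == "receptor", hb$acceptor_resname,
         hb$donor_resname)
}

hbond_receptor_resno <- function(hb) {
  ifelse(hb$acceptor_role == "receptor", hb$acceptor_resno, hb$donor_resno)
}

#' Aggregate per-frame contact lists into an interaction fingerprint
#'
#' Counts each contact type per frame, restricts to the analysis window
#' (leading `window_fraction` of the time span excluded, closed on the left),
#' and builds the amino-acid-by-oxygen-class matrices for direct hydrogen
#' bonds and water bridges plus per-amino-acid hydrophobic counts. Direct
#' ionic contacts are the receptor-ligand pairing; ion-mediated ones are
#' counted through the cation bridges. Matrix cells are window totals; the
#' per-frame means are reported alongside.
#'
#' @param contacts_by_frame list (one element per frame) of
#'   [detect_all_contacts()] results.
#' @param times per-frame times (ns); defaults to 0, 1, 2, ...
#' @param config an [fp_config()].
#' @param oxygen_classes ligand class table from [assign_oxygen_classes()]
#'   (may be `NULL`: ligand atoms then label as `"unmapped"`).
#' @return Object of class `interaction_fingerprint`.
#' @export
fp_accumulate <- function(contacts_by_frame, times = NULL,
                          config = fp_config(), oxygen_classes = NULL) {
  nfr <- length(contacts_by_frame)
  if (nfr == 0L)
    mf_stop("mf_aggregation_error", "no frames to accumulate")
  times <- times %||% (seq_len(nfr) - 1)
  if (length(times) != nfr)
    mf_stop("mf_aggregation_error",
            "times and contact lists disagree on frame count")
  direct_ionic <- function(ic) ic[ic$pairing == "ligand-receptor", ,
                                  drop = FALSE]
  per_frame <- data.frame(
    frame = seq_len(nfr),
    time = times,
    hbond = vapply(contacts_by_frame, function(x) nrow(x$hbonds), numeric(1)),
    water_bridge = vapply(contacts_by_frame,
                          function(x) nrow(x$water_bridges), numeric(1)),
    ionic = vapply(contacts_by_frame,
                   function(x) nrow(direct_ionic(x$ionic)), numeric(1)),
    cation_bridge = vapply(contacts_by_frame,
                           function(x) nrow(x$cation_bridges), numeric(1)),
    hydrophobic = vapply(contacts_by_frame,
                         function(x) nrow(x$hydrophobic), numeric(1))
  )
  win <- window_frames(times, config$window_fraction)
  types <- c("hbond", "water_bridge", "ionic", "cation_bridge", "hydrophobic")
  means <- colMeans(per_frame[win, types, drop = FALSE])
  totals <- colSums(per_frame[win, types, drop = FALSE])

  cls_of <- function(atom_idx) {
    if (is.null(oxygen_classes)) return(rep("unmapped", length(atom_idx)))
    cls <- oxygen_classes$class[match(atom_idx, oxygen_classes$atom)]
    cls[is.na(cls)] <- "unmapped"
    cls
  }
  cls_levels <- c(OXYGEN_CLASSES, "unmapped")
  mat_skel <- function() matrix(0L, 0, length(cls_levels),
                                dimnames = list(NULL, cls_levels))
  build_matrix <- function(aa, cls) {
    if (length(aa) == 0L) return(mat_skel())
    tab <- table(factor(aa), factor(cls, levels = cls_levels))
    m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
    m[order(rownames(m)), , drop = FALSE]
  }
  hb_aa <- character(0); hb_cls <- character(0)
  wb_aa <- character(0); wb_cls <- character(0)
  ph_aa <- character(0)
  contact_resnos <- integer(0)
  for (f in win) {
    cf <- contacts_by_frame[[f]]
    hb <- cf$hbonds
    if (nrow(hb) > 0) {
      hb_aa <- c(hb_aa, hbond_receptor_resname(hb))
      hb_cls <- c(hb_cls, cls_of(hbond_ligand_atom(hb)))
      contact_resnos <- c(contact_resnos, hbond_receptor_resno(hb))
    }
    wb <- cf$water_bridges
    if (nrow(wb) > 0) {
      wb_aa <- c(wb_aa, wb$receptor_resname)
      wb_cls <- c(wb_cls, cls_of(wb$ligand_atom))
      contact_resnos <- c(contact_resnos, wb$receptor_resno)
    }
    ph <- cf$hydrophobic
    if (nrow(ph) > 0) {
      ph_aa <- c(ph_aa, ph$receptor_resname)
      contact_resnos <- c(contact_resnos, ph$receptor_resno)
    }
    di <- direct_ionic(cf$ionic)
    if (nrow(di) > 0) {
      rec_no <- ifelse(di$pos_resname %in% c("LYS", "ARG", "HIS"),
                       di$pos_resno, di$neg_resno)
      contact_resnos <- c(contact_resnos, rec_no)
    }
    cb <- cf$cation_bridges
    if (nrow(cb) > 0) contact_resnos <- c(contact_resnos, cb$receptor_resno)
  }
  structure(list(
    per_frame = per_frame,
    window = win,
    means = means,
    totals = totals,
    hbond_matrix = build_matrix(hb_aa, hb_cls),
    water_bridge_matrix = build_matrix(wb_aa, wb_cls),
    hydrophobic_by_residue = if (length(ph_aa) > 0)
      sort(table(ph_aa), decreasing = TRUE) else table(character(0)),
    contact_resnos = sort(unique(contact_resnos)),
    map_version = if (!is.null(oxygen_classes))
      attr(oxygen_classes, "map_version") else NA_character_,
    config = config
  ), class = "interaction_fingerprint")
}

#' Interaction fingerprint of a trajectory
#'
#' Runs all five detectors on every requested frame of a system and
#' aggregates the results with [fp_accumulate()].
#'
#' @param system a `molsys` object.
#' @param config an [fp_config()].
#' @param frames frames to analyse (default all).
#' @param oxygen_map ligand class map (default shipped map).
#' @return An `interaction_fingerprint` object.
#' @export
interaction_fingerprint <- function(system, config = fp_config(),
                                    frames = seq_len(n_frames(system)),
                                    oxygen_map = default_oxygen_class_map()) {
  ox <- assign_oxygen_classes(system, oxygen_map,
                              strict = config$strict_oxygen_map)
  contacts <- lapply(frames, function(f)
    detect_all_contacts(system, f, config))
  fp_accumulate(contacts, system$times[frames], config, ox)
}

#' Albumin subdomain residue ranges
#'
#' The six subdomains of human serum albumin: IA (5-107), IB (108-197),
#' IIA (198-296), IIB (297-382), IIIA (383-494), IIIB (495-569). Residues
#' outside all ranges map to `other`.
#'
#' @return Data frame with columns `label`, `from`, `to` in canonical order.
#' @export
subdomain_ranges <- function() {
  data.frame(label = c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB"),
             from = c(5, 108, 198, 297, 383, 495),
             to = c(107, 197, 296, 382, 494, 569),
             stringsAsFactors = FALSE)
}

subdomain_of <- function(resno, ranges = subdomain_ranges()) {
  out <- rep("other", length(resno))
  for (i in seq_len(nrow(ranges)))
    out[resno >= ranges$from[i] & resno <= ranges$to[i]] <- ranges$label[i]
  out
}

#' Subdomains contacted by a fingerprint
#'
#' Maps the receptor residues participating in at least one contact to their
#' subdomain labels and returns the labels in canonical order (IA, IB, IIA,
#' IIB, IIIA, IIIB); report output hyphen-joins them. Residues outside all
#' ranges yield the label `other` with a warning.
#'
#' @param x an `interaction_fingerprint` or a numeric vector of receptor
#'   residue numbers.
#' @param ranges subdomain table from [subdomain_ranges()].
#' @return Character vector of labels (possibly empty).
#' @export
contacted_subdomains <- function(x, ranges = subdomain_ranges()) {
  resno <- if (inherits(x, "interaction_fingerprint")) x$contact_resnos else x
  if (length(resno) == 0L) return(character(0))
  lab <- subdomain_of(resno, ranges)
  if (any(lab == "other"))
    warning("contact residue(s) outside all subdomain ranges labelled 'other'")
  ordered <- c(ranges$label, "other")
  intersect(ordered, unique(lab))
}

#' Rank complexes by windowed mean binding energy
#'
#' Orders a collection of binding-energy traces by decreasing windowed mean
#' (positive means stronger binding); ties keep input order.
#'
#' @param traces list of `bind_trace` objects (optionally named).
#' @param window_fraction equilibration fraction to exclude.
#' @return Data frame with complex, mean, sd and rank, sorted by rank.
#' @export
rank_complexes <- function(traces, window_fraction = 0.4) {
  if (length(traces) == 0L)
    mf_stop("mf_domain_error", "need at least one trace")
  nm <- names(traces) %||% as.character(seq_along(traces))
  nm[nm == ""] <- as.character(seq_along(traces))[nm == ""]
  st <- t(vapply(traces, trace_statistics, numeric(3),
                 window_fraction = window_fraction))
  ord <- order(-st[, "mean"], seq_along(traces))
  out <- data.frame(complex = nm[ord], mean = st[ord, "mean"],
                    sd = st[ord, "sd"], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.interaction_fingerprint <- function(x, ...) {
  cat("Interaction fingerprint over", nrow(x$per_frame), "frame(s);",
      length(x$window), "in analysis window\n")
  m <- x$means
  cat(sprintf(
    "  window means: H-bonds %.2f | water bridges %.2f | ionic %.2f | cation bridges %.2f | hydrophobic %.2f\n",
    m["hbond"], m["water_bridge"], m["ionic"], m["cation_bridge"],
    m["hydrophobic"]))
  sd_lab <- tryCatch(contacted_subdomains(x), warning = function(w)
    suppressWarnings(contacted_subdomains(x)))
  if (length(sd_lab) > 0)
    cat("  contacted subdomains:", paste(sd_lab, collapse = "-"), "\n")
  invisible(x)
}

#' @export
summary.interaction_fingerprint <- function(object, ...) {
  print(object)
  if (nrow(object$hbond_matrix) > 0) {
    cat("\nH-bond amino-acid x ligand-class matrix (window totals):\n")
    keep <- colSums(object$hbond_matrix) > 0
    print(object$hbond_matrix[, keep, drop = FALSE])
  }
  if (nrow(object$water_bridge_matrix) > 0) {
    cat("\nWater-bridge amino-acid x ligand-class matrix (window totals):\n")
    keep <- colSums(object$water_bridge_matrix) > 0
    print(object$water_bridge_matrix[, keep, drop = FALSE])
  }
  if (length(object$hydrophobic_by_residue) > 0) {
    cat("\nHydrophobic contacts by amino acid (window totals):\n")
    print(object$hydrophobic_by_residue)
  }
  invisible(object)
}

#' @export
plot.interaction_fingerprint <- function(x, ...) {
  pf <- x$per_frame
  types <- c("hbond", "water_bridge", "ionic", "cation_bridge", "hydrophobic")
  cols <- c("black", "steelblue", "firebrick", "darkorange", "forestgreen")
  graphics::matplot(pf$time, as.matrix(pf[, types]), type = "s", lty = 1,
                    col = cols, xlab = "time (ns)", ylab = "contacts / frame",
                    main = "Per-frame interaction counts", ...)
  if (length(x$window) > 0)
    graphics::abline(v = pf$time[min(x$window)], lty = 2, col = "grey40")
  graphics::legend("topleft", legend = types, col = cols, lty = 1, bty = "n",
                   cex = 0.8)
  invisible(x)
}

#' Write fingerprint tables to a directory
#'
#' Emits TSV tables (per-frame counts, the two amino-acid-by-class matrices,
#' hydrophobic counts) and a JSON summary with the window means, totals,
#' subdomain labels, map version and the configuration echo.
#'
#' @param fp an `interaction_fingerprint`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fingerprint <- function(fp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name)
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tsv(fp$per_frame, "per_frame_counts.tsv")
  wm <- function(m) data.frame(amino_acid = rownames(m), m,
                               check.names = FALSE)
  tsv(wm(fp$hbond_matrix), "hbond_matrix.tsv")
  tsv(wm(fp$water_bridge_matrix), "water_bridge_matrix.tsv")
  tsv(data.frame(amino_acid = names(fp$hydrophobic_by_residue),
                 count = as.integer(fp$hydrophobic_by_residue)),
      "hydrophobic_by_residue.tsv")
  subs <- suppressWarnings(contacted_subdomains(fp))
  jsonlite::write_json(list(
    means = as.list(fp$means), totals = as.list(fp$totals),
    n_frames = nrow(fp$per_frame), window_frames = length(fp$window),
    contacted_subdomains = paste(subs, collapse = "-"),
    map_version = fp$map_version,
    config = unclass(fp$config)
  ), file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(dir)
}

#' Amino-acid by ligand-class contact matrix
#'
#' Accessor for the window-total matrices of an interaction fingerprint:
#' rows are receptor amino-acid types, columns the ligand classes O1..O10, N
#' (plus `unmapped`).
#'
#' @param fp an `interaction_fingerprint`.
#' @param type `"hbond"` or `"water_bridge"`.
#' @return Integer matrix.
#' @export
residue_class_matrix <- function(fp, type = c("hbond", "water_bridge")) {
  type <- match.arg(type)
  if (type == "hbond") fp$hbond_matrix else fp$water_bridge_matrix
}
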
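test_that("a planted water with 2.8 Å legs bridges receptor and ligand once", {
  sys <- plant_water_bridge_system(leg = 2.8)
  wb <- detect_water_bridges(sys)
  expect_equal(nrow(wb), 1L)
  expect_equal(wb$leg_receptor, 2.8, tolerance = 1e-9)
  expect_equal(wb$leg_ligand, 2.8, tolerance = 1e-9)
  expect_equal(wb$receptor_resname, "SER")
  expect_equal(wb$ligand_resname, "NAG")
  expect_equal(oracle_water_bridges(sys), 1)
})

test_that("a leg beyond 3 Å kills the bridge; water-free frames are empty", {
  expect_equal(nrow(detect_water_bridges(plant_water_bridge_system(3.2))), 0L)
  expect_equal(nrow(detect_water_bridges(plant_hbond_system())), 0L)
})

test_that("the water-bridge boundary sits exactly at the 3 Å threshold", {
  hit <- function(leg) nrow(detect_water_bridges(
    plant_water_bridge_system(leg))) == 1L
  boundary <- bisect_boundary(hit, 2.9, 3.1, tol = 1e-7)
  expect_equal(boundary, 3.0, tolerance = 1e-6)
})

test_that("waters without hydrogens raise the typed error", {
  sys <- plant_water_bridge_system()
  keep <- which(!(sys$atoms$role == "water" & sys$atoms$element == "H"))
  bare <- tiny_system(sys$atoms$name[keep], sys$atoms$resname[keep],
                      sys$atoms$element[keep], sys$atoms$role[keep],
                      sys$atoms$resno[keep], sys$xyz[keep, , 1])
  expect_error(detect_water_bridges(bare), class = "mf_missing_hydrogens")
})

test_that("ionic adjusted-distance arithmetic matches hand evaluation", {
  ## radii summing 2.75: raw 4.2 gives adjusted 1.45 (contact);
  ## raw 4.35 gives adjusted 1.6 (no contact)
  cfg <- fp_config(hbond_radii = c(N = 1.05, O = 1.70, C = 1.80, CL = 1.70,
                                   NA. = 1.00, MG = 0.85, CA = 1.10,
                                   K = 1.33))
  sys <- plant_ionic_system(adjusted = 1.45, config = cfg)
  ic <- detect_ionic_contacts(sys, config = cfg)
  direct <- ic[ic$pairing == "ligand-receptor", ]
  expect_equal(nrow(direct), 1L)
  expect_equal(direct$adj_dist, 1.45, tolerance = 1e-9)
  expect_equal(direct$raw_dist, 4.2, tolerance = 1e-9)
  expect_equal(nrow(detect_ionic_contacts(
    plant_ionic_system(adjusted = 1.6, config = cfg), config = cfg)), 0L)
})

test_that("ionic detection is inclusive at both range ends and only there", {
  hit <- function(adj) {
    ic <- detect_ionic_contacts(plant_ionic_system(adjusted = adj))
    sum(ic$pairing == "ligand-receptor") == 1L
  }
  upper <- bisect_boundary(hit, 1.4, 1.7, tol = 1e-7)
  expect_equal(upper, 1.5, tolerance = 1e-6)
  expect_true(hit(0))
  expect_false(hit(-0.05))
})

test_that("systems with only like charges have no ionic contacts", {
  sys <- plant_ionic_system()
  cations_only <- sys$atoms$role != "ligand"
  bare <- tiny_system(sys$atoms$name[cations_only],
                      sys$atoms$resname[cations_only],
                      sys$atoms$element[cations_only],
                      sys$atoms$role[cations_only],
                      sys$atoms$resno[cations_only],
                      sys$xyz[cations_only, , 1])
  expect_equal(nrow(detect_ionic_contacts(bare)), 0L)
})

test_that("ionic detector agrees with the independent centre enumeration", {
  for (seed in c(6, 17)) {
    pc <- make_planted_complex(seed = seed, n_ionic = 3, n_cation_bridge = 2,
                               cation_species = c("CA", "MG"), n_decoys = 3)
    got <- detect_ionic_contacts(pc$system)
    or <- oracle_ionic(pc$system)
    expect_equal(nrow(got), nrow(or))
    expect_equal(sort(got$adj_dist), sort(or$adjusted), tolerance = 1e-9)
    expect_equal(table(got$pairing), table(or$pairing))
  }
})

test_that("cation bridges need simultaneous contact on both sides", {
  cb <- detect_cation_bridges(plant_cation_bridge_system("CA"))
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$species, "CA")
  expect_equal(cb$receptor_resname, "GLU")
  expect_equal(cb$ligand_resname, "GCU")
  ## in range of the ligand only: no bridge
  one_sided <- plant_cation_bridge_system("CA", adjusted_receptor = 2.5)
  expect_equal(nrow(detect_cation_bridges(one_sided)), 0L)
})

test_that("every centre pair around a shared cation becomes its own bridge", {
  base <- plant_cation_bridge_system("CA")
  ion <- which(base$atoms$role == "ion")
  p <- base$xyz[ion, , 1]
  ## second glutamate on the opposite side of the ion, same adjusted range
  raw <- 0.75 + 1.10 + 1.70
  g2 <- p + raw * c(0, 1, 0)
  extra <- tiny_system(c("OE1", "OE2"), c("GLU", "GLU"), c("O", "O"),
                       c("receptor", "receptor"), c(9, 9),
                       rbind(g2 + c(0, 0, 1.082), g2 - c(0, 0, 1.082)))
  atoms <- rbind(base$atoms[, 1:7], extra$atoms[, 1:7])
  atoms$serial <- seq_len(nrow(atoms))
  atoms$resno[atoms$resname == "GLU"][3:4] <- 2
  sys <- tiny_system(atoms$name, atoms$resname, atoms$element, atoms$role,
                     atoms$resno, rbind(base$xyz[, , 1], extra$xyz[, , 1]))
  cb <- detect_cation_bridges(sys)
  expect_equal(nrow(cb), 2L)
  expect_equal(length(unique(cb$cation_resuid)), 1L)
})

test_that("each cation bridge decomposes into two ionic contacts of its ion", {
  pc <- make_planted_complex(seed = 13, n_cation_bridge = 3,
                             cation_species = c("CA", "MG", "CA"))
  cb <- detect_cation_bridges(pc$system)
  ic <- detect_ionic_contacts(pc$system)
  for (ion in unique(cb$cation_resuid)) {
    expect_gte(sum(ic$pos_resuid == ion & ic$pairing == "ion-receptor"), 1L)
    expect_gte(sum(ic$pos_resuid == ion & ic$pairing == "ion-ligand"), 1L)
  }
})

test_that("sodium bridges are excluded by default and included on request", {
  sys <- plant_cation_bridge_system("NA")
  expect_equal(nrow(detect_cation_bridges(sys)), 0L)
  expect_equal(nrow(detect_cation_bridges(sys, species = c("NA", "CA"))), 1L)
})

test_that("hydrophobic contacts respect classes, cutoff and the Calpha rule", {
  sys <- plant_hydrophobic_system(dist = 4.0)
  ph <- detect_hydrophobic_contacts(sys)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$receptor_class, "CH3")
  expect_equal(ph$ligand_class, "CH3")
  expect_equal(ph$dist, 4.0, tolerance = 1e-9)
  expect_equal(nrow(detect_hydrophobic_contacts(
    plant_hydrophobic_system(4.8))), 0L)
  ## an alanine alpha carbon at contact range is invisible
  ala_ca <- plant_hydrophobic_system(3.5)
  ala_ca$atoms$name[ala_ca$atoms$resname == "ALA"] <- "CA"
  expect_equal(nrow(detect_hydrophobic_contacts(ala_ca)), 0L)
  ## but a glycine alpha carbon is not
  gly_ca <- plant_hydrophobic_system(3.5)
  sel <- gly_ca$atoms$resname == "ALA"
  gly_ca$atoms$resname[sel] <- "GLY"
  gly_ca$atoms$name[sel] <- "CA"
  expect_equal(nrow(detect_hydrophobic_contacts(gly_ca)), 1L)
  expect_equal(oracle_hydrophobic(gly_ca), 1)
})

test_that("all detectors recover exact planted inventories across seeds", {
  for (seed in c(1, 7, 23, 40)) {
    pc <- make_planted_complex(n_hbond = 2, n_water_bridge = 2, n_ionic = 1,
                               n_cation_bridge = 2,
                               cation_species = c("CA", "MG"),
                               n_hydrophobic = 2, n_decoys = 5, seed = seed)
    expect_equal(detected_counts(pc$system), pc$truth$counts)
  }
})
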
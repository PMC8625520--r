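test_that("protonation defaults at pH 7.4 give the textbook residue charges", {
  glu <- assign_protonation("GLU", c("CB", "CG", "CD", "OE1", "OE2"))
  expect_equal(sum(glu), -1)
  lys <- assign_protonation("LYS", c("CE", "NZ", "HZ1"))
  expect_equal(unname(lys["NZ"]), 1)
  expect_equal(sum(lys), 1)
  expect_equal(sum(assign_protonation("HOH", c("O", "H1", "H2"))), 0)
  expect_equal(sum(assign_protonation("GCU",
                                      c("C6", "O6A", "O6B", "O2"))), -1)
  expect_equal(sum(assign_protonation("HIS", c("ND1", "NE2"))), 0)
  expect_equal(sum(assign_protonation("HIS", c("ND1", "NE2"),
                                      his_protonated = TRUE)), 1)
  expect_equal(sum(assign_protonation("CA", "CA")), 2)
  expect_equal(sum(assign_protonation("CL", "CL")), -1)
  expect_error(assign_protonation("XYZ", "C1"), class = "mf_typing_error")
})

test_that("system formal charge is the sum over residues and neutral mixes cancel", {
  pc <- make_planted_complex(seed = 2)
  sys <- assign_charges(pc$system)
  by_res <- tapply(sys$atoms$charge, sys$atoms$resuid, sum)
  expect_equal(sum(sys$atoms$charge), sum(by_res))
  ## integral per residue
  expect_true(all(abs(by_res - round(by_res)) < 1e-12))
  ## a planted +2/-1/-1 triple is itself neutral: ion + GLU + GCU carboxylate
  cb <- assign_charges(plant_cation_bridge_system("CA"))
  a <- cb$atoms
  sel <- a$resname %in% c("CA", "GLU") | (a$resname == "GCU")
  expect_equal(sum(a$charge[sel]) + 0, 2 - 1 - 1 + 0)
})

test_that("water and sugar donors/acceptors carry the expected flags", {
  wat <- mdfinger:::assemble_system(mdfinger:::frag_water("W1"))
  da <- find_donors_acceptors(wat)
  expect_length(da$acceptors, 1L)
  expect_length(da$donors, 1L)
  expect_equal(nrow(da$donor_hydrogens), 2L)

  lig <- toy_disaccharide_system()
  da <- find_donors_acceptors(lig)
  a <- lig$atoms
  ## hydroxyl oxygen: both donor and acceptor
  o2 <- which(a$resname == "GCU" & a$name == "O2")
  expect_true(o2 %in% da$donors)
  expect_true(o2 %in% da$acceptors)
  ## amide nitrogen: both donor and acceptor
  n2 <- which(a$resname == "NAG" & a$name == "N2")
  expect_true(n2 %in% da$donors)
  expect_true(n2 %in% da$acceptors)
  ## ring oxygen: acceptor only
  o5 <- which(a$resname == "NAG" & a$name == "O5")
  expect_true(o5 %in% da$acceptors)
  expect_false(o5 %in% da$donors)
  ## every donor heavy atom is N or O
  expect_true(all(a$element[da$donors] %in% c("N", "O")))
})

test_that("donor perception without hydrogens raises the typed error", {
  lig <- toy_disaccharide_system()
  heavy <- select_atoms(lig, element = c("C", "N", "O"))
  expect_error(find_donors_acceptors(lig, idx = heavy),
               class = "mf_missing_hydrogens")
})

test_that("hydrophobic carbon classes follow the three-subcategory rules", {
  expect_equal(unname(classify_hydrophobic_carbons("ALA", "CB")), "CH3")
  expect_equal(unname(classify_hydrophobic_carbons("ALA", "CA")), "none")
  expect_equal(unname(classify_hydrophobic_carbons("GLY", "CA")), "CH2/CH")
  expect_equal(unname(classify_hydrophobic_carbons("PHE", "CD1")),
               "aromatic-CH")
  expect_equal(unname(classify_hydrophobic_carbons("LEU", "CG")), "CH2/CH")
  expect_equal(unname(classify_hydrophobic_carbons("VAL", "CG1")), "CH3")
  expect_equal(unname(classify_hydrophobic_carbons("NAG", "C8")), "CH3")
  ## unknown atoms are none, never an error
  expect_equal(unname(classify_hydrophobic_carbons("ALA", "CQ")), "none")
  ## totality: every template carbon resolves to exactly one class
  for (rn in names(mdfinger:::HYDROPHOBIC_CLASSES)) {
    cls <- mdfinger:::HYDROPHOBIC_CLASSES[[rn]]
    if (length(cls) > 0)
      expect_true(all(cls %in% c("CH3", "CH2/CH", "aromatic-CH")),
                  label = rn)
  }
})

test_that("charge centres sit on the defining atoms or midpoints", {
  lys <- charge_center("LYS", c("CE", "NZ"),
                       rbind(c(0, 0, 0), c(1.3, 0.2, -0.4)))
  expect_equal(lys$point, c(1.3, 0.2, -0.4))
  expect_equal(lys$charge, 1)
  expect_equal(lys$element, "N")

  glu <- charge_center("GLU", c("OE1", "OE2"),
                       rbind(c(0, 1.08, 0), c(0, -1.08, 0)))
  expect_equal(glu$point, c(0, 0, 0))
  expect_equal(glu$charge, -1)

  ca <- charge_center("CA", "CA", rbind(c(2, 3, 4)))
  expect_equal(ca$charge, 2)
  expect_equal(ca$point, c(2, 3, 4))

  expect_error(charge_center("ALA", "CB", rbind(c(0, 0, 0))),
               class = "mf_no_center")
  expect_error(charge_center("HIS", c("ND1", "NE2"),
                             rbind(c(0, 0, 0), c(1, 0, 0))),
               class = "mf_no_center")
})

test_that("the shipped oxygen-class map covers every ligand N/O atom", {
  lig <- toy_disaccharide_system()
  cls <- assign_oxygen_classes(lig, strict = TRUE)
  no_atoms <- select_atoms(lig, role = "ligand", element = c("N", "O"))
  expect_setequal(cls$atom, no_atoms)
  expect_true(all(cls$class %in% c(paste0("O", 1:10), "N")))
  ## carboxylate oxygens share the carboxylate class
  carbox <- cls$class[cls$resname == "GCU" & cls$name %in% c("O6A", "O6B")]
  expect_equal(unique(carbox), "O4")
  ## amide nitrogen is class N
  expect_equal(cls$class[cls$resname == "NAG" & cls$name == "N2"], "N")
  expect_equal(attr(cls, "map_version"), "mdfinger-map-1")
})

test_that("strict mode rejects unmapped ligand N/O atoms", {
  lig <- toy_disaccharide_system()
  partial <- default_oxygen_class_map()
  partial <- partial[partial$atom != "N2", ]
  expect_error(assign_oxygen_classes(lig, partial, strict = TRUE),
               class = "mf_incomplete_map")
  lenient <- assign_oxygen_classes(lig, partial, strict = FALSE)
  expect_true("unmapped" %in% lenient$class)
})
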
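test_that("PDB reading applies the altloc and model policies", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.60 10.00           N",
    "ATOM      2  N  BALA A   1       1.000   0.000   0.000  0.40 10.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "HETATM    4 FE    FE A   2       5.000   0.000   0.000  1.00 10.00          FE",
    "ENDMDL",
    "ATOM      5  N   ALA A   9      99.000  99.000  99.000  1.00 10.00           N")
  m <- read_structure(text = lines)
  # first model only: the post-ENDMDL atom is dropped
  expect_false(9 %in% m$resno)
  # altloc A (occupancy 0.6) wins over B
  n1 <- m[m$atom_name == "N" & m$resno == 1, ]
  expect_equal(nrow(n1), 1)
  expect_equal(n1$x, 0)
  # metal HETATM retained
  expect_true(any(m$het & m$element == "FE"))
})

test_that("PDB reading rejects empty and malformed input", {
  expect_error(read_structure(text = "REMARK nothing"), "no ATOM")
  bad <- "ATOM      1  N   ALA A   1       x.xxx   0.000   0.000  1.00 10.00           N"
  expect_error(read_structure(text = bad), "line 1")
})

test_that("toy helix structures round-trip through PDB files", {
  m <- make_toy_structure(8, with_metal_site = TRUE)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  back <- read_structure(path)
  expect_equal(back[, c("x", "y", "z")], m[, c("x", "y", "z")])
  expect_equal(back$resno, m$resno)
  expect_equal(back$atom_name, m$atom_name)
})

test_that("toy helix has ideal alpha-helix geometry", {
  m <- make_toy_structure(12)
  ca <- as.matrix(m[m$atom_name == "CA", c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.1))
  # i -> i+4 backbone hydrogen bonds along the whole helix
  ints <- detect_interactions(m)
  hb4 <- ints[ints$atom1 == "O" & ints$atom2 == "N" &
                ints$resno2 - ints$resno1 == 4, ]
  expect_equal(hb4$resno1, 1:8)
  expect_true(all(hb4$distance > 2.6 & hb4$distance < 3.3))
})

test_that("active-site distances reduce to the exhaustive pair minimum", {
  m <- atom_model(x = c(0, 3, 10), y = c(0, 4, 0), z = c(0, 0, 0))
  site <- active_site(m, serials = c(2, 3))
  # 3-4-5 triangle
  expect_equal(min_distance_to_active_site(m, 1, site), 5)
  # coincident atoms give zero
  m2 <- atom_model(x = c(0, 0), y = c(0, 0), z = c(0, 0))
  expect_equal(min_distance_to_active_site(m2, 1, active_site(m2, serials = 2)), 0)
  # residue's own atoms excluded from the site; fully-own site errors
  expect_error(min_distance_to_active_site(m2, 1, active_site(m2, serials = 1)),
               "empty")
  # multi-atom case equals brute force
  helix <- make_toy_structure(10, with_metal_site = TRUE, metal_residue = 5)
  s <- active_site(helix, elements = "FE")
  fe <- as.numeric(helix[helix$element == "FE", c("x", "y", "z")])
  for (r in c(2, 5, 8)) {
    atoms <- as.matrix(helix[helix$resno == r & !helix$het, c("x", "y", "z")])
    brute <- min(sqrt(colSums((t(atoms) - fe)^2)))
    expect_equal(min_distance_to_active_site(helix, r, s), brute)
  }
})

test_that("SASA matches closed forms for isolated and paired atoms", {
  m1 <- atom_model(0, 0, 0)
  s1 <- shrake_rupley_sasa(m1, radii = c(C = 1.9))
  expect_equal(s1$total, 4 * pi * (1.9 + 1.4)^2, tolerance = 0.005)
  # two fully separated atoms: each equals the isolated value
  m2 <- atom_model(c(0, 50), c(0, 0), c(0, 0))
  s2 <- shrake_rupley_sasa(m2)
  iso <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(s2$atom_sasa, c(iso, iso), tolerance = 1e-9)
  # overlapping pair matches the analytic two-cap formula within 2%
  for (dd in c(1.0, 2.0, 3.0, 4.5)) {
    m3 <- atom_model(c(0, dd), c(0, 0), c(0, 0))
    s3 <- shrake_rupley_sasa(m3)
    expect_equal(s3$total, two_sphere_area(3.1, 3.1, dd),
                 tolerance = 0.02)
  }
  expect_error(shrake_rupley_sasa(atom_model(0, 0, 0, element = "QQ")),
               "QQ")
})

test_that("residue SASA sums to the structure total and converges", {
  m <- make_toy_structure(8)
  s <- shrake_rupley_sasa(m, n_points = 240)
  expect_equal(sum(s$residue_sasa$sasa), s$total, tolerance = 1e-6)
  s4 <- shrake_rupley_sasa(m, n_points = 960)
  s16 <- shrake_rupley_sasa(m, n_points = 3840)
  expect_lt(abs(s16$total - s4$total), abs(s4$total - s$total))
})

test_that("location classes follow the relative-SASA thresholds", {
  mx <- c(A = 100)
  expect_equal(classify_location(60, "A", mx)$location_class, "surface")
  expect_equal(classify_location(5, "A", mx)$location_class, "core")
  expect_equal(classify_location(10, "A", mx)$location_class, "core")    # boundary inclusive
  expect_equal(classify_location(25, "A", mx)$location_class, "surface") # boundary inclusive
  expect_equal(classify_location(15, "A", mx)$location_class, "intermediate")
  expect_error(classify_location(10, "B", mx), "table entry")
})

test_that("hydrogen bonds and salt bridges follow their cutoffs", {
  base <- make_toy_structure(4, sequence = "KAAE")
  # Lys NZ 3.8 A from Glu OE1 -> salt bridge; 4.2 A -> none
  for (d in c(3.8, 4.2)) {
    m <- add_atoms(base, data.frame(
      atom_name = c("NZ", "OE1"), resno = c(1L, 4L),
      x = c(50, 50 + d), y = c(50, 50), z = c(50, 50),
      element = c("N", "O")))
    ints <- detect_interactions(m)
    sb <- ints[ints$type == "salt_bridge", ]
    if (d <= 4.0) {
      expect_equal(nrow(sb), 1)
      expect_equal(sb$distance, d)
      expect_true(sb$sidechain1 && sb$sidechain2)
    } else {
      expect_equal(nrow(sb), 0)
    }
  }
  # two backbone O/N at 2.9 A in non-adjacent residues -> one H-bond;
  # the peptide-bond O(i)-N(i+1) pair is excluded
  ints0 <- detect_interactions(base)
  expect_false(any(ints0$atom1 == "O" & ints0$atom2 == "N" &
                     ints0$resno2 - ints0$resno1 == 1))
})

test_that("design filters reject by rule with evidence attached", {
  demo <- make_filter_demo()
  v <- apply_design_filters(demo$candidates, demo$model, demo$site)

  expect_equal(sum(v$verdict == "accepted"), 10)
  rej <- v[v$verdict == "rejected", ]
  expect_equal(nrow(rej), 4)
  expect_setequal(rej$rejection_rules,
                  c("active_site_proximity", "hydrophobicity_mismatch",
                    "hydrophobicity_mismatch", "interaction_loss"))
  # every rejection carries evidence; accepted candidates carry none
  expect_true(all(nzchar(rej$evidence)))
  expect_true(all(!nzchar(v$evidence[v$verdict == "accepted"])))
  # rule 1 evidence: the 4.2 A candidate
  r1 <- rej[rej$rejection_rules == "active_site_proximity", ]
  expect_equal(r1$mutation, "N10D")
  expect_lt(r1$min_active_site_distance, 5)
  # order independence
  perm <- sample(nrow(demo$candidates))
  v2 <- apply_design_filters(demo$candidates[perm, ], demo$model, demo$site)
  v2 <- v2[match(v$mutation, v2$mutation), ]
  expect_equal(v2$verdict, v$verdict)
  expect_equal(v2$rejection_rules, v$rejection_rules)
})

test_that("filters fail loudly on unmappable or mismatched positions", {
  demo <- make_filter_demo()
  bad <- demo$candidates
  bad$target_position[1] <- 99L
  expect_error(apply_design_filters(bad, demo$model, demo$site), "99")
  wrongwt <- demo$candidates
  wrongwt$target_aa[5] <- "W"
  expect_error(apply_design_filters(wrongwt, demo$model, demo$site),
               "numbering offset")
})
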
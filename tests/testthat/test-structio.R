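test_that("benzene SDF parses to an aromatic six-ring of heavy atoms", {
  bz <- read_ligand(benzene_sdf())
  expect_equal(n_atoms(bz), 6)
  expect_equal(nrow(bz$bonds), 6)
  expect_true(all(bz$atoms$aromatic))
  expect_true(all(bz$atoms$in_ring))
  expect_true(all(bz$atoms$num_h == 1))
  expect_false(any(bz$atoms$is_protein))
})

test_that("unreadable ligand files raise a parse error naming the file", {
  empty <- tempfile(fileext = ".sdf")
  writeLines("", empty)
  expect_error(read_ligand(empty), "cannot parse ligand file")
  expect_error(read_ligand(tempfile(fileext = ".sdf")), "not found")
})

test_that("mol2 ligands parse with SYBYL-derived annotations", {
  path <- tempfile(fileext = ".mol2")
  writeLines(c(
    "@<TRIPOS>MOLECULE", "ethanol", " 3 2 0 0 0", "SMALL", "NO_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 C1  0.000 0.000 0.000 C.3",
    "  2 C2  1.500 0.000 0.000 C.3",
    "  3 O1  2.250 1.300 0.000 O.3",
    "@<TRIPOS>BOND",
    "  1 1 2 1",
    "  2 2 3 1"
  ), path)
  m <- read_ligand(path)
  expect_equal(n_atoms(m), 3)
  expect_equal(m$atoms$element, c("C", "C", "O"))
  expect_equal(m$atoms$hybridization, rep("sp3", 3))
  expect_equal(m$atoms$num_h, c(3L, 2L, 1L))
})

test_that("pocket reading drops waters and keeps metal ions", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.200   1.300   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.600   2.400   0.000  1.00  0.00           O",
    "HETATM    5  O   HOH A 101      8.000   8.000   8.000  1.00  0.00           O",
    "END"
  ), path)
  poc <- read_pocket(path)
  expect_equal(n_atoms(poc), 4)
  expect_true(all(poc$atoms$is_protein))
  expect_equal(unique(poc$atoms$residue_name), "GLY")

  zn_path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "HETATM    2 ZN    ZN A 200       5.000   0.000   0.000  1.00  0.00          ZN",
    "END"
  ), zn_path)
  poc2 <- read_pocket(zn_path)
  expect_true("Zn" %in% poc2$atoms$element)
  expect_equal(poc2$atoms$degree[poc2$atoms$element == "Zn"], 0L)
})

test_that("affinity conversion follows -log10 molar with interchangeable kinds", {
  expect_equal(affinity_to_pk(1e-6, "M", "Kd"), 6)
  expect_equal(affinity_to_pk(1, "nM", "Ki"), 9)
  expect_equal(affinity_to_pk(50, "uM", "IC50"), 4.30103, tolerance = 1e-5)
  expect_error(affinity_to_pk(0, "M", "Kd"), "positive")
  expect_error(affinity_to_pk(-1, "M", "Kd"), "positive")
  # strictly decreasing; one log-unit per decade
  v <- sort(stats::runif(20, 1e-9, 1))
  pk <- vapply(v, affinity_to_pk, numeric(1), unit = "M", kind = "Kd")
  expect_true(all(diff(pk) < 0))
  for (x in v) {
    expect_equal(affinity_to_pk(10 * x, "M", "Kd"),
                 affinity_to_pk(x, "M", "Kd") - 1)
  }
})

test_that("index parsing handles comments, kinds, years and duplicates", {
  path <- tempfile()
  writeLines(c(
    "# PDBbind-style index",
    "1eby  2.00  1998  8.10  Ki=8nM  // HIV protease",
    "2xyz  1.80  2020  5.25  IC50=5.6uM",
    "3abc  2.50  2015  6.00"
  ), path)
  recs <- parse_index(path)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$complex_id[1], "1eby")
  expect_equal(recs$label_pk[1], 8.10)
  expect_equal(recs$deposit_year[1], 1998L)
  expect_equal(recs$measure_kind[1:2], c("Ki", "IC50"))

  writeLines("# only comments", path)
  expect_equal(nrow(parse_index(path)), 0)

  writeLines(c("1aaa 2.0 2001 4.5", "1aaa 2.0 2001 5.5"), path)
  expect_warning(dup <- parse_index(path), "duplicated")
  expect_equal(nrow(dup), 1)
  expect_equal(dup$label_pk, 5.5) # last occurrence wins

  writeLines("1aaa 2.0", path)
  expect_error(parse_index(path), "line 1")
})

test_that("SDF round trips preserve atoms, bonds and annotations", {
  for (seed in c(3, 14, 27)) {
    lig <- gen_ligand(seed, 18)
    path <- tempfile(fileext = ".sdf")
    write_sdf(lig, path)
    lig2 <- read_ligand(path)
    expect_equal(n_atoms(lig2), n_atoms(lig))
    expect_equal(
      sort(paste(lig2$bonds$i, lig2$bonds$j, lig2$bonds$order)),
      sort(paste(lig$bonds$i, lig$bonds$j, lig$bonds$order))
    )
    expect_equal(lig2$atoms$num_h, lig$atoms$num_h)
    expect_equal(lig2$atoms$formal_charge, lig$atoms$formal_charge)
    expect_equal(lig2$atoms$aromatic, lig$atoms$aromatic)
  }
})

test_that("molecule invariants are enforced", {
  atoms <- data.frame(element = c("C", "C"), x = 0:1, y = 0, z = 0)
  expect_error(
    Molecule(atoms, data.frame(i = 1, j = 1, order = "single")),
    "self-bond"
  )
  expect_error(
    Molecule(atoms, data.frame(i = c(1, 2), j = c(2, 1),
                               order = c("single", "single"))),
    "duplicate"
  )
  expect_error(
    Molecule(atoms, data.frame(i = 1, j = 3, order = "single")),
    "invalid atom"
  )
  atoms$x[1] <- NA
  expect_error(Molecule(atoms, data.frame(i = 1, j = 2, order = "single")),
               "non-finite")
})
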
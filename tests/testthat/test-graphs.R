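test_that("complex node features are 41-long with the documented layout", {
  bz <- read_ligand(benzene_sdf())
  f <- featurize_atom_complex(bz$atoms)
  expect_equal(dim(f), c(6, 41))
  # aromatic ring carbon, ligand side
  expect_equal(f[1, 1], 1) # element block starts with C
  expect_equal(sum(f[1, 1:17]), 1)
  expect_equal(f[1, 39], 1) # aromatic flag
  expect_equal(f[1, 41], 1) # is-ligand flag
  # all benzene carbons identical
  expect_true(all(apply(f, 2, function(col) length(unique(col)) == 1)))

  zn <- single_atom_molecule("Zn", is_protein = TRUE, residue_name = "ZN",
                             atom_name = "ZN", charge = 2)
  fz <- featurize_atom_complex(zn$atoms)
  expect_equal(fz[1, 13], 1)            # Zn slot of the element vocabulary
  expect_equal(fz[1, 18], 1)            # degree one-hot at 0
  expect_equal(fz[1, 24], 2)            # formal charge as real value
  expect_equal(fz[1, 41], 0)            # protein side
  # one-hot blocks sum to exactly one
  blocks <- list(1:17, 18:23, 25:27, 28:32, 33:38)
  for (b in blocks) expect_equal(sum(fz[1, b]), 1)
})

test_that("complex edge features are 21-long with a mirror-symmetric RBF", {
  f <- featurize_edge_complex(TRUE, "aromatic", TRUE, TRUE, 1.39)
  expect_equal(dim(f), c(1, 21))
  expect_equal(f[1, 1], 1) # covalent
  expect_equal(f[1, 5], 1) # aromatic slot
  expect_equal(which.max(f[1, 8:21]), 2) # RBF peaks at the 1.5 A center
  # centers are evenly spaced on [1, 7.5], so the two endpoint responses
  # are reverses of each other
  lo <- featurize_edge_complex(FALSE, NA, FALSE, FALSE, 1.0)[1, 8:21]
  hi <- featurize_edge_complex(FALSE, NA, FALSE, FALSE, 7.5)[1, 8:21]
  expect_equal(lo, rev(hi), tolerance = 1e-12)
  expect_error(featurize_edge_complex(FALSE, NA, FALSE, FALSE, NaN),
               "non-finite")
})

test_that("ligand node features are 27-long and clamp out-of-range values", {
  m <- single_atom_molecule("C")
  f <- featurize_atom_ligand(m$atoms)
  expect_equal(dim(f), c(1, 27))
  expect_equal(f[1, 11], 1) # degree 0
  expect_equal(f[1, 22], 1) # num_h clamps at the 4 slot (methane carbon)
  bz <- read_ligand(benzene_sdf())
  fb <- featurize_atom_ligand(bz$atoms)
  expect_true(all(apply(fb, 2, function(col) length(unique(col)) == 1)))
})

test_that("two-atom complexes respect the contact cutoff", {
  p <- single_atom_molecule("C", 0, 0, 0, is_protein = TRUE,
                            residue_name = "GLY", atom_name = "CA")
  l3 <- single_atom_molecule("C", 3, 0, 0)
  g <- build_complex_graph(p, l3)
  expect_equal(g$num_nodes, 2)
  expect_equal(nrow(g$edges), 2) # one intermolecular contact, two directions
  expect_equal(sort(g$edges[, 1]), c(1, 2))

  l6 <- single_atom_molecule("C", 6, 0, 0)
  expect_warning(g0 <- build_complex_graph(p, l6), "no intermolecular")
  expect_equal(nrow(g0$edges), 0)
})

test_that("ligand graphs double every covalent bond and carry no edge features", {
  m <- single_atom_molecule("C")
  g1 <- build_ligand_graph(m)
  expect_equal(g1$num_nodes, 1)
  expect_equal(nrow(g1$edges), 0)

  bz <- read_ligand(benzene_sdf())
  gb <- build_ligand_graph(bz)
  expect_equal(gb$num_nodes, 6)
  expect_equal(nrow(gb$edges), 12)
  expect_null(gb$edge_features)
  expect_equal(ncol(gb$node_features), 27)
})

test_that("graph dimensions hold for arbitrary synthetic complexes", {
  ds <- small_dataset(4, seed = 21)
  for (cx in ds$complexes) {
    g <- build_complex_graph(cx$pocket, cx$ligand)
    expect_equal(ncol(g$node_features), 41)
    expect_equal(ncol(g$edge_features), 21)
    expect_true(all(is.finite(g$node_features)))
    expect_true(all(is.finite(g$edge_features)))
    expect_equal(nrow(g$edges) %% 2, 0) # symmetric construction
    gl <- build_ligand_graph(cx$ligand)
    expect_equal(ncol(gl$node_features), 27)
  }
})

test_that("intermolecular edges equal the brute-force all-pairs rule", {
  ds <- small_dataset(3, seed = 31)
  for (cx in ds$complexes) {
    g <- build_complex_graph(cx$pocket, cx$ligand, contact_cutoff = 5)
    inter <- g$edge_features[, 1] == 0
    np <- n_atoms(cx$pocket)
    got <- g$edges[inter & g$edges[, 1] <= np, , drop = FALSE]
    # independent O(n*m) double loop
    want <- NULL
    pc <- coords(cx$pocket); lc <- coords(cx$ligand)
    for (i in seq_len(nrow(pc))) {
      for (j in seq_len(nrow(lc))) {
        if (sqrt(sum((pc[i, ] - lc[j, ])^2)) <= 5) {
          want <- rbind(want, c(i, np + j))
        }
      }
    }
    expect_equal(
      sort(paste(got[, 1], got[, 2])),
      sort(paste(want[, 1], want[, 2]))
    )
  }
})

test_that("enlarging the contact cutoff never removes edges", {
  ds <- small_dataset(2, seed = 41)
  cx <- ds$complexes[[1]]
  cuts <- c(3, 4, 5, 6.5)
  counts <- vapply(cuts, function(ct) {
    nrow(suppressWarnings(build_complex_graph(cx$pocket, cx$ligand, ct))$edges)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("relabeling atoms yields an isomorphic featurized graph", {
  ds <- small_dataset(2, seed = 51)
  cx <- ds$complexes[[1]]
  g <- build_ligand_graph(cx$ligand)
  set.seed(9)
  newpos <- sample(g$num_nodes)
  g2 <- g
  g2$node_features[newpos, ] <- g$node_features
  g2$edges <- matrix(newpos[g$edges], ncol = 2)
  # multiset of node rows and of (src-feature, dst-feature) pairs unchanged
  expect_equal(
    sort(apply(g$node_features, 1, paste, collapse = ",")),
    sort(apply(g2$node_features, 1, paste, collapse = ","))
  )
  pair_key <- function(gr) {
    sort(paste(
      apply(gr$node_features[gr$edges[, 1], , drop = FALSE], 1, paste, collapse = ","),
      apply(gr$node_features[gr$edges[, 2], , drop = FALSE], 1, paste, collapse = ",")
    ))
  }
  expect_equal(pair_key(g), pair_key(g2))
})

test_that("graphs round-trip through the serialization container", {
  ds <- small_dataset(1, seed = 61)
  g <- build_complex_graph(ds$complexes[[1]]$pocket, ds$complexes[[1]]$ligand)
  path <- tempfile(fileext = ".rds")
  write_graph(g, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$tag, "complex")
  expect_equal(side$node_dim, 41L)
  g2 <- read_graph(path)
  expect_equal(g2, g)
  # version mismatch refused
  bad <- g
  bad$featurization <- "other-version"
  saveRDS(bad, path)
  expect_error(read_graph(path), "version mismatch")
})
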
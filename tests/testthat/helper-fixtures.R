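# Shared fixtures, built in code at test time.

benzene_sdf <- function() {
  path <- tempfile(fileext = ".sdf")
  writeLines(c(
    "benzene", "  fixture", "",
    "  6  6  0  0  0  0  0  0  0  0999 V2000",
    sprintf("%10.4f%10.4f%10.4f C   0  0  0  0  0  0  0  0  0  0  0  0",
            1.39 * cos(2 * pi * (0:5) / 6), 1.39 * sin(2 * pi * (0:5) / 6),
            rep(0, 6)),
    sprintf("%3d%3d  4  0  0  0  0", 1:6, c(2:6, 1)),
    "M  END", "$$$$"
  ), path)
  path
}

# one-atom Molecule helpers
single_atom_molecule <- function(element = "C", x = 0, y = 0, z = 0,
                                 is_protein = FALSE, residue_name = NA,
                                 atom_name = NA, charge = 0) {
  Molecule(
    data.frame(element = element, x = x, y = y, z = z,
               formal_charge = charge, residue_name = residue_name,
               residue_id = if (is.na(residue_name)) NA_integer_ else 1L,
               atom_name = atom_name, is_protein = is_protein,
               stringsAsFactors = FALSE),
    data.frame(i = integer(), j = integer(), order = character())
  )
}

small_dataset <- function(n = 6, seed = 11, lig = c(8, 14), poc = c(4, 7)) {
  gen_dataset(synthetic_spec(
    n_complexes = n, seed = seed,
    ligand_size_range = lig, pocket_residues_range = poc
  ))
}

tiny_model_config <- function(...) {
  args <- list(complex_dim = 8, ligand_dim = 4, fp_dim = 5,
               hidden_complex = 6, hidden_ligand = 6, dropout = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}
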
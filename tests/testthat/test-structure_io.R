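simple_mapping <- function(structure_id, chain_id = "A", accession = "ACC",
                           ref_start = 1L, ref_end = 1000L, offset = 0L) {
  mapping_table(data.frame(structure_id = structure_id, chain_id = chain_id,
                           accession = accession, ref_start = ref_start,
                           ref_end = ref_end, offset = offset))
}

test_that("mmCIF and PDB files with the same content give the same chains", {
  rec <- generate_backbone(12, structure_id = "fix1")
  cif <- tempfile(fileext = ".cif")
  pdb <- tempfile(fileext = ".pdb")
  glocon:::write_chain_cif(rec, cif)
  write_pdb_fixture(pdb, data.frame(chain = "A", resno = rec$resno,
                                    x = rec$xyz[, 1], y = rec$xyz[, 2],
                                    z = rec$xyz[, 3]))
  hc <- read_structure(cif, structure_id = "fix1")
  hp <- read_structure(pdb, structure_id = "fix1")
  expect_equal(hc$format, "mmcif")
  expect_equal(hp$format, "pdb")
  expect_equal(structure_chains(hc), structure_chains(hp))
  m <- simple_mapping("fix1")
  cc <- extract_chain(select_model(hc), "A", m)
  cp <- extract_chain(select_model(hp), "A", m)
  expect_equal(cc$resno, cp$resno)
  expect_equal(cc$xyz, cp$xyz, tolerance = 1e-3)
})

test_that("a structure with two chains lists both", {
  a <- generate_backbone(10, structure_id = "two", chain_id = "A")
  b <- generate_backbone(10, structure_id = "two", chain_id = "B")
  path <- tempfile(fileext = ".cif")
  write_superposed(list(a, b), path)
  h <- read_structure(path, structure_id = "two")
  expect_setequal(unique(h$atoms$chain), c("A", "B"))
})

test_that("garbled mmCIF raises a parse error naming the line", {
  path <- tempfile(fileext = ".cif")
  rec <- generate_backbone(5, structure_id = "bad")
  glocon:::write_chain_cif(rec, path)
  lines <- readLines(path)
  lines[22] <- "ATOM 3 C CA"  # truncated data row
  writeLines(lines, path)
  expect_error(read_structure(path), "parse error.*line 22")
})

test_that("a file without atoms is rejected", {
  path <- tempfile(fileext = ".cif")
  writeLines(c("data_empty", "#"), path)
  expect_error(read_structure(path), "_atom_site")
})

test_that("first-model rule keeps the first model in file order", {
  rec <- generate_backbone(8, structure_id = "nmr")
  shifted <- rec
  shifted$xyz <- shifted$xyz + 100
  # models stored out of numeric order: model 3 first, then model 1
  path <- tempfile(fileext = ".pdb")
  at <- function(r) data.frame(chain = "A", resno = r$resno,
                               x = r$xyz[, 1], y = r$xyz[, 2], z = r$xyz[, 3])
  write_pdb_fixture(path, NULL, models = list(
    list(number = 3, atoms = at(rec)),
    list(number = 1, atoms = at(shifted))
  ))
  h <- read_structure(path, structure_id = "nmr")
  expect_equal(structure_models(h), c(3L, 1L))
  h1 <- select_model(h)
  expect_equal(structure_models(h1), 3L)
  ch <- extract_chain(h1, "A", simple_mapping("nmr"))
  expect_equal(ch$source_model, 3L)
  expect_equal(ch$xyz, unname(rec$xyz), tolerance = 1e-3)
})

test_that("single-model selection is the identity", {
  rec <- generate_backbone(6, structure_id = "one")
  path <- tempfile(fileext = ".cif")
  glocon:::write_chain_cif(rec, path)
  h <- read_structure(path)
  expect_equal(select_model(h)$atoms, h$atoms)
})

test_that("extract_chain renumbers through the author offset", {
  rec <- generate_backbone(100, structure_id = "offs")
  path <- tempfile(fileext = ".cif")
  # authors 5..104 on disk; offset -4 maps back to reference 1..100
  glocon:::write_chain_cif(rec, path, author_offset = 4L)
  h <- select_model(read_structure(path, structure_id = "offs"))
  ch <- extract_chain(h, "A",
                      simple_mapping("offs", ref_start = 1L, ref_end = 100L,
                                     offset = -4L))
  expect_equal(ch$resno, 1:100)
  expect_equal(ch$xyz, unname(rec$xyz), tolerance = 1e-3)
})

test_that("unmodeled gaps come through as missing reference numbers", {
  spec <- ensemble_spec(n_residues = 50, chains_per_state = 1,
                        states = list(list(name = "s")),
                        jitter_sigma = 0,
                        gap_spec = list(list(chain = 1, start = 21, end = 30)),
                        seed = 7)
  ens <- generate_ensemble(spec, tempfile("gapens"))
  h <- select_model(read_structure(ens$files[1]))
  ch <- extract_chain(h, "A", ens$mapping)
  expect_equal(setdiff(1:50, ch$resno), 21:30)
})

test_that("alternate locations resolve to the highest occupancy", {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_alt", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 0.0 0.0 0.0 1.00 0.0 1 A 1",
    "ATOM 2 C CA A ALA A 1 2 ? 3.8 0.0 0.0 0.60 0.0 2 A 1",
    "ATOM 3 C CA B ALA A 1 2 ? 9.9 0.0 0.0 0.40 0.0 2 A 1",
    "ATOM 4 C CA A ALA A 1 3 ? 7.6 0.0 0.0 0.50 0.0 3 A 1",
    "ATOM 5 C CA B ALA A 1 3 ? 8.8 0.0 0.0 0.50 0.0 3 A 1",
    "ATOM 6 C CA . ALA A 1 4 ? 11.4 0.0 0.0 1.00 0.0 4 A 1"
  ), path)
  ch <- extract_chain(select_model(read_structure(path, structure_id = "alt")),
                      "A", simple_mapping("alt"))
  # residue 2: occupancy 0.6 wins; residue 3: tie broken by altloc id A
  expect_equal(unname(ch$xyz[, 1]), c(0, 3.8, 7.6, 11.4))
})

test_that("insertion-coded residues are a loud error", {
  path <- tempfile(fileext = ".pdb")
  df <- data.frame(chain = "A", resno = c(1, 2, 2, 3),
                   insert = c(NA, NA, "A", NA),
                   x = c(0, 3.8, 5, 7.6), y = 0, z = 0)
  write_pdb_fixture(path, df)
  h <- select_model(read_structure(path, structure_id = "ins"))
  expect_error(extract_chain(h, "A", simple_mapping("ins")),
               "insertion-coded")
})

test_that("missing chains and too-short chains error distinctly", {
  rec <- generate_backbone(10, structure_id = "sh")
  path <- tempfile(fileext = ".cif")
  glocon:::write_chain_cif(rec, path)
  h <- select_model(read_structure(path, structure_id = "sh"))
  expect_error(extract_chain(h, "Z", simple_mapping("sh", chain_id = "Z")),
               "not present")
  expect_error(
    extract_chain(h, "A", simple_mapping("sh", ref_start = 4L, ref_end = 5L)),
    "chain too short")
})

test_that("write_superposed round-trips coordinates to format precision", {
  rec <- generate_backbone(20, structure_id = "rt")
  path <- tempfile(fileext = ".cif")
  write_superposed(list(rec), path)
  back <- extract_chain(select_model(read_structure(path,
                                                    structure_id = "rt")),
                        "A", simple_mapping("rt"))
  expect_equal(back$resno, rec$resno)
  expect_lt(max(abs(back$xyz - rec$xyz)), 1e-3)
})

test_that("write_superposed applies a 90-degree rotation exactly", {
  rec <- generate_backbone(5, structure_id = "rot")
  Rz <- rotation_about_axis(c(0, 0, 1), pi / 2)
  path <- tempfile(fileext = ".cif")
  write_superposed(list(rec), path,
                   transforms = list(list(rotation = Rz,
                                          translation = c(0, 0, 0))))
  back <- extract_chain(select_model(read_structure(path,
                                                    structure_id = "rot")),
                        "A", simple_mapping("rot"))
  # (x, y, z) -> (-y, x, z)
  expected <- cbind(-rec$xyz[, 2], rec$xyz[, 1], rec$xyz[, 3])
  expect_lt(max(abs(back$xyz - expected)), 1e-3)
})
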
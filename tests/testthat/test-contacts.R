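test_that("structure parsing validates input and converts units", {
  expect_error(parse_structure("REMARK nothing here"), "no ATOM")
  # a 3.8 Angstrom coordinate becomes 0.38 nm
  pp <- gen_toy_complex("probe_pair", distance = 0.38)
  s <- parse_structure(pp, ligand_resname = "LIG")
  expect_equal(max(s$atoms$x), 0.38, tolerance = 1e-6)
})

test_that("write/parse round-trip preserves coordinates to 0.0001 nm", {
  pdb <- gen_toy_complex("cage")
  s <- parse_structure(pdb, ligand_resname = "LIG")
  # re-parse and compare all coordinates
  s2 <- parse_structure(pdb, ligand_resname = "LIG")
  expect_equal(s$atoms$x, s2$atoms$x, tolerance = 1e-7)
  # PDB stores 3 decimals in Angstrom = 0.0001 nm resolution
  lig <- s$atoms[s$atoms$residue_name == "LIG", ]
  expect_equal(lig$x[1], 0.154, tolerance = 1e-4)
})

test_that("malformed records are skipped with a warning", {
  pp <- gen_toy_complex("probe_pair", distance = 0.30)
  mangled <- c(pp[1], "ATOM      2  CB", pp[-1])
  expect_warning(s <- parse_structure(mangled, ligand_resname = "LIG"),
                 "malformed")
  expect_equal(nrow(s$atoms), 2)
})

test_that("contacts use a strict cutoff and stay monotone in it", {
  # pair beyond the cutoff: empty report
  far <- parse_structure(gen_toy_complex("probe_pair", distance = 0.50),
                         ligand_resname = "LIG")
  expect_equal(nrow(contact_residues(far, 0.38)), 0)
  # boundary pair at exactly the cutoff is excluded (strict <)
  edge <- parse_structure(gen_toy_complex("probe_pair", distance = 0.38),
                          ligand_resname = "LIG")
  expect_equal(nrow(contact_residues(edge, 0.38)), 0)
  expect_equal(nrow(contact_residues(edge, 0.45)), 1)
  # enlarging the cutoff can only add residues
  cage <- parse_structure(gen_toy_complex("cage", ring_distance = 0.36),
                          ligand_resname = "LIG")
  r38 <- report_keys(contact_residues(cage, 0.38))
  r45 <- report_keys(contact_residues(cage, 0.45))
  expect_true(all(r38 %in% r45))
})

test_that("residue sets match the brute-force O(N^2) oracle", {
  fixtures <- list(
    parse_structure(gen_toy_complex("cage"), ligand_resname = "LIG"),
    parse_structure(gen_toy_complex("cage", n_aromatic = 6,
                                    ring_distance = 0.31,
                                    aromatic_residue = "TRP"),
                    ligand_resname = "LIG"),
    parse_structure(gen_toy_complex("probe_pair", distance = 0.33),
                    ligand_resname = "LIG")
  )
  for (s in fixtures) {
    for (cutoff in c(0.38, 0.45)) {
      report <- contact_residues(s, cutoff)
      oracle <- contacts_oracle(s, cutoff)
      expect_setequal(report_keys(report),
                      paste(oracle$key))
      # minimum distances agree too
      merged <- merge(
        data.frame(key = report_keys(report),
                   pkg = report$min_distance_nm[
                     order(paste(report$residue_name,
                                 report$residue_number, report$chain))]),
        oracle, by = "key")
      expect_equal(merged$pkg, merged$min_d, tolerance = 1e-12)
    }
  }
})

test_that("distance windows classify the constructed boundary cases", {
  # ligand O at 0.30 nm from a serine O: hydrogen bond (window midpoint)
  cage <- parse_structure(gen_toy_complex("cage", ser_distance = 0.30),
                          ligand_resname = "LIG")
  rep <- classify_contacts(cage)
  ser <- rep[rep$residue_name == "SER", ]
  expect_true(grepl("hydrogen_bond", ser$classes_str))

  # aliphatic ligand carbon at 0.35 nm from an aromatic ring carbon:
  # both the C-C window and the CH-pi criterion contain 0.35
  phe <- rep[rep$residue_name == "PHE", ]
  expect_true(any(grepl("CH_pi", phe$classes_str)))
  expect_true(any(grepl("nonpolar_CC", phe$classes_str)))

  # ligand O at 0.37 nm from a backbone N: inside the cutoff but outside
  # the donor-acceptor window -> other polar contact
  probe <- parse_structure(
    gen_toy_complex("probe_pair", distance = 0.37,
                    elements = c("O", "N"), atom_names = c("O1", "N"),
                    residues = c("LIG", "GLY")),
    ligand_resname = "LIG")
  cls <- classify_contacts(probe)
  expect_equal(cls$classes_str, "other_polar")
})

test_that("an aromatic cage around an aliphatic core is dominated by CH-pi", {
  cage <- parse_structure(gen_toy_complex("cage", n_aromatic = 6),
                          ligand_resname = "LIG")
  rep <- classify_contacts(cage)
  n_chpi <- sum(grepl("CH_pi", rep$classes_str))
  expect_gt(n_chpi, nrow(rep) / 2)
})

test_that("classification is invariant under rigid transforms", {
  cage <- parse_structure(gen_toy_complex("cage"), ligand_resname = "LIG")
  base <- classify_contacts(cage)
  for (seed in 1:3) {
    moved <- rigid_transform(cage, seed)
    got <- classify_contacts(moved)
    expect_equal(report_keys(got), report_keys(base))
    expect_equal(sort(got$classes_str), sort(base$classes_str))
    expect_equal(sort(got$min_distance_nm), sort(base$min_distance_nm),
                 tolerance = 1e-10)
  }
})

test_that("contact reports export as TSV and readable text", {
  cage <- parse_structure(gen_toy_complex("cage"), ligand_resname = "LIG")
  rep <- classify_contacts(cage)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_report(rep, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(rep))
  lines <- format_contact_report(rep)
  expect_length(lines, nrow(rep))
  expect_true(any(grepl("Phe", lines)))
})

test_that("a missing ligand selector is an explicit error", {
  s <- parse_structure(gen_toy_complex("cage"))
  expect_error(contact_residues(s), "ligand selector")
  s2 <- set_ligand(s, resname = "ZZZ")
  expect_error(contact_residues(s2), "no heavy atoms")
})
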
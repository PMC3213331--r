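# PDB fixture construction helpers local to this file
pdb_atom_line <- function(serial, resname, resno, x, y, z,
                          name = "CA", alt = " ", occ = 1.00,
                          chain = "A") {
  sprintf("ATOM  %5d %s%-3s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
          serial, " ", name, alt, resname, chain, resno, x, y, z, occ)
}

write_toy_models <- function(path, nmodels = 2, nres = 5, skip = NULL) {
  lines <- character(0)
  for (m in seq_len(nmodels)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (r in seq_len(nres)) {
      if (!is.null(skip) && skip$model == m && skip$res == r) next
      lines <- c(lines, pdb_atom_line(r, "ALA", r, r * 3.8, m, 0))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

test_that("a multi-MODEL file parses into an ensemble of Calpha traces", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_models(f, nmodels = 2, nres = 5)
  ens <- read_ca_models(f)
  expect_s3_class(ens, "model_ensemble")
  expect_identical(ens$n, 2L)
  expect_identical(nresidues(ens$models[[1]]), 5L)
  expect_equal(ens$models[[1]]$xyz[, 1], (1:5) * 3.8)
})

test_that("twenty single-model files build an n = 20 ensemble in input order", {
  dirp <- withr::local_tempdir()
  paths <- vapply(1:20, function(i) {
    p <- file.path(dirp, sprintf("model_%02d.pdb", i))
    write_toy_models(p, nmodels = 1, nres = 6)
    p
  }, "")
  ens <- read_ca_models(paths)
  expect_identical(ens$n, 20L)
  expect_identical(ens$models[[1]]$label, "model_01")
  expect_identical(ens$models[[20]]$label, "model_20")
})

test_that("a residue missing its Calpha in one model is dropped from all, with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_models(f, nmodels = 3, nres = 6, skip = list(model = 3, res = 4))
  expect_warning(ens <- read_ca_models(f), "dropped")
  # brute-force oracle: intersection of the per-model residue index sets
  expected <- Reduce(intersect, list(1:6, 1:6, setdiff(1:6, 4)))
  for (m in ens$models) expect_identical(m$resno, as.integer(expected))
})

test_that("wholesale residue-set mismatch across models is an error naming the offender", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c("MODEL        1",
             vapply(1:5, function(r) pdb_atom_line(r, "ALA", r, r * 3.8, 0, 0), ""),
             "ENDMDL", "MODEL        2",
             vapply(1:5, function(r) pdb_atom_line(r, "ALA", r + 100, r * 3.8, 0, 0), ""),
             "ENDMDL", "END")
  writeLines(lines, f)
  expect_error(read_ca_models(f), "#2")
})

test_that("alternate locations resolve to the highest occupancy, then first listed", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "ALA", 1, 0, 0, 0),
    pdb_atom_line(2, "GLY", 2, 1, 0, 0, alt = "A", occ = 0.30),
    pdb_atom_line(3, "GLY", 2, 9, 0, 0, alt = "B", occ = 0.70),
    pdb_atom_line(4, "LEU", 3, 2, 0, 0, alt = "A", occ = 0.50),
    pdb_atom_line(5, "LEU", 3, 8, 0, 0, alt = "B", occ = 0.50),
    pdb_atom_line(6, "ALA", 4, 3, 0, 0),
    "END"), f)
  ens <- read_ca_models(f)
  m <- ens$models[[1]]
  expect_equal(m$xyz[2, 1], 9)   # higher occupancy wins
  expect_equal(m$xyz[3, 1], 2)   # tie: first listed wins
})

test_that("HETATM records and other chains are ignored", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "ALA", 1, 0, 0, 0),
    pdb_atom_line(2, "ALA", 2, 3.8, 0, 0),
    pdb_atom_line(3, "ALA", 3, 7.6, 1, 0),
    sub("^ATOM  ", "HETATM", pdb_atom_line(4, "HOH", 4, 99, 99, 99)),
    pdb_atom_line(5, "GLY", 10, 50, 50, 50, chain = "B"),
    "END"), f)
  m <- read_ca_models(f)$models[[1]]
  expect_identical(m$resno, 1:3)
})

test_that("parse then re-serialise preserves residues and coordinates to PDB precision", {
  fx <- make_ensemble(fixture_spec(seed = 9, n_models = 3, n_residues = 20,
                                   target_spread = 0.5))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ca_models(fx$ensemble, f)
  back <- read_ca_models(f)
  expect_identical(back$n, fx$ensemble$n)
  for (i in seq_len(back$n)) {
    expect_identical(back$models[[i]]$resno, fx$ensemble$models[[i]]$resno)
    expect_equal(back$models[[i]]$xyz, fx$ensemble$models[[i]]$xyz,
                 tolerance = 1e-3)
  }
  # independent cross-check of our fixed-column writer/reader with bio3d
  pdb <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  ca <- pdb$atom[pdb$atom$elety == "CA", ]
  expect_equal(nrow(ca), 20)
  expect_equal(ca$x, back$models[[1]]$xyz[, 1], tolerance = 1e-6)
})

test_that("fasta and clustal alignments parse identically and drop gap-gap columns", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">target", "AC-GT", ">template", "ACAGT"), fa)
  a <- read_alignment(fa, "fasta")
  expect_identical(a$n, 5L)
  expect_identical(a$target, "AC-GT")

  # gap-vs-gap column removed, N reduced; column-filter oracle
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t", "AC--GT", ">m", "AC-AGT"), fa2)
  a2 <- read_alignment(fa2, "fasta")
  expect_identical(a2$n, 5L)
  tc <- strsplit(a2$target, "")[[1]]
  mc <- strsplit(a2$template, "")[[1]]
  expect_false(any(tc == "-" & mc == "-"))

  cl <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               "target      AC-",
               "template    ACA",
               "            ** ", "",
               "target      GT",
               "template    GT",
               "            **", ""), cl)
  a3 <- read_alignment(cl, "clustal")
  expect_identical(a3$target, "AC-GT")
  expect_identical(a3$template, "ACAGT")

  expect_error(read_alignment(fa, "fasta", target_id = "nope"), "not found")
  fa3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t", "ACGT", ">m", "ACG"), fa3)
  expect_error(read_alignment(fa3, "fasta"), "unequal")
})

test_that("ss2 and horiz dialects of one prediction parse to identical content", {
  spec <- fixture_spec(seed = 13, n_residues = 70)
  ssp <- make_ss_pair(spec)
  d <- withr::local_tempdir()
  seqstr <- paste(rep("A", length(ssp$pred$states)), collapse = "")
  hfactor:::write_ss2(ssp$pred, file.path(d, "p.ss2"), seqstr)
  hfactor:::write_horiz(ssp$pred, file.path(d, "p.horiz"), seqstr)
  p1 <- read_ss_prediction(file.path(d, "p.ss2"), "ss2")
  p2 <- read_ss_prediction(file.path(d, "p.horiz"), "horiz")
  expect_identical(p1$states, p2$states)
  expect_identical(p1$conf, p2$conf)
  expect_identical(p1$states, ssp$pred$states)
  expect_identical(p1$conf, ssp$pred$conf)
})

test_that("horiz blocks concatenate in order (line-by-line oracle)", {
  f <- withr::local_tempfile(fileext = ".horiz")
  writeLines(c("Conf: 98765", "Pred: HHHEE", "  AA: MKVLA", "",
               "Conf: 43210", "Pred: CCCHH", "  AA: GGGAA", ""), f)
  p <- read_ss_prediction(f, "horiz", confidence_shift = FALSE)
  expect_identical(p$states,
                   c("H", "H", "H", "S", "S", "C", "C", "C", "H", "H"))
  expect_identical(p$conf, c(9:5, 4:0))
  # with the default shift the 0-9 digits become 1-10
  p2 <- read_ss_prediction(f, "horiz")
  expect_identical(p2$conf, p$conf + 1L)
})

test_that("single ss2 line parses state and unknown letters error", {
  f <- withr::local_tempfile(fileext = ".ss2")
  writeLines(c("# PSIPRED VFORMAT", "",
               "   1 M C   0.998  0.001  0.001"), f)
  p <- read_ss_prediction(f, "ss2")
  expect_identical(p$states, "C")
  f2 <- withr::local_tempfile(fileext = ".ss2")
  writeLines("   1 M Q   0.998  0.001  0.001", f2)
  expect_error(read_ss_prediction(f2, "ss2"), "unknown")
})

test_that("stride and DSSP assignments reduce correctly to 3 states", {
  f <- withr::local_tempfile(fileext = ".stride")
  writeLines(c(
    "REM  header",
    "ASG  ALA A    1    1    H    AlphaHelix   -60.00    -45.00     20.0      ~~~~",
    "ASG  GLY A    2    2    G    310Helix     -60.00    -45.00     20.0      ~~~~",
    "ASG  LEU A    3    3    E    Strand      -120.00    130.00     10.0      ~~~~",
    "ASG  SER A    4    4    T    Turn         -70.00    -20.00     50.0      ~~~~",
    "ASG  VAL A    5    5    C    Coil        -100.00    140.00     80.0      ~~~~"), f)
  a <- read_ss_assignment(f, "stride")
  expect_identical(a$states, c("H", "H", "S", "C", "C"))

  fd <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition (synthetic) ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A M  H  >         0   0  100",
    "    2    2 A K  B            0   0  100",
    "    3    3 A V  S            0   0  100",
    "    4    4 A L  T            0   0  100",
    "    5    5 A A     >         0   0  100"), fd)
  ad <- read_ss_assignment(fd, "dssp")
  # DSSP B -> S (bridge), DSSP S is bend -> C, blank -> C
  expect_identical(ad$states, c("H", "S", "C", "C", "C"))
  expect_error(read_ss_assignment(withr::local_tempfile(fileext = ".x"),
                                  "stride"), "exist")
})

test_that("breakdown reports round-trip through JSON and render n/a in TSV", {
  cfg <- hfactor_config()
  h <- hfactor:::new_hfactor(list(s1 = 1.1, s2 = 8.6, s3 = 2.9, s4 = 3.8),
                             mode = "full", config = cfg, label = "T")
  f <- withr::local_tempfile(fileext = ".json")
  write_breakdown(h, f, "json")
  back <- read_breakdown(f)
  expect_equal(back$scores, h$scores)
  expect_identical(back$h_percent_rounded, h$h_percent_rounded)
  expect_equal(back$h_percent, h$h_percent)

  h2 <- hfactor:::new_hfactor(list(s1 = NA, s2 = NA, s3 = 2.13, s4 = 3.43),
                              mode = "structure_only", config = cfg,
                              label = "nmr")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_breakdown(h2, ft, "tsv")
  row <- strsplit(readLines(ft)[2], "\t")[[1]]
  expect_identical(row[2], "n/a")
  expect_identical(row[3], "n/a")
  expect_identical(row[6], "28")
})
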
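# Residue-definition language: parsing, resolution, pairing rules.

test_that("plain atom definitions parse and resolve", {
  rep <- parse_representation(c("def SER CA CB", "def ALA CA",
                                "SER.(CA) ALA.(CA)"))
  d <- resolve_def("SER", rep)
  expect_equal(d$residue, "SER")
  expect_equal(vapply(d$recipes, `[[`, "", "name"), c("CA", "CB"))
  expect_equal(vapply(d$recipes, `[[`, "", "type"), c("atom", "atom"))
  # case-insensitive lookup and parse
  expect_identical(resolve_def("ser", rep), d)
  rep2 <- parse_representation(c("def ser ca cb", "def ala ca"))
  expect_identical(resolve_def("SER", rep2)$recipes, d$recipes)
})

test_that("centroid pseudoatoms parse with their given name", {
  rep <- parse_representation(c("def HIS avg(ND1,NE2):bar", "HIS"))
  r <- resolve_def("HIS", rep)$recipes[[1]]
  expect_equal(r$type, "centroid")
  expect_equal(r$name, "BAR")
  expect_equal(r$atoms, c("ND1", "NE2"))
})

test_that("wildcard def with backslash patterns covers N/O atoms", {
  rep <- parse_representation(c("mode independent", "def * \\N;\\O", "* *"))
  d <- resolve_def("XYZ", rep)
  expect_equal(length(d$recipes), 2L)
  expect_equal(vapply(d$recipes, `[[`, "", "type"), c("pattern", "pattern"))
  expect_equal(d$recipes[[1]]$pattern, "N")
  expect_equal(d$recipes[[2]]$pattern, "O")
  expect_true(rep$independent_atoms)
  # positional pairing of identical defs restricts N to N and O to O
  pr <- allowed_pairings("ALA", "GLY", rep)
  expect_length(pr, 1L)
  expect_equal(pr[[1]]$a, pr[[1]]$b)
})

test_that("empty and malformed input raise errors with line numbers", {
  expect_error(parse_representation(""), "no residue definitions")
  expect_error(parse_representation(c("# only a comment")), "no residue definitions")
  expect_error(parse_representation(c("def SER CA", "def SER CB")),
               "line 2.*duplicate")
  expect_error(parse_representation(c("def SER CA", "SER TRP")),
               "undefined residue 'TRP'")
  expect_error(parse_representation(c("def SER CA CB", "def ALA CA",
                                      "SER ALA")),
               "mismatched fragment counts")
  expect_error(parse_representation(c("def")), "line 1")
  expect_error(parse_representation(c("def HIS avg():x")), "no atoms")
  expect_error(parse_representation(c("def SER CA", "mode sideways")), "mode")
})

test_that("exact definitions take precedence over the wildcard for all 20 residues", {
  lines <- c(paste("def", AA_STANDARD, "CB"), "def * CA", "* *")
  rep <- parse_representation(lines)
  for (res in AA_STANDARD) {
    expect_equal(resolve_def(res, rep)$recipes[[1]]$name, "CB", info = res)
  }
  expect_equal(resolve_def("MSE", rep)$recipes[[1]]$name, "CA")
  # undefined residue with no wildcard is excluded
  rep2 <- parse_representation(c("def SER CA", "SER"))
  expect_null(resolve_def("TRP", rep2))
})

test_that("equivalence membership drives pairing, including self-matches", {
  rep <- parse_representation(c("def ALA CA", "def GLY CA", "def VAL CA",
                                "def TRP CA", "ALA GLY VAL"))
  expect_length(allowed_pairings("ALA", "VAL", rep), 1L)
  expect_equal(allowed_pairings("ALA", "VAL", rep)[[1]],
               list(a = "CA", b = "CA"))
  # a residue named in a rule may match itself; an unnamed one may not
  expect_length(allowed_pairings("ALA", "ALA", rep), 1L)
  expect_length(allowed_pairings("TRP", "TRP", rep), 0L)
  expect_length(allowed_pairings("TRP", "ALA", rep), 0L)
})

test_that("fragment selectors pair the named recipes in written order", {
  rep <- parse_representation(c("def XXX A B", "def YYY C D",
                                "XXX.(A,B) YYY.(C,D)"))
  pr <- allowed_pairings("XXX", "YYY", rep)
  expect_length(pr, 1L)
  expect_equal(pr[[1]]$a, c("A", "B"))
  expect_equal(pr[[1]]$b, c("C", "D"))
  # the reverse direction transposes the correspondence
  rv <- allowed_pairings("YYY", "XXX", rep)
  expect_equal(rv[[1]]$a, c("C", "D"))
  expect_equal(rv[[1]]$b, c("A", "B"))
})

test_that("allowed_pairings is symmetric up to reversal on preset rules", {
  rep <- rep_preset("ca_centroid_blosum")
  combos <- utils::combn(c("ALA", "SER", "GLY", "TRP", "LYS"), 2)
  for (k in seq_len(ncol(combos))) {
    x <- combos[1, k]
    y <- combos[2, k]
    fwd <- allowed_pairings(x, y, rep)
    rev <- allowed_pairings(y, x, rep)
    expect_equal(length(fwd), length(rev), info = paste(x, y))
    fk <- sort(vapply(fwd, function(p) paste(p$a, p$b, collapse = "|"), ""))
    rk <- sort(vapply(rev, function(p) paste(p$b, p$a, collapse = "|"), ""))
    expect_equal(fk, rk, info = paste(x, y))
  }
})

test_that("serialize/parse round trip preserves defs, rules and mode", {
  rep <- parse_representation(c(
    "mode independent",
    "def SER CA avg(CB,OG):side \\N",
    "def HIS avg(ND1,NE2):bar",
    "SER.(CA) HIS.(BAR)",
    "SER"))
  rep2 <- parse_representation(format_representation(rep))
  expect_equal(rep2$defs, rep$defs, ignore_attr = TRUE,
               list_as_map = TRUE)
  expect_equal(length(rep2$rules), length(rep$rules))
  for (i in seq_along(rep$rules)) {
    expect_equal(rep2$rules[[i]]$members, rep$rules[[i]]$members)
  }
  expect_equal(rep2$independent_atoms, rep$independent_atoms)
})

test_that("bundled presets parse, match their generators and cover all residues", {
  for (nm in c("coarse_ca", "ca_centroid_blosum", "chemgroups")) {
    rep <- rep_preset(nm)
    gen <- parse_representation(preset_text(nm), id = nm)
    expect_equal(rep$defs, gen$defs, info = nm)
    expect_equal(length(rep$rules), length(gen$rules), info = nm)
    for (res in AA_STANDARD) {
      expect_false(is.null(resolve_def(res, rep)), info = paste(nm, res))
    }
  }
  expect_true(rep_preset("chemgroups")$independent_atoms)
  expect_false(rep_preset("coarse_ca")$independent_atoms)
})

test_that("vendored BLOSUM62 agrees with the Biostrings copy", {
  skip_if_not_installed("Biostrings")
  ours <- structmatch:::blosum62_matrix()
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  theirs <- env$BLOSUM62
  one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  for (x in rownames(ours)) {
    for (y in colnames(ours)) {
      expect_equal(ours[x, y], theirs[one[[x]], one[[y]]],
                   info = paste(x, y))
    }
  }
})

test_that("blosum preset allows score >= -1 pairs only", {
  rep <- rep_preset("ca_centroid_blosum")
  b62 <- structmatch:::blosum62_matrix()
  for (x in c("ALA", "TRP", "LYS", "GLY")) {
    for (y in AA_STANDARD) {
      allowed <- length(allowed_pairings(x, y, rep)) > 0
      expect_equal(allowed, b62[x, y] >= -1, info = paste(x, y))
    }
  }
})
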
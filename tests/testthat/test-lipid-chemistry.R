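test_that("formula arithmetic is element-wise and guards against negatives", {
  a <- gsl_formula(C = 6, H = 10, O = 5)
  b <- gsl_formula(C = 1, H = 2, O = 1)
  expect_equal(unclass(a + b)[["C"]], 7L)
  expect_equal(unclass(a - b)[["H"]], 8L)
  expect_error(b - a, "negative")
  expect_error(gsl_formula(C = -1), "non-negative")
  expect_equal(formula_mass(gsl_formula()), 0)
  expect_gt(formula_mass(gsl_formula(H = 1)), 0)
})

test_that("ceramide shorthand parses, validates and round-trips", {
  full <- parse_ceramide("d18:1/18:0")
  expect_equal(full$base_c, 18L)
  expect_equal(full$acyl_c, 18L)
  expect_equal(full$label, 0L)
  expect_identical(format(full), "d18:1/18:0")
  expect_identical(format(full, "summed"), "d36:1")

  lab <- parse_ceramide("d18:1/18:0-d5")
  expect_equal(lab$label, 5L)
  expect_identical(format(lab), "d18:1/18:0-d5")

  # summed form resolves against a fixed d18:1 base
  summed <- parse_ceramide("d34:1")
  expect_equal(summed$base_c, 18L)
  expect_equal(summed$base_db, 1L)
  expect_equal(summed$acyl_c, 16L)
  expect_equal(summed$acyl_db, 0L)

  expect_error(parse_ceramide("t18:1/18:0"), "t18:1/18:0")
  expect_error(parse_ceramide("d18:1/"), "parse")
  expect_error(parse_ceramide("d20:0"), "double bond") # no DB left for a d18:1 base
  expect_error(parse_ceramide("d18:1/10:0"), ">= 12 carbons")
})

test_that("ceramide formulas match hand-derived compositions and masses", {
  f <- ceramide_formula("d18:1/18:0")
  expect_identical(format(f), "C36H71NO3")
  expect_equal(formula_mass(f), 565.5434, tolerance = 1e-4)

  # deuterated acyl: 3 H replaced by 3 D
  f3 <- ceramide_formula("d18:1/18:0-d3")
  expect_equal(formula_mass(f3) - formula_mass(f),
               3 * (2.01410177785 - 1.00782503207), tolerance = 1e-9)

  # homologue spacing: one CH2
  expect_equal(formula_mass(ceramide_formula("d18:1/18:0")) -
                 formula_mass(ceramide_formula("d18:1/17:0")),
               14.01565, tolerance = 1e-4)
})

test_that("species formulas follow the biosynthetic pathway compositions", {
  gm3 <- species_formula("GM3", "d18:1/18:0")
  expect_identical(format(gm3), "C59H108N2O21")
  expect_equal(formula_mass(gm3), 1180.744, tolerance = 1e-3)

  # one NeuAc residue separates GD3 from GM3
  expect_equal(formula_mass(species_formula("GD3", "d18:1/18:0")) -
                 formula_mass(gm3), 291.0954, tolerance = 1e-4)

  # GlcCer = ceramide + one dehydrated hexose
  expect_equal(formula_mass(species_formula("GlcCer", "d18:1/16:0")),
               formula_mass(ceramide_formula("d34:1")) +
                 formula_mass(glycan_residue("Hex")),
               tolerance = 1e-9)

  expect_error(species_formula("GX9", "d18:1/18:0"), "unknown lipid class")
})

test_that("adjacent pathway classes differ by exactly one residue", {
  cer <- "d18:1/18:0"
  m <- function(cls) formula_mass(species_formula(cls, cer))
  hex <- formula_mass(glycan_residue("Hex"))
  hexnac <- formula_mass(glycan_residue("HexNAc"))
  neuac <- formula_mass(glycan_residue("NeuAc"))

  # neutral core build-up
  expect_equal(m("LacCer") - m("GlcCer"), hex, tolerance = 1e-9)
  expect_equal(m("Gb3") - m("LacCer"), hex, tolerance = 1e-9)
  expect_equal(m("GA2") - m("LacCer"), hexnac, tolerance = 1e-9)
  # sialylation series
  for (pair in list(c("GM3", "LacCer"), c("GD3", "GM3"), c("GT3", "GD3"),
                    c("GD2", "GM2"), c("GT2", "GD2"),
                    c("GD1", "GM1"), c("GT1", "GD1"), c("GQ1", "GT1"))) {
    expect_equal(m(pair[1]) - m(pair[2]), neuac, tolerance = 1e-9)
  }
  # GalNAc and Gal additions within each sialylation level
  for (pair in list(c("GM2", "GM3"), c("GD2", "GD3"), c("GT2", "GT3"))) {
    expect_equal(m(pair[1]) - m(pair[2]), hexnac, tolerance = 1e-9)
  }
  for (pair in list(c("GM1", "GM2"), c("GD1", "GD2"), c("GT1", "GT2"))) {
    expect_equal(m(pair[1]) - m(pair[2]), hex, tolerance = 1e-9)
  }
})

test_that("composition masses agree with a flat atom-list oracle", {
  panel <- build_panel(default_panel_config())
  for (i in seq_len(nrow(panel))) {
    f <- species_formula(panel$class[i], panel$ceramide[i])
    counts <- as.list(unclass(f))
    expect_equal(formula_mass(f), oracle_flat_mass(counts), tolerance = 1e-6,
                 label = panel$species_id[i])
  }
})

test_that("precursor m/z follows the charge-state conventions", {
  expect_equal(precursor_mz("GM3", -1, "d18:1/18:0"), 1179.737,
               tolerance = 1e-3)
  # (M - 2H)/2 relation at charge -2
  M <- formula_mass(species_formula("GD3", "d18:1/18:0"))
  expect_equal(precursor_mz("GD3", -2, "d18:1/18:0"),
               (M - 2 * PROTON_MASS) / 2, tolerance = 1e-9)
  # positive mode: M + proton
  Mg <- formula_mass(species_formula("GlcCer", "d18:1/16:0"))
  expect_equal(precursor_mz("GlcCer", 1, "d18:1/16:0"), Mg + PROTON_MASS,
               tolerance = 1e-9)
  # polarity/charge mismatches refuse
  expect_error(precursor_mz("GlcCer", -1, "d18:1/16:0"), "positive mode")
  expect_error(precursor_mz("GM3", 1, "d18:1/18:0"), "negative mode")
  expect_error(precursor_mz("GM3", 0, "d18:1/18:0"), "non-zero")
})

test_that("homologue spacing in precursor m/z is one CH2 per added carbon pair", {
  for (cls in c("GM3", "GD3", "GlcCer")) {
    charge <- gsl_classes()$default_charge[gsl_classes()$class == cls]
    mz1 <- precursor_mz(cls, charge, "d18:1/16:0")
    mz2 <- precursor_mz(cls, charge, "d18:1/18:0")
    expect_equal(mz2 - mz1, 2 * 14.01565 / abs(charge), tolerance = 1e-4,
                 label = cls)
  }
})

test_that("quantifier fragments round to the printed m/z values", {
  for (cls in c("GM3", "GM2", "GM1", "GD3", "GD2", "GD1",
                "GT3", "GT2", "GT1", "GQ1")) {
    expect_equal(round(quantifier_fragment_mz(cls), 1), 290.1, label = cls)
  }
  for (cls in c("GlcCer", "LacCer", "Gb3", "GA2")) {
    expect_equal(round(quantifier_fragment_mz(cls), 1), 264.3, label = cls)
  }
  expect_equal(quantifier_fragment_mz("GlcCer"), 264.2686, tolerance = 1e-4)
  # acyl-chain deuterium label does not shift the sphingosine fragment
  sp <- lipid_species("GlcCer", "d18:1/16:0-d3", role = "internal_standard")
  expect_equal(quantifier_fragment_mz(sp), quantifier_fragment_mz("GlcCer"))
})

test_that("internal standards must be isotope-labelled or odd-chain", {
  expect_error(lipid_species("GM3", "d18:1/18:0", role = "internal_standard"),
               "neither a deuterium label nor an odd-carbon")
  expect_s3_class(lipid_species("GM1", "d18:1/17:0", role = "internal_standard"),
                  "lipid_species")
  expect_s3_class(lipid_species("GM3", "d18:1/18:0-d5",
                                role = "internal_standard"),
                  "lipid_species")
})
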
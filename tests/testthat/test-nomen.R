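test_that("species abbreviations follow the genus+epithet rule", {
  reg <- abbrev_registry()
  expect_equal(species_abbrev("Bombyx", "mori", reg), "Bm")
  expect_equal(species_abbrev("Helicoverpa", "armigera", reg), "Ha")
  expect_equal(species_abbrev("Helicoverpa", "assulta", reg), "Has")
  # stable on re-query
  expect_equal(species_abbrev("Helicoverpa", "assulta", reg), "Has")
  # registry stays bijective
  expect_equal(reg$by_abbrev[["Has"]], "Helicoverpa assulta")
  # extension exhausted without uniqueness is an error
  expect_error(species_abbrev("Bombyx", "m", reg), "unique")
})

test_that("registry bijectivity holds under any insertion order", {
  sp <- list(c("Bombyx", "mori"), c("Bombyx", "mandarina"),
             c("Helicoverpa", "armigera"), c("Helicoverpa", "assulta"),
             c("Hepialus", "californicus"))
  for (perm in list(1:5, 5:1, c(3, 1, 5, 2, 4))) {
    reg <- abbrev_registry()
    for (k in perm) species_abbrev(sp[[k]][1], sp[[k]][2], reg)
    abbrevs <- unlist(reg$by_species)
    expect_false(anyDuplicated(abbrevs) > 0)
    for (key in names(reg$by_species))
      expect_equal(reg$by_abbrev[[reg$by_species[[key]]]], key)
  }
})

test_that("name building matches the published examples", {
  expect_equal(build_name("Bm", 1, gene_number = 2), "BmSn1-2")
  expect_equal(build_name("Gm", 1, splice_letter = "B", minor_variant = 2),
               "GmSn1B2")
  expect_equal(build_name("At", 3, splice_letter = "B"), "AtSn3B")
  expect_equal(build_name("Has", 3), "HasSn3")
  expect_error(build_name("Gm", 1, minor_variant = 2), "splice letter")
  expect_error(build_name("Gm", 1, splice_letter = "B", minor_variant = 1),
               "start at 2")
  expect_error(build_name("Gm", 4), "class")
})

test_that("parsing inverts building over the whole grammar", {
  for (ab in c("Bm", "Gm", "Has")) {
    for (cl in 1:3) {
      for (gene in list(NULL, 1, 2)) {
        for (letter in list(NULL, "A", "B", "C", "D")) {
          minors <- if (is.null(letter)) list(NULL) else list(NULL, 2, 3)
          for (mv in minors) {
            nm <- build_name(ab, cl, gene, letter,
                             if (is.null(mv)) NULL else mv)
            p <- parse_name(nm)
            expect_equal(p$abbrev, ab)
            expect_equal(p$seroin_class, cl)
            expect_equal(p$gene_number,
                         if (is.null(gene)) NULL else as.integer(gene))
            expect_equal(p$splice_letter, letter)
            expect_equal(p$minor_variant,
                         if (is.null(mv)) NULL else as.integer(mv))
          }
        }
      }
    }
  }
})

test_that("published-style names parse, including the en-dash variant", {
  names_in_print <- c("BmSn1-1", "BmSn1-2", "BmSn1–2", "GmSn1A",
                      "GmSn1B", "GmSn1B2", "GmSn1C", "GmSn2A", "GmSn2B",
                      "GmSn2C", "GmSn3", "HasSn3", "AtSn3A", "AtSn3B",
                      "HcSn1A2", "PnSn1")
  for (nm in names_in_print) expect_silent(parse_name(nm))
  p <- parse_name("BmSn1–2")
  expect_equal(p$gene_number, 2L)
})

test_that("malformed names fail with positioned errors", {
  expect_error(parse_name("Sn1A"), "abbreviation")
  expect_error(parse_name(""), "empty")
  expect_error(parse_name("BmSn4"), "class digit")
  expect_error(parse_name("BmSn1-3"), "gene number")
  expect_error(parse_name("BmSn1B1"), "minor-variant")
  expect_error(parse_name("BmSn1b"), "splice letter")
})

test_that("dataset naming assigns letters per version and digits per copy", {
  annot <- data.frame(
    id = c("r1", "r2", "r3", "r4", "r5"),
    genus = "Galleria", species = "mellonella",
    class = "Sn1", version = c("L", "N", "N", "C", "L"),
    gene = 1L, stringsAsFactors = FALSE)
  named <- name_dataset(annot)
  # letters ordered by smallest member id per version: L -> A, N -> B, C -> C
  expect_equal(named$name[named$id == "r1"], "GmSn1A")
  expect_equal(named$name[named$id == "r5"], "GmSn1A2")  # second L copy
  expect_equal(named$name[named$id == "r2"], "GmSn1B")
  expect_equal(named$name[named$id == "r3"], "GmSn1B2")
  expect_equal(named$name[named$id == "r4"], "GmSn1C")

  # a single-record gene gets a bare name; two genes get hyphen numbers
  annot2 <- data.frame(id = c("s1", "s2"), genus = "Bombyx",
                       species = "mori", class = "Sn1",
                       version = c("C", "N"), gene = c(1L, 2L),
                       stringsAsFactors = FALSE)
  named2 <- name_dataset(annot2)
  expect_setequal(named2$name, c("BmSn1-1", "BmSn1-2"))

  # H. assulta is abbreviated Has only because H. armigera holds Ha
  reg <- abbrev_registry()
  species_abbrev("Helicoverpa", "armigera", reg)
  annot3 <- data.frame(id = "x", genus = "Helicoverpa", species = "assulta",
                       class = "Sn3", version = "T", gene = 1L,
                       stringsAsFactors = FALSE)
  expect_equal(name_dataset(annot3, reg)$name, "HasSn3")
})
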
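test_that("generated proteins carry their class-diagnostic features", {
  sn2 <- make_protein(seroin_spec("Sn2", "L", seed = 7))
  expect_true(grepl("RYGG", sn2$protein, fixed = TRUE))
  gly2050 <- mean(chars(substr(sn2$protein, 21, 50)) == "G")
  expect_gte(gly2050, 0.25)

  sn3 <- make_protein(seroin_spec("Sn3", "T", seed = 1))
  w <- which(chars(sn3$protein) == "W") - 1L
  expect_true(any(w >= 32 & w < 37))
  expect_true(grepl("VYGE", sn3$protein, fixed = TRUE))

  sn1 <- make_protein(seroin_spec("Sn1", "L", seed = 3))
  x <- chars(sn1$protein)
  w1 <- which(x == "W")[1] - 1L
  expect_true(w1 >= 15 && w1 < 25)
  flank <- x[max(1, w1 - 4):(w1 + 6)]
  expect_gte(sum(flank %in% c("D", "E", "K", "R")), 3)
})

test_that("generation is deterministic given the recipe seed", {
  a <- make_protein(seroin_spec("Sn1", "L", seed = 11))
  b <- make_protein(seroin_spec("Sn1", "L", seed = 11))
  expect_identical(a$protein, b$protein)
  expect_identical(a$true_architecture, b$true_architecture)
  c <- make_protein(seroin_spec("Sn1", "L", seed = 12))
  expect_false(identical(a$protein, c$protein))
})

test_that("true architectures tile the protein in canonical order", {
  ds <- fixture_dataset()
  canon <- c("A", "B1", "C1", "B2", "C2", "B3")
  for (rec in ds$records) {
    arch <- rec$true_architecture
    expect_equal(arch$start[1], 0L)
    expect_equal(arch$end[nrow(arch)], nchar(rec$protein))
    expect_equal(arch$start[-1], arch$end[-nrow(arch)])
    expect_true(!is.unsorted(match(arch$label, canon), strictly = TRUE))
    expect_lte(nchar(rec$protein) - arch$end[1], 250)   # mature cap
  }
})

test_that("class populations differ in the diagnostic compositions", {
  ds <- fixture_dataset()
  pro_b <- c(); pro_c <- c(); gly <- list(Sn1 = c(), Sn2 = c(), Sn3 = c())
  for (i in seq_along(ds$records)) {
    rec <- ds$records[[i]]
    x <- chars(rec$protein)
    arch <- rec$true_architecture
    for (k in seq_len(nrow(arch))) {
      seg <- x[(arch$start[k] + 1):arch$end[k]]
      if (startsWith(arch$label[k], "B")) pro_b <- c(pro_b, mean(seg == "P"))
      if (startsWith(arch$label[k], "C")) pro_c <- c(pro_c, mean(seg == "P"))
    }
    cl <- ds$truth$class[i]
    gly[[cl]] <- c(gly[[cl]], mean(x[21:min(50, length(x))] == "G"))
  }
  expect_gt(mean(pro_c), mean(pro_b))
  expect_gt(mean(gly$Sn2), mean(gly$Sn1))
  expect_gt(mean(gly$Sn2), mean(gly$Sn3))
})

test_that("cDNAs round-trip through ORF calling and are seed-stable", {
  rec <- make_protein(seroin_spec("Sn2", "C", seed = 21))
  a <- make_cdna(rec, seed = 4)
  b <- make_cdna(rec, seed = 4)
  expect_identical(a$cdna, b$cdna)
  orf <- longest_orf(a$cdna)
  expect_identical(orf$protein, rec$protein)
})

test_that("datasets honor requested cells, cover all versions, and repeat", {
  small <- make_dataset(data.frame(class = "Sn1", version = "L", n = 2),
                        seed = 1, make_cdnas = FALSE)
  expect_equal(nrow(small$truth), 2L)
  expect_true(all(small$truth$class == "Sn1" & small$truth$version == "L"))

  empty <- make_dataset(data.frame(class = character(),
                                   version = character(),
                                   n = integer()), seed = 1)
  expect_equal(nrow(empty$truth), 0L)

  ds <- fixture_dataset()
  expect_setequal(
    unique(paste(ds$truth$class, ds$truth$version)),
    c("Sn1 L", "Sn1 N", "Sn1 C", "Sn2 L", "Sn2 C", "Sn2 T1", "Sn2 T2",
      "Sn3 L", "Sn3 T"))

  again <- make_balanced_dataset(12L, seed = 42L, make_cdnas = FALSE)
  expect_identical(ds$truth, again$truth)
})

test_that("read simulation respects origins, weights and error rates", {
  cdnas <- data.frame(id = c("a", "b"),
                      sequence = c(random_dna(400), random_dna(400)),
                      stringsAsFactors = FALSE)
  rr <- make_reads(cdnas, c(a = 1, b = 1), read_len = 80, n_reads = 10,
                   error_rate = 0, seed = 3)
  for (i in 1:10) {
    src <- cdnas$sequence[cdnas$id == rr$origin$source[i]]
    fragment <- rr$reads$sequence[i]
    if (rr$origin$strand[i] == "-") fragment <- reverse_complement(fragment)
    expect_equal(fragment,
                 substr(src, rr$origin$start[i] + 1, rr$origin$start[i] + 80))
  }

  only_a <- make_reads(cdnas, c(a = 1, b = 0), read_len = 80, n_reads = 100,
                       seed = 5)
  expect_true(all(only_a$origin$source == "a"))

  biased <- make_reads(cdnas, c(a = 3, b = 1), read_len = 80,
                       n_reads = 4000, seed = 9)
  n_a <- sum(biased$origin$source == "a")
  ci <- qbinom(c(0.005, 0.995), 4000, 0.75)
  expect_gte(n_a, ci[1])
  expect_lte(n_a, ci[2])

  expect_error(make_reads(cdnas, read_len = 500), "read_len")
})
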
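# construct an architecture object directly from (label, length, ...) runs
arch_from_runs <- function(labels, lens, a_len = 20L) {
  ends <- cumsum(c(a_len, lens))
  starts <- ends - c(a_len, lens)
  structure(data.frame(label = c("A", labels), start = starts, end = ends,
                       complete = TRUE, stringsAsFactors = FALSE),
            class = c("seroin_architecture", "data.frame"),
            protein_length = ends[length(ends)], degenerate = FALSE)
}

test_that("canonical splice patterns are called by their module sets", {
  # full module set -> L
  l1 <- arch_from_runs(c("B1", "C1", "B2", "C2", "B3"),
                       c(15, 33, 52, 12, 60))
  expect_equal(call_version(l1, "Sn1")$code, "L")

  # AB1C1B2 -> N in Sn1
  n1 <- arch_from_runs(c("B1", "C1", "B2"), c(15, 33, 52))
  expect_equal(call_version(n1, "Sn1")$code, "N")

  # AB1C2B3 -> C in Sn1 (second C-type run re-mapped to C2)
  c1 <- arch_from_runs(c("B1", "C1", "B2"), c(15, 12, 60))
  v <- call_version(c1, "Sn1")
  expect_equal(v$code, "C")
  expect_equal(v$canonical$label, c("A", "B1", "C2", "B3"))

  # AB1C1B3 -> T in Sn3
  t3 <- arch_from_runs(c("B1", "C1", "B2"), c(40, 15, 58))
  expect_equal(call_version(t3, "Sn3")$code, "T")

  # Sn2 terminal version with incomplete internal modules -> T1
  t1 <- arch_from_runs(c("B1", "C1", "B2", "C2", "B3"),
                       c(40, 12, 13, 10, 100))
  expect_equal(call_version(t1, "Sn2")$code, "T1")

  # and with an incomplete leading B1 -> T2
  t2 <- arch_from_runs(c("B1", "C1", "B2", "C2", "B3"),
                       c(14, 8, 37, 30, 100))
  expect_equal(call_version(t2, "Sn2")$code, "T2")

  expect_error(call_version(l1[0, ], "Sn1"), "empty")
})

test_that("version calling is a pure function of the architecture", {
  ds <- fixture_dataset()
  idx <- seq(1, length(ds$records), by = 5)
  archs <- lapply(ds$records[idx], function(rec) {
    sig <- detect_signal(rec$protein)
    segment_modules(rec$protein, sig$end)
  })
  classes <- ds$truth$class[idx]
  v1 <- mapply(function(a, cl) call_version(a, cl)$code, archs, classes)
  perm <- rev(seq_along(archs))
  v2 <- mapply(function(a, cl) call_version(a, cl)$code,
               archs[perm], classes[perm])
  expect_identical(v1, rev(v2))
})

test_that("version recovery on the synthetic dataset is near-perfect", {
  ds <- fixture_dataset()
  got <- vapply(seq_along(ds$records), function(i) {
    rec <- ds$records[[i]]
    sig <- detect_signal(rec$protein)
    arch <- segment_modules(rec$protein, sig$end,
                            class_hint = ds$truth$class[i])
    call_version(arch, ds$truth$class[i])$code
  }, character(1))
  expect_gte(mean(got == ds$truth$version), 0.95)
})

test_that("same-gene isoforms group together, paralogs apart", {
  # three isoforms of one synthetic Sn2 gene share their N-terminus
  iso <- lapply(c("L", "C", "T1"), function(v)
    make_protein(seroin_spec("Sn2", v, seed = 777), id = paste0("iso_", v)))
  recs <- data.frame(id = vapply(iso, `[[`, "", "id"),
                     protein = vapply(iso, `[[`, "", "protein"),
                     stringsAsFactors = FALSE)
  g <- group_genes(recs)
  expect_length(g, 1L)
  expect_equal(g[[1]]$gene_number, 1L)
  expect_setequal(g[[1]]$members, recs$id)
  expect_equal(g[[1]]$evidence, "n_terminal_identity")

  # an unrelated gene of the same class separates
  par2 <- make_protein(seroin_spec("Sn2", "L", seed = 778), id = "para")
  recs2 <- rbind(recs, data.frame(id = "para", protein = par2$protein))
  g2 <- group_genes(recs2)
  expect_length(g2, 2L)
  expect_equal(vapply(g2, `[[`, 1L, "gene_number"), c(1L, 2L))
  expect_equal(g2[[2]]$members, "para")
  # the output partitions the input
  expect_setequal(unlist(lapply(g2, `[[`, "members")), recs2$id)

  # a single record is one default-evidence group
  g3 <- group_genes(recs[1, , drop = FALSE])
  expect_length(g3, 1L)
  expect_equal(g3[[1]]$evidence, "default")

  # genomic evidence can force a split the sequences would not support
  g4 <- group_genes(recs, genomic_split = list(recs$id[1:2], recs$id[3]))
  expect_length(g4, 2L)
  expect_equal(g4[[1]]$evidence, "genomic")
})
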
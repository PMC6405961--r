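test_that("composition profiles count windowed fractions correctly", {
  p <- composition_profile(strrep("P", 15))
  expect_true(all(p$pro_frac == 1))
  a <- composition_profile(strrep("A", 15))
  expect_true(all(a$ased_frac == 1))
  expect_true(all(a$pro_frac == 0))

  pa <- composition_profile(strrep("PA", 8))
  centre <- pa$pro_frac[8:9]
  expect_true(all(abs(centre - 0.5) <= 1 / 15))

  expect_error(composition_profile("PPP"), "shorter")
})

test_that("signal detection finds the hydrophobic stretch", {
  prot <- paste0("M", strrep("L", 12), "SQA",
                 strrep("SEDKATEDSK", 6))
  sig <- detect_signal(prot)
  expect_gte(sig$end, 15)
  expect_lte(sig$end, 20)
  expect_false(sig$default)

  # generator truth: predicted end within 4 residues of the planted length
  ds <- fixture_dataset()
  errs <- vapply(ds$records, function(rec) {
    abs(detect_signal(rec$protein)$end -
          rec$true_architecture$end[1])
  }, numeric(1))
  expect_true(all(errs <= 4))

  expect_error(detect_signal(paste0("KLMNP", strrep("A", 40))),
               "no initiator Met")
})

test_that("module segmentation recovers B/C alternation from composition", {
  # zero Pro -> a single all-B module
  prot <- paste0("M", strrep("L", 14), "STNQA", strrep("ASEDKATEDS", 8))
  arch <- segment_modules(prot, 20L)
  mature <- arch[arch$label != "A", ]
  expect_equal(mature$label, "B1")

  # B1, C1, B2 from a constructed composition switch
  set.seed(5)
  b_part <- function(n) paste(sample(c("A", "S", "E", "D"), n, TRUE),
                              collapse = "")
  c_part <- paste(ifelse(stats::runif(30) < 0.5, "P", "A"), collapse = "")
  prot <- paste0("M", strrep("L", 14), "STNQA",
                 b_part(40), c_part, b_part(50))
  arch <- segment_modules(prot, 20L)
  expect_equal(arch$label, c("A", "B1", "C1", "B2"))
  expect_lte(abs(arch$start[3] - 60), 5)
  expect_lte(abs(arch$end[3] - 90), 5)
})

test_that("segmentation labels alternate and the call is deterministic", {
  ds <- fixture_dataset()
  for (rec in ds$records[seq(1, length(ds$records), by = 7)]) {
    sig <- detect_signal(rec$protein)
    a1 <- segment_modules(rec$protein, sig$end)
    a2 <- segment_modules(rec$protein, sig$end)
    expect_identical(as.data.frame(a1), as.data.frame(a2))
    types <- substr(a1$label[a1$label != "A"], 1, 1)
    if (length(types) > 1)
      expect_true(all(types[-1] != types[-length(types)]))
    # spans tile the protein
    expect_equal(a1$start[-1], a1$end[-nrow(a1)])
  }
})

test_that("segment boundaries match generator truth within 5 residues", {
  ds <- fixture_dataset()
  total <- 0L; hit <- 0L
  for (i in seq_along(ds$records)) {
    rec <- ds$records[[i]]
    cl <- ds$truth$class[i]
    sig <- detect_signal(rec$protein)
    arch <- segment_modules(rec$protein, sig$end, class_hint = cl)
    canon <- call_version(arch, cl)$canonical
    truth <- rec$true_architecture
    for (k in seq_len(nrow(truth))) {
      total <- total + 1L
      m <- canon[canon$label == truth$label[k], ]
      if (nrow(m) == 1 && abs(m$start - truth$start[k]) <= 5 &&
          abs(m$end - truth$end[k]) <= 5)
        hit <- hit + 1L
    }
  }
  expect_gte(hit / total, 0.9)
})
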
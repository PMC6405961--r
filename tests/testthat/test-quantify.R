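test_that("lambda solves its defining equation in closed-form cases", {
  m <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  diag(m) <- 1
  bg <- c(A = .25, C = .25, G = .25, T = .25)
  kp <- karlin_altschul_params(m, bg)
  expect_equal(kp$lambda, log(3), tolerance = 1e-6)

  # doubling all scores halves lambda exactly
  kp2 <- karlin_altschul_params(m * 2, bg)
  expect_equal(kp2$lambda, kp$lambda / 2, tolerance = 1e-9)

  # the exact K for the +1/-1 uniform walk is 1/3
  expect_equal(kp$K, 1 / 3, tolerance = 1e-3)

  all_neg <- matrix(-1, 2, 2, dimnames = list(c("A", "C"), c("A", "C")))
  expect_error(karlin_altschul_params(all_neg, c(A = .5, C = .5)),
               "invalid scoring")
})

test_that("BLOSUM62 parameters reproduce published ungapped values", {
  kp <- karlin_altschul_params(seroscan:::blosum62())
  expect_equal(kp$lambda, 0.3176, tolerance = 2e-3)
  expect_equal(kp$K, 0.134, tolerance = 0.01)
  expect_equal(kp$H, 0.40, tolerance = 0.02)
})

test_that("E-values decrease strictly in score and increase in length", {
  kp <- karlin_altschul_params(seroscan:::blosum62())
  e <- function(S, n = 50) kp$K * 80 * n * exp(-kp$lambda * S)
  scores <- seq(20, 200, by = 10)
  expect_true(all(diff(e(scores)) < 0))
  expect_gt(e(100, 100), e(100, 50))
})

test_that("translated search finds planted reads on either strand", {
  kp <- karlin_altschul_params(seroscan:::blosum62())
  rec <- make_cdna(make_protein(seroin_spec("Sn1", "L", seed = 11),
                                id = "ref"), seed = 2)
  q <- cterm_query(rec$protein)$query
  expect_equal(nchar(q), 80)
  orf <- longest_orf(rec$cdna)
  cds_end <- orf$end - 3
  read <- substr(rec$cdna, cds_end - 150 + 1, cds_end)
  hit <- local_align_translated(read, q, kp)
  expect_lt(hit$evalue, 1e-20)
  hit_rc <- local_align_translated(reverse_complement(read), q, kp)
  expect_equal(hit_rc$score, hit$score)
  expect_true(hit_rc$frame %in% 3:5)

  short <- local_align_translated("AC", q, kp)
  expect_null(short)
})

test_that("class counting assigns planted reads and ignores noise", {
  specs <- list(Sn1 = seroin_spec("Sn1", "L", seed = 11),
                Sn2 = seroin_spec("Sn2", "L", seed = 12),
                Sn3 = seroin_spec("Sn3", "L", seed = 13))
  recs <- lapply(names(specs), function(cl)
    make_cdna(make_protein(specs[[cl]], id = cl), seed = match(cl, names(specs))))
  names(recs) <- names(specs)
  queries <- vapply(recs, function(r) cterm_query(r$protein)$query, "")
  cterm <- vapply(recs, function(r) {
    cds_end <- longest_orf(r$cdna)$end - 3
    substr(r$cdna, cds_end - 240 + 1, cds_end)
  }, "")
  src <- data.frame(id = names(recs), sequence = unname(cterm),
                    stringsAsFactors = FALSE)
  rr <- make_reads(src, c(Sn1 = 2, Sn2 = 1, Sn3 = 1), read_len = 150,
                   n_reads = 120, error_rate = 0, seed = 5)
  cc <- count_class_reads(rr$reads, queries)
  # perfect recall, zero cross-class assignment
  expect_identical(unname(cc$assignments$class), rr$origin$source)
  expect_equal(cc$unassigned, 0L)
  # conservation: class counts + unassigned = total
  expect_equal(sum(cc$counts) + cc$unassigned, cc$total)

  # random reads produce no hits at the threshold
  set.seed(8)
  rnd <- data.frame(id = sprintf("r%03d", 1:100),
                    sequence = replicate(100, random_dna(150)),
                    stringsAsFactors = FALSE)
  cr <- count_class_reads(rnd, queries)
  expect_true(all(cr$counts == 0))
  expect_equal(cr$unassigned, 100L)

  # with the threshold disabled every positive-scoring read is counted
  cinf <- count_class_reads(rnd[1:10, ], queries["Sn1"],
                            evalue_max = Inf)
  expect_equal(sum(cinf$counts), 10L)
})
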
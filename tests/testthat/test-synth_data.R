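test_that("every generator is byte-deterministic under a fixed seed", {
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_all(42L, dir = d1)
  simulate_all(42L, dir = d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_equal(list.files(d1, recursive = TRUE),
               list.files(d2, recursive = TRUE))
  expect_true(length(f1) >= 8L)
  for (i in seq_along(f1)) {
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "sim_c")
  unlink(d3, recursive = TRUE)
  simulate_all(43L, dir = d3)
  fa1 <- file.path(d1, "transcriptome", "transcripts.fasta")
  fa3 <- file.path(d3, "transcriptome", "transcripts.fasta")
  expect_false(identical(readBin(fa1, "raw", file.size(fa1)),
                         readBin(fa3, "raw", file.size(fa3))))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(555)
  before <- .Random.seed
  invisible(gen_transcriptome(1L, n_background = 5L))
  expect_identical(.Random.seed, before)
})

test_that("the transcriptome generator plants exact truth", {
  g <- gen_transcriptome(99L, n_background = 50L)
  expect_equal(length(g$transcripts), 51L)
  planted <- g$truth$planted[[1]]
  expect_equal(planted$scc_motif, "UGACUAG")
  t <- g$transcripts[[planted$id]]
  e <- find_extension(t)
  expect_equal(substr(e$peptide, 2L, nchar(e$peptide)),
               planted$extension_peptide)
  # background never carries the avoided motif
  expect_equal(count_consensus(g$transcripts, "UGACUAG"), 1L)
  # n = 0 gives only the planted entries
  g0 <- gen_transcriptome(99L, n_background = 0L, planted = list())
  expect_equal(length(g0$transcripts), 0L)
  expect_error(gen_transcriptome(1L, planted = list(
    list(id = "bad", extension_peptide = "L*A"))))
})

test_that("reporter truth is recovered exactly at zero noise", {
  g <- gen_reporter(7L, constructs = data.frame(
    construct = "c", true_readthrough_percent = 4.34),
    sigma = 0, n_replicates = 3L)
  s <- readthrough_percent(g$plate[g$plate$construct == "c", ],
                           g$plate[g$plate$construct == "control100", ])
  expect_equal(s$mean, 4.34, tolerance = 1e-12)
  expect_equal(s$sem, 0)
})

test_that("the reporter estimator is consistent under multiplicative noise", {
  rho <- 4.34
  g <- gen_reporter(1234L, constructs = data.frame(
    construct = "c", true_readthrough_percent = rho),
    sigma = 0.1, n_replicates = 1000L)
  s <- readthrough_percent(g$plate[g$plate$construct == "c", ],
                           g$plate[g$plate$construct == "control100", ])
  expect_lt(abs(s$mean - rho), 0.05 * rho)
})

test_that("a twofold readthrough difference is detected at n = 5, sigma = 0.1", {
  hits <- 0L
  for (seed in 1:40) {
    g <- gen_reporter(seed, constructs = data.frame(
      construct = c("a", "b"), true_readthrough_percent = c(2, 4)),
      sigma = 0.1, n_replicates = 5L)
    ctrl <- g$plate[g$plate$construct == "control100", ]
    va <- readthrough_percent(g$plate[g$plate$construct == "a", ], ctrl)
    vb <- readthrough_percent(g$plate[g$plate$construct == "b", ], ctrl)
    if (compare_groups(va$values, vb$values)$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("zero-jitter peak lists recover exactly the requested variants", {
  db <- build_variant_db(mdh1x_like_construct()$base_seq)
  g <- gen_peaklists(11L, db, variants = c("W", "R"), ppm_sigma = 0)
  call <- match_peaklists(g$peaklists, db)
  expect_setequal(call$stringent, c("W", "R"))
})

test_that("1-ppm jitter is recovered at 3-ppm tolerance across seeds", {
  db <- build_variant_db(mdh1x_like_construct()$base_seq)
  ok <- vapply(1:25, function(seed) {
    g <- gen_peaklists(seed, db, variants = c("W", "R"), ppm_sigma = 1)
    call <- match_peaklists(g$peaklists, db)
    all(c("W", "R") %in% call$stringent)
  }, NA)
  expect_gte(mean(ok), 0.99)
})

test_that("orthologue templates respect clade termini and the substitution rate", {
  g0 <- gen_orthologues(5L, sub_rate = 0)
  expect_equal(length(unique(g0$set$extension[g0$set$clade == "mammal"])), 1L)
  g <- gen_orthologues(5L, sub_rate = 0.3)
  trip <- substr(g$set$extension, nchar(g$set$extension) - 2L,
                 nchar(g$set$extension))
  expect_true(all(trip[g$set$clade == "mammal"] == "CRL"))
  expect_true(all(trip[g$set$clade == "non-mammal-vertebrate"] == "SRL"))
  # conservation decreases as the substitution rate grows (averaged trend)
  mean_cons <- function(rate) {
    mean(vapply(1:8, function(s) {
      mean(align_extensions(gen_orthologues(s, sub_rate = rate)$set)$conservation)
    }, 0))
  }
  expect_gt(mean_cons(0.02), mean_cons(0.4))
})
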
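fixture_measurements <- function() {
  read.delim(system.file("extdata", "scc_measurements.tsv",
                         package = "readthroughx"),
             stringsAsFactors = FALSE)
}

random_scc <- function() {
  nt <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                          collapse = "")
  scc(sample(c("UAA", "UAG", "UGA"), 1L), nt(10L), nt(10L))
}

test_that("featurization activates exactly one indicator per position", {
  s <- scc("UGA", "AACGGCAUCG", "CUAGAAGCAG")
  v <- featurize_scc(s)
  expect_equal(unname(v["stop:UGA"]), 1)
  expect_equal(unname(v["+4:C"]), 1)
  expect_equal(unname(v["+5:U"]), 1)
  expect_equal(unname(v["+6:A"]), 1)
  expect_equal(unname(v["+7:G"]), 1)
  P <- length(rtp_positions())
  expect_equal(sum(v), P)

  # two SCCs differing at one position differ in exactly 2 indicators
  s2 <- scc("UGA", "AACGGCAUCG", "CGAGAAGCAG")
  expect_equal(sum(featurize_scc(s) != featurize_scc(s2)), 2L)

  set.seed(7)
  for (i in 1:25) {
    expect_equal(sum(featurize_scc(random_scc())), P)
  }
})

test_that("a one-point fit returns the log10 measurement as intercept", {
  m <- fit_rtp(data.frame(upstream = "", stop = "UGA", downstream = "CUAGAAGCAG",
                          readthrough_percent = 4.34))
  expect_equal(m$intercept, log10(4.34))
  expect_true(all(unlist(m$coef) == 0))
})

test_that("noiseless planted coefficients are recovered to machine precision", {
  set.seed(33)
  positions <- rtp_positions()
  planted <- lapply(positions, function(p) {
    ab <- if (p == "stop") c("UAA", "UAG", "UGA") else c("A", "C", "G", "U")
    v <- rnorm(length(ab))
    setNames(v - mean(v), ab)  # sum-to-zero truth
  })
  names(planted) <- positions
  intercept <- -0.8
  sccs <- replicate(120, random_scc(), simplify = FALSE)
  y <- vapply(sccs, function(s) {
    intercept + sum(vapply(positions, function(p) {
      planted[[p]][[scc_symbol(s, p)]]
    }, 0))
  }, 0)
  meas <- data.frame(
    upstream = vapply(sccs, `[[`, "", "upstream"),
    stop = vapply(sccs, `[[`, "", "stop"),
    downstream = vapply(sccs, `[[`, "", "downstream"),
    readthrough_percent = 10^y)
  m <- fit_rtp(meas)
  err <- unlist(m$coef)[names(unlist(planted))] - unlist(planted)
  expect_lt(sqrt(mean(err^2)), 1e-8)
  expect_equal(m$intercept, intercept, tolerance = 1e-8)
})

test_that("non-positive measurements and rank-deficient designs are handled", {
  expect_error(fit_rtp(data.frame(upstream = "", stop = "UGA",
                                  downstream = "CUAGAAGCAG",
                                  readthrough_percent = 0)),
               "positive")
  # +4 and +5 perfectly confounded: two SCCs, two symbols each, aligned
  meas <- data.frame(upstream = c("", ""), stop = c("UGA", "UGA"),
                     downstream = c("CUAGAAGCAG", "AGAGAAGCAG"),
                     readthrough_percent = c(4, 0.4))
  expect_warning(m <- fit_rtp(meas), "rank-deficient")
  expect_s3_class(m, "rtp_model")
})

test_that("scoring is linear: single-position swaps move the score by the coefficient difference", {
  m <- default_rtp_model()
  s1 <- scc("UGA", "AACGGCAUCG", "CUAGAAGCAG")
  s2 <- scc("UGA", "AACGGCAUCG", "CAAGAAGCAG")  # +5 U -> A
  expect_equal(score_rtp(m, s1) - score_rtp(m, s2),
               m$coef[["+5"]][["U"]] - m$coef[["+5"]][["A"]])
  expect_error(score_rtp(m, scc("UGG", "", "CUAGAAGCAG")), "sense codon")
})

test_that("increasing a present symbol's coefficient strictly increases RTP", {
  m <- default_rtp_model()
  s <- scc("UGA", "AACGGCAUCG", "CUAGAAGCAG")
  base <- score_rtp(m, s)
  m$coef[["+5"]][["U"]] <- m$coef[["+5"]][["U"]] + 0.3
  expect_gt(score_rtp(m, s), base)
})

test_that("the default model reproduces the wild-type/mutant strict ordering", {
  m <- default_rtp_model()
  meas <- fixture_measurements()
  sc <- vapply(seq_len(nrow(meas)), function(i) {
    score_rtp(m, scc(meas$stop[i], meas$upstream[i], meas$downstream[i]))
  }, 0)
  names(sc) <- meas$label
  mid <- sc[c("p5_U_A", "p5_U_C", "p5_U_G", "p6_A_C", "p6_A_G", "p6_A_U")]
  low <- sc[c("stop_UAA", "stop_UAG", "p4_C_A", "p4_C_G", "p4_C_U")]
  expect_true(all(sc["WT"] > mid))
  expect_true(all(min(mid) > low))
})

test_that("the MDH1-style SCC outscores the LDHB-style SCC", {
  m <- default_rtp_model()
  refs <- reference_sccs()
  expect_gt(score_rtp(m, refs$MDH1), score_rtp(m, refs$LDHB))
})

test_that("consensus extraction returns the maximal contiguous above-threshold run", {
  m <- default_rtp_model()
  cons <- rtp_consensus(m)
  expect_equal(cons$motif, "UGACUAG")
  expect_equal(cons$length, 7L)

  # all-zero downstream coefficients: consensus is the stop codon only
  m0 <- m
  for (p in paste0("+", 4:9)) m0$coef[[p]][] <- 0
  expect_equal(rtp_consensus(m0)$motif, "UGA")

  # planted strong +4..+6 and null beyond: 6-nt consensus
  m6 <- m
  m6$coef[["+7"]][] <- 0
  expect_equal(rtp_consensus(m6)$motif, "UGACUA")
  expect_equal(rtp_consensus(m6)$length, 6L)
})

test_that("model JSON serialization round-trips scores", {
  m <- default_rtp_model()
  f <- tempfile(fileext = ".json")
  write_rtp_model(m, f)
  m2 <- read_rtp_model(f)
  s <- reference_sccs()$MDH1
  expect_equal(score_rtp(m2, s), score_rtp(m, s))
  expect_equal(rtp_consensus(m2)$motif, rtp_consensus(m)$motif)
})
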
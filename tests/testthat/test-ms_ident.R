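test_that("the variant database holds 21 single-position variants with GAP last", {
  db <- build_variant_db("AAXGGK")
  expect_equal(nrow(db$variants), 21L)
  expect_equal(db$variants$label[21], "GAP")
  expect_true(all(c("AAWGGK", "AARGGK") %in% db$variants$sequence))
  expect_equal(db$variants$sequence[db$variants$label == "GAP"], "AAGGK")
  # every variant differs from base only at the marker
  lens <- nchar(db$variants$sequence)
  expect_equal(sort(unique(lens)), c(5L, 6L))
  expect_equal(sum(lens == 5L), 1L)
  subs <- db$variants[db$variants$label != "GAP", ]
  expect_equal(substr(subs$sequence, 1, 2), rep("AA", 20))
  expect_equal(substr(subs$sequence, 4, 6), rep("GGK", 20))
  expect_equal(substr(subs$sequence, 3, 3), subs$label)

  # the W variant equals the sense-codon (UGG) control construct sequence
  cons <- mdh1x_like_construct()
  dbf <- build_variant_db(cons$base_seq)
  expect_equal(dbf$variants$sequence[dbf$variants$label == "W"],
               sub("X", "W", cons$base_seq, fixed = TRUE))
  expect_error(build_variant_db("AAGGK"), "exactly one")
  expect_error(build_variant_db("AXXGGK"), "exactly one")
})

test_that("tryptic digestion applies the Keil rule and partitions the input", {
  d <- digest("AKRP", max_missed = 1L)
  expect_setequal(d$sequence[d$missed_cleavages == 0L], c("AK", "RP"))
  expect_true("AKRP" %in% d$sequence[d$missed_cleavages == 1L])
  # no K/R: whole sequence, 0 missed
  d2 <- digest("AGNST")
  expect_equal(d2$sequence, "AGNST")
  expect_equal(d2$missed_cleavages, 0L)
  # fully cleaved peptides partition the parent in order
  set.seed(14)
  for (i in 1:20) {
    s <- random_peptide(sample(5:40, 1))
    d <- digest(s)
    z <- d[d$missed_cleavages == 0L, ]
    expect_equal(paste(z$sequence[order(z$start)], collapse = ""), s)
  }
  expect_error(digest(""), "empty")
})

test_that("digestion equals the brute-force boundary enumerator on 500 random sequences", {
  set.seed(27)
  for (i in 1:500) {
    s <- random_peptide(sample(4:25, 1))
    got <- digest(s, max_missed = 1L)
    want <- bf_digest(s, max_missed = 1L)
    key <- function(d) {
      sort(paste(d$sequence, d$start, d$end, d$missed_cleavages))
    }
    expect_equal(key(got), key(want))
  }
})

test_that("monoisotopic masses and m/z follow standard arithmetic", {
  expect_equal(peptide_mass("GG"), 132.053485, tolerance = 1e-6)
  expect_equal(mz(999, 2), 500.507276, tolerance = 1e-9)
  expect_equal(peptide_mass("ACK", 57.021464) - peptide_mass("ACK"),
               57.021464)
  expect_error(peptide_mass("AZB"), "unknown residue")
  # mass additivity: mass(pq) = mass(p) + mass(q) - water
  set.seed(8)
  for (i in 1:25) {
    p <- random_peptide(sample(2:12, 1))
    q <- random_peptide(sample(2:12, 1))
    expect_equal(peptide_mass(paste0(p, q)),
                 peptide_mass(p) + peptide_mass(q) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("b/y ladders satisfy counting and complementarity identities", {
  fr <- fragment_ions("TVSWLEATNPK")
  n <- nchar("TVSWLEATNPK")
  expect_equal(sum(fr$series == "b"), n - 1L)
  expect_equal(sum(fr$series == "y"), n - 1L)
  # y1 of a K-terminated peptide
  expect_equal(fr$mz[fr$ion == "y1"], 147.112801, tolerance = 1e-6)
  # b_i + y_(n-i) = M + 2 protons
  M <- peptide_mass("TVSWLEATNPK")
  for (i in 1:(n - 1L)) {
    expect_equal(fr$mz[fr$ion == paste0("b", i)] +
                   fr$mz[fr$ion == paste0("y", n - i)],
                 M + 2 * 1.007276, tolerance = 1e-9)
  }
})

test_that("synthetic Trp and Arg spectra give a stringent {W, R} call", {
  db <- build_variant_db(mdh1x_like_construct()$base_seq)
  g <- gen_peaklists(19, db, variants = c("W", "R"), ppm_sigma = 1)
  call <- match_peaklists(g$peaklists, db)
  expect_setequal(call$stringent, c("W", "R"))
  expect_true(all(call$stringent %in% call$relaxed))
  # Arg substitution creates a new cleavage site: its spanning peptide is
  # shorter than the Trp one
  peps <- setNames(vapply(g$truth$variants, `[[`, "", "peptide"),
                   vapply(g$truth$variants, `[[`, "", "label"))
  expect_lt(nchar(peps[["R"]]), nchar(peps[["W"]]))
  expect_equal(peps[["R"]], "TVSR")
})

test_that("precursor matching respects the ppm tolerance window", {
  db <- build_variant_db(mdh1x_like_construct()$base_seq)
  g <- gen_peaklists(19, db, variants = "W", ppm_sigma = 0)
  pl <- g$peaklists[[1]]
  # shift the precursor by +5 ppm: no match at 3 ppm tolerance
  off <- peaklist(pl$id, pl$precursor_mz * (1 + 5e-6),
                  pl$precursor_charge, pl$fragments)
  call <- match_peaklists(list(off), db)
  expect_equal(length(call$relaxed), 0L)
  # ppm error is computed relative to the theoretical value
  expect_equal(ppm_error(1000.001, 1000), 1, tolerance = 1e-9)
})

test_that("precursor-only spectra reach the relaxed but not the stringent tier", {
  db <- build_variant_db(mdh1x_like_construct()$base_seq)
  qseq <- db$variants$sequence[db$variants$label == "Q"]
  peps <- digest(qseq, 0L)
  span <- peps[peps$start <= db$marker_pos & peps$end >= db$marker_pos, ]
  pl <- peaklist("q_precursor_only", mz(peptide_mass(span$sequence), 2L), 2L)
  call <- match_peaklists(list(pl), db)
  expect_true("Q" %in% call$relaxed)
  expect_equal(length(call$stringent), 0L)
})

test_that("stringent calls are always a subset of relaxed calls", {
  db <- build_variant_db(mdh1x_like_construct()$base_seq)
  for (seed in 1:5) {
    g <- gen_peaklists(seed, db, variants = c("W", "R", "Q"),
                       ppm_sigma = 1)
    call <- match_peaklists(g$peaklists, db)
    expect_true(all(call$stringent %in% call$relaxed))
  }
})

test_that("Leu/Ile mass ambiguity is reported as a set", {
  db <- build_variant_db(mdh1x_like_construct()$base_seq)
  g <- gen_peaklists(3, db, variants = "L", ppm_sigma = 0)
  call <- match_peaklists(g$peaklists, db)
  expect_true(all(c("L", "I") %in% call$stringent))
})

test_that("decoy-only spectra and missing precursors produce no calls", {
  db <- build_variant_db(mdh1x_like_construct()$base_seq)
  decoy <- peaklist("decoys", 1234.5678, 2L,
                    data.frame(mz = c(150.1, 480.2, 990.3),
                               intensity = c(10, 20, 30)))
  call <- match_peaklists(list(decoy), db)
  expect_equal(length(call$relaxed), 0L)
  nop <- peaklist("no_precursor", NA_real_)
  expect_warning(call2 <- match_peaklists(list(nop), db), "no precursor")
  expect_equal(nrow(call2$evidence), 0L)
})

test_that("MGF files round-trip peak lists", {
  db <- build_variant_db(mdh1x_like_construct()$base_seq)
  g <- gen_peaklists(5, db)
  f <- tempfile(fileext = ".mgf")
  write_mgf(g$peaklists, f)
  back <- read_mgf(f)
  expect_equal(length(back), length(g$peaklists))
  expect_equal(vapply(back, `[[`, "", "id"),
               vapply(g$peaklists, `[[`, "", "id"))
  expect_equal(back[[1]]$precursor_charge, g$peaklists[[1]]$precursor_charge)
  expect_equal(back[[1]]$precursor_mz, g$peaklists[[1]]$precursor_mz,
               tolerance = 1e-6)
  expect_equal(back[[1]]$fragments$mz, g$peaklists[[1]]$fragments$mz,
               tolerance = 1e-6)
  # matching works identically from the round-tripped file
  call <- match_peaklists(back, db)
  expect_setequal(call$stringent, c("W", "R"))
})
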
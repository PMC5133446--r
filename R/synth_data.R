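# Seeded generators for every input the pipeline consumes: transcriptomes
# with planted high-readthrough contexts, dual-reporter plates with
# multiplicative noise, variant peptide peak lists with ppm-scale jitter,
# and clade-templated orthologue extension sets. All generators are
# byte-deterministic under a fixed seed and emit their ground truth.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

#' Reverse-translate a peptide to RNA
#'
#' Deterministic by default (alphabetically first codon per residue, so
#' repeated calls agree); with `random = TRUE` a codon is sampled uniformly
#' per residue from the caller's RNG stream.
#'
#' @param peptide Amino-acid string (no placeholder characters).
#' @param random Sample codons instead of the alphabetical choice.
#' @return RNA string, 3x the peptide length, free of in-frame stops.
#' @export
reverse_translate <- function(peptide, random = FALSE) {
  aa <- strsplit(toupper(peptide), "")[[1]]
  codons <- vapply(aa, function(a) {
    cands <- sort(names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE == a])
    if (length(cands) == 0L) stop("no codon for residue '", a, "'")
    if (random) sample(cands, 1L) else cands[1L]
  }, "")
  chartr("T", "U", paste(codons, collapse = ""))
}

#' The canonical synthetic readthrough construct
#'
#' A synthetic MDH1x-style construct used as the default across the
#' generators: a parent tail ending in ...K-T-V-S, the readthrough-position
#' marker `X`, and an 18-residue extension terminating in the mammalian
#' hidden PTS1 tripeptide CRL, so the full readthrough peptide (`X` plus
#' extension) is 19 residues and the extension is encoded by 57 nt (54
#' coding + second stop).
#'
#' @return List: `parent_tail`, `extension_peptide` (18 aa after the
#'   marker), `ext_nt` (54 nt), `base_seq` (parent + `X` + extension, the
#'   variant-database input).
#' @export
mdh1x_like_construct <- function() {
  ext <- "LEATNPKSLESVSAGCRL"
  parent <- "MAGELVKSGAGKTVS"
  list(parent_tail = parent, extension_peptide = ext,
       ext_nt = reverse_translate(ext),
       base_seq = paste0(parent, "X", ext))
}

#' Generate a synthetic transcriptome with planted readthrough candidates
#'
#' Background transcripts get a random coding region, a random stop codon
#' and a random 3' region; any background SCC that would match a motif in
#' `avoid_motifs` is resampled so that planted truth stays exact. Planted
#' transcripts carry the given stop codon, an extension reverse-translated
#' from `extension_peptide` (its first codons determine the SCC downstream
#' sequence), a second stop, and a short 3' tail.
#'
#' @param seed Integer seed.
#' @param n_background Number of background transcripts.
#' @param planted List of planted entries, each a list with `id`,
#'   `extension_peptide` (residues after the readthrough position; must
#'   contain no stop-only-encodable characters), optional `stop`
#'   (default `"UGA"`) and `second_stop` (default `"UAA"`). Default: one
#'   MDH1x-style candidate with the UGA CUA G context and a CRL-terminated
#'   extension.
#' @param avoid_motifs SCC motifs (stop-anchored) excluded from background.
#' @param dir Optional directory: writes `transcripts.fasta` (with `stop=`
#'   header tokens) and `truth.json`.
#' @return List: `transcripts` (named list), `truth` (planted ids/motifs),
#'   and `files` when `dir` was given.
#' @export
gen_transcriptome <- function(seed, n_background = 99L,
                              planted = list(list(
                                id = "planted_MDH1x",
                                extension_peptide =
                                  mdh1x_like_construct()$extension_peptide)),
                              avoid_motifs = "UGACUAG", dir = NULL) {
  with_seed(seed, {
    txs <- list()
    truth_rows <- list()
    for (p in planted) {
      stop_cdn <- if (is.null(p$stop)) "UGA" else p$stop
      second <- if (is.null(p$second_stop)) "UAA" else p$second_stop
      ext_nt <- reverse_translate(p$extension_peptide)
      codons <- substring(ext_nt, seq(1, nchar(ext_nt), 3),
                          seq(3, nchar(ext_nt), 3))
      if (any(codons %in% STOP_CODONS)) {
        stop("planted extension contains an in-frame stop")
      }
      seq <- paste0(random_nt(90L), stop_cdn, ext_nt, second,
                    random_nt(12L))
      txs[[p$id]] <- transcript(p$id, seq, 91L)
      truth_rows[[p$id]] <- list(
        id = p$id,
        scc_motif = paste0(stop_cdn, substr(ext_nt, 1L, 4L)),
        extension_peptide = p$extension_peptide)
    }
    for (i in seq_len(n_background)) {
      id <- sprintf("bg_%03d", i)
      repeat {
        stop_cdn <- sample(STOP_CODONS, 1L)
        three_prime <- random_nt(60L)
        hit <- any(vapply(avoid_motifs, function(m) {
          paste0(stop_cdn, substr(three_prime, 1L, nchar(m) - 3L)) == m
        }, NA))
        if (!hit) break
      }
      txs[[id]] <- transcript(id, paste0(random_nt(90L), stop_cdn,
                                         three_prime), 91L)
    }
    out <- list(transcripts = txs,
                truth = list(planted = unname(truth_rows),
                             n_background = n_background,
                             avoid_motifs = avoid_motifs))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fa <- file.path(dir, "transcripts.fasta")
      tj <- file.path(dir, "truth.json")
      write_transcripts(txs, fa)
      jsonlite::write_json(out$truth, tj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      out$files <- c(fasta = fa, truth = tj)
    }
    out
  })
}

#' Generate a synthetic dual-reporter plate
#'
#' Per replicate, fluorescence is baseline times log-normal noise and
#' luminescence is fluorescence times (true readthrough/100) times the
#' control ratio times independent log-normal noise, so the noise is
#' multiplicative on both channels. A 100%-readthrough control construct
#' (`control100`) is always included.
#'
#' @param seed Integer seed.
#' @param constructs data.frame with columns `construct`,
#'   `true_readthrough_percent`.
#' @param n_replicates Replicates per construct (biological replicates;
#'   default 5).
#' @param sigma Log-scale noise SD (default 0.1).
#' @param baseline Mean fluorescence (arbitrary units).
#' @param control_ratio Luminescence/fluorescence ratio of the control at
#'   100% readthrough.
#' @param dir Optional directory: writes `plate.tsv` and `truth.json`.
#' @return List: `plate` (data.frame construct/replicate/venus/hrluc/
#'   blanks), `truth`, and `files` when `dir` was given.
#' @export
gen_reporter <- function(seed,
                         constructs = data.frame(
                           construct = c("SCC_wt", "SCC_mut"),
                           true_readthrough_percent = c(4.34, 0.06)),
                         n_replicates = 5L, sigma = 0.1,
                         baseline = 1000, control_ratio = 0.5,
                         dir = NULL) {
  stopifnot(sigma >= 0)
  with_seed(seed, {
    all_constructs <- rbind(
      constructs,
      data.frame(construct = "control100", true_readthrough_percent = 100))
    rows <- list()
    for (i in seq_len(nrow(all_constructs))) {
      cn <- all_constructs$construct[i]
      rho <- all_constructs$true_readthrough_percent[i]
      for (r in seq_len(n_replicates)) {
        venus <- baseline * exp(rnorm(1L, 0, sigma))
        hrluc <- venus * (rho / 100) * control_ratio *
          exp(rnorm(1L, 0, sigma))
        rows[[length(rows) + 1L]] <- data.frame(
          construct = cn, replicate = r, venus = venus, hrluc = hrluc,
          blank_venus = 0, blank_hrluc = 0, stringsAsFactors = FALSE)
      }
    }
    plate <- do.call(rbind, rows)
    out <- list(plate = plate,
                truth = list(constructs = all_constructs, sigma = sigma,
                             n_replicates = n_replicates))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      pt <- file.path(dir, "plate.tsv")
      tj <- file.path(dir, "truth.json")
      write.table(plate, pt, sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(out$truth, tj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      out$files <- c(plate = pt, truth = tj)
    }
    out
  })
}

#' Generate synthetic peak lists for readthrough variants
#'
#' For each requested variant the readthrough-spanning fully cleaved
#' tryptic peptide is taken from the database, its precursor m/z (at the
#' requested charge) and complete singly charged b/y ladder are emitted
#' with Gaussian relative mass jitter of `ppm_sigma`, plus uniform random
#' decoy fragment peaks.
#'
#' @param seed Integer seed.
#' @param db A `"variant_db"` (see [build_variant_db()]).
#' @param variants Residue labels to emit spectra for.
#' @param charges Named integer vector of precursor charges per label
#'   (unnamed labels default to 2).
#' @param ppm_sigma Relative mass jitter SD in ppm.
#' @param n_decoys Uniform decoy fragment peaks per spectrum.
#' @param mz_range Decoy m/z range.
#' @param dir Optional directory: writes `spectra.mgf` and `truth.json`.
#' @return List: `peaklists`, `truth` (emitted labels and peptides), and
#'   `files` when `dir` was given.
#' @export
gen_peaklists <- function(seed, db, variants = c("W", "R"),
                          charges = c(W = 3L, R = 2L), ppm_sigma = 1,
                          n_decoys = 5L, mz_range = c(50, 2000),
                          dir = NULL) {
  stopifnot(inherits(db, "variant_db"), ppm_sigma >= 0)
  with_seed(seed, {
    jitter <- function(x) x * (1 + rnorm(length(x), 0, ppm_sigma * 1e-6))
    pls <- list()
    truth_rows <- list()
    for (lab in variants) {
      vi <- match(lab, db$variants$label)
      if (is.na(vi)) stop("unknown variant label '", lab, "'")
      vseq <- db$variants$sequence[vi]
      peps <- digest(vseq, max_missed = 0L)
      peps <- peps[peps$start <= db$marker_pos & peps$end >= db$marker_pos,
                   , drop = FALSE]
      stopifnot(nrow(peps) == 1L)
      pep <- peps$sequence[1L]
      z <- if (lab %in% names(charges)) unname(charges[[lab]]) else 2L
      theo_pre <- mz(peptide_mass(pep), z)
      frag <- fragment_ions(pep)
      frag_mz <- jitter(frag$mz)
      decoy_mz <- runif(n_decoys, mz_range[1], mz_range[2])
      frags <- data.frame(
        mz = c(frag_mz, decoy_mz),
        intensity = c(runif(length(frag_mz), 100, 1000),
                      runif(n_decoys, 10, 100)))
      frags <- frags[order(frags$mz), , drop = FALSE]
      pls[[length(pls) + 1L]] <-
        peaklist(paste0("sim_", lab), jitter(theo_pre), z, frags)
      truth_rows[[lab]] <- list(label = lab, peptide = pep, charge = z)
    }
    out <- list(peaklists = pls,
                truth = list(variants = unname(truth_rows),
                             ppm_sigma = ppm_sigma, n_decoys = n_decoys))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      mg <- file.path(dir, "spectra.mgf")
      tj <- file.path(dir, "truth.json")
      write_mgf(pls, mg)
      jsonlite::write_json(out$truth, tj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      out$files <- c(mgf = mg, truth = tj)
    }
    out
  })
}

#' Generate a synthetic orthologue extension set
#'
#' Clade-templated extensions: a shared body with per-site substitution
#' noise everywhere except the readthrough-position marker and the terminal
#' tripeptide, which is fixed per clade (CRL in mammals, SRL in
#' non-mammalian vertebrates).
#'
#' @param seed Integer seed.
#' @param n_mammal,n_nonmammal Sequences per clade.
#' @param sub_rate Per-site substitution probability.
#' @param dir Optional directory: writes `orthologues.fasta` and
#'   `truth.json`.
#' @return List: `set` (an `"orthologue_set"`), `truth`, and `files` when
#'   `dir` was given.
#' @export
gen_orthologues <- function(seed, n_mammal = 6L, n_nonmammal = 5L,
                            sub_rate = 0.05, dir = NULL) {
  stopifnot(sub_rate >= 0, sub_rate <= 1)
  body <- paste0("X", substr(mdh1x_like_construct()$extension_peptide,
                             1L, 15L))
  templates <- c(mammal = paste0(body, "CRL"),
                 `non-mammal-vertebrate` = paste0(body, "SRL"))
  with_seed(seed, {
    mutate <- function(s) {
      aa <- strsplit(s, "")[[1]]
      n <- length(aa)
      for (i in 2:(n - 3L)) {  # spare the marker and terminal tripeptide
        if (runif(1L) < sub_rate) {
          aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
        }
      }
      paste(aa, collapse = "")
    }
    species <- c(sprintf("mammal_%02d", seq_len(n_mammal)),
                 sprintf("nonmammal_%02d", seq_len(n_nonmammal)))
    clade <- c(rep("mammal", n_mammal),
               rep("non-mammal-vertebrate", n_nonmammal))
    ext <- vapply(clade, function(cl) mutate(templates[[cl]]), "")
    set <- orthologue_set(species, clade, ext)
    out <- list(set = set,
                truth = list(templates = as.list(templates),
                             sub_rate = sub_rate))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fa <- file.path(dir, "orthologues.fasta")
      tj <- file.path(dir, "truth.json")
      seqs <- Biostrings::BStringSet(set$extension)
      names(seqs) <- paste0(set$species, " clade=", set$clade)
      Biostrings::writeXStringSet(seqs, fa, width = 70L)
      jsonlite::write_json(out$truth, tj, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      out$files <- c(fasta = fa, truth = tj)
    }
    out
  })
}

#' Run every generator from one master seed
#'
#' Fans the master seed out to one derived stream per generator so each
#' module's inputs can be regenerated independently.
#'
#' @param seed Master integer seed.
#' @param dir Optional output directory (one subdirectory per generator).
#' @param ... Reserved.
#' @return List with elements `transcriptome`, `reporter`, `peaklists`,
#'   `orthologues`.
#' @export
simulate_all <- function(seed, dir = NULL, ...) {
  sub <- function(name) if (is.null(dir)) NULL else file.path(dir, name)
  db <- build_variant_db(mdh1x_like_construct()$base_seq)
  list(
    transcriptome = gen_transcriptome(seed + 1L, dir = sub("transcriptome")),
    reporter = gen_reporter(seed + 2L, dir = sub("reporter")),
    peaklists = gen_peaklists(seed + 3L, db, dir = sub("peaklists")),
    orthologues = gen_orthologues(seed + 4L, dir = sub("orthologues")))
}
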
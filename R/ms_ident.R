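# Identification of the residue incorporated at the readthrough position
# from peptide-level mass evidence: variant proteoform database, in-silico
# tryptic digestion, monoisotopic mass / m/z / b- and y-ion arithmetic, and
# two-tier ppm matching of peak lists.

# Monoisotopic residue masses (Da), standard table.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

# Variable modifications: name, target residue, monoisotopic delta (Da).
VARIABLE_MODS <- list(
  carbamidomethyl = list(target = "C", delta = 57.021464),
  oxidation = list(target = "M", delta = 15.994915))

#' Monoisotopic residue mass table
#' @return Named numeric vector (Da) over the 20 proteinogenic residues.
#' @export
residue_masses <- function() AA_MONO

#' Matching configuration
#'
#' Defaults follow high-resolution QTOF practice: 3 ppm precursor tolerance
#' for the stringent evidence tier, 10 ppm for fragment ions, m/z range
#' 50-2000, precursor charges 1-3, variable carbamidomethylation of Cys and
#' oxidation of Met, trypsin with one allowed missed cleavage.
#'
#' @param precursor_tol_ppm,fragment_tol_ppm Tolerances (ppm, > 0).
#' @param mz_range Length-2 numeric, acquisition m/z window.
#' @param charges Allowed precursor charge states.
#' @param variable_mods Subset of `c("carbamidomethyl", "oxidation")`.
#' @param max_missed Allowed missed tryptic cleavages.
#' @return List of class `"ms_config"`.
#' @export
ms_config <- function(precursor_tol_ppm = 3, fragment_tol_ppm = 10,
                      mz_range = c(50, 2000), charges = 1:3,
                      variable_mods = c("carbamidomethyl", "oxidation"),
                      max_missed = 1L) {
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0,
            length(mz_range) == 2L,
            all(variable_mods %in% names(VARIABLE_MODS)))
  structure(list(precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm,
                 mz_range = mz_range, charges = as.integer(charges),
                 variable_mods = variable_mods,
                 max_missed = as.integer(max_missed)),
            class = "ms_config")
}

#' Build the readthrough-position variant database
#'
#' From a construct sequence with a single readthrough-position marker,
#' builds 21 variants: one per proteinogenic amino acid substituted at the
#' marker (alphabetical order) plus a one-residue gap (marker deleted),
#' last.
#'
#' @param base_seq Amino-acid string containing `marker` exactly once.
#' @param marker Single marker character (default `"X"`).
#' @return List of class `"variant_db"`: `base_seq`, `marker_pos` and a
#'   data.frame `variants` with columns `label` (residue or `"GAP"`) and
#'   `sequence`.
#' @export
build_variant_db <- function(base_seq, marker = "X") {
  base_seq <- toupper(base_seq)
  hits <- gregexpr(marker, base_seq, fixed = TRUE)[[1]]
  if (length(hits) != 1L || hits[1] == -1L) {
    stop("base_seq must contain exactly one '", marker, "' marker")
  }
  pos <- as.integer(hits[1])
  sub_at <- function(aa) {
    paste0(substr(base_seq, 1L, pos - 1L), aa,
           substr(base_seq, pos + 1L, nchar(base_seq)))
  }
  variants <- data.frame(
    label = c(AA20, "GAP"),
    sequence = c(vapply(AA20, sub_at, ""), sub_at("")),
    stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  structure(list(base_seq = base_seq, marker_pos = pos,
                 variants = variants),
            class = "variant_db")
}

#' @export
print.variant_db <- function(x, ...) {
  cat("<variant_db> ", nrow(x$variants), " variants, readthrough position ",
      x$marker_pos, "\n", sep = "")
  invisible(x)
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is proline
#' (Keil rule), and emits every peptide with 0..`max_missed` missed
#' cleavages with its 1-based coordinates in the parent.
#'
#' @param seq Amino-acid string of standard residues.
#' @param max_missed Maximum missed cleavages.
#' @return data.frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`.
#' @export
digest <- function(seq, max_missed = 1L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  if (grepl(paste0("[^", paste(AA20, collapse = ""), "]"), seq)) {
    stop("sequence contains non-standard residues")
  }
  aa <- strsplit(seq, "")[[1]]
  # cut after position i when aa[i] is K/R and aa[i+1] is not P
  cuts <- which(aa[-n] %in% c("K", "R") & aa[-1] != "P")
  bounds <- c(0L, cuts, n)  # fragment i spans bounds[i]+1 .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nfrag) break
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      out[[length(out) + 1L]] <-
        data.frame(sequence = substr(seq, s, e), start = s, end = e,
                   missed_cleavages = m, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus any modification
#' deltas.
#'
#' @param seq Amino-acid string.
#' @param mod_deltas Optional numeric vector of modification mass deltas
#'   (Da), e.g. one entry per modified residue.
#' @return Mass in Da.
#' @export
peptide_mass <- function(seq, mod_deltas = NULL) {
  aa <- strsplit(toupper(seq), "")[[1]]
  if (!all(aa %in% names(AA_MONO))) {
    stop("unknown residue in '", seq, "'")
  }
  sum(AA_MONO[aa]) + WATER_MASS + sum(mod_deltas)
}

#' m/z of a (peptide) mass at a given charge
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge.
#' @return m/z = (mass + charge * proton) / charge.
#' @export
mz <- function(mass, charge) (mass + charge * PROTON_MASS) / charge

#' Relative mass deviation in ppm
#' @param observed,theoretical m/z or mass values.
#' @return |observed - theoretical| / theoretical * 1e6.
#' @export
ppm_error <- function(observed, theoretical) {
  abs(observed - theoretical) / theoretical * 1e6
}

#' b- and y-fragment ions of a peptide
#'
#' b_i is the N-terminal prefix of length i (prefix residue mass + proton);
#' y_i the C-terminal suffix of length i (suffix residue mass + water +
#' proton). No neutral-loss ions are generated.
#'
#' @param seq Amino-acid string, length >= 2.
#' @param charge Fragment charge (default 1).
#' @param mod_deltas Optional per-residue modification delta vector (length
#'   of the peptide; unmodified residues 0).
#' @return data.frame with columns `ion` (e.g. `"b2"`, `"y5"`), `series`,
#'   `index`, `mz`.
#' @export
fragment_ions <- function(seq, charge = 1L, mod_deltas = NULL) {
  aa <- strsplit(toupper(seq), "")[[1]]
  n <- length(aa)
  stopifnot(n >= 2L)
  res <- AA_MONO[aa]
  if (!is.null(mod_deltas)) {
    stopifnot(length(mod_deltas) == n)
    res <- res + mod_deltas
  }
  pre <- cumsum(res)[-n]
  suf <- rev(cumsum(rev(res)))[-1]
  data.frame(
    ion = c(paste0("b", seq_len(n - 1L)), paste0("y", rev(seq_len(n - 1L)))),
    series = rep(c("b", "y"), each = n - 1L),
    index = c(seq_len(n - 1L), rev(seq_len(n - 1L))),
    mz = c((pre + charge * PROTON_MASS) / charge,
           (suf + WATER_MASS + charge * PROTON_MASS) / charge),
    row.names = NULL, stringsAsFactors = FALSE)
}

# All variable-modification assignments for a peptide: list of per-residue
# delta vectors with a readable label each.
mod_combinations <- function(seq, variable_mods) {
  aa <- strsplit(toupper(seq), "")[[1]]
  sites <- list()
  for (mn in variable_mods) {
    m <- VARIABLE_MODS[[mn]]
    for (p in which(aa == m$target)) {
      sites[[length(sites) + 1L]] <- list(pos = p, name = mn,
                                          delta = m$delta)
    }
  }
  combos <- list(list(deltas = numeric(length(aa)), label = ""))
  for (s in sites) {
    combos <- c(combos, lapply(combos, function(cb) {
      d <- cb$deltas
      d[s$pos] <- d[s$pos] + s$delta
      list(deltas = d,
           label = paste0(cb$label, s$name, "@", s$pos, ";"))
    }))
  }
  combos
}

#' Construct a peak list
#' @param id Spectrum identifier.
#' @param precursor_mz Precursor m/z (NA allowed; such spectra are skipped
#'   by the matcher with a warning).
#' @param precursor_charge Precursor charge (NA = unknown, all configured
#'   charges are tried).
#' @param fragments data.frame with columns `mz`, `intensity` (may be
#'   empty).
#' @return List of class `"peaklist"`.
#' @export
peaklist <- function(id, precursor_mz, precursor_charge = NA_integer_,
                     fragments = data.frame(mz = numeric(0),
                                            intensity = numeric(0))) {
  structure(list(id = id, precursor_mz = precursor_mz,
                 precursor_charge = precursor_charge,
                 fragments = fragments),
            class = "peaklist")
}

# GAP-variant peptides span the readthrough position when they cover the
# deletion junction (residues marker_pos-1 and marker_pos of the shortened
# sequence, clamped at the termini).
spans_marker_gap <- function(start, end, marker_pos, seq_len_total) {
  lo <- max(1L, marker_pos - 1L)
  hi <- min(seq_len_total, marker_pos)
  start <= lo & end >= hi
}

#' Match peak lists against a readthrough variant database
#'
#' For every peak list and every variant, readthrough-spanning tryptic
#' peptides (allowing missed cleavages and every variable-modification
#' assignment) are compared with the precursor m/z at the configured charge
#' states within `precursor_tol_ppm`. A precursor-level match puts the
#' variant's residue in the relaxed tier. The stringent tier additionally
#' requires at least one matched b- or y-ion (within `fragment_tol_ppm`) on
#' each side of the readthrough position, so that the fragment series
#' covers the incorporated residue; a peptide terminus counts as a bound on
#' its side. Leucine and isoleucine are mass-identical and always reported
#' together.
#'
#' @param peaklists List of `"peaklist"` objects.
#' @param db A `"variant_db"`.
#' @param config An `"ms_config"`.
#' @return List of class `"incorporation_call"`: `relaxed` and `stringent`
#'   (sorted residue-label character vectors, stringent a subset of
#'   relaxed), and `evidence` (data.frame of all precursor matches with
#'   fragment-coverage flags).
#' @export
match_peaklists <- function(peaklists, db, config = ms_config()) {
  stopifnot(inherits(db, "variant_db"), inherits(config, "ms_config"))
  ev <- list()
  for (pl in peaklists) {
    if (is.null(pl$precursor_mz) || is.na(pl$precursor_mz)) {
      warning("peak list '", pl$id, "' has no precursor; skipped")
      next
    }
    charges <- if (!is.na(pl$precursor_charge)) pl$precursor_charge
               else config$charges
    for (vi in seq_len(nrow(db$variants))) {
      label <- db$variants$label[vi]
      vseq <- db$variants$sequence[vi]
      gap <- label == "GAP"
      peps <- digest(vseq, config$max_missed)
      keep <- if (gap) {
        spans_marker_gap(peps$start, peps$end, db$marker_pos, nchar(vseq))
      } else {
        peps$start <= db$marker_pos & peps$end >= db$marker_pos
      }
      peps <- peps[keep, , drop = FALSE]
      for (pi in seq_len(nrow(peps))) {
        pep <- peps[pi, ]
        for (cb in mod_combinations(pep$sequence, config$variable_mods)) {
          m <- peptide_mass(pep$sequence, cb$deltas)
          for (z in charges) {
            theo <- mz(m, z)
            if (ppm_error(pl$precursor_mz, theo) >
                config$precursor_tol_ppm) next
            cov <- fragment_coverage(pl, pep$sequence, cb$deltas,
                                     db$marker_pos - pep$start + 1L,
                                     gap, config)
            ev[[length(ev) + 1L]] <- data.frame(
              spectrum = pl$id, label = label, peptide = pep$sequence,
              mods = cb$label, charge = z, theo_mz = theo,
              precursor_ppm = ppm_error(pl$precursor_mz, theo),
              n_side_covered = cov$n_side, c_side_covered = cov$c_side,
              stringent = cov$n_side && cov$c_side,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(spectrum = character(0), label = character(0),
               peptide = character(0), mods = character(0),
               charge = integer(0), theo_mz = numeric(0),
               precursor_ppm = numeric(0), n_side_covered = logical(0),
               c_side_covered = logical(0), stringent = logical(0))
  expand_li <- function(labels) {
    labels <- unique(labels)
    if (any(c("L", "I") %in% labels)) labels <- union(labels, c("L", "I"))
    sort(labels)
  }
  structure(list(relaxed = expand_li(ev$label),
                 stringent = expand_li(ev$label[ev$stringent]),
                 evidence = ev),
            class = "incorporation_call")
}

# Fragment coverage of the readthrough position: a matched b/y ion whose
# cleavage site falls strictly before the marker residue bounds its N side,
# one at or after the marker bounds its C side. marker_local is the marker
# residue index within the peptide (for GAP variants, the junction: the
# residue right of the deleted position, clamped into the peptide).
fragment_coverage <- function(pl, pep_seq, deltas, marker_local, gap,
                              config) {
  n <- nchar(pep_seq)
  if (gap) marker_local <- min(max(marker_local, 1L), n)
  if (n < 2L || nrow(pl$fragments) == 0L) {
    return(list(n_side = marker_local <= 1L, c_side = marker_local >= n))
  }
  theo <- fragment_ions(pep_seq, charge = 1L, mod_deltas = deltas)
  # cleavage site of b_i / y_{n-i} is i (between residues i and i+1)
  theo$site <- ifelse(theo$series == "b", theo$index, n - theo$index)
  matched <- vapply(theo$mz, function(tm) {
    any(ppm_error(pl$fragments$mz, tm) <= config$fragment_tol_ppm)
  }, NA)
  sites <- unique(theo$site[matched])
  list(n_side = marker_local <= 1L || any(sites < marker_local),
       c_side = marker_local >= n || any(sites >= marker_local))
}

#' @export
print.incorporation_call <- function(x, ...) {
  cat("<incorporation_call> relaxed {",
      paste(x$relaxed, collapse = ","), "}, stringent {",
      paste(x$stringent, collapse = ","), "}; ",
      nrow(x$evidence), " precursor match(es)\n", sep = "")
  invisible(x)
}

#' Read / write Mascot generic format (MGF) peak lists
#'
#' Minimal MGF support: BEGIN/END IONS blocks with TITLE, PEPMASS, CHARGE
#' and `m/z intensity` fragment lines.
#'
#' @param path File path.
#' @return List of `"peaklist"` objects (read); `path` (write).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      id <- NA_character_
      pmz <- NA_real_
      z <- NA_integer_
      frags <- list()
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) {
          id <- sub("^TITLE=", "", ln)
        } else if (startsWith(ln, "PEPMASS=")) {
          pmz <- as.numeric(strsplit(sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
        } else if (startsWith(ln, "CHARGE=")) {
          z <- as.integer(sub("\\+$", "", sub("^CHARGE=", "", ln)))
        } else if (grepl("^[0-9]", ln)) {
          v <- as.numeric(strsplit(ln, "\\s+")[[1]])
          frags[[length(frags) + 1L]] <-
            c(v[1], if (length(v) > 1L) v[2] else 1)
        }
        i <- i + 1L
      }
      fr <- if (length(frags)) {
        m <- do.call(rbind, frags)
        data.frame(mz = m[, 1], intensity = m[, 2])
      } else data.frame(mz = numeric(0), intensity = numeric(0))
      out[[length(out) + 1L]] <- peaklist(id, pmz, z, fr)
    }
    i <- i + 1L
  }
  out
}

#' @rdname read_mgf
#' @param peaklists List of `"peaklist"` objects.
#' @export
write_mgf <- function(peaklists, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (pl in peaklists) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", pl$id), con)
    if (!is.na(pl$precursor_mz)) {
      writeLines(sprintf("PEPMASS=%.6f", pl$precursor_mz), con)
    }
    if (!is.na(pl$precursor_charge)) {
      writeLines(paste0("CHARGE=", pl$precursor_charge, "+"), con)
    }
    if (nrow(pl$fragments)) {
      writeLines(sprintf("%.6f %.2f", pl$fragments$mz,
                         pl$fragments$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}
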
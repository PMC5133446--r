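#' @importFrom stats contr.sum plogis rnorm runif sd setNames t.test
#' @importFrom utils read.delim write.table
NULL

STOP_CODONS <- c("UAA", "UAG", "UGA")

#' Create a transcript record
#'
#' A transcript carries a nucleotide sequence together with the 1-based
#' position of the first base of its annotated stop codon. DNA input (T) is
#' normalised to RNA (U) on load; all downstream motifs are handled as RNA.
#'
#' @param id Transcript identifier.
#' @param seq Nucleotide sequence (A/C/G/U or T; case-insensitive).
#' @param stop_start 1-based index of the first nucleotide of the stop codon.
#' @param species Optional species label.
#' @param sense_control If `TRUE` the record is a sense-codon control (e.g. a
#'   UGG construct standing in for 100% readthrough) and the triplet at
#'   `stop_start` need not be a stop codon.
#' @return An object of class `"transcript"`.
#' @export
transcript <- function(id, seq, stop_start, species = NULL,
                       sense_control = FALSE) {
  seq <- chartr("Tt", "Uu", toupper(as.character(seq)))
  if (grepl("[^ACGU]", seq)) {
    stop("transcript '", id, "': sequence contains non-ACGU/T characters")
  }
  stop_start <- as.integer(stop_start)
  if (stop_start < 1L || stop_start + 2L > nchar(seq)) {
    stop("transcript '", id, "': stop_start out of range")
  }
  triplet <- substr(seq, stop_start, stop_start + 2L)
  if (!sense_control && !(triplet %in% STOP_CODONS)) {
    stop("transcript '", id, "': codon at stop_start is '", triplet,
         "', not a stop codon (flag sense_control for sense-codon controls)")
  }
  structure(list(id = id, seq = seq, stop_start = stop_start,
                 species = species, sense_control = sense_control),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript> ", x$id, ": ", nchar(x$seq), " nt, stop at ",
      x$stop_start, " (", substr(x$seq, x$stop_start, x$stop_start + 2L),
      ")\n", sep = "")
  invisible(x)
}

#' Construct a stop codon context directly from its parts
#'
#' Positions follow the +1..+3 convention: the stop codon occupies +1..+3 and
#' the first downstream base is +4. `upstream` is written 5' to 3', so its
#' last character is position -1 (adjacent to the stop).
#'
#' @param stop 3-nt stop codon (or sense triplet for controls).
#' @param upstream Nucleotides -U..-1 (may be "").
#' @param downstream Nucleotides +4..+(3+D) (may be "").
#' @param truncated Logical flag: flanks shorter than requested.
#' @return An object of class `"scc"`.
#' @export
scc <- function(stop, upstream = "", downstream = "", truncated = FALSE) {
  stop_cdn <- chartr("T", "U", toupper(stop))
  structure(list(stop = stop_cdn,
                 upstream = chartr("T", "U", toupper(upstream)),
                 downstream = chartr("T", "U", toupper(downstream)),
                 u_len = nchar(upstream), d_len = nchar(downstream),
                 truncated = truncated),
            class = "scc")
}

#' @export
print.scc <- function(x, ...) {
  cat("<scc> ", x$upstream, " [", x$stop, "] ", x$downstream,
      if (x$truncated) "  (truncated flanks)" else "", "\n", sep = "")
  invisible(x)
}

#' Reassemble an SCC into the contiguous subsequence it was taken from
#' @param x An `"scc"` object.
#' @return Single nucleotide string upstream+stop+downstream.
#' @export
scc_seq <- function(x) paste0(x$upstream, x$stop, x$downstream)

#' Extract the stop codon context of a transcript
#'
#' Default flanks are 10 nt on either side of the stop codon. Flanks that
#' would run past the sequence ends are truncated and the context flagged.
#'
#' @param t A `"transcript"`.
#' @param u_len,d_len Requested upstream/downstream flank lengths (nt).
#' @return An `"scc"` object.
#' @export
extract_scc <- function(t, u_len = 10L, d_len = 10L) {
  stopifnot(inherits(t, "transcript"), u_len >= 0, d_len >= 0)
  triplet <- substr(t$seq, t$stop_start, t$stop_start + 2L)
  if (!(triplet %in% STOP_CODONS) && !t$sense_control) {
    stop("codon at stop_start is a sense codon and the record is not ",
         "flagged as a control")
  }
  up_from <- max(1L, t$stop_start - u_len)
  up <- if (u_len > 0) substr(t$seq, up_from, t$stop_start - 1L) else ""
  down_to <- min(nchar(t$seq), t$stop_start + 2L + d_len)
  down <- if (d_len > 0) substr(t$seq, t$stop_start + 3L, down_to) else ""
  scc(triplet, up, down,
      truncated = nchar(up) < u_len || nchar(down) < d_len)
}

#' Translate an RNA/DNA sequence with the standard genetic code
#'
#' Stops translate to `*`. The codon table is `Biostrings::GENETIC_CODE`.
#'
#' @param nt Nucleotide string, length divisible by 3.
#' @return Amino-acid string.
#' @export
translate_nt <- function(nt) {
  nt <- chartr("Tt", "Uu", toupper(nt))
  if (nchar(nt) %% 3L != 0L) stop("length of 'nt' not divisible by 3")
  if (nchar(nt) == 0L) return("")
  if (grepl("[^ACGU]", nt)) stop("ambiguous or invalid base in 'nt'")
  codons <- substring(chartr("U", "T", nt),
                      seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Find the readthrough extension downstream of the annotated stop
#'
#' Scans codon-by-codon from position +4 to the first in-frame stop codon
#' (the "second stop") or, failing that, to the end of the transcript. The
#' translated peptide is prefixed with a placeholder residue for the
#' readthrough position itself (the residue actually incorporated at the
#' suppressed stop codon is heterogeneous).
#'
#' @param t A `"transcript"`.
#' @param placeholder Single character used for the readthrough position
#'   (default `"X"`; callers may substitute e.g. `"W"` or `"R"`).
#' @return An object of class `"readthrough_extension"` with fields
#'   `ext_nt` (nucleotides +4 .. last base before the second stop),
#'   `second_stop` (3-nt string or `NA` when the transcript ends without an
#'   in-frame stop) and `peptide` (placeholder + translation of `ext_nt`).
#' @export
find_extension <- function(t, placeholder = "X") {
  stopifnot(inherits(t, "transcript"), nchar(placeholder) == 1L)
  pos <- t$stop_start + 3L
  n <- nchar(t$seq)
  ext <- character(0)
  second <- NA_character_
  while (pos + 2L <= n) {
    codon <- substr(t$seq, pos, pos + 2L)
    if (codon %in% STOP_CODONS) {
      second <- codon
      break
    }
    ext <- c(ext, codon)
    pos <- pos + 3L
  }
  ext_nt <- paste(ext, collapse = "")
  structure(list(ext_nt = ext_nt, second_stop = second,
                 peptide = paste0(placeholder, translate_nt(ext_nt))),
            class = "readthrough_extension")
}

#' @export
print.readthrough_extension <- function(x, ...) {
  cat("<readthrough_extension> ", nchar(x$ext_nt), " nt, peptide ",
      x$peptide,
      if (is.na(x$second_stop)) " (no second in-frame stop)"
      else paste0(" (second stop ", x$second_stop, ")"), "\n", sep = "")
  invisible(x)
}

#' Read transcripts from FASTA
#'
#' The stop position is taken from a `stop=<int>` token in the FASTA header
#' (e.g. `>MDH1 stop=1003 species=human`) or, preferentially, from a sidecar
#' table with columns `id` and `stop_start`. A `control=1` token flags
#' sense-codon controls.
#'
#' @param fasta Path to a FASTA file.
#' @param stops Optional data.frame (or TSV path) with columns `id`,
#'   `stop_start`.
#' @return List of `"transcript"` objects, named by id.
#' @export
read_transcripts <- function(fasta, stops = NULL) {
  set <- Biostrings::readBStringSet(fasta)
  if (is.character(stops)) {
    stops <- read.delim(stops, stringsAsFactors = FALSE)
  }
  out <- lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    toks <- strsplit(header, "\\s+")[[1]]
    id <- toks[1]
    kv <- grep("=", toks[-1], value = TRUE)
    vals <- setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    ss <- NA_integer_
    if (!is.null(stops) && id %in% stops$id) {
      ss <- as.integer(stops$stop_start[match(id, stops$id)])
    } else if ("stop" %in% names(vals)) {
      ss <- as.integer(vals[["stop"]])
    }
    if (is.na(ss)) stop("no stop position for transcript '", id, "'")
    transcript(id, as.character(set[[i]]), ss,
               species = if ("species" %in% names(vals))
                 vals[["species"]] else NULL,
               sense_control = "control" %in% names(vals) &&
                 vals[["control"]] == "1")
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write transcripts to FASTA with `stop=` header tokens
#' @param transcripts List of `"transcript"` objects.
#' @param path Output path.
#' @export
write_transcripts <- function(transcripts, path) {
  seqs <- Biostrings::BStringSet(vapply(transcripts, `[[`, "", "seq"))
  names(seqs) <- vapply(transcripts, function(t) {
    paste0(t$id, " stop=", t$stop_start,
           if (!is.null(t$species)) paste0(" species=", t$species) else "",
           if (isTRUE(t$sense_control)) " control=1" else "")
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
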
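# Independent brute-force oracles used across the suite.

# Random transcript with a stop at a known position.
random_transcript <- function(id, n5 = 30L, n3 = 45L) {
  nt <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                          collapse = "")
  transcript(id, paste0(nt(n5), sample(c("UAA", "UAG", "UGA"), 1L), nt(n3)),
             n5 + 1L)
}

# Brute-force extension scan: walk every downstream codon index and return
# the nucleotides before the first in-frame stop.
bf_extension_nt <- function(t) {
  stops <- c("UAA", "UAG", "UGA")
  if (t$stop_start + 3L > nchar(t$seq) - 2L) return("")
  starts <- seq(t$stop_start + 3L, nchar(t$seq) - 2L, by = 3L)
  codons <- substring(t$seq, starts, starts + 2L)
  hit <- which(codons %in% stops)
  keep <- if (length(hit)) head(codons, hit[1] - 1L) else codons
  paste(keep, collapse = "")
}

# Brute-force tryptic digestion: enumerate every substring and keep those
# whose boundaries are cleavage boundaries with at most max_missed internal
# cut sites (cut after K/R unless followed by P).
bf_digest <- function(seq, max_missed = 1L) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  is_cut <- function(i) {
    i >= 1L && i < n && aa[i] %in% c("K", "R") && aa[i + 1L] != "P"
  }
  boundary <- function(i) i == 0L || i == n || is_cut(i)
  out <- list()
  for (s in 1:n) {
    for (e in s:n) {
      if (!boundary(s - 1L) || !boundary(e)) next
      internal <- sum(vapply(seq_len(max(0L, e - s)), function(k) {
        is_cut(s + k - 1L)
      }, NA))
      if (internal <= max_missed) {
        out[[length(out) + 1L]] <- data.frame(
          sequence = paste(aa[s:e], collapse = ""), start = s, end = e,
          missed_cleavages = internal, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

random_peptide <- function(len) {
  paste(sample(names(residue_masses()), len, replace = TRUE), collapse = "")
}
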
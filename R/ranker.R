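# Combining readthrough propensity and hidden-PTS1 probability into the
# product score used to rank candidate functional-readthrough transcripts.

#' Rank transcripts by the RTP+ x PTS1 product score
#'
#' For every transcript the SCC is scored under the RTP model and the
#' readthrough extension's C-terminus under the PTS1 model. RTP scores are
#' min-max normalised over the cohort to RTP+ in [0, 1]; the product score
#' is RTP+ times the PTS1 probability. Transcripts whose extension lacks a
#' bounding second stop keep their RTP but get no PTS1 or product score and
#' sort below all scored transcripts.
#'
#' @param transcripts List of `"transcript"` objects.
#' @param rtp_model An `"rtp_model"`.
#' @param pts1_model A `"pts1_model"`.
#' @param u_len,d_len SCC flank lengths used for RTP scoring.
#' @param parent_cterms Optional named character vector of parent C-terminal
#'   residues per transcript id, prepended before PTS1 scoring.
#' @param consensus_threshold Threshold passed to [rtp_consensus()] for the
#'   per-transcript consensus-match flag.
#' @return data.frame (one row per transcript, ordered by descending
#'   product, ties by RTP then id) with columns `transcript_id`, `rtp`,
#'   `rtp_plus`, `pts1_prob`, `product`, `consensus_match`. Cohort
#'   normalisation bounds are attached as attributes `rtp_min`/`rtp_max`.
#' @export
rank_candidates <- function(transcripts, rtp_model, pts1_model,
                            u_len = 10L, d_len = 10L,
                            parent_cterms = NULL,
                            consensus_threshold = 0.1) {
  stopifnot(length(transcripts) >= 2L)
  ids <- vapply(transcripts, `[[`, "", "id")
  sccs <- lapply(transcripts, extract_scc, u_len = u_len, d_len = d_len)
  rtp <- vapply(sccs, function(s) score_rtp(rtp_model, s), 0)
  rng <- range(rtp)
  if (rng[1] == rng[2]) {
    warning("all transcripts share one RTP value; RTP+ set to 1 for all")
    rtp_plus <- rep(1, length(rtp))
  } else {
    rtp_plus <- (rtp - rng[1]) / (rng[2] - rng[1])
  }
  pts1 <- vapply(seq_along(transcripts), function(i) {
    ext <- find_extension(transcripts[[i]])
    if (is.na(ext$second_stop)) return(NA_real_)
    parent <- if (!is.null(parent_cterms) && ids[i] %in% names(parent_cterms))
      parent_cterms[[ids[i]]] else ""
    # a terminus shorter than the tripeptide cannot carry a PTS1
    if (nchar(parent) + nchar(ext$peptide) < 3L) return(NA_real_)
    score_extension(pts1_model, ext, parent)$probability
  }, 0)
  product <- rtp_plus * pts1
  motif <- rtp_consensus(rtp_model, consensus_threshold)$motif
  cmatch <- vapply(sccs, function(s) scc_matches_motif(s, motif), NA)
  out <- data.frame(transcript_id = ids, rtp = rtp, rtp_plus = rtp_plus,
                    pts1_prob = pts1, product = product,
                    consensus_match = cmatch, stringsAsFactors = FALSE)
  ord <- order(-ifelse(is.na(out$product), -Inf, out$product),
               is.na(out$product), -out$rtp, out$transcript_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rtp_min") <- rng[1]
  attr(out, "rtp_max") <- rng[2]
  out
}

scc_matches_motif <- function(s, motif) {
  stopifnot(inherits(s, "scc"))
  full <- paste0(s$stop, s$downstream)
  nchar(full) >= nchar(motif) &&
    substr(full, 1L, nchar(motif)) == motif
}

#' Count transcripts whose SCC matches a consensus motif
#'
#' The motif is anchored at the stop codon: a transcript matches when its
#' stop codon plus downstream bases equal the motif over the motif's span.
#'
#' @param transcripts List of `"transcript"` objects (may be empty).
#' @param motif RNA motif starting with the stop codon, e.g. `"UGACUAG"`.
#' @return Integer count.
#' @export
count_consensus <- function(transcripts, motif) {
  motif <- chartr("T", "U", toupper(motif))
  if (length(transcripts) == 0L) return(0L)
  d_need <- max(0L, nchar(motif) - 3L)
  sum(vapply(transcripts, function(t) {
    s <- extract_scc(t, u_len = 0L, d_len = d_need)
    scc_matches_motif(s, motif)
  }, NA))
}

#' Write a ranking report as TSV
#' @param ranking Output of [rank_candidates()].
#' @param path Output path.
#' @export
write_ranking <- function(ranking, path) {
  write.table(ranking, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
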
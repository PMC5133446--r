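# Positional linear-regression model of readthrough propensity (RTP).
# Response is log10(readthrough %): readthrough spans less than 0.1% up to
# several percent, an order-of-magnitude scale, so effects are modelled as
# additive on the log scale.

RTP_DOWNSTREAM <- paste0("+", 4:9)
RTP_UPSTREAM <- paste0("-", 1:6)
NT_ALPHABET <- c("A", "C", "G", "U")

#' Default modelled SCC positions
#'
#' The stop codon plus downstream positions +4..+9. Upstream positions
#' -1..-6 can be added by the caller but are off by default: the
#' high-readthrough consensus involves only the stop codon and +4..+7.
#' @param upstream Include upstream positions -1..-6.
#' @return Character vector of position labels.
#' @export
rtp_positions <- function(upstream = FALSE) {
  c(if (upstream) RTP_UPSTREAM, "stop", RTP_DOWNSTREAM)
}

position_alphabet <- function(pos) {
  if (pos == "stop") STOP_CODONS else NT_ALPHABET
}

#' Symbol of an SCC at a modelled position
#' @param x An `"scc"` object.
#' @param pos Position label: `"stop"`, `"+4"`..`"+9"` or `"-1"`..`"-6"`.
#' @return Single-character nucleotide, or the 3-nt stop codon for `"stop"`.
#' @export
scc_symbol <- function(x, pos) {
  stopifnot(inherits(x, "scc"))
  if (pos == "stop") return(x$stop)
  k <- suppressWarnings(as.integer(pos))
  if (is.na(k)) stop("unknown position label '", pos, "'")
  sym <- if (k > 0) {
    if (k - 3L > nchar(x$downstream)) NA_character_
    else substr(x$downstream, k - 3L, k - 3L)
  } else {
    i <- nchar(x$upstream) + 1L + k  # -1 is the last upstream character
    if (i < 1L) NA_character_ else substr(x$upstream, i, i)
  }
  if (is.na(sym) || sym == "") {
    stop("SCC does not cover position ", pos)
  }
  sym
}

#' One-hot featurization of an SCC over the modelled positions
#'
#' Exactly one indicator per position is active; names are `"pos:symbol"`.
#' @param x An `"scc"` object covering all modelled positions.
#' @param positions Position labels (see [rtp_positions()]).
#' @return Named 0/1 numeric vector.
#' @export
featurize_scc <- function(x, positions = rtp_positions()) {
  unlist(lapply(positions, function(p) {
    ab <- position_alphabet(p)
    v <- setNames(numeric(length(ab)), paste0(p, ":", ab))
    v[paste0(p, ":", scc_symbol(x, p))] <- 1
    v
  }))
}

#' Fit the RTP model to SCC readthrough measurements
#'
#' Least-squares fit of log10(readthrough percent) on per-position nucleotide
#' indicators. Coefficients are made identifiable by a sum-to-zero constraint
#' per position over the symbols observed in the data; symbols never observed
#' at a position carry coefficient 0. Positions with a single observed symbol
#' contribute no coefficients (their effect is absorbed by the intercept).
#' A rank-deficient design (confounded positions) falls back to a small
#' ridge penalty with a warning.
#'
#' @param measurements data.frame with columns `upstream`, `stop`,
#'   `downstream` (RNA strings) and `readthrough_percent` (> 0, the 0-100
#'   scale of a dual-reporter assay); an optional `label` column is carried
#'   through to diagnostics.
#' @param positions Modelled positions (default stop and +4..+9).
#' @param ridge Ridge penalty used only on rank-deficient designs.
#' @return An object of class `"rtp_model"`.
#' @export
fit_rtp <- function(measurements, positions = rtp_positions(),
                    ridge = 1e-6) {
  stopifnot(is.data.frame(measurements), nrow(measurements) >= 1L)
  if (any(measurements$readthrough_percent <= 0)) {
    stop("readthrough_percent must be positive (log10 response)")
  }
  sccs <- lapply(seq_len(nrow(measurements)), function(i) {
    scc(measurements$stop[i], measurements$upstream[i],
        measurements$downstream[i])
  })
  y <- log10(measurements$readthrough_percent)
  sym <- vapply(positions, function(p) {
    vapply(sccs, scc_symbol, "", pos = p)
  }, character(length(sccs)))
  sym <- matrix(sym, nrow = length(sccs),
                dimnames = list(NULL, positions))

  # design: intercept + sum-to-zero (contr.sum) block per multi-symbol position
  blocks <- list()
  for (p in positions) {
    obs <- sort(unique(sym[, p]))
    if (length(obs) < 2L) next
    idx <- match(sym[, p], obs)
    cmat <- stats::contr.sum(length(obs))
    blk <- cmat[idx, , drop = FALSE]
    colnames(blk) <- paste0(p, ":", obs[-length(obs)])
    blocks[[p]] <- list(obs = obs, design = blk)
  }
  X <- cbind(`(intercept)` = rep(1, length(y)))
  for (b in blocks) X <- cbind(X, b$design)

  qrX <- qr(X)
  if (qrX$rank == ncol(X)) {
    beta <- qr.coef(qrX, y)
  } else {
    warning("rank-deficient design; fitting with ridge penalty ", ridge)
    pen <- diag(c(0, rep(ridge, ncol(X) - 1L)), ncol(X))
    beta <- solve(crossprod(X) + pen, crossprod(X, y))[, 1]
    names(beta) <- colnames(X)
  }

  coefs <- list()
  for (p in positions) {
    ab <- position_alphabet(p)
    v <- setNames(numeric(length(ab)), ab)
    if (!is.null(blocks[[p]])) {
      obs <- blocks[[p]]$obs
      c_part <- beta[paste0(p, ":", obs[-length(obs)])]
      v[obs] <- c(c_part, -sum(c_part))
    }
    coefs[[p]] <- v
  }
  fitted <- as.numeric(X %*% beta[colnames(X)])
  structure(list(intercept = unname(beta["(intercept)"]),
                 coef = coefs, positions = positions,
                 scale = "log10_percent",
                 observed = lapply(blocks, `[[`, "obs"),
                 residuals = y - fitted,
                 labels = measurements$label,
                 constrained = character(0)),
            class = "rtp_model")
}

#' @export
print.rtp_model <- function(x, ...) {
  cat("<rtp_model> intercept ", signif(x$intercept, 4), ", positions: ",
      paste(x$positions, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Score an SCC under an RTP model
#'
#' RTP = intercept + one coefficient per modelled position (the coefficient
#' of the symbol the SCC carries there), on the log10(readthrough %) scale.
#'
#' @param model An `"rtp_model"`.
#' @param x An `"scc"` covering all modelled positions.
#' @return Numeric RTP score.
#' @export
score_rtp <- function(model, x) {
  stopifnot(inherits(model, "rtp_model"), inherits(x, "scc"))
  if (!(x$stop %in% STOP_CODONS)) {
    stop("cannot score a sense codon at the stop position: ", x$stop)
  }
  contrib <- vapply(model$positions, function(p) {
    model$coef[[p]][[scc_symbol(x, p)]]
  }, 0)
  model$intercept + sum(contrib)
}

#' Extract the high-readthrough consensus element of an RTP model
#'
#' Per position the consensus symbol is the coefficient argmax (alphabetical
#' tie-break, flagged). The consensus element is the maximal contiguous run
#' of positions, starting at the stop codon and extending downstream, whose
#' coefficient range (max minus min over symbols) is at least `threshold`.
#'
#' @param model A fitted `"rtp_model"`.
#' @param threshold Minimum per-position coefficient range (log10 units) for
#'   a position to enter the consensus element.
#' @return List with `motif` (nucleotide string; the stop codon contributes
#'   its 3 nt), `length` (nt), `positions` included, and `ties` (positions
#'   where the argmax was tied).
#' @export
rtp_consensus <- function(model, threshold = 0.1) {
  stopifnot(inherits(model, "rtp_model"))
  downstream <- intersect(paste0("+", 4:9), model$positions)
  run <- c("stop", downstream)
  motif <- character(0)
  kept <- character(0)
  ties <- character(0)
  for (p in run) {
    v <- model$coef[[p]]
    if (max(v) - min(v) < threshold) break
    best <- names(v)[v == max(v)]
    if (length(best) > 1L) ties <- c(ties, p)
    motif <- c(motif, sort(best)[1])
    kept <- c(kept, p)
  }
  motif <- paste(motif, collapse = "")
  list(motif = motif, length = nchar(motif), positions = kept, ties = ties)
}

#' The packaged default RTP model
#'
#' Fitted to the packaged wild-type/mutant SCC reporter fixture
#' (`scc_measurements.tsv`): the wild-type UGA CUA context at 4.34%
#' readthrough, stop-swap and +4 mutants at background, and +5/+6 mutants
#' between 0.4 and 0.8%. The fixture varies only the stop codon and
#' positions +4..+6, so the fit carries no information about +7; the default
#' model additionally encodes the weak G preference at +7 that mutational
#' scans of high-readthrough contexts support, as a small sum-to-zero
#' coefficient set. With the default consensus threshold this yields the
#' 7-nt high-readthrough element UGACUAG.
#'
#' @return An `"rtp_model"`.
#' @export
default_rtp_model <- function() {
  path <- system.file("extdata", "scc_measurements.tsv",
                      package = "readthroughx", mustWork = TRUE)
  m <- fit_rtp(read.delim(path, stringsAsFactors = FALSE))
  m$coef[["+7"]] <- c(A = -0.05, C = -0.05, G = 0.15, U = -0.05)
  m$constrained <- "+7"
  m
}

#' Packaged SCC fixtures for MDH1- and LDHB-style contexts
#'
#' Representative stop codon contexts: both carry the UGA CUA
#' high-readthrough motif; the MDH1-style context continues with G at +7
#' (the full consensus) while the LDHB-style context does not.
#' @return Named list of two `"scc"` objects.
#' @export
reference_sccs <- function() {
  list(MDH1 = scc("UGA", "AACGGCAUCG", "CUAGAAGCAG"),
       LDHB = scc("UGA", "GGCAAGGACU", "CUACCUGCUG"))
}

#' Serialize / deserialize an RTP model as JSON
#' @param model An `"rtp_model"`.
#' @param path Output (input) file path.
#' @return `path` (for write); an `"rtp_model"` (for read).
#' @export
write_rtp_model <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept, positions = model$positions,
         scale = model$scale, coef = lapply(model$coef, as.list),
         constrained = model$constrained),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rtp_model
#' @export
read_rtp_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = j$intercept,
                 coef = lapply(j$coef, unlist),
                 positions = j$positions, scale = j$scale,
                 observed = NULL, residuals = NULL, labels = NULL,
                 constrained = j$constrained),
            class = "rtp_model")
}
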
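# Scoring of candidate C-terminal peroxisomal targeting signals (PTS1).
# The signal is centred on the terminal tripeptide (canonical S-K-L) but the
# preceding context contributes: basic residues upstream of the tripeptide
# favour import, acidic stretches disfavour it. The model is a transparent
# log-odds position weight matrix over positions -3..-1 plus weak pooled
# residue-class weights over positions -12..-4, trained by maximum
# likelihood (count-based log-odds with pseudocounts) on a packaged fixture
# of known-functional and non-functional termini.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PTS1_CLASSES <- list(basic = c("K", "R", "H"),
                     acidic = c("D", "E"),
                     hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C"),
                     polar = c("G", "S", "T", "N", "Q", "P", "Y"))

aa_class <- function(aa) {
  for (cl in names(PTS1_CLASSES)) {
    if (aa %in% PTS1_CLASSES[[cl]]) return(cl)
  }
  NA_character_
}

#' Train a PTS1 scoring model on labelled C-termini
#'
#' @param fixture data.frame with columns `terminus` (amino-acid string,
#'   the C-terminal residues of a protein; at least 3, at most 12 are used)
#'   and `label` (1 = functional PTS1, 0 = not).
#' @param pseudocount Additive smoothing for the count-based log-odds.
#' @param context_scale Multiplier (< 1) keeping the -12..-4 context weights
#'   weak relative to the tripeptide PWM.
#' @return An object of class `"pts1_model"` with `tripeptide_pwm`
#'   (3 x 20 matrix of log-odds, rows -3..-1), `context_weights` (per
#'   residue class), `bias`, and a functional `threshold` on the raw score
#'   (set by [set_pts1_threshold()]; `default_pts1_model()` ships one).
#' @export
fit_pts1 <- function(fixture, pseudocount = 0.5, context_scale = 0.25) {
  stopifnot(is.data.frame(fixture),
            all(c("terminus", "label") %in% names(fixture)))
  pos <- toupper(fixture$terminus[fixture$label == 1])
  neg <- toupper(fixture$terminus[fixture$label == 0])
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("fixture must contain both labels")
  }
  at <- function(s, i) {
    n <- nchar(s)
    ifelse(n + 1L + i >= 1L, substr(s, n + 1L + i, n + 1L + i), "")
  }
  logodds <- function(cp, np, cn, nn) {
    log((cp + pseudocount) / (np + 20 * pseudocount)) -
      log((cn + pseudocount) / (nn + 20 * pseudocount))
  }
  pwm <- matrix(0, nrow = 3, ncol = 20,
                dimnames = list(c("-3", "-2", "-1"), AA20))
  for (i in c(-3L, -2L, -1L)) {
    rp <- at(pos, i)
    rn <- at(neg, i)
    for (aa in AA20) {
      pwm[as.character(i), aa] <-
        logodds(sum(rp == aa), length(rp), sum(rn == aa), length(rn))
    }
  }
  ctx <- function(strs) {
    unlist(lapply(strs, function(s) {
      n <- nchar(s)
      i <- seq(max(1L, n - 11L), max(0L, n - 3L))
      if (length(i) == 0L || i[1] > i[length(i)]) return(character(0))
      strsplit(substr(s, i[1], i[length(i)]), "")[[1]]
    }))
  }
  cp <- ctx(pos)
  cn <- ctx(neg)
  cw <- vapply(names(PTS1_CLASSES), function(cl) {
    context_scale *
      (log((sum(cp %in% PTS1_CLASSES[[cl]]) + pseudocount) /
             (length(cp) + 4 * pseudocount)) -
       log((sum(cn %in% PTS1_CLASSES[[cl]]) + pseudocount) /
             (length(cn) + 4 * pseudocount)))
  }, 0)
  structure(list(tripeptide_pwm = pwm, context_weights = cw,
                 bias = 0, threshold = NA_real_),
            class = "pts1_model")
}

#' @export
print.pts1_model <- function(x, ...) {
  cat("<pts1_model> tripeptide PWM over -3..-1; threshold ",
      signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Set the functional threshold from a labelled fixture
#'
#' The threshold is placed midway between the lowest raw score among
#' positives carrying a canonical tripeptide (`[SAC][KRH][LM]`, the
#' SKL-class) and the highest raw score among negatives (which include
#' terminal-leucine deletions of functional signals).
#'
#' @param model A `"pts1_model"`.
#' @param fixture The labelled fixture (see [fit_pts1()]).
#' @return The model with `threshold` set.
#' @export
set_pts1_threshold <- function(model, fixture) {
  raw <- vapply(toupper(fixture$terminus), function(s) {
    score_pts1(model, s, check_threshold = FALSE)$raw
  }, 0)
  canon <- grepl("[SAC][KRH][LM]$", toupper(fixture$terminus))
  lo <- min(raw[fixture$label == 1 & canon])
  hi <- max(raw[fixture$label == 0])
  if (hi >= lo) {
    warning("fixture positives and negatives overlap; threshold midpoint ",
            "does not separate them")
  }
  model$threshold <- (lo + hi) / 2
  model
}

#' Score a C-terminus as a PTS1
#'
#' Only the last 12 residues matter: the terminal tripeptide through the
#' PWM, positions -12..-4 through weak residue-class weights (absent
#' positions contribute 0). A placeholder `X` within the terminal tripeptide
#' is scored with the minimum PWM weight at that position and flagged.
#'
#' @param model A `"pts1_model"` with a threshold set.
#' @param cterm Amino-acid string of length >= 3.
#' @param check_threshold Internal; skip the threshold requirement.
#' @return A `"pts1_score"` list: `raw`, `probability` (logistic of raw),
#'   `functional` (probability at or above the logistic threshold) and
#'   `flags`.
#' @export
score_pts1 <- function(model, cterm, check_threshold = TRUE) {
  stopifnot(inherits(model, "pts1_model"))
  cterm <- toupper(cterm)
  if (nchar(cterm) < 3L) stop("PTS1 scoring needs at least 3 residues")
  if (check_threshold && is.na(model$threshold)) {
    stop("model has no functional threshold; see set_pts1_threshold()")
  }
  s <- substr(cterm, max(1L, nchar(cterm) - 11L), nchar(cterm))
  n <- nchar(s)
  flags <- character(0)
  raw <- model$bias
  for (i in c(-3L, -2L, -1L)) {
    aa <- substr(s, n + 1L + i, n + 1L + i)
    row <- model$tripeptide_pwm[as.character(i), ]
    if (aa == "X") {
      raw <- raw + min(row)
      flags <- c(flags, paste0("placeholder_at_", i))
    } else if (aa %in% AA20) {
      raw <- raw + row[[aa]]
    } else {
      stop("invalid residue '", aa, "' in terminal tripeptide")
    }
  }
  if (n > 3L) {
    for (aa in strsplit(substr(s, 1L, n - 3L), "")[[1]]) {
      cl <- aa_class(aa)
      if (!is.na(cl)) raw <- raw + model$context_weights[[cl]]
    }
  }
  p <- plogis(raw)
  structure(list(raw = raw, probability = p,
                 functional = if (is.na(model$threshold)) NA
                              else p >= plogis(model$threshold),
                 flags = flags),
            class = "pts1_score")
}

#' @export
print.pts1_score <- function(x, ...) {
  cat("<pts1_score> raw ", signif(x$raw, 4), ", p ",
      signif(x$probability, 4), ", functional: ", x$functional, "\n",
      sep = "")
  invisible(x)
}

#' Score the C-terminus exposed by a readthrough extension
#'
#' Concatenates the parent protein's C-terminal residues with the extension
#' peptide (placeholder residue included) and scores the resulting terminus.
#' Extensions without a bounding second stop codon are unbounded and cannot
#' be scored.
#'
#' @param model A `"pts1_model"`.
#' @param ext A `"readthrough_extension"` with a second stop present.
#' @param parent_cterm C-terminal residues of the parent protein (may be "").
#' @return A `"pts1_score"`.
#' @export
score_extension <- function(model, ext, parent_cterm = "") {
  stopifnot(inherits(ext, "readthrough_extension"))
  if (is.na(ext$second_stop)) {
    stop("extension has no second in-frame stop (unbounded); not scored")
  }
  score_pts1(model, paste0(parent_cterm, ext$peptide))
}

#' The packaged default PTS1 model
#'
#' Trained on the packaged fixture of functional and non-functional
#' C-termini (`pts1_training.tsv`), with the functional threshold set on
#' the same fixture.
#' @return A `"pts1_model"`.
#' @export
default_pts1_model <- function() {
  path <- system.file("extdata", "pts1_training.tsv",
                      package = "readthroughx", mustWork = TRUE)
  fixture <- read.delim(path, stringsAsFactors = FALSE)
  set_pts1_threshold(fit_pts1(fixture), fixture)
}

#' Serialize / deserialize a PTS1 model as JSON
#' @param model A `"pts1_model"`.
#' @param path File path.
#' @return `path` (write); a `"pts1_model"` (read).
#' @export
write_pts1_model <- function(model, path) {
  jsonlite::write_json(
    list(tripeptide_pwm = as.data.frame(model$tripeptide_pwm),
         context_weights = as.list(model$context_weights),
         bias = model$bias, threshold = model$threshold),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pts1_model
#' @export
read_pts1_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pwm <- as.matrix(j$tripeptide_pwm)
  rownames(pwm) <- c("-3", "-2", "-1")
  structure(list(tripeptide_pwm = pwm,
                 context_weights = unlist(j$context_weights),
                 bias = j$bias, threshold = j$threshold),
            class = "pts1_model")
}
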
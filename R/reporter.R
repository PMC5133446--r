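# Readthrough quantification from dual-reporter plates, western-blot
# densitometry and live-cell peroxisomal import measurements.

sem <- function(x) sd(x) / sqrt(length(x))

#' Readthrough percentage from dual-reporter measurements
#'
#' Each replicate carries a fluorescence (expression control) and a
#' luminescence (readthrough) reading. Blanks are subtracted from both
#' channels first; the per-replicate luminescence/fluorescence ratio is then
#' normalised to the mean ratio of the 100% control construct:
#' r = 100 * (lum/fluo)_test / mean[(lum/fluo)_control].
#'
#' @param test,control100 data.frames with columns `venus`, `hrluc` and
#'   optionally `blank_venus`, `blank_hrluc` (default 0); one row per
#'   biological replicate. `control100` is the construct defined as 100%
#'   readthrough (no-SCC vector or matched sense-codon construct).
#' @return List with `mean`, `sem`, `n` and the per-replicate `values`
#'   (percent).
#' @export
readthrough_percent <- function(test, control100) {
  ratios <- function(df, who) {
    bv <- if ("blank_venus" %in% names(df)) df$blank_venus else 0
    bh <- if ("blank_hrluc" %in% names(df)) df$blank_hrluc else 0
    v <- df$venus - bv
    h <- df$hrluc - bh
    keep <- v > 0
    if (!all(keep)) {
      warning(sum(!keep), " ", who,
              " replicate(s) dropped: fluorescence at or below blank")
    }
    if (!any(keep)) stop("all ", who, " replicates dropped")
    h[keep] / v[keep]
  }
  rt <- ratios(test, "test")
  rc <- ratios(control100, "control")
  values <- 100 * rt / mean(rc)
  list(mean = mean(values), sem = sem(values), n = length(values),
       values = values)
}

#' Readthrough percentage from western-blot densitometry
#'
#' 100 * I_extended / (I_extended + I_parent), where I_extended is the
#' intensity of the readthrough (extended-isoform) band and I_parent the
#' intensity of the parental band.
#'
#' @param intensity_x Extended-isoform band intensity (>= 0).
#' @param intensity_0 Parental band intensity (>= 0).
#' @return Percent in [0, 100]. Vectorised.
#' @export
western_readthrough <- function(intensity_x, intensity_0) {
  if (any(intensity_x < 0 | intensity_0 < 0)) {
    stop("band intensities must be non-negative")
  }
  if (any(intensity_x + intensity_0 == 0)) {
    stop("both band intensities are zero")
  }
  100 * intensity_x / (intensity_x + intensity_0)
}

#' Peroxisomal import efficiency from pre/post-wash fluorescence
#'
#' After permeabilisation and washout of the cytosol, the retained
#' (organellar) fraction is (post - background) / (pre - background),
#' clipped to [0, 1] (a post > pre reading is clipped and flagged with a
#' warning).
#'
#' @param pre,post Mean fluorescence before/after cytosol removal.
#' @param background Background fluorescence (subtracted from both).
#' @return Efficiency in [0, 1]. Vectorised.
#' @export
import_efficiency <- function(pre, post, background = 0) {
  if (any(pre <= background)) {
    stop("pre-wash fluorescence must exceed background")
  }
  e <- (post - background) / (pre - background)
  if (any(e > 1)) warning("post > pre reading(s); efficiency clipped to 1")
  pmin(pmax(e, 0), 1)
}

#' Two-sample comparison of measurement groups
#'
#' Equal-variance two-sided Student's t-test, with group means, SEMs and
#' the B/A fold change (the induction factor when B is a treated condition).
#' Differences are called significant at p < 0.05.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @return List: `t`, `p`, `mean_a`, `sem_a`, `mean_b`, `sem_b`,
#'   `fold_change` (mean_b / mean_a), `significant`.
#' @export
compare_groups <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 replicates")
  }
  tt <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_a = mean(group_a), sem_a = sem(group_a),
       mean_b = mean(group_b), sem_b = sem(group_b),
       fold_change = mean(group_b) / mean(group_a),
       significant = tt$p.value < 0.05)
}

#' Summarise a dual-reporter plate table construct by construct
#'
#' @param plate data.frame with columns `construct`, `replicate`, `venus`,
#'   `hrluc` and optional blank columns (see [readthrough_percent()]).
#' @param control Name of the 100% control construct in `plate`.
#' @return data.frame with columns `construct`, `mean`, `sem`, `n`.
#' @export
summarise_plate <- function(plate, control = "control100") {
  stopifnot(control %in% plate$construct)
  ctrl <- plate[plate$construct == control, , drop = FALSE]
  constructs <- unique(plate$construct)
  rows <- lapply(constructs, function(cn) {
    s <- readthrough_percent(plate[plate$construct == cn, , drop = FALSE],
                             ctrl)
    data.frame(construct = cn, mean = s$mean, sem = s$sem, n = s$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
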
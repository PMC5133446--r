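# Cross-species comparison of readthrough extensions and the strength of
# the hidden PTS1 they carry.

#' Read an orthologue extension set from FASTA
#'
#' Headers carry a `clade=` token (`mammal`, `non-mammal-vertebrate`, or
#' `other` for rows excluded from the clade contrast, e.g. amphibia).
#'
#' @param fasta Path to a FASTA of extension peptides.
#' @return data.frame of class `"orthologue_set"` with columns `species`,
#'   `clade`, `extension`.
#' @export
read_orthologues <- function(fasta) {
  set <- Biostrings::readBStringSet(fasta)
  toks <- strsplit(names(set), "\\s+")
  species <- vapply(toks, `[[`, "", 1L)
  clade <- vapply(toks, function(tk) {
    hit <- grep("^clade=", tk, value = TRUE)
    if (length(hit)) sub("^clade=", "", hit[1]) else NA_character_
  }, "")
  orthologue_set(species, clade, as.character(set))
}

#' Construct an orthologue extension set
#' @param species,clade,extension Equal-length character vectors.
#' @return data.frame of class `"orthologue_set"`.
#' @export
orthologue_set <- function(species, clade, extension) {
  if (any(is.na(clade))) stop("every entry needs a clade label")
  structure(data.frame(species = species, clade = clade,
                       extension = toupper(extension),
                       stringsAsFactors = FALSE),
            class = c("orthologue_set", "data.frame"))
}

#' C-terminal-anchored alignment of extension peptides
#'
#' Extensions are short and biologically aligned at their C-terminus (the
#' PTS1 end), so rows are right-aligned and padded on the left with `-`.
#' Per-column conservation is the frequency of the most common residue
#' (denominator: number of rows; padding does not count as a residue).
#'
#' @param set An `"orthologue_set"` with >= 2 entries.
#' @return List: `alignment` (character matrix, one row per species),
#'   `conservation` (numeric per column), `terminal_tripeptides`
#'   (data.frame species/clade/tripeptide).
#' @export
align_extensions <- function(set) {
  stopifnot(inherits(set, "orthologue_set"))
  if (nrow(set) == 0L) stop("empty orthologue set")
  if (nrow(set) < 2L) stop("alignment needs at least 2 entries")
  w <- max(nchar(set$extension))
  padded <- sprintf(paste0("%", w, "s"), set$extension)
  padded <- chartr(" ", "-", padded)
  mat <- do.call(rbind, strsplit(padded, ""))
  rownames(mat) <- set$species
  cons <- apply(mat, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return(0)
    max(table(col)) / nrow(mat)
  })
  trip <- substr(set$extension, nchar(set$extension) - 2L,
                 nchar(set$extension))
  list(alignment = mat, conservation = as.numeric(cons),
       terminal_tripeptides = data.frame(species = set$species,
                                         clade = set$clade,
                                         tripeptide = trip,
                                         stringsAsFactors = FALSE))
}

#' Clade contrast of PTS1 strength
#'
#' Mean PTS1 probability of mammalian versus non-mammalian-vertebrate
#' extensions and the direction of the difference. Rows with other clade
#' labels (e.g. amphibia) are excluded.
#'
#' @param set An `"orthologue_set"`.
#' @param pts1_model A `"pts1_model"`.
#' @return List: `mean_mammal`, `mean_nonmammal`, `direction` (one of
#'   `"nonmammal>mammal"`, `"mammal>nonmammal"`, `"equal"`), and the
#'   per-species probabilities.
#' @export
clade_pts1_contrast <- function(set, pts1_model) {
  stopifnot(inherits(set, "orthologue_set"))
  keep <- set$clade %in% c("mammal", "non-mammal-vertebrate")
  set <- set[keep, , drop = FALSE]
  if (!all(c("mammal", "non-mammal-vertebrate") %in% set$clade)) {
    stop("both clades must be represented")
  }
  prob <- vapply(set$extension, function(e) {
    score_pts1(pts1_model, e)$probability
  }, 0)
  mm <- mean(prob[set$clade == "mammal"])
  nm <- mean(prob[set$clade == "non-mammal-vertebrate"])
  list(mean_mammal = mm, mean_nonmammal = nm,
       direction = if (nm > mm) "nonmammal>mammal"
                   else if (mm > nm) "mammal>nonmammal" else "equal",
       per_species = data.frame(species = set$species, clade = set$clade,
                                pts1_prob = unname(prob),
                                stringsAsFactors = FALSE))
}

#' Packaged orthologue extension fixture
#'
#' A synthetic vertebrate MDH1x-style orthologue set: mammalian extensions
#' end in CRL, non-mammalian vertebrate extensions in SRL, plus one
#' amphibian row labelled `other` (excluded from clade contrasts).
#' @return An `"orthologue_set"`.
#' @export
reference_orthologues <- function() {
  read_orthologues(system.file("extdata", "orthologue_extensions.fasta",
                               package = "readthroughx", mustWork = TRUE))
}
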
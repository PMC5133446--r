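---
title: "Models and methods: stop codon readthrough, hidden PTS1 signals, and readthrough-residue identification"
author: "readthroughx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readthroughx)
```

## The biological problem

Translational readthrough occurs when the ribosome decodes a stop codon as
a sense codon and continues to the next in-frame stop. For most human
transcripts the rate is far below 0.1%, but a small set of genes carries a
*stop codon context* (SCC) that raises readthrough by an order of
magnitude or more. When the 3' extension downstream of the stop encodes a
C-terminal peroxisomal targeting signal (PTS1), readthrough produces an
extended isoform that is imported into peroxisomes — *functional*
translational readthrough. Cytoplasmic malate dehydrogenase (MDH1) is the
archetype: a high-readthrough UGA context, a 19-residue extension
terminating in a hidden PTS1, and heterogeneous amino-acid incorporation
(tryptophan and arginine) at the suppressed stop codon.

This package implements the computational side of that analysis as
reusable, testable components: sequence handling, readthrough-propensity
(RTP) regression, PTS1 scoring, candidate ranking, reporter quantification,
and mass-spectrometric identification of the readthrough residue — plus a
synthetic-data module that generates every input the pipeline consumes.

## Coordinates and sequence conventions

Positions are 1-based on the transcript. The stop codon occupies relative
positions +1..+3 and the first 3' base is +4, so mutant names like "+4
C-to-G" map directly onto string indices. The default SCC spans 10 nt on
either side of the stop. DNA input is normalised to RNA on load, and all
motifs are handled as RNA.

Extensions are discovered by a codon walk from +4 to the first in-frame
stop. Transcripts without a downstream in-frame stop are retained with an
absent second stop but excluded from PTS1 scoring: an unbounded extension
has no defined C-terminus. The readthrough-position residue is represented
by the placeholder `X` because the incorporated amino acid is
heterogeneous; callers may substitute a concrete residue.

One reading ambiguity is worth making explicit: a "57 nt following the
stop codon" construct is taken to comprise 54 coding nucleotides plus the
second stop, the only reading consistent with a 19-residue extension
(readthrough residue + 18). The construct helpers therefore treat the
second stop as part of the downstream tail, and `find_extension()` reports
it separately from the coding nucleotides.

## The RTP regression model

Readthrough efficiency is modelled as additive on the log scale: the
response is log10(readthrough %), because measured efficiencies span less
than 0.1% to several percent. Each modelled SCC position (the stop codon
as a 3-way factor, downstream positions +4..+9 as 4-way factors)
contributes one coefficient per observed symbol under a per-position
sum-to-zero constraint, which makes coefficients interpretable as
deviations from the positional mean. Upstream positions -1..-6 are
supported but off by default; the high-readthrough consensus involves only
the stop codon and +4..+7.

The design matrix uses `contr.sum` blocks per multi-symbol position and is
solved by exact least squares when full rank; a rank-deficient
(confounded) design falls back to a ridge penalty of 1e-6 with a warning.
Positions observed with a single symbol contribute no coefficients — their
effect is absorbed by the intercept — and symbols never observed at a
position carry coefficient 0.

The packaged default model is fitted to a 12-measurement fixture of a
wild-type UGA CUA context at 4.34% readthrough, stop-swap (UAA/UAG) and +4
mutants at background (0.05-0.08%), and +5/+6 mutants at 0.4-0.8%. That
mutational series varies only the stop and +4..+6, so it is silent about
+7; the default model additionally encodes the weak G preference at +7
supported by mutational scans of high-readthrough contexts, as a small
sum-to-zero coefficient set (G +0.15, others -0.05). Absolute RTP values
from this model are not meaningful across datasets; every comparison in
the package uses orderings.

The consensus element is extracted per position as the coefficient argmax
(alphabetical tie-break, flagged), and the element is the maximal
contiguous run starting at the stop codon whose coefficient range (max
minus min) is at least the threshold, default 0.1 log10 units — i.e. a
position enters the consensus only if symbol choice there moves predicted
readthrough by at least ~26%. With the default model this yields the 7-nt
element:

```{r consensus}
model <- default_rtp_model()
rtp_consensus(model)$motif
```

## The PTS1 model

No closed-form scoring function for PTS1 strength is in general
circulation, so the package defines a transparent one: a log-odds position
weight matrix over the terminal tripeptide (positions -3..-1) plus weak
pooled residue-class weights (basic, acidic, hydrophobic, polar) over
positions -12..-4, reflecting that the tripeptide dominates but the
preceding context modulates receptor binding. Counts come from a packaged
fixture of 30 functional and 30 non-functional termini (all synthetic
contexts carrying real tripeptide classes: SKL/AKL/SRL/CKL/CRL and
friends versus terminal-leucine deletions, acidic and generic cytosolic
termini), smoothed with a pseudocount of 0.5; context weights are scaled
by 0.25 to keep them weak. The raw score maps to a probability through
the logistic function.

The functional threshold is not hard-coded: it is placed midway between
the lowest-scoring canonical positive (`[SAC][KRH][LM]` termini) and the
highest-scoring negative on the training fixture, and stored with the
model. Scoring uses only the last 12 residues; shorter termini use what
exists; a placeholder `X` inside the tripeptide scores as the worst
residue at that position and is flagged.

The fixture was calibrated once so that the orderings the model must
reproduce hold: SKL-class and SRL termini above CRL, CRL functional, and
terminal-L deletions non-functional. One consequence of count-based
log-odds worth knowing: a residue absent from the negatives can score
spuriously high at a position, so the negative set deliberately includes
cysteine-containing non-signal termini.

## Candidate ranking

RTP scores are cohort-normalised to RTP+ in [0, 1] by min-max scaling (the
normalisation bounds are stored with the ranking for reproducibility), and
the product score is RTP+ times the PTS1 probability of the extension's
C-terminus. Min-max over the scored cohort was chosen over, say, rank or
z-scaling because it preserves the score's ordering, maps to the unit
interval required by a product with a probability, and needs no
distributional assumptions; the cost is cohort dependence, which is why
the bounds are recorded. Transcripts with unbounded extensions keep their
RTP but receive no product score and sort last; a degenerate cohort with a
single shared RTP value sets RTP+ to 1 for all, with a warning.

## Reporter, western and import quantification

Dual-reporter readthrough is the blank-subtracted luminescence /
fluorescence ratio normalised to the mean ratio of a 100% control
construct, times 100. Blank subtraction precedes ratio formation, and the
control enters through its mean ratio rather than replicate-wise pairing —
both choices stabilise the denominator and make the estimator invariant to
channel-wide rescaling. Replicates whose fluorescence does not exceed
blank are dropped with a warning. Western readthrough is 100 * Ix/(Ix+I0)
over band intensities; import efficiency is the background-corrected
post/pre-wash fluorescence ratio clipped to [0, 1]. Group comparisons use
the equal-variance two-sided Student's t-test with significance at
p < 0.05, and report means, SEMs, and the B/A fold change (the induction
factor for drug-treatment comparisons).

## Mass-spectrometric identification of the readthrough residue

The search space is a 21-entry variant database: each proteinogenic amino
acid substituted at the readthrough position, plus a one-residue gap.
Digestion is tryptic with the Keil rule (no cleavage before proline) and
one allowed missed cleavage. Masses are monoisotopic (standard residue
table, proton 1.007276 Da, water 18.010565 Da); variable modifications are
carbamidomethyl-C (+57.021464) and oxidation-M (+15.994915), expanded
combinatorially per peptide. Fragment ions are the plain b/y series
without neutral losses.

Matching is two-tier, mirroring the escalation from precursor-level to
fragment-level evidence. A *relaxed* call requires the precursor m/z of a
readthrough-spanning peptide (any allowed charge and modification state)
within 3 ppm. A *stringent* call additionally requires at least one
matched b- or y-ion within 10 ppm on each side of the readthrough
position, so that the fragment series brackets the incorporated residue; a
peptide terminus counts as a bound on its side, since the precursor mass
then pins the residue from that direction. Leucine and isoleucine are
mass-identical and always reported as an ambiguity set; lysine and
glutamine (0.036 Da apart) are deliberately *not* collapsed, because 3 ppm
resolves them for tryptic-size peptides. Intensities are carried through
but never used for identification: ionisation differences (notably the
shorter tryptic peptide created when arginine introduces a new cleavage
site) make them uninformative about incorporation ratios.

## Synthetic data: what it emulates and what it does not

The generators produce, under a single fanned-out seed: transcriptomes
with planted high-readthrough, PTS1-bearing candidates among random
background (background SCCs matching a planted motif are resampled so
planted truth is exact); dual-reporter plates with multiplicative
log-normal noise (sigma 0.1 by default — readouts are positive,
arbitrary-unit intensities — with 5 replicates per construct, within the
3-7 biological replicates typical of such assays); peak lists for chosen
variants with Gaussian relative mass jitter (1 ppm) plus uniform decoys;
and clade-templated orthologue sets with per-site substitution noise that
spares the terminal tripeptide (CRL in mammals, SRL in non-mammalian
vertebrates). Every generator writes a ground-truth sidecar and is
byte-deterministic under a fixed seed.

What passing tests on these data do show: the estimators are consistent
under the assumed noise model, the matcher recovers planted variants at
the stated tolerances, and orderings derive from the models rather than
from accidents of the inputs. What they do not show: robustness to real
instrument artefacts (chromatographic co-elution, isotope envelopes, lock
mass drift), to reporter-assay plate effects, or to genuine phylogenetic
correlation structure in orthologue sets — none of which are simulated.

## Numerical and design choices

* Exact QR least squares whenever the RTP design is full rank; ridge 1e-6
  only on rank-deficient designs, with a warning. Recovery of planted
  coefficients at zero noise is tested to RMSE < 1e-8.
* Consensus ties break alphabetically and are flagged rather than silently
  resolved.
* ppm errors are computed relative to the theoretical value.
* The C-terminal-anchored orthologue alignment pads left instead of
  running a full MSA: extensions are short and the biologically aligned
  end is the C-terminus (the PTS1), so anchored padding avoids importing
  alignment heuristics whose parameters would themselves need defending.
  Rows shorter than the longest extension contribute no residue to their
  padded columns.
* Problem sizes in the test suite (1000 random transcripts for the
  extension oracle, 500 random sequences for the digestion oracle, 1000
  replicates for estimator consistency) were chosen so each property is
  exercised well past its edge cases while the full suite stays
  interactive (well under a minute).

## Known limitations

The default RTP model is fitted to a single mutational series around one
wild-type context and is intended for orderings, not absolute readthrough
prediction; genome-scale scans would need refitting to a larger training
set. The PTS1 model ignores PTS2 signals, receptor structure and
piggyback import. The MS matcher searches a single-construct space and so
does not implement target-decoy FDR. RNA secondary structure downstream
of the second stop, which may modulate readthrough in vivo, is out of
scope.
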
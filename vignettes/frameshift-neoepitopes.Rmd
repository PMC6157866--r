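---
title: "From a coding frameshift to prioritized neoepitopes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a coding frameshift to prioritized neoepitopes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neofs)
```

## The problem

Familial adenomatous polyposis (FAP) is driven by germline loss-of-function
mutations in the *APC* tumor suppressor. A truncating frameshift creates a
short run of residues that exist in no human protein — candidate neoantigens.
Whether any of those peptides is actually presented by the carrier's HLA
class-I molecules and engaged by T-cell receptors is a computational
prioritization problem before it is an experimental one. This package
implements that computational route as small, composable, testable steps:
variant parsing, consequence calling, peptide-pair enumeration, score
attachment, threshold filtering, HLA restriction, and cohort tallies.

## Consequence calling

Variants are parsed from a deliberately minimal c.-notation grammar (SNV,
insertion, deletion, delins on the coding sequence, 1-based inclusive
coordinates). Full HGVS coverage — intronic and UTR positions, inversions,
repeat notation, and in particular 3'-rule normalisation of indels in
repeated sequence — is out of scope; the package assumes its inputs are
already left-anchored the way clinical reports print them. This is a
documented limitation, acceptable because a coding-exon frameshift such as
`c.735_736insT` is unambiguous.

The consequence is derived *by construction*, not by annotation lookup: the
variant is applied to the CDS, both sequences are translated (standard
nuclear code, frame 1, first stop wins; trailing partial codons are
ignored), and the proteins are compared. The first differing residue gives
`Ref`, `Pos`, `Alt`; the indel length mod 3 gives the frameshift flag; and
for a frameshift the stop offset is `TerN` with
`N = len(mutant) + 2 - Pos`, so the mutant protein has `Pos + N - 2`
residues. Degenerate cases are kept as data rather than errors: a variant
with an unchanged protein yields a consequence flagged `silent`; a
frameshift whose first shifted codon is already a stop is reported as the
nonsense substitution it is (`p.XxxNTer`); a shifted frame that never
reaches a stop carries a `no_stop` flag.

Translation is delegated to Biostrings; the test suite checks it against an
independently hand-entered codon table on a thousand random sequences, so
the wrapper's frame/stop/partial-codon conventions are pinned down
independently of the library.

## The packaged coding context is synthetic

The source family study prints the local nucleotide/protein context of its
mutation only as a figure panel, which is not machine-readable text. The
package therefore ships a *synthetic* 261-codon CDS
(`apc_synthetic_cds()`, `inst/extdata/apc_cds_synthetic.fasta`)
constructed so that every printed fact about the variant holds exactly:

* `c.735_736insT` applies at its true coding offset;
* the consequence is `p.Ser246PhefsTer6` and the mutant protein has
  250 residues;
* wildtype residues 238–246 read `QATEAERSS`, so the 9-mer pair at
  start 238 is `QATEAERSS`/`QATEAERSF`;
* 9-mer enumeration yields exactly five pairs (starts 238–242).

Residues outside that constrained window are arbitrary sense codons. The
fixture is labelled synthetic everywhere; it reproduces the published local
context, not the native *APC* transcript (full-length APC is ~2843
residues, and the figure caption and introduction of the source study
disagree by one residue on the exact count — the package takes no position
on full-length APC).

## Peptide-pair enumeration

For a mutant protein differing from wildtype, the altered window is
`[first, last]`: `first` is the first differing residue; for
length-changing variants every residue from `first` to the mutant's end
counts as altered, for equal-length substitutions `last` is the last
differing residue. One pair is emitted per k-mer start
`max(1, first-k+1) .. min(last, len(mut)-k+1)` — every window fully inside
the mutant protein covering at least one altered residue. Windows never
pad past the mutant stop. The wildtype counterpart is the *same-start*
window on the wildtype protein; this convention is fixed by the only fully
printed pair in the source material, where the two 9-mers differ in their
final residue only. When the wildtype window overruns the wildtype protein
the pair is flagged `wt_truncated` rather than padded. Duplicate mutant
peptides from repetitive sequence collapse to their first start with all
starts retained in a provenance column.

The enumeration is verified against a brute-force all-windows scan on 500
random instances per run of the test suite; the five-pair count for the
packaged case is asserted directly.

## Scoring and prioritization

A *scorer* is any function `(peptide, allele) -> record | miss`, where a
record carries IC50 affinity (nM), TAP score, processing score and a
TCR-binding call. Two backends ship: a table backend over the transcribed
published score tables (the authoritative source for reproduction), and a
seeded mock whose affinities are log-uniform on [1, 50000] nM — a pure
function of (peptide, allele, seed) used for property tests. External
predictor adapters are deliberately absent: re-implementing or wrapping
MHC-binding, proteasomal-cleavage, TAP or TCR predictors is a non-goal.
Misses are carried as `NA` rows with a count, never as crashes, because a
printed table legitimately covers only the peptides its authors discussed.

Prioritization keeps rows with mutant IC50 at or below the threshold
(inclusive — "≤ 500 nM" is the conventional strong-binder cut), a passing
mutant TCR call when required, and optionally a minimum wildtype/mutant
affinity ratio (agretopicity). Two profiles are provided:

* `priority_config()` — 500 nM, TCR required, no ratio: the screen profile
  used for database-derived candidate tables.
* `family_profile()` — 1000 nM, TCR required, tenfold ratio: the profile
  that reproduces the family analysis, which retained a 621.64 nM binder
  and leaned on the ~50–100x wildtype/mutant differential. The source
  study never states a single numeric rule for this step, so the package
  exposes both profiles and treats the threshold as configuration.

Two deliberate asymmetries mirror the printed tables: wildtype strong
binders are *not* auto-excluded (one published wildtype counterpart binds
at 100.41 nM yet its pair stayed in the tested set — exclusion is opt-in
via the ratio), and wildtype TCR calls are not required (the published
family table marks even the deprioritized wildtype peptide TCR-positive;
the effective discriminator there is the affinity differential).

Ranking is by ascending mutant IC50 with (peptide, allele) lexicographic
tie-breaks, making the output a stable total order. HLA restriction keeps
candidates whose allele matches a donor allele on the two-field key
(`B*35:01:01:02` ≡ `B35:01`), because binding predictions are two-field
while typing is four-field; restriction is idempotent and commutes with
prioritization, both of which are tested.

## Cohort tallies

The family table is transcribed verbatim; `summarize_cohort()` computes
exact counts (individuals, carriers, carriers with/without the FAP
diagnosis, non-carriers) plus descriptive min–max age bands per carrier
group, and asserts the partition identities on every call. The source
material contains an internal inconsistency in how one donor's genotype is
described in the narrative versus the tables; the package transcribes the
tables and leaves the discrepancy unresolved. Pedigree drawing,
segregation analysis and penetrance modeling are non-goals.

## The synthetic-data generator

`sim_config()` fixes the simulation conditions; every draw is a pure
function of its seed (threaded through a private RNG so the user's global
RNG state is untouched).

* **CDS generation.** ATG start, uniform sense codons, a fixed three-codon
  tail before the stop that places stop codons in both shifted reading
  frames as late as structurally possible, and whole-interior rejection
  resampling until a +1/−1 frameshift starting at any codon in
  `2 .. n_codons - 3` reaches a stop within `fs_max_extension` (default
  30) codons. The last two sense codons are excluded from the guarantee
  because stop codons end in A/G while the terminal stop begins with T, so
  no shifted stop can fit there at all — a structural fact, not a
  generator weakness. Rejection gets slower as `n_codons` grows (shifted
  stop gaps are geometric with rate 3/64); the defaults (100 codons,
  30-codon budget) resample a handful of times.
* **Variant generation.** A codon drawn uniformly from the guaranteed
  interior; a 1-nt insertion (the published class of mutation), 1-nt
  deletion, SNV or delins. Silent SNV draws propagate their `silent` flag
  downstream instead of being redrawn.
* **Score generation.** Mutant IC50s are
  `10^Normal(1.7, 0.5)` (median ≈ 50 nM), wildtype IC50s
  `10^Normal(4.2, 0.3)` (median ≈ 16,000 nM), except that with
  probability `p_wt_strong = 0.125` a wildtype counterpart is drawn from
  the mutant law. These defaults are calibrated to the published tables:
  printed mutant affinities span 13.71–621.64 nM, printed wildtypes mostly
  13,575–28,178 nM with a single strong outlier, i.e. one of eight rows,
  hence 0.125. TCR calls are Bernoulli(0.5); wildtype TCR calls stay `NA`
  as in the published tables.

What the simulation emulates is the *statistical contrast* the analysis
assumes — strong mutant binders against weak wildtype counterparts with a
small strong-wildtype admixture. What it does not emulate: real
peptide–MHC binding chemistry (affinities are independent of sequence
content), anchor-residue structure, predictor correlation between alleles,
or immune-assay readouts. A green synthetic test therefore demonstrates
that the pipeline's logic is correct under the assumed contrast, not that
any particular peptide is immunogenic in a real donor.

## Numerical and design choices

* Coordinates are 1-based inclusive on the CDS; genomic coordinates are
  carried as opaque labels only.
* Amino acids are three-letter codes in variant notation, one-letter in
  peptide work.
* The 500 nM boundary is inclusive; ties in ranking break
  lexicographically; classification of an `NA` affinity is `NA` and never
  passes a filter.
* Problem sizes in the test suite (500 enumeration instances, 1,000
  translation strings, 10,000-record score tables, 100 generated CDSs of
  60 codons) were chosen so each property has enough replicates to be
  sharp — e.g. the strong-binder fraction check at n = 10,000 has a
  standard error ≈ 0.15 percentage points against a ±3-point band.

## Known limitations

* No 3'-rule normalisation: variants in repeats must arrive left-anchored.
* Class-II (15-mer) windows, splice variants, multi-exon transcript
  assembly and stop-loss extension naming beyond a flag are out of scope.
* The score-table backend is only as complete as the table it wraps;
  candidate peptides missing from it surface as counted misses.
* The published study's figure panel listing its four deprioritized
  peptide windows is ambiguous about whether those windows contain the
  full frameshift run; this package emits true mutant-protein substrings
  and does not attempt to guess the figure's exact strings.
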
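# neofs

Trace a coding-level mutation to prioritized neoepitope candidates.

`neofs` is an R package for the computational core of a
frameshift-neoantigen study: given a coding sequence (CDS) and an
HGVS-style coding variant, it names the protein-level consequence,
enumerates the wildtype/mutant peptide pairs the mutation creates,
attaches per-peptide/per-HLA presentation scores, filters and ranks
candidates under conventional strong-binder rules, restricts them to a
donor's HLA genotype, and tallies carrier/phenotype structure in a family
cohort. It is aimed at analysts reproducing or stress-testing
neoepitope-prioritization workflows for inherited cancer syndromes such
as familial adenomatous polyposis (FAP), where a germline truncating
mutation in the *APC* tumor suppressor segregates with disease.

## The model

A coding indel whose length is not divisible by 3 shifts the reading
frame at residue `r = ceil(pos / 3)`. Translation of the shifted frame
produces a run of novel residues and usually reaches a premature stop:
the consequence is written `p.<Ref><r><Alt>fsTer<N>`, where the new stop
sits `N - 1` residues after the first altered one, so the truncated
protein has `r + N - 2` residues.

Every k-mer window (default k = 9, the MHC class-I convention) of the
mutant protein that covers at least one altered residue is a candidate
neoepitope; its wildtype counterpart is the same-start window on the
wildtype protein. Candidates are scored per HLA allele with an IC50
binding affinity (nM), TAP and proteasomal-processing scores, and a
TCR-binding call, then filtered:

* strong binder: IC50 &le; 500 nM (inclusive; configurable),
* TCR-binding call passes (`Positive`/`High`),
* optionally, agretopicity `IC50_wt / IC50_mut >= ratio`
  favours mutant-selective binders.

HLA matching uses two-field keys (`B*35:01:01:02` presents what
`B35:01` predicts). Scorers are pluggable: a table backend replays
published score tables; a seeded mock supplies log-uniform affinities
for property testing. Binding/processing/TCR predictors themselves are
out of scope — the package consumes their outputs.

## Worked example

The package ships a synthetic 261-codon coding context built to carry a
published family's *APC* frameshift at its true coding offset (see the
vignette for why it is synthetic), plus the study's transcribed score,
HLA-typing and cohort tables.

```r
library(neofs)

run <- run_pipeline(
  cds      = apc_synthetic_cds(),
  variant  = "c.735_736insT",
  scores   = table3_scores(),
  hla      = table2_hla(), donor = "IV.9",
  cohort   = table1_cohort(),
  priority = family_profile())
run
#> <neofs_run> c.735_736insT -> p.Ser246PhefsTer6
#>   pairs: 5  candidates: 2  donor-restricted (IV.9): 2
```

The single-nucleotide insertion between coding positions 735 and 736
shifts the frame at Ser246; the shifted frame stops six codons later, a
250-residue truncated protein. Exactly five 9-mers span the novel
residues:

```r
run$pairs
#>   start     k wt_peptide mut_peptide n_altered wt_truncated
#> 1   238     9 QATEAERSS  QATEAERSF           1 FALSE
#> 2   239     9 ATEAERSSG  ATEAERSFR           2 FALSE
#> ...
```

Under the family profile (TCR-positive, IC50 &le; 1000 nM, tenfold
wildtype/mutant differential) one pair survives, presented by the two
alleles donor IV.9 carries:

```r
tidy(run)[, c("rank", "mut_peptide", "allele", "mut_affinity_nm",
              "wt_affinity_nm", "wt_mut_ratio")]
#>   rank mut_peptide allele  mut_affinity_nm wt_affinity_nm wt_mut_ratio
#> 1    1 QATEAERSF   B*35:01          151.47       14485.65         95.6
#> 2    2 QATEAERSF   C*03:03          621.64       28178.94         45.3
```

and the cohort tally reproduces the family structure:

```r
run$cohort_summary[, 1:6]
#>   n     carriers affected_carriers unaffected_carriers noncarriers affected_noncarriers
#> 1 26          10                 6                   4          16                    0
```

`autoplot(run)` draws the scored windows per allele with the retained
candidates highlighted; `simulate_run(sim_config(seed = 1))` generates a
fully synthetic CDS/variant/score-table run for testing.

A command-line wrapper is installed at
`system.file("exec", "neofs", package = "neofs")` with subcommands
`consequence`, `peptides`, `score`, `prioritize`, `cohort`, `simulate`
and `run`.

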
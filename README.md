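# champtools

In-silico terminomics: modeling one-step chromatographic isolation of
protein terminal peptides and annotating the neo-N-terminome.

## The problem

Proteoforms produced by proteolysis or by non-canonical translation
initiation differ in their protein termini, so cataloguing N- and
C-termini (terminomics) is a direct readout of presequence processing,
initiator-methionine (iMet) excision, exopeptidase trimming and
alternative start-codon use. The CHAMP family of methods isolates
terminal peptides in a single chromatographic step, without chemical
labeling:

* **CHAMP-N** — digest with LysargiNase (cleaves the *N-terminal* side
  of Lys/Arg) and separate on strong cation exchange (SCX). Internal
  peptides start with Lys/Arg, so their alpha-amine and N-terminal side
  chain form two *proximal* positive charges and are strongly retained;
  N-terminal peptides carry charge Z ≤ 1 (or Z = 2 with distant
  charges) and flow through.
* **CHAMP-NC** — tryptic digest + SCX. Acetylated N-terminal and
  C-terminal peptides have Z ≤ 1; everything else has Z ≥ 2.
* **CHAMP-C** — V8 (Glu-C) digest + metal-oxide ligand-exchange
  (MOLEX). Internal peptides end in Asp/Glu, present two carboxylates
  and chelate the metal oxide; C-terminal peptides carry a single
  carboxylate and elute.

Here `Z` is the charge number at acidic pH: the free alpha-amine (lost
on Nt-acetylation) plus the Lys, Arg and His count of the peptide.

The package implements this retention model together with the
surrounding pipeline: in-silico digestion with missed cleavages and
semi-specific "N-terminal free" expansion, neo-N-terminus annotation
(acetylation classes Ac-MX / M/Ac-X / Other, exact matching of neo
positions to signal/transit-peptide cleavage ends, near-cognate start
codons read from the CDS, exopeptidase-ladder detection), the summary
metrics used to judge such experiments (intensity-based selectivity, Z
distributions, replicate RSD, method and fraction overlaps), and a
fully seeded synthetic-study generator with exported ground truth.

## Worked example

```r
library(champtools)

cfg <- champ_sim_config(n_proteins = 200)   # defaults: 5% contamination share
sim <- generate_proteome(cfg, seed = 7)
sim
#> champ_sim: 200 proteins; 77 planted neo-N-termini
#>               ladder         near_cognate presequence_cleavage
#>                   24                    5                   38
#>             residue3
#>                   10

res    <- simulate_evidence(sim, "CHAMP_N", seed = 8)
report <- champ_report(res$evidence, sim$proteome)
report
#> champ_report
#>   CHAMP_N: 417 entries, 132 terminal peptides, selectivity 96.9%
```

The selectivity (96.9% here) is the share of total MS intensity carried
by terminal peptides — the planted contamination share was 5%, so a
clean pipeline recovers a value near 95%. The Z distribution of the
isolated peptides sits entirely at Z ≤ 2, as the SCX model demands:

```r
summary(report)
#> == CHAMP_N ==
#> entries 417 | terminal ids 132 | selectivity 96.9%
#> Z distribution:
#> Z
#>   0   1   2
#>  57 180 180
#> median replicate RSD 8.5% over 139 peptides
```

Matching observed neo-N-terminal positions against predicted signal
peptide ends (mature protein starts at presequence end + 1) on the
bundled example table:

```r
ex <- champ_cleavage_examples("signal")
data.frame(gene = ex$gene, predicted = ex$predicted_end,
           neo = ex$neo_position,
           match = match_cleavage(ex$neo_position, ex$predicted_end))
#>     gene predicted neo match
#> 1 DNASE2        16  17  TRUE
#> 2  PDIA4        24  25  TRUE
#> 3   RPN1        24  25  TRUE
#> 4   RCN2        25  26  TRUE
#> 5  TMED3        27  28  TRUE
#> 6  FKBP9        29  30  TRUE
#> 7  LAMC1        35  36  TRUE
```

All seven neo positions match the predictor's cleavage ends exactly,
while none match the corresponding database-annotated spans — the
observed termini support the predicted cleavage sites.

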
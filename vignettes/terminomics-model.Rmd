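---
title: "Modeling one-step terminal-peptide isolation and the neo-N-terminome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling one-step terminal-peptide isolation and the neo-N-terminome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(champtools)
```

# The retention model

All three isolation chemistries reduce to rules on a single quantity
per peptide, its charge number at acidic pH:

$$Z = \mathbf{1}[\text{free }\alpha\text{-amine}] + \#K + \#R + \#H$$

Nt-acetylation removes the alpha-amine term, so an acetylated peptide
always has one charge fewer than its free form (`charge_z()`).

**CHAMP-N** (LysargiNase + SCX). LysargiNase cleaves the N-terminal
side of Lys/Arg, so every internal peptide *starts* with K or R: its
alpha-amine (position 0) and N-terminal side chain (position 1) form
two charges one residue apart. Under the charge/orientation retention
model, two proximal charges bind SCX strongly while the same two
charges far apart do not. The selection rule is therefore: keep
peptides with $Z \le 1$, keep $Z = 2$ peptides whose two charge
positions are more than `proximity` residues apart, reject everything
else. Acetylated ($Z=0$) and free ($Z=1$) N-terminal peptides pass;
internal peptides are always a proximal pair and are rejected.

**CHAMP-NC** (trypsin + SCX). Tryptic peptides *end* in K/R, so a free
N-terminal tryptic peptide already carries $Z = 2$ and is lost; only
acetylated N-terminal ($Z \le 1$) and C-terminal peptides
($Z = 1$ when free of internal basics) pass. The rule is a plain
$Z \le 1$ with no proximity clause.

**CHAMP-C** (V8 + MOLEX). V8 cleaves after Asp/Glu, so internal
peptides end with an acidic residue and present two C-terminal
carboxylates that chelate the metal oxide; the rule keeps exactly the
peptides whose last residue is not D/E. Protein C-termini that happen
to end in D/E are a structural blind spot of the chemistry and are
flagged `blind_spot_acidic_ct` rather than silently dropped. Because
the rule only inspects the C-terminal residue, missed cleavages cannot
change a CHAMP-C decision — a property the test suite asserts.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `proximity` | 2 | residues | The model distinguishes "close" from "distant" charge pairs without quantifying the cut. Two is the smallest value that both rejects every internal LysargiNase peptide (separation 1) and admits N-terminal peptides with a His three or more residues in. It is exposed, not inferred. |
| `distant_his_only` | `FALSE` | — | The distant-Z=2 acceptance is usually illustrated with His-containing peptides, but nothing in the chemistry restricts it to His; a distant internal Lys behaves the same in this model. The restriction is available for sensitivity analysis. |
| `min_len`, `max_len` | 6, 45 | residues | Detectability window: shorter peptides are not matched confidently, longer ones fragment poorly. These are conventional search-engine bounds. |
| `max_missed` | 2 | sites | Standard search setting for all three enzymes. |
| `imet_rule` | A,C,G,P,S,T,V | residue set | Methionine aminopeptidase excises the iMet when residue 2 has a small side-chain radius. The set is configurable because annotation pipelines differ at the margins (notably V). |
| `ragged_window` | 3 | residues | A neo terminus a few residues away from an annotated cleavage end may reflect ragged processing or a stale annotation; such calls get a `near_native` review flag, never a match. |
| `min_run` (ladders) | 3 | positions | One ragged pair is not evidence of processive exopeptidase trimming; three consecutive starts are. |
| near-cognate set | 9 codons | — | The single-nucleotide neighbours of ATG; CUG is the most active in vivo. Configurable because the efficiency ranking is context dependent. |

## Category and annotation conventions

Coordinates are 1-based and inclusive throughout, matching the
notation of presequence annotations ("1–24" means residues 1..24 and a
mature start at 25); `parse_span_end()` accepts hyphen or en-dash
spans, bare integers, and returns `NA` for undefined spans (`"-"`,
`"1-?"`).

A peptide is `protein_nt` when it starts at residue 1 or at residue 2
of a Met-initiated protein under the iMet rule — starts at residue 2
are treated as specific, which is a modeling choice: search engines
differ on whether post-iMet starts count as enzyme-specific, and
treating them as native avoids inflating the neo class with ordinary
iMet processing. A whole-protein peptide is labeled `protein_nt`
(precedence over `protein_ct`). `internal` requires an enzyme-specific
start; any other start is a `neo_nt` candidate. The evidence-side
classifier `classify_native_or_neo()` is coarser by design: any start
beyond the native set is neo, whatever the enzyme context, because an
identified peptide's start may coincide with a cleavage site by
chance.

Cleavage-site matching is exact (`neo_position == presequence_end +
1`). A tolerant window would conflate ragged processing with the
annotated site, and the review flag already captures near misses.

Acetylation classes partition every acetylated call: `Ac_MX`
(acetylated residue is Met, i.e. a retained initiator), `M_Ac_X` (the
preceding residue is Met, i.e. acetylation after Met excision), else
`Other`. When both residues are Met, `Ac_MX` wins — the acetylated
residue itself is the stronger evidence for the initiator position.
For start-codon checks the putative initiator sits at the call
position (`Ac_MX`) or one residue upstream (`M_Ac_X`).

For selectivity, an evidence entry counts as N-terminal-class under
CHAMP-N when its start is native *or* non-enzyme-specific: internal
LysargiNase peptides that leak through isolation always begin at
Lys/Arg, so a non-specific start marks a proteoform N-terminus. The
same reasoning restricts ladder detection to non-specific starts —
specific starts are ambiguous between trimming and digestion.
Peptides are required to map to a single accession; multi-mapping
resolution is a search-engine concern and is deliberately out of
scope. Protein groups are approximated by accession for the same
reason.

Replicate RSD is computed on raw (not log) intensities, as
$100\,\mathrm{sd}/\mathrm{mean}$ over per-replicate sums; intensity
aggregation within a replicate is a plain sum because charge states
and injections are not modeled separately. Entries without an
intensity are excluded from both sums of the selectivity ratio rather
than imputed as zero.

# The synthetic-study generator

`champ_sim_config()` fixes the study conditions; `generate_proteome()`
and `simulate_evidence()` realize them reproducibly from a seed.

What it emulates:

* Met-initiated proteins, 80–300 residues, human-like residue
  composition; signal (12%) or transit (8%) presequences of 10–50
  residues, mutually exclusive, whose cleavage releases a mature
  (neo) N-terminus at end + 1.
* iMet removal by the small-residue rule, and co-translational
  Nt-acetylation with class-dependent probabilities (0.7 after
  removal, 0.5 on a retained Met) — rough literature-scale values for
  mammalian proteomes.
* Neo mechanisms with per-protein rates: residue-3 over-cleavage by
  methionine aminopeptidase (10%, acetylated in 17% of cases),
  exopeptidase ladders of 3–6 consecutive starts (5%), near-cognate
  CUG initiation at an internal Met (2%), the latter written into the
  back-translated CDS so that the codon check can recover it. Planted
  neo starts avoid Lys/Arg so that a neo terminus is distinguishable
  from a digestion product — in real data this ambiguity exists and
  such sites would be missed.
* A 60/30/10 missed-cleavage mix sampled per terminal peptide, an
  isolation step applying the package's own selection rules plus the
  6–45 detectability window, internal-peptide contamination sized so
  the *expected* internal intensity share equals
  `contamination_share` (default 5%), log-normal intensities
  (`meanlog = log(1e6)`, `sdlog = 0.8`) and three replicates that
  jitter intensities only (`sdlog = 0.1`).

What it does not emulate: missing values and interference, retention
time, decoys and FDR, peptide-to-protein ambiguity, digestion
kinetics, chromatographic fraction profiles, and gas-phase charge
states. Passing tests therefore demonstrate the correctness of the
rules and metrics under controlled conditions, not performance on
real spectra. One visible consequence: with this composition the
terminal peptides fall inside the 6–45 window more often than real
terminomes do (where roughly forty percent are detectable), because
real proteomes have more extreme terminal-fragment lengths; the
window was left at its conventional value rather than tuned.

The contamination control is worth spelling out: contaminant count is
set to $\lceil c/(1-c)\, n_t \rfloor$ for $n_t$ terminal peptides, so
with iid intensities the expected internal share is $c$ and the
realized share fluctuates with sampling noise — the parameter-recovery
tests allow for that noise rather than asserting the closed form
exactly.

# Numerical and degenerate-input choices

* Digestion enumerates boundary windows directly; the test oracle
  instead enumerates all substrings and applies the boundary
  definitions, so the two meet only if both are right. The peptide
  count law $\sum_{k=0}^{m} \max(B+1-k, 0)$ for $B$ boundaries is
  asserted against brute force.
* Proteins without cleavable residues digest to a single
  whole-protein peptide; empty feature/evidence/prediction tables are
  valid and give empty results; `is_proximal()` refuses anything but
  exactly two positions (a contract, not a coercion).
* Ties: a whole-protein peptide is `protein_nt`; `Ac_MX` beats
  `M_Ac_X` on a double-Met context; ladder runs are maximal and
  non-overlapping by construction.
* Seeds: every stochastic routine takes an explicit seed;
  `generate_proteome()`/`simulate_evidence()` are bit-reproducible at
  fixed seed and config.

# Problem sizes

The test suite verifies digestion against brute force on 500 random
proteins of up to 50 residues, isolation rules on exhaustive
evaluation over random digests, and parameter recovery on a
1,500-protein study (giving over a thousand distinct identified
peptides), chosen as the smallest sizes at which the stochastic checks
are comfortably stable. The acceptance script uses the same
1,500-protein study.

# Known limitations

* The proximity threshold is a free parameter of the model, not an
  estimate; real SCX retention is a continuum that the binary rule
  only caricatures. Likewise CHAMP-C retention is modeled as a binary
  acidic-C-terminus rule with no retention-strength continuum.
* Selectivity attribution relies on start specificity and so cannot
  see a genuine neo terminus that coincides with a cleavage site.
* The generator's ground-truth acetylation classes are assigned from
  the planted mechanism; agreement checks are meaningful because the
  classifier sees only sequence context, but both ultimately describe
  the same planted reality.
* No FDR modeling: "identified" peptides in the simulation are true
  by construction.
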
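---
title: "Methods: m1A58 quantification and codon-switch design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m1A58 quantification and codon-switch design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnaswitch)
```

## The biological question

N1-methyladenosine at tRNA position 58 (m1A58), installed by the
TRMT6/TRMT61A methyltransferase complex, modulates how efficiently tRNAs
decode their codons during translation elongation. When the catalytic
subunit is lost, different tRNA families lose different amounts of m1A58,
and mRNAs that lean heavily on codons read by the most-affected tRNAs lose
translational output. The in-silico counterpart of the wet-lab
"codon-switch" rescue is: quantify the per-tRNA m1A58 decrease between
wild-type (WT) and knockout (KO), rank tRNAs by sensitivity, profile the
codon usage of a target coding sequence, and rewrite its sensitive codons
with synonymous codons read by insensitive tRNAs — leaving the protein
untouched.

`trnaswitch` implements that chain end to end, with a synthetic tRNA-seq
generator standing in for sequencing data so every downstream estimate can
be checked against a known ground truth.

## The reference model

**Position 58 by motif, not coordinate.** Cytosolic m1A58 sites sit inside
a conserved T-loop 9-mer, consensus `GUUCNANNC`, whose single fixed
adenosine (base 6 of the 9-mer) is the methylated site. `locate_position58()`
returns the 0-based index of that adenosine in the first consensus match.
Locating the site by motif rather than by absolute index keeps the model
honest for synthetic tRNAs that are not exactly 76 nt.

**Naming.** tRNA families are labelled by their decoded codon
(`tRNA-Ser-TCC`), the convention that makes the codon-level
cross-referencing direct. Anticodons are stored and drive the decoding map.

**Decoding and wobble.** `build_decoding_map()` supports two policies.
`strict` (the default) admits only the exact Watson-Crick reverse
complement of the anticodon — appropriate here because the codon-switch
logic treats each listed codon as served by its own tRNA. `crick` adds the
classical wobble pairings at anticodon position 34 (G34:U/C, U34:A/G,
I34:U/C/A). Wobble expansions that would change the encoded amino acid are
excluded, so the map always translates consistently. Inosine is only
defined by the classical rules at position 34; under `strict` we let I pair
C (its strongest Watson-Crick-like partner) — a package choice, documented
here because the strict behaviour of I34 is not standardised.

Sequences are DNA internally; RNA input is mapped U→T on read, since codon
tables are conventionally DNA. Coordinates are 0-based throughout.

## The synthetic-data generator

`simulate_pileup()` draws per-read outcomes at the m1A58 column: with
probability `s` (the stoichiometry — the methylated fraction of the tRNA
pool) the site is modified, in which case reverse transcription terminates
with probability `p_stop` or misincorporates with probability `p_mis`
(uniform over the three wrong bases); with probability `1 - s`, and at
every other position, bases err independently at the background rate
`e_bg`. Reads are full-length from the tRNA 3' end until a stop — the
direction RT actually runs — so every read enters the m1A58 column and a
stop there removes coverage from all positions 5' of it. This makes the
mismatch-fraction denominator unambiguous.

Defaults `p_mis = 0.5`, `p_stop = 0.2`, `e_bg = 0.001` are representative
of published m1A RT signatures and are configurable. The model is
deliberately minimal: no RT jumping or indels, no PCR duplicates, no
ligation bias, no other modification sites (e.g. m1A9), no isodecoder
structure. A green test therefore establishes that the estimator inverts
*this* generative process correctly — not that it is robust to every
artefact of a real library. Mitochondrial tRNAs (methylated by different
enzymes) are out of scope.

**The demonstration world** (`demo_truth()`) encodes the stated
experimental outcome as simulation truth: 12 tRNA families in which the
serine TCC/AGC and leucine CTG/TTG decoders lose most of their m1A58 on
knockout (WT stoichiometries 0.90/0.85/0.80/0.75 dropping to 0.05 — the
WT/KO magnitudes used by the paired-experiment contract), six bystanders
show graded intermediate decreases (deltas 0.60 down to 0.10), and the
serine TCG / leucine CTT decoders are nearly untouched (deltas 0.04 and
0.02). The bystander and escape magnitudes are package choices — no
stoichiometry scale is published for the ranking figure this emulates —
fixed before any acceptance measurement and not tuned afterwards. Distinct
deltas make rank recovery testable; near-zero (rather than exactly zero)
escape deltas keep the KO-only-removes-methylation invariant strict.

## Estimating m1A58 levels

At the m1A58 column let `mismatch_rate` be wrong bases over base calls and
`stop_rate` be stops over reads entering. Under the generative model their
expectations are

    E[stop_rate]     = s * p_stop
    E[mismatch_rate] = (s * p_mis + (1 - s) * e_bg) / (1 - s * p_stop)

The combined signature rate — any signal per read entering the site — is

    r = mismatch_rate * (1 - stop_rate) + stop_rate
      -> s (p_mis + p_stop) + (1 - s) e_bg

and `estimate_stoichiometry()` inverts it by method of moments:

    s_hat = (r - e_bg) / (p_mis + p_stop - e_bg),  clipped to [0, 1]

Using the combined rate pools both signals into a single sufficient
summary under this model; it is exact at the boundaries (`s = 0`, `s = 1`)
and unbiased in simulation (mean error < 0.005 at depth 10^4). When
`p_mis + p_stop = 0` yet signal is present, the estimate is flagged `NA`
(unidentifiable) rather than guessed. The raw `mismatch_rate` is retained
in every level table as a model-free fallback, because published analyses
differ in whether they report mismatch, stop, or a combined score.

Positions with coverage below `min_coverage` (default 100 reads) are
excluded, never imputed: rates on a handful of reads are unstable and a
missing row is more honest than a noisy one.

`delta_m1a()` reports the WT − KO decrease per tRNA with a dense rank
(ties share a rank; ordering ties broken by tRNA id so output is
deterministic). No significance testing is performed: the sensitivity
ranking is a magnitude ordering, not an inference, and dressing it in
p-values would overstate what it is.

## Codon usage and vulnerability

`codon_frequency()` counts in-frame codons with the terminal stop excluded
from the denominator — the standard codon-usage convention (the source
figure this emulates does not define its denominator; we state ours).
Internal stops are warned about with positions and excluded.
`vulnerability_report()` flags codons that are both decoded by one of the
`k_top` most-affected tRNAs and within the top `m` usage ranks. Defaults
`k_top = 4` and `m = 10` reflect the four focal tRNAs of the motivating
experiment and a round "most frequently used" cutoff; both are tunable and
the flag logic is a pure set intersection, verified against a brute-force
oracle.

## Codon-switch design

`build_recoding_plan()` resolves "replace codons of sensitive tRNAs with
synonymous codons of insensitive tRNAs" into a deterministic rule: for each
amino acid with codons decoded by a top-`k_top` tRNA, the replacement is
the synonymous codon (present in the decoding map, not itself decoded by an
affected tRNA) whose decoding tRNA has the smallest delta, ties broken
lexicographically. The minimal-delta rule is the package's resolution of an
outcome the source experiment states without stating its selection
procedure; on the demonstration world it selects exactly TCG (serine) and
CTT (leucine). One replacement per amino acid mirrors the many-to-one swap
design (TCC/AGC→TCG, TTG/CTG→CTT). Only codons actually decoded by affected
tRNAs are rewritten — other synonymous codons of the same amino acid (TCT,
TCA, AGT, CTC, CTA, TTA) are left alone, matching the stated construct.

Hard constraints: stop codons are never rewritten; amino acids with no
synonymous escape (Met, Trp, or a fully-affected family) are skipped with a
warning rather than mutated. `recode_cds()` applies the plan in frame and
logs every substitution (0-based nucleotide position of the codon start,
from, to). `verify_recoding()` independently re-derives the diff and checks
(a) exact protein identity, (b) zero residual source codons, (c)
log/diff/plan consistency, naming the first offending position on failure.
Idempotence follows from the plan invariant that a replacement codon is
never a source codon.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → quantify → delta → usage → plan →
switch → verify, writing every stage table to the run directory plus a
manifest (configuration, seed, package version, MD5 per file). One master
seed fans out to per-stage seeds by a fixed integer derivation (kept below
2^31), so a rerun with the same configuration is byte-identical — asserted
by the determinism acceptance test. Every stage is also an ` ts_cli()`
subcommand exchanging the same files, so a chain of subcommands reproduces
`run-all`.

## Numerical and degenerate-input choices

* Stoichiometry estimates are clipped to [0, 1]; deltas live in [−1, 1].
* A stop-only CDS yields an empty usage table (total 0), not an error.
* `k_top = 0` yields an empty plan and an identity recode.
* Multinomial draws make simulation cost O(positions), not O(reads), so
  the acceptance suite's 500-replicate recovery study and the
  10^3–10^5-depth consistency sweep run in seconds at full size.

## Known limitations

The generator's error model is a two-parameter caricature of RT behaviour;
estimator accuracy on real libraries depends on calibrating `p_mis`,
`p_stop`, `e_bg` for the enzyme and protocol at hand, which is out of
scope. Isoacceptor families are single species — no isodecoder
deconvolution or expression weighting. The decoding map ignores
modification-dependent wobble changes. No codon-optimisation objectives
(GC content, secondary structure, restriction sites) enter the switch
design: it is a pure tRNA-sensitivity swap.
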
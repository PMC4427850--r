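---
title: "Predicting microProteins by two-tier homology search and domain filtering"
author: "microProteinR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microProteins by two-tier homology search and domain filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microProteinR)
```

# The model

A microProtein (miP) is a small protein homologous to a transcription
factor (TF) that retains a protein–protein interaction (PPI) domain but
lacks the DNA-binding domain (DBD). The prediction model is therefore
purely sequence-based and rests on three assumptions:

1. miPs share detectable local-alignment similarity with their target
   TFs (they arose by truncation, alternative transcription or imprecise
   duplication of TF genes);
2. miPs are short — every characterized example is below 550 aa and most
   are below 200 aa;
3. a genuine miP carries no DBD and no domain absent from all of its
   target TFs.

`runPipeline()` operationalizes this as two candidate-generating
searches followed by three set-based filters. The stringent tier
searches TF queries against all proteins shorter than 550 aa at
E ≤ 1e-7. The permissive tier searches proteins shorter than 200 aa at
E ≤ 0.5 — deliberately lax, because short proteins cannot accumulate
large alignment scores, so their E-values are intrinsically high — and
controls the resulting false positives by a reverse search: each forward
hit is realigned, as a query, against the whole TF set, and kept only if
it reciprocally matches a TF at E ≤ 0.1. The reverse hits, not the
forward ones, define the candidate's target list: the forward search
only establishes candidacy, while the reverse search measures which TFs
the candidate itself most credibly resembles (the choice matters when a
permissive forward hit is asymmetric; the alternative readings —
forward-hit targets or the intersection — are stricter than anything the
filters downstream require).

The filters then run in a fixed order: unwanted-domain filter, length-ratio
filter, foreign-domain filter. The order matters because the
foreign-domain test compares a candidate's domain set against the union
of its *surviving* targets' domain sets: removing an over-long pair
first shrinks that union. Running the domain filter first is also the
cheapest way to discard the large class of DBD-retaining relatives.

# Alignment engine and E-values

Searches use Smith–Waterman local alignment under affine gap penalties
(a gap of length $g$ costs $o + (g-1)e$, the BLAST convention, defaults
$o=11$, $e=1$) over BLOSUM62, computed by `Biostrings::pairwiseAlignment`.
Raw scores are converted to E-values with the Karlin–Altschul formula

$$E = K \, m \, n \, e^{-\lambda S},$$

with $m$ the query length, $n$ the total residue count of the searched
partition, and the published gapped-search constants $\lambda = 0.267$,
$K = 0.041$ for BLOSUM62/11/1. Two deliberate simplifications: the
constants are fixed rather than re-derived per run (determinism, desk
scale), and no edge-effect or composition-based corrections are applied.
Absolute E-values therefore differ from BLAST's; what the pipeline needs
is only a calibrated quantity that is monotone in the score and linear
in database size, with the same cutoff interface. Users who need
bit-compatibility with BLAST+ can run it externally and replay its
12-column tabular output through `precomputedBackend()`; the pipeline's
result depends only on the hit tables, never on which backend produced
them (asserted by a byte-identity test).

The ambiguity letter `X` is scored as the matrix minimum (−4) against
everything: a worst-case reading that can only suppress, never create,
candidacy. Alignments whose optimal score is non-positive are reported
as score 0 with an empty alignment.

# Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `maxMipLength` | 550 | aa | upper size of any characterized miP; strict `<` |
| `smallProteinLength` | 200 | aa | typical miP size; bounds the permissive tier; strict `<` |
| `tier1Cutoff` | 1e-7 | E-value | stringent-tier cutoff, recall-calibrated |
| `tier2Cutoff` | 0.5 | E-value | permissive forward cutoff; short proteins need lax E |
| `reverseCutoff` | 0.1 | E-value | reciprocality requirement that controls tier-2 noise |
| `lengthRatio` | 1.1 | ratio | 10 % tolerance for miPs with longer linkers; inclusive boundary |

Boundary conventions are read literally and tested exactly: "shorter
than 550/200" is strict `<` (a 550-aa protein never enters tier 1, a
200-aa protein never enters tier 2), "larger than 1.1 times" is strict
`>` (a 440-aa candidate with a 400-aa target sits exactly at the bound
and survives). The length-ratio filter is applied per candidate–target
pair, and a candidate survives if at least one pair survives — the only
reading under which the 10 % tolerance and the per-target phrasing stay
consistent.

Further fixed policies on degenerate inputs: a proteome record whose id
equals any query-TF id is never a candidate (otherwise every sub-550-aa
TF would trivially report itself before dying at the DBD filter, and
unannotated TFs would survive even that); candidates with *no* mapped
domains pass both domain filters (the filters can only act on mapped
domains; such predictions are flagged with `-` in the domains column);
targets missing from the annotation contribute an empty set to the
foreign-domain union; duplicate FASTA ids, internal `*` and residues
outside the 20 amino acids + `X` are hard errors rather than silent
repairs; identical sequences under different ids are *not* deduplicated.
Ties in hit tables are broken deterministically (query, then E-value,
then subject; best HSP per pair by minimal E-value, then higher score,
then first occurrence), so repeated runs are byte-identical.

# The synthetic benchmark

`generateFixture()` builds a proteome in which every pipeline behaviour
has a planted witness. Each TF family receives a unique random 15-aa DBD
motif (listed in the unwanted set and the scanner library) and a unique
12-aa PPI motif (library only), embedded at fixed layout positions in
random uniform-background sequence; family members diverge from the
family base at 5 % per-residue substitution with motifs held intact.

* **Stringent-tier miPs** are C-terminal truncations (80–180 aa)
  retaining the intact PPI motif, diverged at 5 %.
* **Permissive-tier miPs** share only a 28-residue window of the PPI
  region, diverged at 45 %, planted in otherwise random sequence. The
  window length is the one genuinely free design constant; 28 aa was
  chosen from the score arithmetic: at 45 % substitution the expected
  Smith–Waterman score of such a window (≈ 80–90) falls between the
  stringent-tier score threshold (≈ 104 at E = 1e-7 for this database
  size) and the permissive/reverse thresholds (≈ 42–46), so these
  proteins are findable only by the permissive tier.
* **Decoys**: DBD-retaining truncations (die at the unwanted-domain
  filter), oversized paralogs at 1.1 × family length + 8 aa with the DBD
  region scrambled (die at the length-ratio filter — or at the 550-aa
  partition for long families), PPI-retaining truncations with an extra
  foreign motif (die at the foreign-domain filter), and unrelated random
  sequences (never gain candidacy).

Because alignment scores are stochastic, the generator does not trust
the arithmetic: it *verifies* every promise by running the three
searches (`verifyFixture()`) and redraws any violating permissive-tier
miP, stringent-tier miP or random decoy, up to a bounded number of
rounds, all under the single spec seed. A fixture is only returned once
its detectability promises hold, so the benchmark's expected outcome
(recall 1.0, zero decoys) is a property of the construction, not of
luck. Redraw never touches thresholds or the verification itself.

What the generator deliberately does **not** emulate: realistic amino
acid composition (uniform background makes absolute E-values
unrealistic), indels and domain shuffling (divergence is
substitution-only), low-complexity regions, profile-strength domain
signatures (motifs are exact consensus strings, matched with `.`
wildcards, not HMMs), and paralogy across families. Passing the
benchmark therefore demonstrates that the pipeline's logic — partitions,
two-tier search, reverse rescue, three filters, output contract — is
correct, not that recall on a real proteome will be 1.0: real miPs
diverge in messier ways and real domain databases miss degenerate
domains.

# Threshold calibration

`sweepThresholds()` reproduces the recall-driven calibration procedure
on any fixture: the three searches are computed once at the loosest
cutoff of each axis and replayed through the precomputed backend at
every grid point — valid because a hit table at a stricter cutoff is
exactly the loose table filtered (asserted against naive full runs) —
and the selected row is the one with maximal recall and, among those,
lexicographically smallest (tier-1, tier-2, reverse) cutoffs. The
lexicographic tie-break is our choice; "most stringent at highest
recall" does not by itself order three axes. Recall is provably
non-decreasing along each axis (hit sets grow with the cutoff and every
filter acts per candidate on a growing target union), and the suite
asserts this on a 3×3×3 grid.

Precision on synthetic data counts any true-miP-labelled output as
correct even when its reported targets are wrong; target correctness is
reported separately (`target_accuracy`), since homology-based target
assignment and physical-interaction validation are different claims.
With zero predictions, precision is reported as `NA` — undefined, not
zero.

# Problem sizes

The default benchmark is 29 proteins (2 families × 2 TFs, 6 + 3 planted
miPs, 16 decoys, ≈ 6,800 residues), small enough that the full test
suite — including fixture generation with construction-time
verification, the 100-pair alignment-oracle comparison, a 27-point
threshold sweep and two full determinism re-runs — completes in about
two minutes on one core. The generator scales linearly if larger
benchmarks are wanted; counts, length ranges and rates are all spec
fields.

# Known limitations

* miPs whose domain is present but functionally degenerate (e.g. an HLH
  domain missing its basic residues) are indistinguishable from
  DBD-carriers at the domain-annotation level and are filtered out;
  detecting them would require residue-level constraints on top of
  domain mapping, which is out of scope here.
* miPs with no recognisable similarity to their target TF (convergent
  origin, extreme divergence) are invisible to any homology method.
* The built-in E-values are calibrated but not BLAST-identical (no
  length adjustment, no composition statistics); cutoffs tuned against
  real BLAST runs should be re-examined when switching backends.
* The built-in domain scanner is an exact-consensus matcher intended for
  self-contained runs and the benchmark; real-proteome work should
  import InterProScan annotations, which feed the identical filters.
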
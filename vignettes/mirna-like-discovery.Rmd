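---
title: "Discovering phased and half-phased miRNA-like RNAs on miRNA precursors"
author: "mirphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering phased and half-phased miRNA-like RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirphase)
```

## The problem

A plant pre-miRNA is a stem-loop RNA from which Dicer-like enzymes excise a
miRNA/miRNA\* duplex with 2-nt 3' overhangs. In deep-sequencing data, reads
that map back to a precursor but sit outside the annotated mature miRNA were
long dismissed as noise. Stacking those reads along the hairpin shows that
many precursors shed *additional* discrete species: some sit exactly on the
register grid anchored at the major miRNA's 5' end (spaced by multiples of
the miRNA length — *phased* miRNA-like RNAs), others deviate by 4–11 nt from
that grid (*half-phased*), i.e. land mid-register. Both differ from isomiRs,
which are mere 1–3-nt 5' variants of an existing species. `mirphase`
implements the discovery procedure and its downstream validation arithmetic
as a tested, reusable pipeline.

## The discovery model

The pipeline is a deterministic sequence of rules; each is a tunable
parameter of `pipeline_params()`.

1. **Exact mapping** (`map_reads`). Collapsed reads are matched to the
   precursor panel allowing *no mismatches*, sense strand only (a pre-miRNA
   is single stranded). Every occurrence is reported; a read hitting several
   precursors carries its full count to each (no fractional splitting —
   panels of precursors are small and the conservative choice is to let each
   locus see the evidence).
2. **Block construction** (`detect_blocks`). The unassigned alignment with
   the highest count becomes a block representative; every unassigned
   alignment lying within the representative's span extended by
   `overhang_tol = 3` nt on either end joins the block, and the loop repeats.
   The 3-nt tolerance absorbs imprecise dicing and isomiRs. Ties for the
   representative break toward the smaller start, then the longer read, so
   block construction is a pure function of the alignment multiset. This
   single greedy pass replaces the usual two-stage practice of running an
   external block finder and re-aggregating its output: given the
   representative-plus-tolerance aggregation rule, the most abundant
   unassigned read determines each block completely, so no separate
   clustering tool (and none of its probabilistic read-density machinery) is
   needed.
3. **Filtering** (`filter_blocks`). Two rules, in order:
   * *Spanning rule.* A block that bridges two distinct neighbouring blocks
     — overlapping one on its 5' side and another on its 3' side, each by
     more than `overhang_tol` nt — is discarded as an artifact (degradation
     fragments straddling two real species). "Neighbouring block" is not
     formally defined in the discovery literature; here a neighbour must be
     **at least as abundant** as the candidate bridge. This is an
     interpretation, and a deliberate one: bridge artifacts are low-abundance
     relative to the species they straddle, and without the abundance
     condition a handful of stray single-read blocks around a genuine
     species would flag the species itself as "spanning". The condition also
     keeps the rule independent of the count threshold below, so raising
     `min_block_count` can only shrink the result set.
   * *Count rule.* Blocks with `total_count < min_block_count` (default 5)
     are discarded as likely sequencing error. The boundary is sharp: 4
     reads are removed, 5 retained.
4. **Phasing classification** (`classify_offset`, `call_precursor`). Let `d`
   be a block's 5' offset from the major miRNA's 5' end and `P` the major
   miRNA's length (the phase period; using the major's own length rather
   than a fixed 21 keeps 22-nt families consistent). With the symmetric
   residual `r = min(d mod P, P − (d mod P))`:
   * `d = 0` and matching length → **canonical**;
   * `1 ≤ |d| ≤ 3` → **isomiR** of the major;
   * `r ≤ 3` → **phased** (on-grid);
   * `4 ≤ r ≤ 11` → **half-phased** (mid-register);
   * otherwise **unphased** (cannot occur for `P = 21` with defaults, since
     `r ≤ 10`).
   The 4–11-nt band is measured as a residual on the grid, not as an
   absolute offset: "11 nt before" and "10 nt after" a grid point are both
   mid-register, which is what the name half-phased describes. This is a
   documented choice — the band could equally be read as an absolute
   deviation, but the residual reading is the only one that stays consistent
   beyond one period.
5. **Naming.** The block covering the major annotation is `{major}.1`;
   phased and half-phased blocks are numbered `.2`, `.3`, … 5'→3'; a block
   whose 5' end lies within 3 nt of an already named species is an isomiR
   and inherits that name; unphased blocks get `.u1`, `.u2`, …. When no
   block overlaps the major annotation the pipeline warns and starts at
   `.2`.
6. **Duplex validation** (`star_partner`, `assess_duplex`). On the hairpin
   structure, a species' star interval is the paired region on the opposite
   arm extended so each strand's 3' end overhangs the partner's 5' end by
   `duplex_overhang = 2` nt. A duplex passes when at least half of its
   positions pair into the partner and both 3' overhangs are within
   `duplex_overhang_tol = 1` of 2 nt — "~2 nt" encoded as 2 ± 1, the
   tightest symmetric reading. Overhangs are measured on the **median
   pairing register** (the median of `i + partner(i)`), so single-nucleotide
   bulges — common in plant stems — do not corrupt the measurement;
   endpoint-based measurement would. GU wobble counts as paired, as is
   standard for RNA secondary structure.

### Folding fallback

Externally computed structures (RNAfold-style dot-bracket files) are
preferred. When none is supplied, `fold_nussinov()` provides a
base-pair-maximizing nested fold (Watson–Crick + GU, minimum loop 3,
deterministic leftmost-pairing traceback). It is a combinatorial folder, not
a thermodynamic one: adequate for deciding which arm pairs with which on a
desk-scale hairpin, not a substitute for MFE structures on long or
multi-branched precursors. The cubic dynamic program is guarded at 400 nt.

## Expression arithmetic

* `rpm_normalize()` — reads per million mapped; the cross-library
  normalization applied before comparing conditions.
* `condition_fold_changes()` — `log2(RPM_t + 1) − log2(RPM_c + 1)` against
  the control library. The 1-RPM pseudocount is the package's choice for
  handling species absent from one condition (a species undetected in the
  control but abundant under stress must yield a finite fold change); no
  significance test is attached, since sequencing-side fold changes are
  descriptive and qRT-PCR is the validation instrument.
* `ddct()` — the 2^−ΔΔCT method: `ΔCT = CT(target) − CT(reference U6)` per
  sample, `ΔΔCT = ΔCT(sample) − ΔCT(control)`, relative concentration
  `2^−ΔΔCT`. Technical replicates are averaged on the CT scale before ΔCT.
  The no-template-control rule is absolute: a target CT above the NTC CT
  means *not detected*, whatever the fold change.
* `amplicon_length()` — the assay amplicon is the mature length plus the
  30-nt adaptor, giving the characteristic ~55-nt product for a 25-nt
  species.

## Concordance and cleavage classification

`classify_amplicon()` reproduces the three-way verdict used when cloned PCR
products are compared with RNA-seq-determined sequences: identity **or
reverse-complement identity** is a `match` (cloning orientation is
arbitrary; several exactly matching pairs in the packaged fixture are
reverse complements), a shared contiguous run of at least `near_min_len =
13` nt is `near`, anything else — including an empty clone — is `no_match`.
The 13-nt threshold is the largest value that reproduces the packaged
table's verdicts: the shortest shared run among its `near` rows is the
miR390b.2 pair's 13+ nt run against the reverse complement, while the ARF1
pair shares a 17-nt prefix. The fixture itself
(`inst/extdata/amplicon_validation.tsv`) documents two inferred column
splits, since the published table concatenates the two sequence columns.

`classify_cleavage()` places 5' RACE clone positions relative to the
miRNA:target binding interval (half-open): `within` includes the interval
start and excludes its end; everything before is `upstream`, everything from
the end on is `downstream`.

One published summary is knowingly left out of machine checks: the
half-phased detection row prints "7/8 (83.3%)", but 7/8 is 87.5% — the
printed percentage is internally inconsistent. `detection_ratios()` returns
the recomputed 87.5 alongside the consistent 50% / 50% / 62.5% rows.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_srna()` generate hairpins with known truth so the
whole pipeline is testable without external data. Defaults were fixed once,
before any acceptance run, to mirror the discovery setting:

* 60-nt arms + 12-nt loop (132-nt precursors, inside the 50–900-nt range of
  plant fold-backs), 5% per-position stem mismatches;
* a 21-nt major miRNA at position 5 of the 5' arm, mean 100 reads;
* alternating planted species: one phased at +21 nt (mean 50) on
  odd-numbered precursors; two half-phased at +7 and +28 nt (means 30/20) on
  even-numbered ones — the two archetypes seen on real precursors (a single
  in-register companion vs. a pair of mid-register species);
* the major's star with exact 2-nt 3' overhangs (mean 30);
* 10% isomiR jitter (uniform ±1–3-nt shifts), background noise at 0.02
  reads/nt with uniform 18–26-nt spans (emulating degradation fragments the
  spanning and count rules must reject);
* libraries NC/CA/CCA/CS with fold changes 1/2/4/0.5 — a cold-responsive
  profile: induction under acclimation, strong induction under stress after
  acclimation, repression under shock;
* negative-binomial counts (size 5): overdispersion is the realistic stress
  test for the 5-read filter.

Deliberately **not** simulated: sequencing errors (the pipeline maps with no
mismatches, so errored reads would simply not map — they are
indistinguishable from absent reads), multi-precursor cross-mapping
(arms are random, so shared 21-mers essentially never occur), realistic
positional bias of degradation, or alternative fold-backs. Passing the
recovery tests therefore shows the *rules* are implemented correctly and are
robust to overdispersion, jitter and uniform noise — not that the pipeline's
thresholds are optimal for any particular real library.

## Problem sizes and numerical choices

The test suite and the acceptance script run 20 noiseless simulations of 3
precursors by 4 libraries each (≈ 60–120 distinct collapsed reads per run),
sizes at which every stage is exact and a full recovery sweep completes in
seconds; the noise-degradation property uses 6 seeds at rates 0, 1 and 4
reads/nt. Degenerate inputs are defined, not accidental: empty read files
yield empty (header-only) outputs with a warning; a block fully inside the
terminal loop has no star partner; star intervals are clipped to the
precursor; an offset-0 block of non-major length is an isomiR, not
canonical; `detect_blocks` on an empty alignment set returns an empty block
table. All randomness flows from the single seed in `sim_config`.

## Known limitations

* The spanning rule is an operationalization of an informally stated
  filter; alternative readings (e.g. ignoring relative abundance) change
  which bridges are removed in dense stacks.
* Reads are never fractionally assigned across precursors; paralogous
  precursors sharing a mature sequence will each report the full count.
* `fold_nussinov` maximizes pair count, which can overpair relative to an
  MFE structure; supply real structures for anything beyond sanity checks.
* Per-library quantification sums alignment counts within a call's span ±
  3 nt; it does not deconvolve isomiRs shared between adjacent species.
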
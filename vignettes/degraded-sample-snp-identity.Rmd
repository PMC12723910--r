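---
title: "Genotyping and identity matching for degraded skeletal samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping and identity matching for degraded skeletal samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forensnp)
```

# Scope and data model

`forensnp` begins where read processing ends. Its primary input is a
per-sample, per-marker read-count table — for every biallelic SNP the
number of reads supporting the reference allele, the alternate allele and
any other base, the forward/reverse strand split, and the mean Phred
quality — together with a panel definition carrying each marker's
chromosome and population alternate-allele frequency. Everything upstream
(trimming, host-read filtering, mapping, duplicate removal) is assumed done
by the sequencing workflow; everything downstream (genotype calls, identity
likelihood ratios, concordance and call-rate statistics) is computed here.

Three marker classes are handled: autosomes (diploid in everyone), X
(diploid in females, haploid in males) and Y (haploid in males, absent in
females). Genotypes are stored as alt-allele dosages: 0/1/2 where diploid,
0/1 where haploid.

# Threshold genotype calling

`call_genotype()` applies five rules in a fixed order, so that every
no-call has exactly one reason:

1. *Coverage*: informative depth `d = n_ref + n_alt` below `min_depth`
   (default 10 reads) is `low_depth`.
2. *Quality*: mean Phred below `min_quality` (default 20) is `low_quality`.
3. *Other alleles*: `n_other / (d + n_other)` above `max_other_fraction`
   (default 0.10) is `excess_other`.
4. *Strand balance*: when `d >= strand_check_min_depth` (default 20), a
   minority-strand fraction below `strand_min_fraction` (default 0.10) is
   `strand_imbalance`. The rule is skipped at lower depth, where a skewed
   split carries no signal.
5. *Allelic balance* `ab = n_alt / d`: at most `hom_ab_max` (default 0.10)
   is a reference homozygote, at least `1 - hom_ab_max` an alternate
   homozygote, inside `[het_ab_low, het_ab_high]` (default 0.30–0.70) a
   heterozygote; anything between the homozygote and heterozygote bands is
   `ambiguous_balance`, never a forced call. The gap is deliberate: in
   low-template typing an allelic balance of, say, 0.2 is equally
   compatible with drop-in on a homozygote and drop-out on a heterozygote,
   and forensic practice prefers a no-call to either guess.

Balance uses ref + alt depth only; other-allele reads are policed by their
own rule so a third allele cannot drag a heterozygote out of its band. The
published assays defer their exact thresholds to supplementary validation
tables, so the defaults here are common forensic MPS practice, exposed both
as arguments and as named profiles (`calling_profile("force_like")`,
`"twist_like"`) that laboratories should overwrite with validated values.
The rule order itself is a design choice of this package: the source
workflows do not state one, and a fixed order is what makes the no-call
reasons well defined.

`consensus_replicates()` implements replicate-consensus calling: a marker
is typed only when both replicates agree exactly; discordantly typed
markers are recorded with the dedicated reason `replicate_discordant`.
Consensus trades overlap for reliability — its typed set is a subset of
each replicate's — which is precisely the behaviour verified in the test
suite (consensus concordance against an independent call set is at least
each single replicate's, with no larger overlap).

# The direct-match likelihood ratio

For identity testing between two low-coverage samples, calling genotypes
first throws information away. `per_snp_lr()` therefore works on read
depths directly. At a marker with alt frequency $p$, Hardy–Weinberg priors
$\pi(g) = (1-p)^2,\ 2p(1-p),\ p^2$ and per-read alt probability
$q(g) = \varepsilon,\ \tfrac12,\ 1-\varepsilon$ for dosage $g = 0, 1, 2$,
the genotype likelihood of $a$ alt reads among $n$ informative reads is
$L(g) = q(g)^a (1-q(g))^{n-a}$ (binomial coefficients are omitted — they
cancel in every ratio). The per-marker LR of H1 *same donor* versus H2
*different, unrelated donors* is

$$
LR_j=\frac{\sum_g \pi(g)\,L_a(g)\,L_b(g)}
{\bigl[\sum_g \pi(g) L_a(g)\bigr]\bigl[\sum_g \pi(g) L_b(g)\bigr]},
$$

and the total is $\ln LR = \sum_j \ln LR_j$ over the selected autosomal
markers. Numerical choices: all sums are computed in log space with a
three-term log-sum-exp (a 50,000-marker panel at capture depth would
underflow in linear space); a marker uncovered in either sample contributes
exactly 0; frequencies are clamped to `[freq_floor, 1 - freq_floor]`
(default 0.001) so monomorphic markers cannot contribute infinite
penalties.

The error model has two knobs: `base_error` (default 0.01, the
sequencing/mapping error) and `sample_error_factor` (default 2),
interpreted multiplicatively: $\varepsilon_{\rm eff} = \min(k\varepsilon,
0.49)$. The multiplicative reading of the sample-specific factor is a
stated assumption of this package — it reproduces the intended effect
(extra per-sample noise beyond the sequencer's) without claiming to mirror
any external software's internals. Linkage between markers is deliberately
ignored: for the identity hypothesis pair the independence approximation
is far less consequential than for kinship, and linkage-aware chains are
out of scope.

`select_snps()` mirrors the usual marker selection: autosomal markers with
reference frequency data, ranked by total read count across all samples
(ties broken lexicographically). `direct_match()` classifies a comparison
as `inconclusive` unless at least `min_snps` markers (default 150) are
covered in both samples; otherwise the sign of ln(LR) decides. The 150-SNP
floor is the mitigation for capture-bias false positives, which in both the
published data and our simulations concentrate exclusively at very small
overlap counts.

# Concordance, accuracy and call rates

`compare_callsets()` counts markers typed in both call sets, classifying
every discordance as a *false homozygote* (het vs hom — the drop-in/drop-out
signature) or a *contradictory homozygote* (opposite homozygotes). The two
classes are exhaustive for typed diploid pairs. A haploid call meeting a
diploid call (possible on X under inconsistent sex metadata) is concordant
when the haploid allele matches the dosage-equivalent homozygote,
contradictory otherwise. Y markers can be excluded (`exclude_y = TRUE`)
because shared paternal lineages inflate between-individual concordance.
Rates are kept at full precision and reported rounded half-up to one
decimal; `aggregate_discordance()` pools counts before dividing, never
averaging rates.

`call_rate()` divides typed markers by the sex-adjusted panel size (Y
markers are not targetable in females; unknown sex conservatively uses the
full panel with a warning). `dynamic_top_n_call_rate()` calls only the N
deepest markers per sample and keeps N as the denominator, which makes
assays with wildly different panel sizes comparable. The statistical
comparisons use the standard machinery: `regress_called_snps()` is OLS with
per-coefficient t-tests (rank-deficient designs are refused with advice
rather than silently dropped), and `compare_call_rates()` is a one-way
fixed-effects ANOVA with Tukey HSD (Tukey–Kramer at unequal group sizes).
Call rates enter the ANOVA untransformed; an arcsine or logit transform is
left to the caller since the reference analysis used raw proportions.

# What the simulator emulates — and what it does not

`simulate_reads()` generates read counts with the statistical structure of
degraded skeletal samples:

* **Depth**: negative binomial with mean $\lambda t_j$ and dispersion
  `depth_dispersion` (default 1; `Inf` gives the Poisson limit). Capture
  coverage is empirically over-dispersed, and no published dispersion value
  exists for these panels, so the default is an exposed guess. The
  per-marker efficiency $t_j$ is lognormal and *shared across samples*,
  which is what makes the same markers systematically deep in every sample
  and lets depth-ranked selection (and capture bias) behave realistically.
  $t_j$ is parameterised with mean 1 rather than median 1 so that the
  expected depth equals `mean_depth` exactly, whatever the efficiency
  spread — the anchor regimes (0.3x shotgun, ~30x capture, ~100x control)
  are stated as means.
* **Reads**: each read is independently an other-allele misread with
  probability $\varepsilon/3$, else a contaminant read with probability
  `contamination` (drawn from one independent HWE individual resimulated
  per sample), else an endogenous read with alt probability $q(g)$. At C/T-
  and G/A-typed markers an extra symmetric flip `damage_rate` stands in for
  terminal deamination.
* **Bookkeeping**: `nonhuman_fraction` and `duplicate_fraction` scale the
  implied total/human/duplicate read counts consumed by `summarize_run()`;
  they do not alter the count tables.

Presets: `wgs_like` (0.3x, 95% non-endogenous reads), `capture_like` (30x,
efficiency sd 0.8, 30% duplicates), `control_like` (100x, clean). Where the
emulated study pinned a value (0.3x shotgun mean, 1% read error), the
preset uses it; the remaining preset values are single upfront choices of
plausible magnitudes for degraded skeletal material and are not tuned.

Not emulated: raw reads or alignment, position-within-read damage
profiles, library-chemistry differences, mapping quality, linked Y
haplotypes (an optional shared-haplogroup mode was considered and left out;
Y markers are excluded from the LR anyway and can be excluded from
concordance). A green simulation test therefore establishes internal
correctness of the statistics under the stated generative model — not
performance on any particular real assay.

One identifiability caveat documented by the tests: "noiseless" data are
not error-free at moderate depth. With zero sequencing error, a true
heterozygote covered by 10–12 reads still drops an allele with probability
about 1–2%, so exact caller-vs-truth agreement is a property of the deep
Poisson regime (every site deep), which is what the correctness tests use;
under the over-dispersed default, shallow sites exist at any mean depth and
are handled by the no-call rules instead.

# Degenerate inputs and tie-breaks

Zero-depth sites are `low_depth` no-calls; a zero overlap yields an `NA`
concordance rate (reported as not available), never a division error; a
comparison with no shared covered markers has ln(LR) exactly 0 and is
inconclusive. All rankings (marker selection, top-N calling) break ties
lexicographically on marker id under C collation, making every output
independent of input row order. TSV writers emit a fixed column order and
`\n` line endings; readers reject malformed rows with their line number
rather than coercing.

# Reproducibility

Every stochastic function takes an explicit integer seed, and identical
configuration yields byte-identical outputs. `run_pipeline()` writes the
effective config and a manifest with an MD5 config hash, the seed, package
version and per-stage record counts; re-running with the same config
reproduces the hash and every table.
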
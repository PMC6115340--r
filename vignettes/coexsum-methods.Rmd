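---
title: "Methods: cross-tissue co-expression ranking, promoter motif scanning and line-profile colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-tissue co-expression ranking, promoter motif scanning and line-profile colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexsum)
library(dplyr)
```

# Scope

`coexsum` packages three computational procedures that recur in studies of
smooth-muscle gene regulation, each with a synthetic-data generator that
plants known structure so the procedure can be validated end to end:

1. **Cross-tissue co-expression ranking.** Given expression for one query
   gene across many tissues, correlate the query against every other gene
   within each tissue and sum the per-tissue coefficients into a single
   statistic, `R_sum`. Genes in the positive extreme of the `R_sum`
   distribution form a candidate co-regulated module.
2. **Degenerate promoter-motif scanning.** Locate CArG boxes
   (`CCWWWWWWGG`), MCAT (`CATTCCT`), GATA and glucocorticoid-receptor
   elements in promoter sequence, with mismatch tolerance, both strands,
   and signed positions relative to the transcription start site (TSS).
3. **Membrane line-profile colocalization.** Correlate two fluorescence
   channels sampled along a membrane contour, aggregate per-profile
   coefficients with a one-sample t-test versus 0, quantify the
   channel-ratio fluctuation, and compare colocalization between two
   staining pairs with a two-sample t-test.

# The co-expression model and the R_sum statistic

## Procedure

For a panel of tissues each holding a genes-by-samples matrix on a shared
gene universe:

1. `rank_tissues_by_query()` orders tissues by the query's **median**
   expression and keeps the top ten. The level statistic is a free choice —
   only "highest expression" is required by the procedure — and the median
   is robust to the long right tail of expression data. Ties fall back to
   tissue-identifier order so the selection is deterministic.
2. `correlate_query()` computes, per kept tissue, the Pearson correlation
   between the query's sample vector and every other gene's (Spearman
   available; it is implemented as Pearson on average ranks, and a test
   asserts that identity). A gene with zero variance in a tissue has no
   defined correlation and is recorded as missing there. The query's
   self-correlation row is excluded: it would score the maximum trivially.
3. `rsum()` forms \(R_{sum} = \sum_t r_t\). Missing coefficients are
   zero-imputed by default — conservative for the positive extreme, since a
   gene absent from a tissue can only lose score. The alternative
   (`missing_policy = "min_observed"`, default threshold 5 of 10 tissues)
   drops genes observed too rarely.
4. `extreme()` keeps the `ceiling(q * n)` genes with the highest `R_sum`
   (default `q = 0.005`, the top 0.5%). Ties at the boundary value are all
   included, so the set is deterministic and order-independent.

Correlation is computed on log2-scale values (for counts, the TMM-scaled
log2-CPM below); a linear-scale analysis is possible by passing linear
values in the panel, since the panel format is agnostic to the transform.

## What the generator plants

`simulate_expression_panel()` uses a one-factor latent model per tissue:
sample \(s\) carries \(f_s \sim N(0,1)\); the query gene loads on it with
\(\lambda_q\), each of the module genes with \(\lambda_m\), all other genes
with 0; every gene adds independent \(N(0, \sigma^2)\) noise on top of a
per-gene baseline. This is the simplest mechanism with a closed-form
planted correlation,

\[ r = \frac{\lambda_q \lambda_m}
          {\sqrt{(\lambda_q^2 + \sigma^2)(\lambda_m^2 + \sigma^2)}}, \]

recorded per tissue in the returned truth object. The defaults
(`n_tissues = 10`, `samples_per_tissue = 60`, `n_genes = 2000`,
`n_module = 20`, \(\lambda_q = \lambda_m = 1\), \(\sigma^2 = 2/3\), hence
\(r = 0.60\)) are a desk-scale panel: ten tissues matches the procedure's
top-ten convention; 60 samples per tissue is a round working size in the
spirit of public multi-tissue RNA-seq panels, whose per-tissue cohorts
commonly run from under a hundred to a few hundred donors; 2,000 genes
keeps a full recovery experiment fast enough to repeat over many seeds.

```{r recovery}
sim <- simulate_expression_panel(seed = 1)
tab <- rsum(correlate_query(sim$panel, sim$truth$query_gene_id))
ext <- extreme(tab, quantile = 0.005)
glance(ext)
mean(sim$truth$planted_gene_ids %in% ext$gene_id)
```

A structural point worth stating explicitly: the top-0.5% extreme of a
2,000-gene table holds exactly `ceiling(0.005 * 1999) = 10` genes (absent
boundary ties), so when 20 module genes are planted, at most half of them
can ever sit inside it — recall is bounded by the set size, not by the
statistic. In this regime the extreme is essentially pure module
(precision near 1, null genes nearly absent), and enlarging either the
quantile or the gene universe relative to the module raises the recall
ceiling accordingly.

What the generator does **not** emulate: count noise (the panel is
Gaussian on the log scale), gene–gene correlation outside the planted
module, tissue-specific module membership, and heavy-tailed expression.
Passing tests therefore demonstrate correctness of the ranking machinery
and its behaviour under the stated model, not robustness to every property
of real RNA-seq panels.

# TMM normalization

`tmm_factors()` implements trimmed-mean-of-M-values scaling. For library
\(j\) against a reference \(r\), with depth-adjusted abundances
\(p = y/N\): genes with a zero count in either library are dropped;
\(M_g = \log_2(p_{gj}/p_{gr})\) and \(A_g = \frac12\log_2(p_{gj} p_{gr})\)
are formed; the top and bottom 30% of \(M\) and 5% of \(A\) are trimmed
(the published defaults, adopted because the procedure names the method
without parameters); and the factor is \(2\) raised to the weighted mean of
the surviving \(M_g\) with inverse delta-method binomial variance weights
\(w_g^{-1} = (N_j-y_{gj})/(N_j y_{gj}) + (N_r-y_{gr})/(N_r y_{gr})\).
The reference library is the one whose upper-quartile abundance is closest
to the mean upper-quartile; factors are rescaled to geometric mean 1 so
panels are comparable and the identity case is exact.

Two behaviours matter for interpretation. A **pure depth change** leaves
the factor at 1 because every \(M_g\) is 0 and the depth is absorbed by
the library size. On heterogeneous libraries the factor is *nearly* but
not *exactly* invariant to scaling one library, because the precision
weights depend on absolute counts; the movement is of order \(10^{-3}\)
and the reference Bioconductor implementation (edgeR, against which a unit
test compares to `1e-8`) shows the identical behaviour.

`normalize_log_cpm()` then computes
\(\log_2( y_{gj} / (N_j f_j) \times 10^6 + 1)\); the pseudocount of 1
avoids \(-\infty\) at zero counts.

`simulate_count_matrix()` provides the test bed: negative-binomial counts
(dispersion 0.1, log-normal baseline means) with per-library depth
multipliers and, optionally, an asymmetric fraction of genes up-shifted by
a fold factor in designated libraries — the composition bias TMM exists to
remove.

# Promoter motif scanning

## Conventions

* **Coordinates.** Signed, 1-based, no zero: the TSS base is `+1`, the base
  immediately upstream `-1`. A hit's position names the 5′-most base of the
  window **on the plus strand**, whichever strand matched; minus-strand
  hits are detected by comparing the reverse complement of each window to
  the pattern. The first-base convention (rather than motif centre) is
  assumed; `to_tss_coordinates()` / `from_tss_coordinates()` are exact
  inverses.
* **Alphabet.** Patterns over `A C G T W R N` (`W` = A/T, `R` = A/G,
  `N` = any); sequences over `A C G T N`, lowercase accepted, anything
  else rejected. A sequence `N` matches only a pattern `N`.
* **Mismatch profile.** `mismatch_profile()` counts mismatches per
  position and splits them by the motif's core mask. For the CArG box
  the A/T track is the core and the `CC`/`GG` dinucleotides the flank;
  `rank_carg_hits()` orders hits by core mismatches, then total
  mismatches, then distance to the TSS. This encodes the observation that
  of two single-mismatch CArG variants, the one broken in its A/T core is
  the functionally poorer match — a flank mismatch (e.g. `ACTTTTATGG`,
  profile 1/0/1) outranks a core mismatch (`CCAGATATGG`, 1/1/0).
* **Defaults.** CArG tolerates one mismatch (to admit "CArG-like"
  elements); MCAT, GATA and GRE are scanned exactly. The GATA and GRE
  patterns (`WGATAR`, half-site `TGTTCT`; both strands scanned, so
  `AGAACA` is covered) are canonical stand-ins, configurable through
  `builtin_motifs(overrides = )`, because degenerate families have no
  single printed sequence.

```{r scan}
sim <- simulate_promoter(
  length = 1000, tss_index = 801,
  planted = tibble::tibble(
    name = c("CArG", "CArG", "MCAT"),
    sequence = c("ACTTTTATGG", "CCAGATATGG", "CATTCCT"),
    tss_position = c(57L, -710L, -232L), strand = "+"
  ),
  avoid_motifs = builtin_motifs()[c("CArG", "MCAT")], seed = 1
)
scan_promoter(sim$sequence, builtin_motifs()$CArG, sim$tss_index)
```

`simulate_promoter()` substitutes planted elements into a random background
of chosen GC content (reverse-complementing minus-strand plantings). With
`avoid_motifs`, the background is redrawn until it carries no off-target
hits for the listed motifs on either strand: a 1-kb random sequence would
otherwise contain on the order of one spurious 1-mismatch CArG window per
strand, making "the scan finds exactly the planted elements" seed-dependent.
The CArG consensus is its own reverse complement, so a planted element is
legitimately reported on both strands at one position.

# Line-profile colocalization

`profile_correlations()` computes one coefficient per profile — Pearson by
default, since downstream the coefficients are averaged and t-tested as
continuous observations; Spearman is available when monotone rather than
linear association is wanted. Profiles with a zero-variance channel are
excluded with a warning rather than failing the batch.

`aggregate_profiles()` reports mean ± SEM and the two-tailed one-sample
Student t versus 0 with \(n-1\) degrees of freedom. The all-equal
(zero-variance) input is flagged `degenerate` and reported with p of 0 or
1 by the sign of the mean, so batch runs complete. `compare_groups()` is
the two-sample pooled-variance Student test (Welch by option).

`intensity_ratio()` forms `channel1 / max(channel2, epsilon)` along the
profile, with `epsilon` defaulting to 1% of the channel-2 mean (flagged in
the output) so the ratio stays finite through dark pixels, and
`ratio_fluctuation()` summarizes each profile by the coefficient of
variation of that ratio. The CV is this package's operationalization of
"the ratio fluctuates along the membrane": interdigitating domains give a
large CV, coincident channels a CV near 0.

`simulate_membrane_profiles()` draws alternating domain segments with
geometric lengths (mean `domain_length_mean = 15` points, so traces are
aperiodic like real contours, within profiles of 200 points). Channel 1 is
high in odd segments; channel 2 mixes the channel-1 pattern with its
complement under the `overlap` parameter, so `overlap = 1` duplicates
channel 1 and `overlap = 0` is exactly anti-phase (per-profile r of −1,
noise-free). Both channels sit on a constant background of one tenth of
the amplitude — fluorescence never reaches zero in practice, and a nonzero
floor is what lets the ratio CV separate the overlap regimes — with
truncated Gaussian noise (sd one tenth of the amplitude) on top. Twelve
profiles per condition mirrors typical image counts (N of 11–14 per
staining pair). The generator emulates trace structure only: no 2-D image
rendering, no point-spread function, no contour-drawing variability.

```{r coloc}
prof <- simulate_membrane_profiles(n_profiles = 12, overlap = 0.8, seed = 1)
aggregate_profiles(profile_correlations(prof$profiles))
```

# Numerical and design notes

* **Exact Spearman p.** For \(n \le 10\), `spearman_pair()` enumerates all
  \(n!\) permutations (chunked on the first element so at most \(9!\)
  permutations are materialized at once) and defines the two-sided tail as
  \(|\rho_{perm}| \ge |\rho_{obs}|\) with a \(10^{-12}\) guard against
  ties in floating point. Above \(n = 10\) the usual t-approximation with
  \(n-2\) degrees of freedom is used. Ranks are averaged over ties.
* **Determinism.** Every generator takes one explicit seed and touches no
  global state beyond `set.seed()` at entry; equal seeds give bit-identical
  output, a property under test.
* **Problem sizes.** The recovery experiments in the test suite use the
  default desk-scale panel (10 × 60 × 2,000, twenty planted genes, twenty
  seeds) and the membrane experiments 4–12 profiles of 120–200 points over
  twenty seeds; these sizes give stable Monte-Carlo averages while keeping
  a full run in tens of seconds.
* **Degenerate inputs.** Constant genes are missing, not errors;
  zero-variance profiles are excluded and logged; all-equal coefficient
  vectors are flagged; empty hit tables and empty profile files error with
  a clear message and, through the command-line wrapper, a nonzero exit
  status.

# Limitations

The generators validate machinery, not biology: latent-factor Gaussians
are an idealization of co-expression, the NB count model carries a single
dispersion, promoter backgrounds are i.i.d. with optional rejection of
off-target hits, and membrane traces are binary domain patterns under
Gaussian noise. Printed effect sizes from imaging or cohort data (specific
R values, cohort Rho values) depend on source material this package does
not ship and are deliberately out of scope; the package reproduces the
*procedures* and verifies them against planted truth and closed forms.
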
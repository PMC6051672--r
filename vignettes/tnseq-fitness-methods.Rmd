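---
title: "Serial-passage Tn-seq fitness estimation: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial-passage Tn-seq fitness estimation: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnfit)
```

# The measurement problem

A transposon insertion screen tracks tens of thousands of insertion mutants
in one pooled culture. Each mutant is identified by its insertion site; its
abundance is read out by sequencing across serial growth periods, under a
paired control and treatment (here, sub-inhibitory DNA-damaging agents).
Two facts make raw read-count ratios insufficient:

* read counts only measure *frequencies* — the whole population also grew,
  by a factor the sequencing cannot see;
* treatment changes total growth, so treatment/control count ratios mix the
  mutant's specific response with the population-wide one.

`tnfit` therefore combines sequencing with viable-cell counts. For one
growth period the culture expands from $N_0$ to $N_f$ viable cells, giving
the expansion factor $d = N_f / N_0$ and population generations
$G = \log_2 d$. A mutant at frequency $F_0$ at the start and $F_f$ at the
end of the period has fitness

$$
W = \frac{\ln\!\left(F_f\, d / F_0\right)}
         {\ln\!\left((1 - F_f)\, d / (1 - F_0)\right)},
$$

its realised doublings relative to the rest of the population: $W = 1$ for
a mutant that kept pace ($F_f = F_0$ gives exactly 1), $W = 0$ for one that
never divided, $W > 1$ for a mutant outgrowing the pool. The treatment
effect of an insertion is then isolated as the ratio
$w_{rel} = W_{treatment} / W_{control}$, computed per growth period — a
mutant that is merely slow-growing has $W < 1$ in both conditions and
$w_{rel} \approx 1$.

Two boundary conventions matter in practice:

* **Extinction.** A mutant absent from the end sample ($F_f = 0$) gets
  $W = 0$ and an `extinct` flag rather than a pseudocount; a configurable
  pseudocount (default 0) exists only for sensitivity analysis. A mutant
  extinct *in the control* carries no information about the treatment and
  is excluded from $w_{rel}$.
* **Domain.** The denominator measures the expansion of the mutant's
  complement and changes sign at $F_f^{*} = 1 - (1 - F_0)/d$. $W$ is
  well defined and strictly increasing in $F_f$ only below that bound;
  `insertion_fitness()` warns if it is crossed. Screens operate at
  frequencies of $10^{-5}$–$10^{-4}$, far from the singularity.

Because $W$ is measured against the population mean, a treatment that
depresses a fraction $x$ of sites inflates every neutral site's $W$ by
roughly $x(1 - \tfrac{\ln d^{w}}{\ln d})$; at the screen's scale
($x \approx 2\%$, $w = 0.5$) this is a ~0.6% shift, far below the effect
sizes of interest.

# From sites to genes

Sites are assigned to genes by 1-based inclusive coordinates (strand
ignored; a site inside overlapping genes counts for all of them); sites in
no gene are grouped by the intergenic region they fall in (`ig_<k>`),
which is carried through the analysis like a gene. Per gene and growth
period the package reports the arithmetic mean of $w_{rel}$ across its
insertions, the 95% CI $\bar w \pm t_{0.975,\,n-1}\, s/\sqrt n$, a
two-sided one-sample t-test against 1, and Benjamini–Hochberg adjusted
p-values. Candidates for one period are the (up to) 200 genes with the
lowest mean $w_{rel}$ and adjusted $p < 0.01$; ties at the cap break by
smaller adjusted p, then gene id. Overlaps of candidate lists across
screens (Venn regions and plain intersections) identify generally required
genes versus treatment-specific ones.

Choices made where the procedure was genuinely open:

* **Read filter.** Sites must have *strictly more than* 10 reads in the
  period's control start sample, applied to the replicate-pooled sample.
  This removes sites whose frequency estimates are dominated by counting
  noise, using only control information so the filter cannot bias the
  treatment contrast.
* **Replicates.** Replicate cultures are averaged at the frequency level
  within (condition, period) before $W$ is computed (the default);
  `replicate_mode = "pairs"` instead forms replicate-paired ratios and
  averages those. With balanced designs and shared growth conditions the
  two agree closely; both are provided because neither is canonical.
* **Period-1 start.** The starter culture (the last sample before the
  split) provides $F_0$ for growth period 1 of both conditions; each later
  period starts from the same condition's previous sample. Periods are
  self-contained — no compounding of $d$ across periods.
* **Expansion factor.** $d$ comes from viable-cell counts (geometric mean
  over replicate growth records), never from optical density or from the
  nominal dilution.
* **Sufficient data.** A gene needs at least 3 insertions in a period
  (configurable); zero-variance genes get $p = 1$ and a flag rather than an
  undefined test.
* **BH family.** Adjustment is within each growth period across genes, so
  each period's ranking is a self-contained screen readout.

# What the simulator emulates — and what it does not

`simulate_experiment()` generates the full study design with known truth:
a ~1 Mb single-replicon genome of 1,000 non-overlapping genes
(~900 ± 180 bp, 15% intergenic), two contiguous clusters of essential genes
(5% of genes) that carry no insertions, a library of 120,000 distinct
insertion sites otherwise uniform over the genome, equal initial
abundances, a starter passage, then control and treatment cultures over
three growth periods. Defaults: 20 sensitive genes at treatment fitness
0.5, expansion $d = 8$ per period (3 generations, the scale indicated by
viable counts of the $5\times10^6 \to 4\times10^7$ kind), $5\times10^6$
reads per sample, 2 replicate cultures. Growth is deterministic
exponential ($\times\, d^{W}$ per period, with realised $N_f$ reflecting
the fitness mixture); the only noise is multinomial sequencing noise, plus
an optional between-period bottleneck for drift. Per-sample randomness is
seeded by a stable hash of (condition, period, replicate), so datasets are
byte-reproducible.

Deliberately **not** modelled: PCR jackpots and mapping artefacts,
TA-site insertion bias, unequal library abundances, biological replicate
variation beyond sampling, and fitness effects that vary within a gene.
Passing recovery tests therefore shows the *estimator and inference
machinery* are correct under the stated noise model — not that real
libraries meet these assumptions; the QC module (coverage profile,
log-count skewness, $w_{rel}$ distribution) exists to check the
assumptions on real data.

With these defaults a site starts at $\sim 8\times10^{-6}$ frequency
(~40 reads): a sensitive site decays $\sqrt 8 \approx 2.8$-fold per
period in the treatment, so by period 3 extinction flags and the control
filter begin to bite — matching the behaviour of real screens, where
late periods lose the weakest mutants.

# Downstream follow-up statistics

Screen hits are validated with two further quantitative assays:

* **Spectral-count differential abundance.** Per protein, fold change
  $\bar b / \bar a$ (mutant over wild type) and a two-sample t-test;
  pooled-variance Student by default with a Welch option, since the
  original analysis does not name the variant. Counts are total-scaled so
  sample sums match the mean total. Zero wild-type means give a flagged
  infinite fold change; zero-variance proteins give $p=1$ (identical
  groups) rather than an error.
* **Filamentation proportions.** The fraction of cells strictly longer
  than 6.75 μm (three 2.25 μm cell lengths) with binomial SD
  $\sqrt{p(1-p)/n}$ — note this corrects a printed legend form
  $p(1-p)n$, which is not a standard deviation — and a one-tailed
  two-proportion z-test (pooled proportion by default, unpooled
  available), alternative "mutant exceeds wild type".

# Numerical and testing choices

Problem sizes used in the automated checks: identity and closed-form
properties at $10^4$ random points; recovery on the full default screen
(120,000 sites, 1,000 genes); FDR calibration on a 2,000-gene all-neutral
screen; tri-screen overlap on three full screens sharing 15 true hits;
differential-abundance calibration on 2,000 proteins at 3 vs 3. The
t-test calibration null is drawn from a normal count model because the
5% ± 1.5% band presumes the test's normality assumption — the screen's own
workflow verifies approximate normality before applying the test, and on
skewed (log-normal) counts the pooled t-test at $n = 3$ is mildly
conservative (~3.5% at the 5% level), which costs sensitivity, not
validity.

```{r example, eval = FALSE}
exp <- simulate_experiment(sim_config(seed = 42))
rf <- fitness_per_period(exp)
gt <- gene_fitness(rf, exp$annotation)
head(select_candidates(gt, growth_period = 2))
```

# Known limitations

* Fitness is estimated per site from two samples and a viable-count pair;
  no shrinkage is applied across sites or periods, so very low-coverage
  sites are noisy and are instead removed by the read filter.
* Extinct-in-treatment sites contribute $w_{rel} = 0$, which is a floor,
  not an estimate; gene means for strongly deleterious genes are
  correspondingly compressed toward zero in late periods.
* Gene assignment takes annotated gene bodies at face value (no 3′-end
  trimming, no polar-effect modelling) — in real data, polarity onto
  downstream operon members is a known source of false positives.
* The overlap module matches genes by identifier only; cross-screen
  comparisons require a shared annotation.
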
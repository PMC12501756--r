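---
title: "Mendelian sampling variance, haplotype similarity and contribution selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian sampling variance, haplotype similarity and contribution selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapsel)
```

## The model

A diploid parent $i$ with phased biallelic genotypes transmits to each gamete
one allele per marker, drawn by meiosis. Writing $m_k$ for the additive
(allele-substitution) effect of marker $k$ and $c_{ik} \in \{1, 0, -1\}$ for
the genotype indicator (homozygous reference / heterozygous / homozygous
alternate), the parent's breeding value is $b_i = c_i' m$. The variance of
the breeding values of its gametes — the Mendelian sampling variance (MSV) —
is driven entirely by segregation at heterozygous loci and by the linkage
between them.

`hapsel` computes the MSV as a quadratic form. The expected within-family
linkage disequilibrium between transmitted-allele indicators at two markers
$k, l$ on one chromosome is, under the Haldane mapping function,

$$\rho_{kl} = \frac{\exp(-2 d_{kl})}{4},$$

with $d_{kl}$ the map distance in Morgans; $\rho_{kk} = 1/4$, and markers on
different chromosomes are uncorrelated, so the matrix $R = (\rho_{kl})$ is
block-diagonal by chromosome and **identical for every parent**
(`build_R()`, `build_R_list()`). All parent specificity is moved into a
signed effect vector: a phase indicator $\delta_{ik}$ is $+1$ when the
reference allele sits on the first haplotype, $-1$ when on the second and
$0$ at homozygous loci, and $m_{ik} = \delta_{ik} m_k$
(`signed_effects()`). Then

$$\operatorname{var}(b_i) = m_i' R\, m_i \qquad \text{(gamete MSV, `gamete_msv()`)}.$$

Because $R$ is built once and shared, MSVs for thousands of parents cost one
quadratic form each. The older parent-specific formulation — carrying the
linkage-phase signs inside a per-parent matrix $R_i$ and zeroing its
homozygous rows — is retained unexported as a validation oracle and agrees
with the quadratic form to $10^{-10}$ on randomized instances; a third,
fully independent check enumerates all $2^L$ segregation patterns of a small
chromosome exactly (`enumerate_patterns()`, `oracle_moments()`).

Multi-trait and zygote extensions stack trait rows into $M_i$ and add
parents: $V_i = \sum_c M_{ic} R_c M_{ic}'$ has per-trait MSVs on the
diagonal and Mendelian sampling covariances off it (`multitrait_V()`); an
index $a$ gives the aggregate-genotype MSV $a'V_i a$ (`aggregate_msv()`);
and zygote quantities are sums of the two parental terms (`zygote_msv()`,
`zygote_V()`), because the two meioses are independent.

## Haplotype similarity

The same bilinear structure defines a similarity between two parents:

$$s_{ij} = \sum_c \left| m_{ic}' R_c\, m_{jc} \right|,$$

large when the parents are both heterozygous, in matching linkage phase, at
linked markers with large effects — i.e. when they would transmit similar
high-value haplotype blocks. The absolute value is taken **per chromosome**:
each parent's haplotype order is arbitrary, a swap flips the sign of its
whole per-chromosome contribution, and only the per-chromosome modulus is
invariant (verified exhaustively over all flip combinations in the tests).
A parent's similarity to itself is exactly its MSV, so the matrix $S$
assembled over a candidate set (`build_S()`) carries MSVs on the diagonal.
Standardising by the Mendelian standard deviations,
$K = D^{-1} S D^{-1}$ with $D_{ii} = \sqrt{S_{ii}}$
(`standardize_similarity()`), gives a unit diagonal and, by per-chromosome
Cauchy–Schwarz, off-diagonals in $[0, 1]$. We implement $D$ as the square
root of the diagonal; this is the only reading under which
$\operatorname{diag}(K) = 1$. Parents with MSV below $10^{-12}$ carry no
Mendelian sampling information and are excluded from $K$ with a warning
rather than dividing by zero.

Zygotic similarity between matings $(i,j)$ and $(u,v)$ matches parents
positionally (sire with sire, dam with dam) and applies the modulus per
parental term per chromosome:
$s_{ij,uv} = \sum_c (|m_{ic}' R_c m_{uc}| + |m_{jc}' R_c m_{vc}|)$. The
alternative — taking the modulus of the grand total — is not
haplotype-order invariant parent by parent, which is why the per-term
convention was adopted.

Rank deficiency (more parents than informative heterozygous loci) can make
an empirical $S$ numerically indefinite. `near_pd()` projects a symmetric
matrix onto the PSD cone in the Frobenius norm. With no linear constraint on
the repaired matrix, the alternating-projections scheme reduces to its first
step — eigen-decompose and clamp negative eigenvalues at zero — which is the
exact minimiser, so that closed form is used directly (cross-checked against
`Matrix::nearPD` in the tests). It leaves PSD input untouched.

## Contribution optimisation

Optimal contributions $n_t$ maximise the expected genetic return $n_t' r_t$
subject to $n_t' Q_t n_t / 2 \le \bar{Q}$, the sex sums
$n_t'v_f = n_t'v_m = 1/2$, non-negativity and optional per-candidate bounds
(`contribution_problem()`, `solve_contributions()`). $Q_t$ can be $S$, $K$
or a VanRaden Method 1 genomic relationship matrix (`vanraden_grm()`): one
solver, two selection philosophies (haplotype-diversity versus coancestry
control). The constraint direction is "at most": the optimisation restricts
the average similarity of the selected group, and tightening it trades gain
for diversity.

The program — linear objective, one convex quadratic constraint, box and
equality constraints — is solved by a primal log-barrier interior-point
method written for this package: Newton steps on the barrier with the
equality constraints handled by block elimination on the (SPD) barrier
Hessian, a Cholesky solve with adaptive jitter, backtracking line search,
and barrier parameter grown by 20 per stage until the duality gap is below
`gap_tol` (default $10^{-10}$). Feasibility is decided by first minimising
the quadratic form itself; if even the most-diverse contribution vector
violates $\bar{Q}$ the solver reports `infeasible` and returns that
minimiser rather than silently relaxing anything. Fixed candidates
(`lb == ub`, e.g. the female side) are eliminated algebraically, leaving the
constraint with a linear term. Solutions are deterministic; with symmetric
candidates the central path converges to the analytic centre of the optimal
face, so exact ties split evenly. Final sex sums are rescaled to machine
precision and the KKT stationarity residual is reported in the solution.

Two cardinality rules from breeding practice cannot be expressed in the
continuous program and are enforced by iterative adaptation: if more males
than `max_males` are supported, the smallest contributors' upper bounds are
zeroed and the program re-solved; if fewer than `min_males`, the best
excluded males by criterion receive a floor contribution (one mating's
worth, $1/(2 F)$ for $F$ females). `allocate_matings()` converts
contributions to mating counts by largest-remainder rounding, applies the
cap on females per male with proportional redistribution, and randomises the
male-female assignment under an explicit seed.

The selection criterion can be the breeding value itself or the
usefulness-style index $I_i = b_i + 2 x_p \sigma_{g i}$
(`selection_index()`), with $x_p$ the standard-normal truncation point of
the selected proportion $p$ and $\sigma_{gi} = \sqrt{\mathrm{MSV}_i}$;
at $p = 0.5$ or $\sigma_{gi} = 0$ it reduces to $b_i$.

### Calibrating the constraint

`calibrate_constraint()` fixes $\bar{Q}$ once, from the base population, as
a percentile of the off-diagonal similarity distribution (after scaling $S$
by its maximum element or maximum MSV; $K$ needs no scaling), and the same
$\bar{Q}$ is applied in every later generation. One genuinely open point is
the scale on which a similarity percentile should bound the quadratic form.
Since contributions sum to one, $n'Qn$ is the contribution-weighted
*average* similarity of the selected group, so `form = "average"` (the
default) bounds that average by the chosen percentile, i.e.
$\bar{Q} = q_{\text{percentile}} / 2$ on the $n'Qn/2$ scale. The literal
alternative `form = "quantile"` uses the raw percentile as the bound on
$n'Qn/2$, which is looser by a factor of two; in our simulated base
populations it essentially never binds, and every constrained scheme then
degenerates to truncation. The default therefore reflects the
interpretation under which the constraint does the work it is meant to do.

## The simulator

`run_scheme()` is a compact, self-contained breeding-program simulator used
to compare schemes: truncation selection on breeding value or index, and
contribution selection constrained by $S$, $K$ or a GRM. The full-scale
configuration (`sim_config()`) is 1000 individuals (500/500 by sex), 10
chromosomes of 1 Morgan with 1000 SNPs and 200 QTLs each, additive QTL
effects from $N(0, 100)$, heritability 0.25, 50 generations; under
truncation the top 1% of males (5 sires, 50 females each) and top 50% of
females (250, one mating each) are selected and each mating leaves 4
offspring with alternating sexes, keeping the population size constant.
Selection uses the true QTL effects throughout (the known-marker-effects
assumption), and similarity matrices are computed on the QTL loci by
default.

Founders draw allele frequencies from a U-shaped Beta(0.5, 0.5) and
haplotypes marker-wise; map-consistent LD is then built by 10 random-mating
burn-in generations through the package's own meiosis. This replaces a
coalescent cattle demography: it produces realistic within-chromosome LD
decay (verified in the tests), but not any particular livestock LD
spectrum, so simulation results are read as *directional* comparisons
between schemes, never as quantitative reproductions of empirical gains.
Meiosis itself exploits that a no-interference (Poisson) crossover process
restricted to marker loci is a Markov chain: the transmitted haplotype
starts Bernoulli(1/2) and switches between adjacent markers with probability
$\theta = (1 - e^{-2d})/2$. This is exact at marker resolution and fully
vectorised; its empirical gamete-BV variance matches `gamete_msv()` within
Monte-Carlo error, which ties the simulator to the analytical core.

The monitored records per generation are genetic gain in base-generation
genetic-SD units, the SD of true breeding values, genomic inbreeding
$F_t = 1 - Ho_t$ (mean observed SNP heterozygosity), favourable QTL alleles
lost (favourable = the allele with positive substitution effect; lost =
frequency exactly zero), mean favourable QTL allele frequency, SNP loci with
an allele lost, and the number of distinct sires used.

Routine test and demonstration runs use a reduced preset, `desk_config()`:
200 individuals, 3 chromosomes with 100 SNPs + 20 QTLs each, 15 generations,
30 replicates, top 5% of males (5 sires, 10 females each) and 50 selected
females — the same 5-sire structure and mating ratios as the full design at
one fifth the size, chosen so a full scheme comparison completes in minutes.
At this scale the qualitative contrasts of interest reproduce: tightly
$K$-constrained contribution selection retains far more terminal genetic SD
than truncation on breeding value, loses fewer favourable QTL alleles (the
contrast is clearest for the index-criterion schemes, and is under-powered
at 60 QTLs with the plain-BV criterion), and recruits more sires as the
constraint tightens. If a generation's program is infeasible — the fixed
female block plus any male allocation already exceeds $\bar{Q}$ — the
configured fallback uses the minimum-similarity contribution vector (the
feasibility minimiser, i.e. the most diverse choice) and flags the
generation in the records; the alternative `infeasible_action = "abort"`
stops the replicate instead. A previous generation's solution is not a
usable fallback because the candidate set has changed.

Randomness is controlled by one master seed; each replicate derives its own
seed, and the mating shuffle takes an explicit seed drawn from the
replicate stream, so every run is bit-reproducible.

## Numerical choices and limitations

* Tolerances: PSD tolerance $10^{-10}$ for Mendelian covariance matrices;
  constraint satisfaction asserted at $10^{-8}$; path equivalences tested at
  $10^{-10}$; `near_pd` relative symmetry tolerance $10^{-8}$.
* Co-located markers (zero map distance, distinct loci) are accepted with
  $\rho = 1/4$ and a warning; the paper-style worked inputs given as
  recombination fractions are converted to cumulative positions through the
  Haldane function so both input styles share one code path.
* Ties in truncation selection break lexicographically by (criterion, id);
  the enumeration oracle refuses beyond 20 loci rather than approximate.
* Only the Haldane map function is supported (no interference); no
  dominance or epistasis; phasing, imputation and marker-effect estimation
  are out of scope — inputs must be completely phased, and unphased or
  missing genotypes are rejected at read time with coordinates.
* Dense matrix storage: populations beyond ~20k candidates are outside the
  intended contract.

## Worked example

```{r example}
ex <- worked_example()      # 2 parents, 3 markers, theta = (0.1, 0.2)
Rl <- build_R_list(ex$map)
se1 <- signed_effects(ex$pg, ex$effects, "parent1")
se2 <- signed_effects(ex$pg, ex$effects, "parent2")
c(msv1 = gamete_msv(se1, Rl, ex$map),
  msv2 = gamete_msv(se2, Rl, ex$map),
  s12  = pairwise_similarity(se1, se2, Rl, ex$map))
standardize_similarity(build_S(ex$pg, ex$effects, ex$map))[1, 2]
oracle_moments(enumerate_patterns(ex$theta, ex$pg, c(1, 0.2, 0.02)))$var
```
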
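# allergotype

Bayesian clustering and longitudinal tracking of allergen-component IgE
sensitization, with outcome association — for epidemiologists and
biostatisticians analysing component-resolved diagnostics (CRD) panels from
birth cohorts.

Multiplex chips such as ISAC measure IgE against >100 individual allergenic
proteins ("components") per serum sample. Across childhood follow-ups these
per-age panels hide a latent structure: sets of components to which children
respond jointly, which form, merge, split and dissolve as children age, and
whose sensitization carries different risks of asthma and rhinitis.
`allergotype` implements the full analysis chain for such data:

1. **Panel handling** — read/write delimited panels, binarize at the
   positivity cutoff (0.30 ISU, inclusive), apply the activity rule (a
   component is *active* at an age when ≥3 children respond), restrict to
   responders, and annotate component drop-outs as resolution vs attrition.
2. **Cross-sectional clustering** — a Bernoulli mixture model over
   components with an unknown number of clusters *K*. For cluster *k* with
   members $\{x_i\}$, subject $j$, the per-subject success probabilities
   $\theta_{kj} \sim \mathrm{Beta}(a,b)$ and the mixture weights
   $w \sim \mathrm{Dirichlet}(\gamma)$ are integrated out analytically,
   giving the collapsed posterior over an allocation $z$:

   $$p(K, z \mid X) \propto p(K)\;
     \frac{\Gamma(K\gamma)}{\Gamma(n+K\gamma)}
     \prod_{k=1}^{K}\frac{\Gamma(n_k+\gamma)}{\Gamma(\gamma)}
     \prod_{k=1}^{K}\prod_{j=1}^{J}
     \frac{B(a+s_{kj},\, b+n_k-s_{kj})}{B(a,b)}$$

   with $s_{kj}$ the positive count of cluster $k$ in subject $j$. The
   sampler is an allocation sampler (full-conditional Gibbs sweeps, three
   Metropolis block moves, and a trans-dimensional eject/absorb pair)
   embedded in Metropolis-coupled MCMC (MC³) with inverse temperatures
   $\beta_c = 1/(1+\delta(c-1))$; only cold-chain draws are retained.
3. **Relabeling** — label switching is resolved with the Equivalence
   Classes Representatives (ECR) algorithm against the MAP pivot,
   conditional on the modal $K^\*$; the result is a component × cluster
   matrix of posterior assignment probabilities.
4. **Cluster flows** — per-age clusterings (fit independently) are linked
   into a weighted flow graph through shared components, with an explicit
   "inactive" pool, and cluster-level events (persist / split / absorb /
   newly-formed / reabsorbed / dropout) labeled from the topology.
5. **Outcome association** — subject-level cluster-sensitization profiles
   (sensitized = responds to ≥1 member component; the all-negative children
   form the nonsensitized group), and univariable plus multiple logistic
   regression yielding odds ratios with Wald 95% CIs, with separation and
   collinearity flagged rather than crashed on.
6. **Synthetic cohorts** — a generator that plants exactly the assumed
   mixture structure, longitudinal flow scripts, subject attrition and
   logistic outcome models, so that every stage is testable end to end
   without access to any cohort data.

## Worked example

Fit the well-separated synthetic scenario (4 planted clusters over 70
components × 400 subjects) and associate cluster sensitization with asthma:

```r
library(allergotype)

cohort <- simulate_longitudinal("s1", seed = 1)
panel  <- cohort$panels_binary[["5"]]

fit <- cluster_components(panel, mixture_config(Kmax = 10, n_sweeps = 3000, seed = 2))
glance(fit)
#>   n_items n_subjects n_draws K_star prob_K_star swap_rate
#> 1      70        400    1500      4       0.959     0.901
```

The posterior over the number of clusters concentrates on the planted
*K* = 4 with probability 0.96. Membership is then inferred conditional on
*K*\*, relabeled with ECR:

```r
rel <- relabel_chain(select_conditional_draws(fit, modal_K(fit)))
asg <- assignment_matrix(rel)
head(tibble::as_tibble(asg)[, c("component_id", "modal_cluster", "modal_prob")], 4)
#>   component_id modal_cluster modal_prob
#> 1 C001                     4          1
#> 2 C002                     4          1
#> 3 C003                     4          1
#> 4 C004                     4          1
```

Assignment probabilities are 1.0 throughout — the planted partition is
recovered exactly (the cluster indices are arbitrary labels). Finally, the
adjusted odds ratios from one joint logistic model:

```r
prof <- build_profiles(panel, modal_membership(asg))
associate_clusters(prof, cohort$outcomes, "current_asthma", models = "multiple")
#>  exposure    or ci_low ci_high  p_value
#> cluster_1 1.130  0.641    1.99 6.72e-01
#> cluster_2 0.842  0.487    1.46 5.40e-01
#> cluster_3 1.386  0.799    2.41 2.46e-01
#> cluster_4 7.467  3.141   17.76 5.37e-06
```

One cluster (the generator's risk cluster, planted OR 3.5) stands out;
at n = 400 the single-replicate estimate is noisy but its CI covers the
planted value, and the null clusters sit near OR 1. `autoplot()` methods
exist for the chain, the assignment matrix, the flow graph and the
association table; `run_pipeline()` drives the whole chain from one YAML
or list config and writes every table plus a reproducibility manifest.

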
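# irtlab

An estimation laboratory for the one- and two-parameter logistic item
response models (1PL/Rasch and 2PL), built for studying how the choice of
prior distribution affects Bayesian parameter recovery.

A person $i$ with ability $\theta_i$ answers item $k$ (difficulty $b_k$,
discrimination $a_k$) correctly with probability

$$P(Y_{ik}=1\mid\theta_i,b_k,a_k)=\frac{e^{a_k(\theta_i-b_k)}}{1+e^{a_k(\theta_i-b_k)}},$$

and irtlab fits this model four ways, behind one common estimate container:

| method | idea | priors |
|---|---|---|
| `fit_cml()` | conditional ML via elementary symmetric functions, sum-to-zero difficulties, ML person scoring (1PL only) | none |
| `fit_mml()` | Bock–Aitkin EM against a fixed N(0,1) ability distribution | none |
| `fit_mcmc()` | Metropolis-within-Gibbs (C++), burn-in 5000 / 1000 retained draws, posterior means and SDs | matched, standard-vague, hierarchical |
| `fit_vb()` | mean-field variational Bayes with the Saul–Jordan bound on the logistic function | matched, standard-vague, hierarchical |

The *matched* regime equals the generating distributions
($\theta,b\sim N(0,1)$, $a\sim$ lognormal(0, sd 0.25)); *standard-vague*
widens the item priors to variance $10^3$ (difficulty) and 8
(log-discrimination); *hierarchical* puts $N(0,10^6)$ hyperpriors on the
population means and Gamma(1,1) on the precisions. Around the estimators
sits a complete simulation-study harness: synthetic data generation,
shift/scale identifiability alignment, average-RMSE and SE recovery
metrics, $\eta^2$ ANOVA effect sizes, marginal-mean report tables, and a
resumable crossed-design runner. The methods vignette
(`vignettes/irtlab-methods.Rmd`) documents the models, numerical design
choices, and limitations.

## Worked example

```r
library(irtlab)

truth <- draw_parameters(S = 500, L = 10, model = "2PL", seed = 1)
Y <- simulate_responses(truth, seed = 2)

fit <- fit_vb(Y, "2PL", make_prior("hierarchical", "2PL"), tol = 0.05)
fit
#> vb_fit: 2PL, hierarchical prior, 106 sweeps, bound -3024.0005, converged: TRUE

al <- align_estimates(fit$estimates, truth)
al
#> irt_alignment: s = 0.6999, t = -0.0121, J = 0.93427
sqrt(mean((al$aligned$b - truth$b)^2))   # difficulty RMSE: 0.168
sqrt(mean((al$aligned$a - truth$a)^2))   # discrimination RMSE: 0.138
```

The hierarchical prior leaves the latent scale free, so the fit settles at
about 70% of the generating scale (`s = 0.70`); the alignment step maps it
back through the likelihood-equivalent transform
$(\theta,b,a)\to(s\theta+t,\,sb+t,\,a/s)$ before errors are computed. At
$S=500$ the difficulty and discrimination RMSEs land near 0.17 and 0.14,
shrinking roughly as $1/\sqrt{S}$ in the full study.

A design cell of the recovery study, and its report row:

```r
cs <- run_condition("1PL", "CML", S = 250, L = 10, R = 5, root_seed = 42)
tabulate_results(cs, "T3")
#>   method ability_rmse ability_se difficulty_rmse difficulty_se probability_rmse
#> 1    CML         0.87       0.83             0.1          0.14             0.15
```

Full crossed studies run from a YAML config via `run_study()` (per-cell
CSVs, resumable), or from the shell through the thin CLI in
`inst/scripts/irtlab.R` (`simulate`, `fit`, `study`, `report` verbs).

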
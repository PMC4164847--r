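# fahp — improved fuzzy AHP for sustainability evaluation

`fahp` is an R package for multi-criteria evaluation of competing
alternatives against a layered indicator hierarchy, built on an improved
fuzzy analytic hierarchy process. It was written for ecological
sustainability assessment — the bundled case study compares two
timber-skidding technologies (light cableway skidding vs. traditional
road-skidding) on 39 ecological, economic and social indicators — but the
engine is generic: any target / criteria / indicator tree with expert
pairwise judgments and per-alternative indicator values will do.

## The method

Experts compare sibling criteria pairwise on the three-scale division
{0, 0.5, 1} (less / equally / more important). Per hierarchy node:

1. plurality aggregation of expert scores into a complementary **fuzzy
   judgment matrix** F (fᵢⱼ + fⱼᵢ = 1, fᵢᵢ = 0.5);
2. the row-sum transform rᵢⱼ = (rᵢ − rⱼ)/2n + 0.5 into a **fuzzy consistent
   matrix** R, additively consistent by construction (no consistency-ratio
   check needed);
3. closed-form priority vectors by row normalization or geometric mean;
4. the ratio conversion eᵢⱼ = rᵢⱼ/rⱼᵢ into a positive **reciprocal matrix**
   E, whose principal eigenvector — found by power iteration, seeded with
   the normalizing vector — is the refined ranking vector, with λ_max
   reported as the infinity norm of the final iterate.

Local weights are synthesized down the tree by path products into composite
leaf weights λᵢ, raw indicator values are standardized to [0, 1] (min-max by
indicator direction, percentages by fractional scaling, qualitative grades
passed through), and each alternative is scored by the comprehensive index

    P = Σᵢ xᵢ λᵢ + c        (correction c = 0 by default)

The methods vignette (`vignettes/fahp-methods.Rmd`) gives the full account
of the model, the numerical choices and the limitations.

## Worked example

The bundled case study ships the full 4-level hierarchy (1 target, 3
benefit criteria, 9 sub-criteria, 39 leaf indicators), the aggregated
expert judgment matrices for the target node and the natural-ecology node,
the standardized indicator values for both skidding methods, and the field
cost measurements.

```r
library(fahp)
case <- skidding_case()
fit  <- fahp(case$hierarchy, case$values, panels = case$judgments)
fit
#> Fuzzy-AHP comprehensive evaluation (iterative weights)
#> 39 leaf indicators, 2 alternatives; correction c = 0
#>
#> Comprehensive scores P:
#> cableway     road
#>   0.6727   0.4475

compare_alternatives(fit)
#>  alternative      P rank delta_next
#>     cableway 0.6727    1     0.2252
#>         road 0.4475    2         NA
```

Cableway skidding scores 0.67 against 0.45 for road-skidding: on these
indicators the cableway method dominates, and `delta_next` quantifies the
margin (0.23 on the unit scale). The per-node pipeline is available piecewise:

```r
node_weights(case$judgments$C11)   # five natural-ecology indicator weights
#> Priority vector (iterative method)
#>     D1     D2     D3     D4     D5
#> 0.0647 0.1665 0.3310 0.3310 0.1069
#> lambda_max = 5.0106 in 4 iteration(s)
```

`summary(fit)` prints the full 39-row evaluation table (composite weight,
standardized and integrated value per alternative); `fahp_report(fit, file)`
writes it as TSV. `coef(fit)` returns the composite weights, and
`predict(fit, newdata)` scores fresh alternatives with the fitted weights.

Synthetic fixtures for experimentation come from `random_hierarchy()`,
`generate_panels()` and `random_values()`, all seed-reproducible. A thin
command-line front end over the same functions is installed at
`inst/cli/fahp.R` (subcommands `weights`, `evaluate`, `report`,
`fixtures`).

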
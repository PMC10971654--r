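# gardsim

Stochastic simulation of the GARD (graded autocatalysis replication domain)
model of micellar reproduction, with the two observables used to place its
dynamics on an order–complexity diagram: the reciprocal sequential entropy
of virtual random walks through the system, and a combinatorial code-size
estimate of Kolmogorov complexity.

## The science

In the "Lipid World" picture of the origin of life, micelles made of many
amphiphile types can reproduce *compositional* information without any
polymer genome. Accretion of amphiphile type *i* into an assembly of
composition *n* (total size *N*) follows the mutually catalytic rate law

    dn_i/dt = (k_i π_i N − k_−i n_i) · (1 + (1/N) Σ_j β_ij n_j)

where *π_i* are the buffered external fractions, *k_i*, *k_−i* forward and
backward rate constants, and *β_ij* the matrix of rate-enhancement factors
by which resident molecules of type *j* catalyze the accretion of type *i*.
Grown assemblies split into two random halves; compositions that the
catalytic network reproduces faithfully across growth–split generations are
**composomes**, and clusters of similar composomes are **compotypes** with
population fractions *P_k*, composition profiles *p_i,k*, and mean sizes
*N_k*.

Two observables summarize the population's evolutionary state:

* **Order** — the reciprocal of the sequential entropy assigned to the
  ensemble of virtual random walks through monomers and micelles,

      S_r = k_B · [M·N_rw/(M+N)] · Σ_i π_i ln(1/π_i)
          + k_B · Σ_k P_k · [N_rw/(M+N)] · N_k · Σ_i p_i,k ln(1/p_i,k)

  with *M* the mean number of aqueous monomers between micelles on the
  walk, *N* the mean micelle size, and *N_rw* the number of walk units.
  Dividing *N_rw* by Avogadro's number gives molar units, J/(K·mol).

* **Complexity** — the code needed on top of a plain random generator to
  reproduce the walk statistics once composomes deviate from the
  environment: each compotype drawing on an effective repertoire of *N_Ck*
  types over *N_k* molecules contributes
  `c_k = P_k · N_rw/(M+N) · log2[ (N_Ck+N_k−1)! / (N_k!·(N_Ck−1)!) ]` bits.

The simplest information coding assigns one bit per amphiphile type (1 =
enriched or unchanged relative to the solution, 0 = depleted), so a
composome over twenty types carries 20 bits — the content of a ten-base RNA
strand at two bits per base.

## Worked example

Run the slow-takeover scenario — two engineered catalytic attractors, the
later of which gradually displaces the earlier — then cluster compotypes
and compute the order/complexity time series:

```r
library(gardsim)
p   <- gard_preset("slow_takeover", seed = 1)
sim <- gard_simulate(preset = "slow_takeover", seed = 1, out_dir = "demo")
res <- gard_analyze(sim$trajectory, out_dir = "demo", k = p$k, eta = p$eta,
                    walk = p$walk, epsilon = p$epsilon)
res$series
#> <gard_compotype_series> 4500 generations, 2 compotypes (eta = 0.95)
#>   final P_k: 0.42 0.4; final drift: 0.18
gard_report(res$metrics)
```

The report compares the first and last generation:

```text
{"complexity_change_pct": 4000, "order_change_pct": 5.05,
 "delta_S_r": -0.889, "S_r_start": 18.48, "S_r_end": 17.59}
```

Complexity grows from its near-zero starting value as composomes form
(+4000 %), the order rises by 5 % and the molar sequential entropy drops by
0.89 J/(K·mol): the population has moved up the order–complexity diagonal.
`demo/` now holds the trajectory CSV with its JSON sidecar, the compotype
fractions and centroids, the metrics table, and `diagram.csv` with the
(c, order, t) points of the order–complexity diagram.

The same pipeline is scriptable from a shell through `inst/cli/gard.R`
(`simulate`, `analyze`, `report`, `preset-list`).

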
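# hicblocks

Detection of conserved and reorganized higher-order chromatin blocks
between two biological conditions from Hi-C contact maps.

## The problem

Hi-C contact maps organize into topologically associating domains (TADs):
contiguous genomic regions whose loci preferentially contact one another.
Comparing this higher-order organization between two conditions (two ages,
two treatments, two cell states) is hard for two reasons: contact maps are
noisy and sparse, and domains called independently per condition cannot be
matched to each other, so "this domain changed" is ill-posed.

`hicblocks` is for genomicists who have per-chromosome binned contact
matrices in two conditions and want a matched, per-bin answer to *what
stayed and what moved*. It combines:

1. **Network enhancement (NE)** — graph-diffusion denoising. The localized
   row-stochastic kernel *P* (top-*k* neighbors per bin) is turned into a
   symmetric doubly-stochastic kernel *T*, which is diffused by
   `W <- a T W T + (1 - a) T` (equivalently, in closed form, by mapping
   each eigenvalue λ of *T* to `(1 - a) λ / (1 - a λ²)`).
2. **Consensus-regularized multiview NMF (MVNMF)** — a joint factorization
   of the two enhanced maps,

   ```
   min_{U,V,Vc >= 0}  Σ_t  || X(t) - U(t) V(t)ᵀ ||²_F + α || V(t) - V(c) ||²_F
   ```

   solved by hierarchical alternating least squares (HALS) with exact
   column-wise non-negative updates, so the objective is monotone and the
   task factors share cluster identities through the consensus factor V(c).
3. **Block calling** — each bin goes to its dominant latent feature,
   `c_i(t) = argmax_j U(t)[i, j]`; maximal constant runs of ≥ 5 bins
   (50 kb at 10 kb resolution) where the conditions disagree are **dynamic
   blocks**, agreeing runs are **static blocks**, everything else is noise.
   Blocks carry the sum of absolute count differences over their bin pairs
   plus t-test and Wilcoxon rank-sum p-values.

Also included: ICE matrix balancing, HiC-Pro sparse-format I/O, a
distance-stratified z-score filter for differential chromatin interactions
(DCIs) built from external caller outputs, gene/GWAS-locus linking, a
fully seeded synthetic two-condition Hi-C generator with planted domain
reorganizations, and a command-line interface.

## Worked example

Generate the default synthetic pair — a 2 Mb chromosome at 10 kb bins with
four domains and a planted 10-bin reassignment (bins 101–110 moved to the
adjacent domain in condition B) — and run the full pipeline:

```r
library(hicblocks)
sim <- generate_pair(synthetic_spec(seed = 1))
res <- run_pipeline(sim$A, sim$B, pipeline_config(rank = 4, seed = 101))
res$blocks[, c("start_bin", "end_bin", "kind", "label_a", "label_b",
               "abs_count_diff_sum", "t_test_p")]
#>   start_bin end_bin    kind label_a label_b abs_count_diff_sum  t_test_p
#> 1         3      50  static       2       2              13493 9.991e-01
#> 2        51     100  static       1       1              13896 8.586e-01
#> 3       101     110 dynamic       4       1               2546 4.214e-14
#> 4       111     150  static       4       4               9566 9.158e-01
#> 5       151     198  static       3       3              13540 9.338e-01
```

The planted reassignment is recovered exactly as the single dynamic block
(bins 101–110): its cluster label switches from 4 to 1 between conditions
and its within-block counts differ significantly (t-test p ≈ 4e-14), while
the static blocks — despite summing more raw Poisson noise over their much
larger spans — show no systematic difference (p ≈ 1). Cluster assignments
agree perfectly with the generating domain maps:

```r
rand_index(res$track_a$labels, sim$domains_a)
#> [1] 1
rand_index(res$track_b$labels, sim$domains_b)
#> [1] 1
```

`run_pipeline()` optionally writes `blocks.tsv`, per-bin cluster labels,
factor matrices, the objective trace, and a provenance JSON to an output
directory. The same stages are scriptable from a shell:

```sh
Rscript inst/cli/hicblocks.R simulate --n-bins 200 --domains 4 --seed 7 --out-prefix sim
Rscript inst/cli/hicblocks.R run --bins-a sim_A_abs.bed --matrix-a sim_A.matrix \
    --bins-b sim_B_abs.bed --matrix-b sim_B.matrix --chrom chrS --rank 4 --out results/
```

(after installation, `system.file("cli", "hicblocks.R", package =
"hicblocks")` locates the script). Subcommands `ice`, `enhance`,
`factorize`, `blocks`, `dci`, and `link` expose the individual stages so
externally computed interaction-significance tables can be injected
mid-pipeline.

## Further reading

The methods vignette (`vignettes/hicblocks-methods.Rmd`) documents the
model and its assumptions, the HALS updates and their monotonicity, every
tunable parameter with units and defaults, what the synthetic generator
does and does not emulate, and known limitations.
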
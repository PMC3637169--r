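# focalDrivers

Prioritizing candidate cancer driver genes by integrating somatic
copy-number alterations and point mutations across a tumor cohort.

## The problem

Driver genes are usually buried inside large copy-number lesions spanning
dozens to hundreds of bystander genes, while point mutations point at
single genes but are sparse. Two signals distinguish a driver from a
passenger: its alterations **recur** across many samples, and they tend to
be **focal** — small lesions are more informative about which gene is
under selection than broad chromosomal events. `focalDrivers` turns both
signals into posterior probability distributions over the gene universe
and integrates them with recurrent point-mutation evidence, producing a
ranked, tiered list of candidate oncogenes (from gains) and tumor
suppressors (from deletions).

## The model

A lesion is a pair *M = (C, N)*: an amplitude *C* (copies deviated from
ploidy; 1 for a mutation) and the set *N* of genes it covers. The lesions
of one sample form a disjoint set *S = {M₁, …, Mₜ}*. For a prior *Pᵈ* over
genes, two posteriors give the probability that gene *D* drives the
phenotype:

- **Recurrence (global) score**
  *R(D|S) = Σᵢ Cᵢ δ(D∈Nᵢ) Pᵈ(D) / Σᵢ Cᵢ Σ_{G∈Nᵢ} Pᵈ(G)* —
  every altered gene is a candidate; with a uniform prior and unit
  amplitudes each of the *K* altered genes gets *1/K*.
- **Focality (local) score**
  *F(D|S) = Σᵢ (Cᵢ/Σⱼ Cⱼ) δ(D∈Nᵢ) Pᵈ(D) / Σ_{G∈Nᵢ} Pᵈ(G)* —
  lesions get equal (amplitude-weighted) chances of containing the driver,
  so a gene in a lesion of *L* genes among *t* lesions gets *1/(tL)*:
  focal events score higher.

Per-sample posteriors are averaged over the cohort. By default the prior
is then **iterated to its empirical fixed point**
*Pⱼ₊₁(D) = (1/T) Σᵢ Pⱼ(D|Sᵢ)*, stopping when the Kullback–Leibler
divergence between consecutive iterates drops below a tolerance (bits).
Focality × recurrence (renormalized) gives the combined copy-number
score; mutation scores (*1/N* per sample over the *N* mutated genes,
restricted to recurrently mutated genes) are integrated as
*mutation × (recurrence + focality)*, separately for gains and deletions.
Each resulting distribution is cut into **entropy tiers** (round *k*
keeps genes with probability above *2^−H(Pₖ)*, removes them,
renormalizes, repeats) and top-tier genes are grouped into contiguous
genomic **regions**, each labeled with its highest-scoring **leader**
gene.

## Worked example

A small simulated cohort ships with the package (80 genes on 4
chromosomes, 10 samples, five implanted drivers; written by
`writeCohort(simulateCohort(...))`):

```r
library(focalDrivers)
gm  <- readGeneModel(system.file("extdata", "genes.bed", package = "focalDrivers"))
res <- runPipeline(gm,
    segments  = readSeg(system.file("extdata", "cohort.seg", package = "focalDrivers")),
    mutations = readMutations(system.file("extdata", "mutations.tsv",
                                          package = "focalDrivers"),
                              format = "tsv", model = gm))
res$scores$integrated_gain
#> ScoreVector (integrated) over 80 genes, 8 with positive score
#>   top: G00040=0.7758, G00072=0.1213, G00008=0.1029, G00024=1.3e-08, ...
res$regions$gain[, c("rank", "chromosome", "n_genes", "leader", "leader_score")]
#>   rank chromosome n_genes leader leader_score
#> 1    1       chr2       1 G00040    0.8105121
res$metadata$iteration$gain_focality[c("n_iter", "converged")]
#> $n_iter
#> [1] 49
#> $converged
#> [1] TRUE
```

The three genes with the highest integrated gain score — G00040, G00072,
G00008 — are exactly the three implanted gain drivers: their focal,
recurrent gains plus elevated mutation rates dominate the broad passenger
lesions covering everything else. The region report names G00040 as the
leader of the top gain region, and the metadata records that the
empirical-prior iteration for the gain focality family converged after 49
updates.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/focaldrivers.R score \
    --genes genes.bed --seg cohort.seg --mut-tsv mutations.tsv --out out/
Rscript inst/scripts/focaldrivers.R simulate --n-genes 2000 --seed 42 --out sim/
```

writing `{analysis}.scores.tsv`, `{analysis}.tiers.tsv`,
`{analysis}.regions.tsv/.json` and `run_metadata.json`.

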
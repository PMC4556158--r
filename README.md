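# tetrabin

Metagenome binning: grouping assembled contigs into genome bins by combining
sequence composition with per-sample coverage, using empirically calibrated
probabilistic distances and an iterative medoid clustering.

## The problem and the model

Shotgun metagenome assemblies fragment each community member into many
contigs. Binning reconstructs draft (population) genomes by grouping contigs
that share two signals:

1. **Composition.** Each contig gets a tetranucleotide frequency (TNF)
   vector: 4-mers counted strand-invariantly over 136 canonical classes and
   normalized. The Euclidean TNF distance *D* between two contigs is
   calibrated into the **tetranucleotide distance probability**

   TDP = 1 / (1 + exp(−(b + c·D)))

   the posterior probability that the contigs derive from *different*
   genomes. The parameters b and c are fitted, per fragment-size pair, to
   the empirical posterior P(T | D) obtained by shredding training genomes
   (2.5–500 kb), sampling intra-/inter-genome fragment pairs, and applying
   Bayes' rule with prior odds P(T) = 10·P(R). Short contigs carry noisier
   TNF estimates, so b and c form surfaces over a fragment-size grid,
   interpolated bilinearly in log size; lengths are clamped at 2.5 kb.

2. **Abundance.** In each sample a contig's read depth is summarized by a
   mean μ and variance σ² (depth is super-Poisson in real data, so the
   variance is modelled, not assumed equal to the mean). The **abundance
   distance probability** of two contigs in one sample is the non-shared
   area of their normal depth distributions,
   ½∫|φ(μ₁,σ₁²) − φ(μ₂,σ₂²)|, evaluated in closed form via the density
   crossing points. Per-sample values combine by geometric mean over
   *informative* samples (those where at least one contig exceeds a minimum
   depth c = 1).

The two distances merge into one composite distance per pair:

    composite = max(TDP, ADP)            if TDP > 0.05
              = ADP·w + TDP·(1 − w)      otherwise,

with w = min(log(n+1)/log(m+1), α), n the pair's informative sample count,
m = 100, α = 0.9 — with ~10 samples the abundance signal carries about half
the weight, and with none the distance is pure TDP.

Bins are grown by a modified k-medoid sweep: seed on the deepest unbinned
contig, recruit everything within 1−p1 of the medoid, re-elect the medoid,
iterate to convergence, refine at 1−p2, repeat until no contigs remain; bins
at or below 200 kb dissolve, and (with ≥10 samples) leftover contigs can be
recruited into bins by Pearson correlation of their depth profiles (≥0.9).

The package also ships a synthetic-community generator (Markov-chain genomes
with distinct compositional bias, exponentially sized contigs >2.5 kb,
log-uniform abundances with variance = k·mean) and a base-weighted
precision/recall evaluator, so the whole method is testable offline.

## Worked example

```r
library(tetrabin)

# a small community: 4 genomes x 4 samples
spec <- community_spec(n_genomes = 4, genome_length = 500000, n_samples = 4,
                       seed = 7)
fx <- make_fixture(spec, outdir = "demo")

model <- train_default_model(seed = 7)
D <- build_distance_matrix(fx$contigs, model = model, profiles = fx$profiles)
res <- bin_all(fx$contigs, D, fx$profiles,
               binning_config(min_bin_size = 100000))
scores <- score_bins(res$bins, fx$truth)
print(scores)
cat("good genomes:", count_good_genomes(scores), "of", spec$n_genomes, "\n")
```

Output (printed by the code above):

```
  bin_id best_genome precision    recall bin_bases genome_bases
1      1         g04         1 0.9120124    455511       499457
2      2         g01         1 0.8955483    447304       499475
3      3         g02         1 0.8692204    433681       498931
4      4         g03         1 0.7554733    377683       499929
good genomes: 4 of 4
```

Each bin is pure (precision 1: every base in the bin comes from its best
genome) and captures 76–91 % of its genome's assembled bases (recall); all
four genomes clear the "good bin" bar of >90 % precision and >30 % recall.
On the package's reference benchmark (10 genomes × 3 Mb, 5 samples, seed
42) the same pipeline recovers 10/10 genomes — recomputed on every test run
in `tests/testthat/test-acceptance.R`.

## Command line

```sh
Rscript inst/cli/tetrabin.R make-fixture --out fx --seed 42
Rscript inst/cli/tetrabin.R bin -i fx/assembly.fa -o out --depth fx/depth.tsv
Rscript inst/cli/tetrabin.R evaluate --membership out/membership.tsv --truth fx/truth.tsv
```

`bin` accepts `--bam` (repeatable, sorted+indexed) or `--depth` (the usual
`contigName contigLen totalAvgDepth sample sample-var …` table) or neither
(composition-only mode). Key flags mirror the method constants: `--p1 0.9`,
`--p2 0.95`, `--min-contig 2500`, `--min-bin 200000`, `--tdp-switch 0.05`,
`--min-cv 1.0`. TNF vectors, BAM depths and the default TDP model are cached
under `out/intermediates/` and reused on reruns.

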
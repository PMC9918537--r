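# migrarch

Tools and a worked analysis for dissecting the genomic architecture of
spring migration timing in wild birds that were tracked with light-level
geolocators and genotyped by whole-genome resequencing.

Arrival at the breeding grounds is a climate-sensitive, largely
endogenously controlled phenotype. Given per-bird twilight series and a
genotype matrix, the package answers three questions:

1. **How heritable is timing?** A Bayesian sparse linear mixed model
   (BSLMM) estimates the proportion of phenotypic variance explained by
   genotyped SNPs,

       y = Wα + Xβ + u + ε,   u ~ N(0, σ²λᵤK),   βⱼ ~ π·N(0, σ²λ_β) + (1−π)·δ₀,

   with covariates W (sex, year, age, PC1), a standardized genomic
   relatedness matrix K, and spike-and-slab SNP effects. It reports the
   PVE posterior median with an 89% equal-tailed interval, and per-SNP
   posterior inclusion probabilities (PIP > 0.1 flags candidate loci).
2. **Is timing predictable from genotype?** A clumping + p-value
   thresholding polygenic score (PGS), tuned leak-free on internal training
   splits and evaluated by 100-partition jackknife cross-validation
   (85%/15%; 74/13 birds at n = 87), summarized by decile: low-scoring
   birds should arrive earlier.
3. **Is any genomic region tied to the phenotype?** Windowed (5 kb)
   Weir–Cockerham F_ST between the 10 earliest and 10 latest migrants,
   corrected by subtracting the southernmost-vs-northernmost population
   contrast (net differentiation, ΔF_ST = F_ST^pheno − F_ST^pop), plus
   nucleotide diversity π and Tajima's D within groups, robust-Z outlier
   region calling, and gene overlap.

Phenotypes come from threshold geolocation: longitude from the
sunrise/sunset midpoint, latitude from day length via the sunrise equation,
and arrival as the first persistent stay within a radius of the colony.

A synthetic-cohort generator (Balding–Nichols population structure, a
plantable selective sweep with configurable differentiation and diversity
loss, an exact-PVE polygenic phenotype with a latitudinal cline, and
realistic missingness) makes every stage testable end to end with no
external data; variant QC (QUAL/MQ, missingness, MAF, exact Hardy–Weinberg,
biallelic sites, mean-dosage imputation) mirrors standard resequencing
practice.

## Worked example

The `analysis/` scripts run the whole study on the bundled generator and
write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # 87 birds, 5000 SNPs, 2 Mb sweep, 13 genes
Rscript analysis/02_variant_qc.R           # filters + mean imputation
Rscript analysis/03_geolocator_phenotype.R # twilight -> arrival closed loop
Rscript analysis/04_bslmm_pve.R            # PVE posterior + PIPs
Rscript analysis/05_pgs_crossvalidation.R  # 100x jackknife PGS + deciles
Rscript analysis/06_selection_scans.R      # delta-FST / pi / Tajima's D + regions
```

Step 2 prints the filter ledger (counts are removals attributed to the
first failing stage):

```
       stage count
       input  5000
   biallelic     0
        qual     0
          mq     0
 missingness  2421
         maf   228
         hwe    82
        pass  2269
2269 of 5000 variants pass; mean missingness among survivors 0.166
```

With 20% of calls missing at random, roughly half of all loci exceed the
20% per-variant missingness ceiling — the single biggest loss, as in real
low-coverage panels.

Step 3 closes the geolocation loop: noisy twilights (2-minute timing noise)
simulated for three birds are converted back into positions and arrival
dates:

```
     bird true_arrival estimated_arrival n_equinox_flagged mean_abs_lon_err
 FL_early           40                42                23        0.3184622
   VA_mid          110               110                24        0.2890299
  AB_late          150               150                 5        0.2696066
arrival dates recovered within 2 day(s) of truth (2-minute twilight noise)
```

Step 4 summarizes the PVE posterior. The default cohort plants a
phenotype-linked sweep whose timing morph shifts arrival by 30 days, so
genomics explains most of the variance and the strongest sweep markers are
individually detectable:

```
BSLMM posterior: 1000 retained samples
  PVE median 0.919, 89% ETI [0.735, 0.993]
  split R-hat (PVE) 1.000; 5 SNPs with PIP > 0.1
PIP > 0.1 candidates:
            variant   pip
 scaffold_1:5224071 1.000
 scaffold_1:5412662 0.506
 scaffold_1:4243326 0.247
 scaffold_1:5475875 0.216
 scaffold_1:4685639 0.191
```

All five candidates sit inside the planted 4–6 Mb sweep region. Step 5
evaluates the polygenic score:

```
PGS jackknife CV: 100 reps, mean test R2 = 0.439 (sd 0.212)
full-sample incremental R2 = 0.666
decile index vs per-decile mean arrival: Spearman rho = 0.25
```

Held-out accuracy (0.44) is well below the full-sample fit (0.67) — the
cross-validated number is the honest one — and the extreme deciles separate
cleanly (decile 1 mean arrival 86.6, decile 10 mean 167.4) while the middle
deciles are noisy at n = 87.

Step 6 scans a sweep scaffold simulated at study-like marker density
(12k loci on 8 Mb, 2 Mb phenotype-linked sweep at 3–5 Mb, 13 planted
genes):

```
11 region(s) of elevated delta-FST detected
detected regions jointly span 3.00-5.00 Mb and contain 13 of the 13 planted genes
early-group pi inside/outside: 6.18e-05 / 0.000255
early-group Tajima's D inside/outside: -0.71 / 0.93
```

The ΔF_ST outlier regions tile exactly the planted 2 Mb interval and
recover every planted gene, with nucleotide diversity reduced four-fold and
Tajima's D depressed in the early group inside the region — the full
selective-sweep signature. The script also notes that the exact-HWE filter
would have removed 298 sites, all inside the sweep (a Wahlund effect of the
phenotype split), which is why the scan runs on all biallelic sites.

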
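# homeoCAPS

Tools for studying the fate of duplicated gene copies (**homeologs**)
in recently formed allopolyploid plants, built around the two assays
such studies rely on:

* **CAPS** (cleaved amplified polymorphic sequence) genotyping — a PCR
  amplicon is digested with a restriction enzyme whose cut pattern
  differs between the two parental alleles, and the gel bands reveal
  which parental copies an individual carries (genomic DNA tier) and
  expresses (cDNA tier);
* **cDNA-AFLP** fragment screens — presence/absence fragment profiles
  over the polyploid and its two diploid parents, used to shortlist
  candidate genes.

The scientific problem: in a young allopolyploid such as *Tragopogon
mirus* (formed repeatedly in the last ~80 years from *T. porrifolius* ×
*T. dubius*), each gene exists as a maternal and a paternal homeolog.
Copies can be **lost** from the genome or **silenced** despite being
present, and transcript data alone cannot tell these apart. The package
implements the full two-tier classification workflow:

1. `design_assays()` — in-silico restriction digestion of parental
   allele pairs (IUPAC-degenerate sites, duplex scanning) under an
   explicit gel model (detection limit, co-migration tolerance),
   selecting enzymes whose band patterns distinguish the parents;
2. `call_genotype()` / `genotype_study()` — per individual × locus
   genomic calls: `additive`, `loss_maternal`, `loss_paternal`,
   `ambiguous_polymorphism` (within-parent polymorphism excludes a
   locus), or `unscorable`; `confirm_loss()` replays the
   sequencing-based check that separates true loss from
   restriction-site polymorphism;
3. `call_expression()` / `expression_study()` — cDNA-tier calls that
   only report **silencing** when the genomic tier shows the homeolog
   is still present (`silenced_*` vs `absent_due_to_genomic_loss`);
4. `classify_fragment()` / `summarize_matrix()` — cDNA-AFLP scoring
   into monomorphic / polymorphic (novel, maternal-origin,
   paternal-origin, other) with survey-table percentages;
5. `tally_gene_status()`, `tally_by_parent()`, `tally_silencing()`,
   `per_population_breakdown()` — study-level statistics over
   homeolog denominators (2 × informative genes);
6. `simulate_cohort()` and friends — a ground-truthed synthetic study
   generator (parent-biased loss, conditional silencing, within-parent
   polymorphism, F1 hybrids, band dropout/jitter noise) for end-to-end
   validation.

See the methods vignette
(`vignettes/homeolog-fate-methods.Rmd`) for the model, parameter
defaults and design rationale.

## Worked example

A 200-bp locus where a single substitution destroys the paternal EcoRI
site — the textbook CAPS situation:

```r
library(homeoCAPS)

maternal <- paste0(strrep("A", 79), "GAATTC", strrep("A", 115))
paternal <- paste0(strrep("A", 79), "AAATTC", strrep("A", 115))
assay <- design_assays("TRX1", maternal, paternal)[[1]]
assay
#> CAPS assay: locus TRX1 | enzyme EcoRI (GAATTC/1) [informative]
#>   maternal bands: 120, 80
#>   paternal bands: 200
#>   diagnostic (maternal): 120, 80
#>   diagnostic (paternal): 200
```

The maternal allele digests into 120 + 80 bp fragments; the paternal
allele stays uncut at 200 bp. All three bands are parent-diagnostic, so
a polyploid lane is directly interpretable:

```r
call_genotype(c(200, 120, 80), assay)$call  # full additive pattern
#> [1] "additive"
call_genotype(c(120, 80), assay)$call       # paternal band missing
#> [1] "loss_paternal"
call_expression("additive", c(120, 80), assay)
#> [1] "silenced_paternal"
```

The last call is the package's key distinction: the same missing
paternal bands mean *loss* when seen in genomic DNA, but *silencing*
when genomic DNA is additive and only the transcript lacks them.

Study-level tallies use homeolog denominators. For a 30-gene survey
with one locus excluded for parental polymorphism, 7 genes losing the
paternal homeolog and 4 the maternal (two genes losing either copy in
different individuals):

```r
f <- caps_fixture_from_counts(n_genes = 30, paternal_loss_genes = 7,
                              maternal_loss_genes = 4,
                              both_parent_loss_genes = 2,
                              excluded_genes = 1, silenced_genes = 2,
                              cdna_genes = 15)
st <- genotype_study(f$observations, f$assays, f$individuals)
tally_gene_status(st$locus_summaries)
#>  additive_all loss_detected      excluded uninformative
#>            20             9             1             0
tp <- tally_by_parent(st$locus_summaries, st$calls)
tp$paternal$percent_of_homeologs   # 7 of 58 homeologs
#> [1] 12.1
tp$maternal$percent_of_homeologs   # 4 of 58
#> [1] 6.9
```

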
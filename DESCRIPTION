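Package: pbctrace
Title: Tracking Unadapted Donor Genome in Marker-Assisted Pseudo-Backcross Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and haplotype-based analysis of
    marker-assisted pseudo-backcross introgression programs, modelled on
    apple (Malus) resistance breeding. Provides a gamete and cross
    simulator on a genetic map (Haldane model, centimorgan coordinates),
    foreground marker-assisted selection from coupling-phase marker
    panels, shared-haplotype tracing of residual unadapted exotic donor
    genome in descendants (minimum-SNP segment rules with a
    non-admixed-parent filter), Mendelian-error pedigree checks with
    null-allele call adjustment, and breeding-funnel, seed-planning and
    phenotype summaries (one-way ANOVA with compact-letter Tukey groups).
    User-facing results are tidy tibbles; fitted summaries have tidy()
    and glance() methods and ggplot2 plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
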
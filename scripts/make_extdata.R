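#!/usr/bin/env Rscript
# Regenerates inst/extdata/epas1_cline_synthetic.tsv, the synthetic stand-in
# for the deposited 23-locality Epas1 sampling table (the deposited
# spreadsheet is not redistributable here). Conditions: a sigmoid cline
# centered at 1399.5 m a.s.l. with width 400 m, lowland frequency 0.02 and
# highland frequency 0.84 (the study population's highland allele frequency
# is 0.83); 10 transect localities spanning the Great Plains to Rocky
# Mountain gradient plus 13 regional localities whose frequencies carry
# extra logit-normal between-locality scatter (sd 1) representing geographic
# structure off the transect; 266 diploids over 23 sites. Fixed seed 20191.
library(altadapt)

truth <- list(center = 1399.5, width = 400, pmin = 0.02, pmax = 0.84)
set.seed(20191)

transect_elev <- c(360, 650, 900, 1100, 1250, 1400, 1600, 2000, 3000, 4350)
transect_n <- c(14, 12, 12, 10, 12, 14, 12, 10, 12, 16)   # diploids
regional_elev <- c(150, 250, 500, 800, 1200, 1500, 1800, 2100, 2400, 2700,
                   3000, 3300, 3600)
regional_n <- c(8, 10, 10, 10, 12, 12, 10, 12, 12, 10, 12, 10, 14)
stopifnot(sum(c(transect_n, regional_n)) == 266)

tr <- gen_cline_dataset(transect_elev, truth, 2 * transect_n)

p_reg <- cline_frequency(regional_elev, truth)
p_reg <- plogis(qlogis(pmin(pmax(p_reg, 1e-4), 1 - 1e-4)) + rnorm(13, 0, 1))
kr <- rbinom(13, 2 * regional_n, p_reg)

out <- data.frame(
  locality = c(sprintf("transect_%02d", seq_along(transect_elev)),
               sprintf("regional_%02d", seq_along(regional_elev))),
  elevation_m = c(transect_elev, regional_elev),
  allele_H_count = c(tr$k, kr),
  total_alleles = c(2 * transect_n, 2 * regional_n),
  transect = rep(c(TRUE, FALSE), c(10, 13)))

path <- file.path("inst", "extdata", "epas1_cline_synthetic.tsv")
con <- file(path, "w")
writeLines(c(
  "# SYNTHETIC stand-in for the deposited Epas1 sampling-locality table:",
  "# binomial allele counts drawn from a sigmoid cline (center 1399.5 m,",
  "# width 400 m, pmin 0.02, pmax 0.84; regional sites add logit-normal",
  "# scatter, sd 1). Regenerate with scripts/make_extdata.R (seed 20191)."),
  con)
write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)
cat("wrote", path, "\n")
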
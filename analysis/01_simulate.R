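#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study — two cell lines x two conditions
# of ChIP fragments/peaks with planted super-enhancer structure, plus a
# tumor/normal expression cohort with planted prognostic genes — and a
# small gene-set file for the enrichment step.

suppressPackageStartupMessages(library(segain))

cfg <- synthetic_config(seed = 17)
out <- "scratch/simdata"
paths <- write_simulation(cfg, out)

truth <- planted_truth(cfg)
cat("Synthetic study written to", out, "\n")
cat(sprintf("  genome: %s\n",
            paste(sprintf("%s (%.1f Mb)", names(cfg$genome),
                          cfg$genome / 1e6), collapse = ", ")))
cat(sprintf("  planted loci: %d constitutive, %d shared gains, %d private gains/line, 1 boundary control\n",
            sum(truth$role == "base"), sum(truth$is_shared_gain),
            cfg$n_private_gain))
cat(sprintf("  fragments/sample: %d; cohort: %d tumor / %d normal\n",
            cfg$n_fragments, cfg$n_tumor, cfg$n_normal))

# gene sets for the enrichment stage: the planted prognostic genes'
# neighbourhood versus arbitrary decoy sets
genes <- read_gene_table(paths$genes)
planted <- utils::read.table(paths$planted_genes, header = TRUE)$symbol
set.seed(17)
decoys <- split(sample(setdiff(genes$symbol, planted), 60),
                rep(1:3, each = 20))
gmt <- file.path(out, "sets.gmt")
lines <- c(paste(c("planted_neighbourhood", "synthetic", planted,
                   sample(setdiff(genes$symbol, planted), 6)),
                 collapse = "\t"),
           vapply(seq_along(decoys), function(i)
             paste(c(sprintf("decoy_%d", i), "synthetic", decoys[[i]]),
                   collapse = "\t"), character(1)))
writeLines(lines, gmt)
cat("  gene sets:", gmt, "\n")
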
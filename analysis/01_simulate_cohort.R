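#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates every input the downstream analyses consume — a synthetic genome
# with valid gene models, PK/TF gene labels, Pfam-style domain placements,
# fusion breakpoint calls with a controlled in-frame fraction (plus a few
# recurrent in-frame PK/TF pairs planted across samples), an interaction
# network, a rooted pathway hierarchy, dirty clinical records, and
# negative-binomial expression counts with planted fold changes — and writes
# them as the on-disk formats the pipeline reads (GTF/FASTA/TSV/HTSeq).

suppressMessages(library(fusionscope))

seed <- 1L
spec <- cohort_spec(seed = seed)
gen <- write_synthetic_inputs(spec, "results/analysis/inputs")

truth <- gen$cohort$truth
cat(sprintf("cohort: %d genes (%d PK, %d TF), %d samples, %d fusion calls\n",
            nrow(gen$models$genes), sum(gen$models$genes$is_pk),
            sum(gen$models$genes$is_tf), nrow(gen$cohort$samples),
            nrow(gen$cohort$calls)))
cat(sprintf("true in-frame fraction: %.3f (target %.2f)\n",
            mean(truth$effect == "in-frame"), spec$frac_inframe))
cat(sprintf("recurrent pairs planted: %d; planted DE gene sets: %d\n",
            length(unique(truth$pair[truth$recurrent])),
            length(gen$planted)))
cat("inputs written under results/analysis/inputs\n")
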
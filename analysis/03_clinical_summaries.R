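#!/usr/bin/env Rscript
# Stage 3: clinical joins and cohort summaries.
#
# Joins fusions to clinical records on the TCGA-style barcode prefix,
# harmonizes stage strings ("Stage IIA" -> "Stage II"; "Stage 0"/"Stage X"/
# "I/II NOS" ignored) and ICD-O-3 topography codes (C56.9 -> C56), then
# tabulates PK/TF fusions per project and stage and bins breakpoints into
# 5% chromosomal intervals.

suppressMessages(library(fusionscope))

ind <- "results/analysis/inputs"
ann <- read.delim("results/analysis/fusions_all_calls.tsv")
clinical <- read_clinical(file.path(ind, "clinical.tsv"))
models <- read_gene_models(file.path(ind, "genes.gtf"),
                           file.path(ind, "genome.fa"))

per_sample <- ann[!duplicated(paste(ann$fusion_key, ann$sample_barcode)), ]
joined <- join_clinical(per_sample, clinical)
s <- summarize_by_project_stage(joined, clinical)
write.table(s$stage_summary, "results/analysis/stage_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(s$project_summary, "results/analysis/project_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

calls <- read_fusion_calls(file.path(ind, "fusion_calls.tsv"))
lens <- setNames(Biostrings::width(models$genome), names(models$genome))
bins <- bin_breakpoints(c(calls$contig5, calls$contig3),
                        c(calls$pos5, calls$pos3), lens)
write.table(bins, "results/analysis/breakpoint_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

by_stage <- aggregate(n_pk_tf_fusions ~ stage, s$stage_summary, sum)
cat("PK/TF fusion-sample pairs by simplified stage:\n")
print(by_stage)
cat(sprintf("overall PK/TF fusions per staged sample: %.2f\n",
            sum(s$stage_summary$n_pk_tf_fusions) /
              sum(s$stage_summary$n_samples)))
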
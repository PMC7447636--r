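#!/usr/bin/env Rscript
# Stage 5: maximal foreseeable interactors and pathway mapping.
#
# Filters the interaction network to physical, experimentally supported
# edges, builds each protein-producing fusion's interactor set (partner
# neighborhoods minus the partners), computes every pathway node's shortest
# distance to a hierarchy root (unit edge weights), aggregates per-pathway
# interactor loads with per-project normalization, and measures cancer-gene
# census enrichment of the interactor universe.

suppressMessages(library(fusionscope))

ind <- "results/analysis/inputs"
edges <- read_interactions(file.path(ind, "interactions.mitab.tsv"))
dag <- pathway_dag(read_pathway_edges(file.path(ind, "pathway_edges.tsv")),
                   read_pathway_annotations(
                     file.path(ind, "pathway_annotations.tsv")))
census <- read_gene_list(file.path(ind, "census.tsv"))
uni <- read.delim("results/analysis/fusions_unique.tsv")
clinical <- read_clinical(file.path(ind, "clinical.tsv"))

pp <- join_clinical(uni[uni$protein_producing, ], clinical)
sets <- interactor_sets(pp, edges)
dist <- root_distances(dag)
loads <- pathway_loads(sets[pp$fusion_key[pp$category != "other"]], dag, pp)
enr <- census_enrichment(sets, census, fusions = pp)

write.table(data.frame(pathway_id = names(dist), root_distance = dist),
            "results/analysis/pathway_root_distances.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(loads, "results/analysis/pathway_loads.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("physical+experimental edges: %d of %d\n",
            sum(edges$is_physical & edges$is_experimental), nrow(edges)))
cat(sprintf("median interactors per protein-producing fusion: %d\n",
            as.integer(median(lengths(sets)))))
cat(sprintf("census fraction of all interactors: %.3f\n", enr$overall))
print(enr$by_category)
top <- loads[is.na(loads$project), ]
top <- top[order(-top$n_interacting_fusions), ][1:5, ]
cat("top pathways by interacting fusions:\n")
print(top[, c("pathway_id", "n_interacting_fusions", "summed_load")])
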
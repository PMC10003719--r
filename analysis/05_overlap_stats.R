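#!/usr/bin/env Rscript
# Stage 5: statistics — Monte-Carlo significance of AGO-like peak overlap
# with proximal promoters, peak-to-TSS distance profile with a rolling
# average, and hypergeometric enrichment of flipon-hosting promoters among
# matched genes.

library(flipmir)

dir <- "results/synthetic"
genes <- parse_gene_annotation(file.path(dir, "genes.gtf"))
sizes <- read_chrom_sizes(file.path(dir, "chrom_sizes.tsv"))
peaks <- parse_bed(file.path(dir, "ago_peaks.narrowPeak"))
genome <- load_genome(file.path(dir, "genome.fa"))
flipons <- parse_bed(file.path(dir, "flipons.bed"), class_field = 4L)
mirs <- load_mir_table(file.path(dir, "mir_table.tsv"))

promoters <- build_promoters(genes, sizes)
mc <- mc_overlap_test(promoters, peaks, sizes, n_iter = 1000, rng_seed = 101)

anchors <- data.frame(chrom = genes$genes$chrom, pos = genes$genes$tss)
dp <- distance_profile(anchors, peaks, max_dist = 20000, bin = 500)
smooth <- rolling_mean(dp$profile$count, window = 8)

# enrichment: are genes whose promoter hosts a matched flipon enriched among
# genes with any promoter flipon?
matches <- classify_matches(scan_mrs_matches(genome, flipons, mirs), flipons)
matches <- annotate_match_genes(matches, genes, sizes)
hosting <- unique(promoters$gene_id[overlaps_any(promoters, flipons)])
matched_genes <- unique(stats::na.omit(matches$gene_id[matches$site_class != "none"]))
enr <- hypergeom_bh(matched_genes,
                    list(flipon_promoter = hosting,
                         coding = genes$genes$gene_id[genes$genes$biotype == "coding"]),
                    genes$genes$gene_id)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(observed = mc$observed, p_value = mc$p_value,
                       n_iter = mc$n_iter, seed = 101),
            "results/tables/mc_promoter_peaks.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cbind(dp$profile, smoothed = smooth),
            "results/tables/tss_distance_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(enr, "results/tables/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(mc$observed, " of ", nrow(peaks), " AGO-like peaks overlap proximal ",
        "promoters; Monte-Carlo p = ", signif(mc$p_value, 3),
        " (n_iter = ", mc$n_iter, ")")
message("promoter-flipon gene set enrichment among matched genes:")
print(enr)
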
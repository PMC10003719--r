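#!/usr/bin/env Rscript
# Stage 4: TSS-centered 100 bp window profiles, coding vs noncoding flipon
# fractions, and the promoter heptamer census (occurrences versus distinct
# flipons per heptamer).

library(flipmir)

dir <- "results/synthetic"
genome <- load_genome(file.path(dir, "genome.fa"))
flipons <- parse_bed(file.path(dir, "flipons.bed"), class_field = 4L)
genes <- parse_gene_annotation(file.path(dir, "genes.gtf"))
sizes <- read_chrom_sizes(file.path(dir, "chrom_sizes.tsv"))
mirs <- load_mir_table(file.path(dir, "mir_table.tsv"))

matches <- classify_matches(scan_mrs_matches(genome, flipons, mirs), flipons)
promoters <- build_promoters(genes, sizes)
wp <- window_profile(flipons, matches, promoters)
fr_pp <- coding_noncoding_fractions(flipons, genes, sizes, scope = "PP")
fr_body <- coding_noncoding_fractions(flipons, genes, sizes, scope = "gene_body")
cen <- heptamer_census(promoters, genome, flipons)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(wp, "results/tables/window_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rbind(cbind(scope = "PP", fr_pp), cbind(scope = "gene_body", fr_body)),
            "results/tables/fractions.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cen_tab <- data.frame(heptamer = names(cen$pp_counts),
                      pp_count = as.integer(cen$pp_counts))
cen_tab$flipon_count <- as.integer(cen$flipon_counts[cen_tab$heptamer])
cen_tab$flipon_count[is.na(cen_tab$flipon_count)] <- 0L
cen_tab <- cen_tab[order(-cen_tab$pp_count), ]
write.table(cen_tab, "results/tables/heptamer_census.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("flipon fractions (percent of all flipons):")
print(cbind(scope = c("PP", "PP", "gene_body", "gene_body"), rbind(fr_pp, fr_body)))
message("top heptamers by promoter occurrence (multi-copy flipons count once ",
        "in flipon_count):")
print(head(cen_tab, 5))
peaked <- aggregate(flipon_count ~ window, data = wp, FUN = sum)
message("window with most flipons: ", peaked$window[which.max(peaked$flipon_count)],
        " bp relative to TSS")
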
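#!/usr/bin/env Rscript
# Step 2 - the compiled cytogenetic record table.
# Summary statistics over all published chromosome counts of fungus-farming
# ants, formula-vs-count validation, the heterochromatin-richness split at
# n = 15, and the genome-size exceptions.

library(attinakaryo)

dir.create("results", showWarnings = FALSE)
rec <- attina_records()

s <- summarize_records(rec)
print(s)

cat("\nFormula-vs-count validation (compilations mix conventions):\n")
status <- validate_records(rec)
print(table(status))
flagged <- rec[status == "inconsistent", c("taxon", "diploid_number",
                                           "haploid_number", "karyotype")]
cat("records whose formula matches neither 2n nor n:\n")
print(flagged, row.names = FALSE)
write.table(data.frame(taxon = rec$taxon, source = rec$source, status),
            "results/record_validation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nHeterochromatin band richness against the n = 15 split:\n")
cmp <- band_richness_by_threshold(rec)
print(cmp, row.names = FALSE)
cat("High-n karyotypes carry more positive C-band positions on average,\n")
cat("consistent with repetitive-DNA growth accompanying fissions.\n")
write.table(cmp, "results/band_richness_by_n.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nGenome-size exceptions (1C >= 0.50 pg):\n")
ex <- gs_exceptions(rec)
print(ex[, c("taxon", "genome_size_1C", "source")], row.names = FALSE)
write.table(ex[, c("taxon", "diploid_number", "haploid_number",
                   "genome_size_1C", "source")],
            "results/gs_exceptions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

summary_tbl <- data.frame(
  statistic = c("records", "distinct_taxon_karyotype", "morphospecies_records",
                "taxa_with_genome_size", "min_haploid", "max_haploid",
                "mean_gs_pg", "sd_gs_pg"),
  value = c(s$record_count, s$distinct_taxon_karyotype_count,
            s$unidentified_count, s$taxa_with_gs_count, s$min_haploid,
            s$max_haploid, round(s$mean_gs, 4), round(s$sd_gs, 4)))
write.table(summary_tbl, "results/record_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nwritten: results/record_summary.tsv, record_validation.tsv,",
    "band_richness_by_n.tsv, gs_exceptions.tsv\n")
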
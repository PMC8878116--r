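#!/usr/bin/env Rscript
# LEfSe-style differential abundance between provinces: Kruskal-Wallis
# screen at 0.05, bootstrapped LDA effect sizes, significance at
# LDA score > 2. Recovery is checked against the planted truth.

suppressMessages(library(phyllocore))
tab <- read_otu_table("results/synthetic_study/table.tsv")
md <- read_sample_metadata("results/synthetic_study/metadata.tsv")
truth <- jsonlite::read_json("results/synthetic_study/truth.json",
                             simplifyVector = TRUE)
dir.create("results/lefse", showWarnings = FALSE)
grp <- md$group[match(sample_ids(tab), md$sample_id)]

res <- lefse(tab, grp, seed = 1)
write.table(res, "results/lefse/lefse.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- res[res$significant, ]
cat(sprintf("%d taxa significant (KW p < 0.05 and LDA > 2)\n", nrow(sig)))
print(sig[order(-sig$lda_score),
          c("taxon", "kruskal_wallis_p", "lda_score", "enriched_group")],
      row.names = FALSE, digits = 3)

planted <- truth$differential$otu
hit <- res$significant[match(planted, res$taxon)]
correct_group <- res$enriched_group[match(planted, res$taxon)] ==
  truth$differential$group
cat(sprintf("planted 10x taxa recovered: %d/%d (enriched group correct for
%d of the recovered)\n", sum(hit), length(planted),
            sum(correct_group[hit], na.rm = TRUE)))
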
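#!/usr/bin/env Rscript
# Cohort analyses of the prediction population: relationship-group
# assignment from shared male ancestors, close-relative counts against the
# training population (genomic relationship >= 0.45), the power-curve
# regression of reliability on relatives, and the heifer-to-cow efficiency
# re-ranking cross-tab.

library(rfiherd)

ped <- read_pedigree("results/herd/pedigree.tsv")
gtab <- read.table("results/herd/genotypes.txt", header = TRUE, sep = "\t",
                   check.names = FALSE)
geno <- as.matrix(gtab[, -1])
rownames(geno) <- as.character(gtab$animal)
G <- stabilize_G(build_G(qc_genotypes(genotype_matrix(geno))))
gebv <- read.csv("results/gebv.csv", colClasses = c(animal_id = "character"))

train <- gebv$animal_id[gebv$population == "training"]
pred <- gebv$animal_id[gebv$population == "prediction"]
grp <- assign_groups(ped, train, pred)
cat("Relationship groups of the prediction animals:\n")
print(table(grp$groups$group))
if (length(grp$unresolved)) {
  cat(sprintf("%d candidates had incomplete 3-generation male ancestry\n",
              length(grp$unresolved)))
}

n_rel <- count_close_relatives(G[pred, train, drop = FALSE])
rel <- gebv$reliability[match(pred, gebv$animal_id)]
cat(sprintf("Close relatives per candidate: median %d (range %d..%d)\n",
            median(n_rel), min(n_rel), max(n_rel)))
pc <- fit_power_curve(rel, n_rel)
cat(sprintf("Power curve rel = a*(n+1)^b: a = %.3f, b = %.3f (rss %.4f, %d animals)\n",
            pc$a, pc$b, pc$rss, pc$n))

by_grp <- tapply(rel, grp$groups$group[match(pred, grp$groups$animal_id)], mean)
cat("Mean reliability by group:\n")
print(round(by_grp, 3))

rfi_cow <- read.csv("results/rfi_cow.csv", colClasses = c(animal_id = "character"))
rfi_hfr <- read.csv("results/rfi_heifer.csv", colClasses = c(animal_id = "character"))
both <- intersect(rfi_cow$animal_id, rfi_hfr$animal_id)
xt <- rank_cross_tab(rfi_hfr$rfi[match(both, rfi_hfr$animal_id)],
                     rfi_cow$rfi[match(both, rfi_cow$animal_id)])
print(xt)

write.csv(data.frame(animal_id = pred, n_close_relatives = n_rel,
                     reliability = rel,
                     group = grp$groups$group[match(pred, grp$groups$animal_id)]),
          "results/cohorts.csv", row.names = FALSE)
write.csv(as.data.frame(xt$percent), "results/reranking_crosstab.csv",
          row.names = TRUE)
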
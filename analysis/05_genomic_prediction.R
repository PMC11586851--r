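#!/usr/bin/env Rscript
# Two-step genomic prediction of cow RFI: freeze the pedigree-based variance
# components, solve the training mixed model equations on G, indirectly
# predict the non-phenotyped animals and approximate their reliabilities.

library(rfiherd)

ped <- read_pedigree("results/herd/pedigree.tsv")
gtab <- read.table("results/herd/genotypes.txt", header = TRUE, sep = "\t",
                   check.names = FALSE)
geno <- as.matrix(gtab[, -1])
rownames(geno) <- as.character(gtab$animal)
G <- stabilize_G(build_G(qc_genotypes(genotype_matrix(geno))))

rfi_cow <- read.csv("results/rfi_cow.csv", colClasses = c(animal_id = "character"))
vc <- read.csv("results/variance_components.csv")
sa <- vc$value[vc$quantity == "sigma_a2_cow"]
se <- vc$value[vc$quantity == "sigma_e2_cow"]

train <- rfi_cow$animal_id
pred <- setdiff(rownames(G), c(train, as.character(ped$animal[ped$generation == 0])))
gebv <- gblup_predict(rfi_cow$rfi, G, train, pred, sa, se)

rel_t <- mean(gebv$reliability[gebv$population == "training"])
rel_p <- mean(gebv$reliability[gebv$population == "prediction"])
cat(sprintf("Training: %d animals, mean reliability %.1f%%; prediction: %d animals, %.1f%%\n",
            length(train), 100 * rel_t, length(pred), 100 * rel_p))
cat(sprintf("Training reliability exceeds prediction by %.1f%% (absolute)\n",
            100 * (rel_t - rel_p)))
cat(sprintf("GEBV SD: training %.2f kg, prediction %.2f kg\n",
            sd(gebv$gebv[gebv$population == "training"]),
            sd(gebv$gebv[gebv$population == "prediction"])))

write.csv(gebv, "results/gebv.csv", row.names = FALSE)
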
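#!/usr/bin/env Rscript
# Estimate variance components for the derived RFI phenotypes: a univariate
# animal model on the pedigree matrix for cow RFI (heritability with both
# delta-method and asymptotic-sampling SEs), and a bivariate heifer x cow
# model for the genetic correlation between the two life stages.

library(rfiherd)

ped <- read_pedigree("results/herd/pedigree.tsv")
A <- build_A(ped)
rfi_cow <- read.csv("results/rfi_cow.csv", colClasses = c(animal_id = "character"))
rfi_hfr <- read.csv("results/rfi_heifer.csv", colClasses = c(animal_id = "character"))

ids <- rfi_cow$animal_id
fit <- reml_univariate(rfi_cow$rfi, A[ids, ids])
se_h2 <- h2_se_sampling(fit, seed = 1)
cat(sprintf("Cow RFI: sigma_a2 = %.3f, sigma_e2 = %.3f, h2 = %.3f (delta SE %.3f, sampling SE %.3f)\n",
            fit$sigma_a2, fit$sigma_e2, fit$h2, fit$h2_se, se_h2$se))

both <- intersect(ids, rfi_hfr$animal_id)
Y <- cbind(rfi_heifer = rfi_hfr$rfi[match(both, rfi_hfr$animal_id)],
           rfi_cow = rfi_cow$rfi[match(both, rfi_cow$animal_id)])
bfit <- reml_bivariate(Y, A[both, both])
se_rg <- rg_se_sampling(bfit, seed = 1)
cat(sprintf("Heifer x cow RFI: rg = %.3f (delta SE %.3f, sampling SE %.3f over %d animals)\n",
            bfit$rg, bfit$rg_se, se_rg$se, length(both)))

out <- data.frame(
  quantity = c("sigma_a2_cow", "sigma_e2_cow", "h2_cow", "h2_se_sampling",
               "rg_heifer_cow", "rg_se_sampling"),
  value = c(fit$sigma_a2, fit$sigma_e2, fit$h2, se_h2$se, bfit$rg, se_rg$se))
write.csv(out, "results/variance_components.csv", row.names = FALSE)
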
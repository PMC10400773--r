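#!/usr/bin/env Rscript
# Phantom validation of the tensor-fit -> ROI-extraction -> ALPS chain.
#
# Generates noise-free and noisy DWI phantoms whose periventricular tensor
# geometry is known exactly, runs the full pipeline on them, and checks the
# recovered ALPS index against the closed-form value
#   ALPS = (d_perp + g (d_axial - d_perp)) / d_perp.
# Writes results/phantom_alps.csv.

library(dtialps)

dir.create("results", showWarnings = FALSE)
gtab <- default_gradient_table(n_dir = 32, b = 1000)

rows <- list()
for (g in c(0, 0.25, 0.5, 0.75, 1)) {
  for (sigma in c(0, 20)) {                   # noise-free and SNR 50
    spec <- phantom_spec(g = g, noise_sigma = sigma, seed = 1000 + g * 100)
    ph <- generate_phantom_dwi(spec, gtab)
    r <- alps_from_dwi(ph$dwi, gtab, ph$rois,
                       subject_id = sprintf("g%.2f_sigma%g", g, sigma))
    analytic <- (spec$d_perp + g * (spec$d_axial - spec$d_perp)) / spec$d_perp
    rows[[length(rows) + 1]] <- cbind(g = g, noise_sigma = sigma,
                                      analytic_alps = analytic, r)
  }
}
out <- do.call(rbind, rows)
write.csv(out, "results/phantom_alps.csv", row.names = FALSE)

nf <- out[out$noise_sigma == 0, ]
cat(sprintf("noise-free phantoms: max |pipeline - analytic| ALPS = %.2e\n",
            max(abs(nf$Bi_ALPS - nf$analytic_alps))))
cat(sprintf("ALPS is monotone in g (noise-free): %s\n",
            all(diff(nf$Bi_ALPS) > 0)))
ny <- out[out$noise_sigma == 20, ]
cat(sprintf("at SNR 50 the ALPS error stays below %.3f\n",
            max(abs(ny$Bi_ALPS - ny$analytic_alps))))
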
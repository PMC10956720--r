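library(corrscale)
for (seed in c(1, 3, 4, 5, 6)) {
  t0 <- Sys.time()
  fam <- lattice_box_family(P=0.066, S=128, obs_side=48,
                            L_values=c(14,16,18,20,24,28,32,40,48), steps=5e5,
                            n_seeds=12, seed=seed, stride=4)
  g <- gamma_estimate(fam)
  cat(sprintf("seed=%d gamma=%.3f t=%.0fs\n", seed, g$gamma,
      as.numeric(Sys.time()-t0,units="secs")))
}
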
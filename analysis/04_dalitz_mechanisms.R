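#!/usr/bin/env Rscript
# Three-body breakup mechanisms: Newton-frame and Dalitz observables of the
# triple coincidence channel H+ + H2O+ + C2H3+, split at 20 a.u. proton
# momentum, plus simulated Dalitz distributions of the three sequential
# breakup pathways (C2H3+ first / H2O+ first / H+ first).

library(ceimig)

out_dir <- "results/dalitz"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 1

gated <- read.csv("results/gating/events_gated.csv")
triples <- events_from_table(gated[gated$channel == "TRIPLE", ])
cat("triple coincidence events:", length(triples), "\n")

if (length(triples) > 0) {
  split_ev <- split_by_proton_momentum(triples, p_split_au = 20)
  cat("proton momentum split at 20 a.u.: low", length(split_ev$low),
      " high", length(split_ev$high), "\n")
  obs <- do.call(rbind, lapply(triples, function(ev) {
    nt <- newton_transform(ev)
    dd <- dalitz_from_event(ev)
    p_h <- nt$p[nt$species == "H+"]
    data.frame(delay_fs = ev$delay_fs, ker_eV = ker(ev),
               p_h_au = p_h, region = if (p_h < 20) "low" else "high",
               x_d = dd$x_d, y_d = dd$y_d,
               h2o_p_par = nt$p_parallel[2], h2o_p_perp = nt$p_perp[2],
               h_p_par = nt$p_parallel[3], h_p_perp = nt$p_perp[3])
  }))
  write.csv(obs, file.path(out_dir, "triple_observables.csv"),
            row.names = FALSE)
}

# sequential-process Dalitz simulation, all processes contributing equally
sim <- do.call(rbind, lapply(names(process_defs()), function(pr) {
  evs <- simulate_process_ensemble(pr, 500, seed = seed)
  dd <- do.call(rbind, lapply(evs, dalitz_from_event))
  data.frame(process = pr, x_d = dd$x_d, y_d = dd$y_d,
             ker_eV = vapply(evs, function(e) attr(e, "ker_eV"), 0))
}))
write.csv(sim, file.path(out_dir, "sequential_dalitz.csv"), row.names = FALSE)
agg <- aggregate(cbind(y_d, ker_eV) ~ process, sim, mean)
print(agg)
cat("deprotonation-first (seq_iii) occupies the upper Dalitz region:",
    agg$y_d[agg$process == "seq_iii"] > max(agg$y_d[agg$process != "seq_iii"]),
    "\n")
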
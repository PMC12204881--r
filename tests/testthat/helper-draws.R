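# Construct a deterministic one-row (or n-row) draws data.frame for
# trajectory tests. Defaults are chosen so that no optional event fires:
# implant never fails (LTS 400), no revision (TTR 200), upgrades every
# 7 years (TTUb 0.7), no further surgeries (DSH 50), long pre-implant draw.
make_draws <- function(n = 1, AFIa = 54, AFIb = 54, AFIc = 54,
                       ISB = 14409, REV = 4000,
                       LTS = c(400, 400, 400), TTR = c(200, 200, 200, 200),
                       TTUb = 0.7, THIt = 3,
                       DSH = rep(50, 15), HIS = rep(4000, 15)) {
  d <- data.frame(run = seq_len(n), AFIa = AFIa, AFIb = AFIb, AFIc = AFIc,
                  ISB = ISB, REV = REV)
  for (i in 1:3) d[[paste0("LTS", i)]] <- LTS[i]
  for (i in 1:4) d[[paste0("TTR", i)]] <- TTR[i]
  d$TTUb <- TTUb
  d$THIt <- THIt
  for (i in 1:15) d[[paste0("DSH", i)]] <- DSH[i]
  for (i in 1:15) d[[paste0("HIS", i)]] <- HIS[i]
  d
}
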